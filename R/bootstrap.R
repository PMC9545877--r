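#' Nonparametric bootstrap of edge weights
#'
#' Resamples respondents with replacement `B` times, re-runs the full network
#' estimation (path + refits + stepwise search by default) on each resample,
#' and summarises per-edge 2.5%/97.5% quantile confidence intervals plus
#' pairwise edge-difference tests: two edges are flagged different when the
#' bootstrap 95% CI of their weight difference excludes zero.
#'
#' @param data a `response_table`.
#' @param B bootstrap replicates (>= 50).
#' @param seed root seed; replicate r uses a deterministic child stream.
#' @param method correlation type for estimation.
#' @param fast if `TRUE`, replicates skip the stepwise search (BIC-best path
#'   refit only) -- an approximation suitable for CI sanity checks.
#' @param diff_pairs which edge pairs get difference tests: `"nonzero"`
#'   (default, pairs of edges present in the full-sample network) or
#'   `"none"`.
#' @param max_failure_rate error out when more than this fraction of
#'   replicates fails to refit.
#' @param ... passed to [estimate_network()].
#' @return An object of class `stability_report` with elements `network`
#'   (full-sample fit), `edge_ci` (data frame), `edge_diff` (data frame or
#'   `NULL`), `draws` (B x p(p-1)/2 matrix of bootstrap weights),
#'   `n_failures`.
#' @export
bootstrap_edges <- function(data, B = 1000, seed = 1L, method = "pearson",
                            fast = FALSE, diff_pairs = c("nonzero", "none"),
                            max_failure_rate = 0.1, ...) {
  stopifnot(inherits(data, "response_table"), B >= 50)
  diff_pairs <- match.arg(diff_pairs)
  net <- estimate_network(data, method = method, stepwise = !fast, ...)
  p <- nrow(net$weights)
  ut <- upper.tri(net$weights)
  ids <- net$items$item_id
  pair_idx <- which(ut, arr.ind = TRUE)
  pair_names <- paste0(ids[pair_idx[, 1]], "--", ids[pair_idx[, 2]])
  draws <- matrix(NA_real_, B, sum(ut),
                  dimnames = list(NULL, pair_names))
  failures <- 0L
  for (r in seq_len(B)) {
    idx <- with_seed(child_seed(seed, paste0("edge-boot-", r)),
                     sample.int(data$n, data$n, replace = TRUE))
    rep_data <- response_table(data$responses[idx, , drop = FALSE],
                               data$items)
    wb <- tryCatch({
      nb <- estimate_network(rep_data, method = method, stepwise = !fast, ...)
      nb$weights[ut]
    }, error = function(e) NULL)
    if (is.null(wb)) failures <- failures + 1L else draws[r, ] <- wb
  }
  if (failures > max_failure_rate * B)
    stop(failures, " of ", B, " bootstrap replicates failed to refit",
         call. = FALSE)
  ok <- stats::complete.cases(draws)
  est <- net$weights[ut]
  qs <- apply(draws[ok, , drop = FALSE], 2, stats::quantile,
              probs = c(0.025, 0.975))
  edge_ci <- data.frame(
    edge = pair_names,
    from = ids[pair_idx[, 1]], to = ids[pair_idx[, 2]],
    estimate = est, ci_lower = qs[1, ], ci_upper = qs[2, ],
    row.names = NULL)
  edge_diff <- NULL
  if (diff_pairs == "nonzero") {
    nzi <- which(est != 0)
    if (length(nzi) >= 2) {
      cmb <- utils::combn(nzi, 2)
      d <- draws[ok, cmb[1, ], drop = FALSE] -
        draws[ok, cmb[2, ], drop = FALSE]
      dl <- apply(d, 2, stats::quantile, probs = 0.025)
      du <- apply(d, 2, stats::quantile, probs = 0.975)
      edge_diff <- data.frame(
        edge1 = pair_names[cmb[1, ]], edge2 = pair_names[cmb[2, ]],
        ci_lower = dl, ci_upper = du,
        significant = dl > 0 | du < 0, row.names = NULL)
    }
  }
  structure(list(network = net, edge_ci = edge_ci, edge_diff = edge_diff,
                 draws = draws, n_failures = failures, B = B, seed = seed,
                 fast = fast),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat("<stability_report>")
  if (!is.null(x$edge_ci))
    cat(" edge bootstrap: B = ", x$B, " (", x$n_failures, " failures)",
        sep = "")
  if (!is.null(x$cs_coefficients)) {
    cat(" CS coefficients:",
        paste(names(x$cs_coefficients), round(x$cs_coefficients, 2),
              sep = " = ", collapse = ", "))
  }
  cat("\n")
  invisible(x)
}

# centrality vector for a named index
centrality_by_index <- function(net, index) {
  switch(index,
         expected_influence = expected_influence(net),
         closeness = closeness(net),
         betweenness = betweenness(net),
         stop("unknown centrality index: ", index, call. = FALSE))
}

#' Case-dropping subset bootstrap for centrality stability
#'
#' Re-estimates the network on progressively smaller subsamples (drawn
#' without replacement) and correlates each subsample's centrality values
#' with the full-sample values. The correlation-stability (CS) coefficient of
#' an index is the largest drop proportion at which at least `cs_prob` of the
#' subsamples correlate at least `cs_cor` with the original centrality.
#'
#' @param data a `response_table`.
#' @param indices centrality indices to track.
#' @param drop_grid drop proportions within (0, 0.75].
#' @param B subsamples per drop level.
#' @param seed root seed.
#' @param method correlation type for estimation.
#' @param cs_cor,cs_prob CS rule constants (defaults 0.7 and 0.95).
#' @param fast if `TRUE`, skip the stepwise search in each re-estimation.
#' @param ... passed to [estimate_network()].
#' @return A `stability_report` with `cs_curve` (mean correlation per level
#'   and index), `cs_coefficients` (named vector), `cs_draws` (array of
#'   per-subsample correlations, level x B x index) for exact recomputation,
#'   and `full_centrality`.
#' @export
case_dropping <- function(data,
                          indices = c("expected_influence", "closeness",
                                      "betweenness"),
                          drop_grid = seq(0.05, 0.75, by = 0.05),
                          B = 1000, seed = 1L, method = "pearson",
                          cs_cor = 0.7, cs_prob = 0.95, fast = FALSE, ...) {
  stopifnot(inherits(data, "response_table"),
            all(drop_grid > 0), all(drop_grid <= 0.75))
  drop_grid <- sort(drop_grid)
  net0 <- estimate_network(data, method = method, stepwise = !fast, ...)
  cent0 <- lapply(indices, function(ix) centrality_by_index(net0, ix))
  names(cent0) <- indices
  draws <- array(NA_real_,
                 dim = c(length(drop_grid), B, length(indices)),
                 dimnames = list(paste0("drop", drop_grid), NULL, indices))
  failures <- 0L
  for (li in seq_along(drop_grid)) {
    m <- max(round((1 - drop_grid[li]) * data$n), nrow(data$items) + 2)
    for (b in seq_len(B)) {
      idx <- with_seed(
        child_seed(seed, paste0("case-drop-", drop_grid[li], "-", b)),
        sample.int(data$n, m, replace = FALSE))
      res <- tryCatch({
        nb <- estimate_network(response_table(
          data$responses[idx, , drop = FALSE], data$items),
          method = method, stepwise = !fast, ...)
        vapply(indices, function(ix) {
          cb <- centrality_by_index(nb, ix)
          suppressWarnings(stats::cor(cent0[[ix]], cb))
        }, 0)
      }, error = function(e) NULL)
      if (is.null(res)) failures <- failures + 1L else draws[li, b, ] <- res
    }
  }
  curves <- data.frame(drop = drop_grid)
  for (ix in indices)
    curves[[ix]] <- apply(draws[, , ix, drop = FALSE], 1, mean, na.rm = TRUE)
  cs <- vapply(indices, function(ix)
    cs_coefficient(draws[, , ix, drop = FALSE][, , 1, drop = TRUE],
                   drop_grid, cs_cor, cs_prob), 0)
  names(cs) <- indices
  structure(list(network = net0, full_centrality = cent0,
                 cs_curve = curves, cs_coefficients = cs,
                 cs_draws = draws, drop_grid = drop_grid,
                 cs_cor = cs_cor, cs_prob = cs_prob,
                 n_failures = failures, B = B, seed = seed, fast = fast),
            class = "stability_report")
}

#' Correlation-stability coefficient from stored correlation draws
#'
#' @param cors matrix of correlations, rows = drop levels, columns =
#'   subsamples (NA = failed replicate, counted against stability).
#' @param drop_grid drop proportions matching the rows.
#' @param cs_cor,cs_prob rule constants.
#' @return The largest drop proportion at which at least `cs_prob` of the
#'   subsamples correlate at least `cs_cor` with the original centrality;
#'   0 if none qualifies.
#' @export
cs_coefficient <- function(cors, drop_grid, cs_cor = 0.7, cs_prob = 0.95) {
  cors <- matrix(cors, nrow = length(drop_grid))
  ok <- rowMeans(!is.na(cors) & cors >= cs_cor) >= cs_prob
  if (!any(ok)) return(0)
  max(drop_grid[ok])
}
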