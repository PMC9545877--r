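#' Profiled Gaussian log-likelihood of a precision matrix
#'
#' `(n/2) * (log det K - trace(S K))`, dropping additive constants that are
#' identical across models of the same data, so BIC differences between
#' models fitted to the same `S` and `n` are valid. With `S = K = I` the
#' value is `-n p / 2`.
#'
#' @param S p x p sample correlation (or covariance) matrix.
#' @param K p x p positive-definite precision matrix.
#' @param n sample size.
#' @return Scalar log-likelihood.
#' @export
gaussian_loglik <- function(S, K, n) {
  S <- as.matrix(S); K <- as.matrix(K)
  L <- tryCatch(chol(K), error = function(e)
    stop("precision matrix is not positive definite", call. = FALSE))
  0.5 * n * (2 * sum(log(diag(L))) - sum(S * K))
}

# normalize an edge-set argument (m x 2 index matrix, character pairs, or
# logical/0-1 adjacency) to a 0/1 adjacency matrix
as_adjacency <- function(edge_set, p, ids = NULL) {
  if (is.matrix(edge_set) && nrow(edge_set) == p && ncol(edge_set) == p) {
    A <- (edge_set != 0) * 1L
    diag(A) <- 0L
    storage.mode(A) <- "integer"
    return(A)
  }
  A <- matrix(0L, p, p)
  if (length(edge_set)) {
    es <- as.matrix(edge_set)
    if (is.character(es)) {
      stopifnot(!is.null(ids))
      es <- matrix(match(es, ids), ncol = 2)
    }
    stopifnot(ncol(es) == 2, all(es >= 1), all(es <= p))
    for (r in seq_len(nrow(es))) {
      A[es[r, 1], es[r, 2]] <- 1L
      A[es[r, 2], es[r, 1]] <- 1L
    }
    diag(A) <- 0L
  }
  A
}

edge_matrix_from_adj <- function(A, ids = NULL) {
  idx <- which(upper.tri(A) & A != 0, arr.ind = TRUE)
  colnames(idx) <- c("i", "j")
  if (!is.null(ids)) {
    data.frame(i = idx[, 1], j = idx[, 2],
               from = ids[idx[, 1]], to = ids[idx[, 2]])
  } else {
    as.data.frame(idx)
  }
}

weights_from_precision <- function(K) {
  d <- sqrt(diag(K))
  W <- -K / outer(d, d)
  diag(W) <- 0
  W
}

new_ggm_fit <- function(cpp, S, n, ids) {
  K <- cpp$K
  dimnames(K) <- list(ids, ids)
  W <- weights_from_precision(K)
  structure(list(
    edge_set = edge_matrix_from_adj(cpp$adj %||% (1 * (K != 0)), ids),
    adjacency = 1 * (abs(W) > 0),
    precision = K,
    weights = W,
    loglik = cpp$loglik,
    bic = cpp$bic,
    n_edges = as.integer(cpp$edges),
    n = n,
    S = S), class = "ggm_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.ggm_fit <- function(x, ...) {
  cat("<ggm_fit> ", nrow(x$precision), " nodes, ", x$n_edges, " edges, ",
      "logLik = ", format(x$loglik), ", BIC = ", format(x$bic), "\n", sep = "")
  invisible(x)
}

#' Constrained Gaussian graphical model MLE on a fixed edge set
#'
#' Maximizes the Gaussian likelihood subject to zeros in the precision matrix
#' off the given edge set, by cyclic regression updates on the working
#' covariance. At convergence the implied covariance matches `S` on every
#' edge and on the diagonal, and `K_ij = 0` exactly for non-edges.
#'
#' @param S sample correlation matrix.
#' @param edge_set m x 2 index matrix, character id pairs, or adjacency
#'   matrix.
#' @param n sample size (enters the log-likelihood and BIC).
#' @param tol convergence tolerance on the maximum absolute change of the
#'   implied covariance.
#' @param maxit iteration budget; non-convergence is an error reporting the
#'   residual.
#' @param W_init optional warm-start working covariance.
#' @return A `ggm_fit`: edge set, precision matrix `K`, partial-correlation
#'   `weights` (`-K_ij / sqrt(K_ii K_jj)`), `loglik` and `bic`
#'   (`-2 loglik + edges * log(n)`).
#' @export
constrained_mle <- function(S, edge_set, n, tol = 1e-8, maxit = 2000,
                            W_init = NULL) {
  S <- as.matrix(S)
  p <- nrow(S)
  ids <- rownames(S) %||% paste0("V", seq_len(p))
  A <- as_adjacency(edge_set, p, ids)
  cpp <- cpp_ggm_mle(S, A, n, tol, maxit, W_init)
  if (!cpp$converged)
    stop("constrained MLE did not converge within ", maxit,
         " iterations (residual ", format(cpp$resid), ")", call. = FALSE)
  cpp$adj <- A
  new_ggm_fit(cpp, S, n, ids)
}

#' Graphical lasso regularization path
#'
#' Solves the graphical lasso at `n_lambda` logarithmically spaced penalties
#' between `lambda_max` (the smallest penalty giving the empty graph, i.e.
#' `max |S_ij|` off-diagonal) and `lambda_max * lambda_min_ratio`, and
#' returns the distinct supports (candidate edge sets) along the path.
#'
#' @param S sample correlation matrix (positive semi-definite).
#' @param n_lambda number of penalties (>= 1).
#' @param lambda_min_ratio lower end of the grid as a fraction of
#'   `lambda_max`.
#' @param lambdas optional explicit penalty vector overriding the grid.
#' @param tol coordinate-descent convergence tolerance (scaled by the mean
#'   absolute off-diagonal of `S`).
#' @param maxit outer-loop iteration budget per penalty.
#' @return A list with `lambdas`, `supports` (one 0/1 adjacency per penalty),
#'   `edge_sets` (distinct supports in path order) and `path_edges` (edge
#'   count per penalty).
#' @export
glasso_path <- function(S, n_lambda = 100, lambda_min_ratio = 0.01,
                        lambdas = NULL, tol = 1e-7, maxit = 200) {
  S <- as.matrix(S)
  stopifnot(n_lambda >= 1)
  if (is.null(lambdas)) {
    lmax <- max(abs(S[upper.tri(S)]))
    if (lmax <= 0) lmax <- 1e-4
    lambdas <- if (n_lambda == 1) lmax else
      exp(seq(log(lmax), log(lmax * lambda_min_ratio), length.out = n_lambda))
  }
  lambdas <- sort(lambdas, decreasing = TRUE)
  sup <- cpp_glasso_path(S, lambdas, tol, maxit)
  keys <- vapply(sup, function(A) paste(A[upper.tri(A)], collapse = ""), "")
  distinct <- !duplicated(keys)
  list(lambdas = lambdas,
       supports = sup,
       edge_sets = sup[distinct],
       path_edges = vapply(sup, function(A) sum(A[upper.tri(A)] != 0), 0L))
}

#' Greedy stepwise BIC search over edge sets
#'
#' From a starting edge set, repeatedly evaluates the BIC of every
#' single-edge addition and removal (each via a warm-started constrained
#' MLE), applies the single best strictly improving change, and stops at a
#' local BIC optimum. Ties within `1e-10` prefer removal over addition, then
#' the lexicographically smallest pair.
#'
#' @param S sample correlation matrix.
#' @param n sample size.
#' @param start starting edge set (adjacency, index pairs, or a `ggm_fit`).
#' @param tol,maxit constrained-MLE settings per candidate evaluation.
#' @param max_moves move cap guarding against floating-point cycling;
#'   exceeding it is an error.
#' @param screen_tol looser convergence tolerance used only while screening
#'   candidate moves; every applied move and the final model are refitted at
#'   `tol`.
#' @return The final `ggm_fit`, with the move log in attribute `"moves"`.
#' @export
stepwise_bic_search <- function(S, n, start, tol = 1e-8, maxit = 1000,
                                max_moves = NULL, screen_tol = 1e-3) {
  S <- as.matrix(S)
  p <- nrow(S)
  ids <- rownames(S) %||% paste0("V", seq_len(p))
  if (inherits(start, "ggm_fit")) start <- start$adjacency
  A0 <- as_adjacency(start, p, ids)
  if (is.null(max_moves)) max_moves <- 10 * p * (p - 1) / 2
  cpp <- cpp_stepwise(S, n, A0, tol, maxit, max_moves, 1e-10, screen_tol)
  if (isTRUE(cpp$hit_cap))
    stop("stepwise search exceeded the move cap (", max_moves, " moves)",
         call. = FALSE)
  fit <- new_ggm_fit(cpp, S, n, ids)
  attr(fit, "moves") <- as.data.frame(cpp$moves)
  fit
}

# shared core: correlation matrix -> selected ggm_fit (path + BIC + stepwise)
fit_ggm_from_S <- function(S, n, n_lambda = 100, lambda_min_ratio = 0.01,
                           stepwise = TRUE, glasso_tol = 1e-7,
                           mle_tol = 1e-8, maxit = 1000) {
  path <- glasso_path(S, n_lambda, lambda_min_ratio, tol = glasso_tol)
  p <- nrow(S)
  ids <- rownames(S) %||% paste0("V", seq_len(p))
  best <- NULL
  path_bics <- numeric(length(path$edge_sets))
  for (k in seq_along(path$edge_sets)) {
    A <- path$edge_sets[[k]]
    storage.mode(A) <- "integer"
    cpp <- cpp_ggm_mle(S, A, n, mle_tol, maxit, NULL)
    path_bics[k] <- cpp$bic
    if (is.finite(cpp$bic) && (is.null(best) || cpp$bic < best$bic)) {
      cpp$adj <- A
      best <- cpp
    }
  }
  if (is.null(best))
    stop("no path model could be refitted", call. = FALSE)
  if (stepwise) {
    fit <- stepwise_bic_search(S, n, best$adj, tol = mle_tol, maxit = maxit)
  } else {
    fit <- new_ggm_fit(best, S, n, ids)
    attr(fit, "moves") <- data.frame()
  }
  attr(fit, "report") <- list(
    lambdas = path$lambdas, path_edges = path$path_edges,
    n_candidates = length(path$edge_sets), path_bics = path_bics,
    start_bic = best$bic, moves = attr(fit, "moves"))
  fit
}

#' Estimate a symptom network from item responses
#'
#' The full estimation pipeline: item correlation matrix, graphical-lasso
#' regularization path (default 100 penalties), unregularized constrained-MLE
#' refit of every distinct candidate edge set, BIC selection, then greedy
#' stepwise single-edge search to a BIC optimum. The selected model's
#' partial-correlation matrix is returned as a [symptom_network()].
#'
#' @param data a `response_table`.
#' @param method correlation type fed to the model (default `"pearson"`;
#'   `"polychoric"` targets the latent scale of ordinal items).
#' @param n_lambda,lambda_min_ratio path grid controls.
#' @param stepwise set `FALSE` to stop at the BIC-best path refit
#'   (approximate fast mode).
#' @param ... passed to the internal fitter (tolerances).
#' @return A `symptom_network`; the `ggm_fit` is in attribute `"fit"` and a
#'   fit report (penalty grid, path edge counts, BIC trajectory, move log)
#'   in attribute `"report"`.
#' @export
estimate_network <- function(data, method = "pearson", n_lambda = 100,
                             lambda_min_ratio = 0.01, stepwise = TRUE, ...) {
  stopifnot(inherits(data, "response_table"))
  S <- correlation_matrix(data, method)
  fit <- fit_ggm_from_S(unclass(S), data$n, n_lambda, lambda_min_ratio,
                        stepwise, ...)
  net <- symptom_network(fit$weights, data$items)
  attr(net, "fit") <- fit
  attr(net, "report") <- attr(fit, "report")
  net
}

#' Serialize a fit report to JSON
#'
#' @param net a network from [estimate_network()].
#' @param path output path.
#' @export
write_fit_report <- function(net, path) {
  rep <- attr(net, "report")
  if (is.null(rep)) stop("network carries no fit report", call. = FALSE)
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}
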