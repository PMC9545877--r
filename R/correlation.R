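#' Pairwise correlation matrix of a response table
#'
#' Computes the item correlation matrix feeding the Gaussian graphical model.
#' `pearson` (default) and `spearman` use [stats::cor()]; `polychoric`
#' estimates each pair's latent correlation by two-step maximum likelihood on
#' the contingency table (marginal thresholds from the empirical margins,
#' then a 1-D likelihood optimization under the bivariate-normal model).
#' A non-positive-semi-definite polychoric matrix is repaired to the nearest
#' PSD correlation matrix (eigenvalue clipping) with a warning.
#'
#' @param data a `response_table`.
#' @param method one of `"pearson"`, `"spearman"`, `"polychoric"`.
#' @return A p x p correlation matrix with attributes `method`, `n` and
#'   `psd_repaired`.
#' @export
correlation_matrix <- function(data,
                               method = c("pearson", "spearman", "polychoric")) {
  stopifnot(inherits(data, "response_table"))
  method <- match.arg(method)
  X <- data$responses
  if (nrow(X) < 3) stop("need at least 3 respondents", call. = FALSE)
  cst <- apply(X, 2, function(v) length(unique(v)) == 1L)
  if (any(cst))
    stop("constant column(s): ",
         paste(colnames(X)[cst], collapse = ", "), call. = FALSE)
  repaired <- FALSE
  if (method %in% c("pearson", "spearman")) {
    S <- stats::cor(X, method = method)
  } else {
    p <- ncol(X)
    S <- diag(p)
    taus <- lapply(seq_len(p), function(k) {
      lev <- data$items$min_score[k]:data$items$max_score[k]
      cum <- cumsum(tabulate(X[, k] - data$items$min_score[k] + 1L,
                             nbins = length(lev))) / nrow(X)
      stats::qnorm(utils::head(cum, -1))
    })
    for (i in seq_len(p - 1)) {
      for (j in (i + 1):p) {
        S[i, j] <- S[j, i] <- polychoric_pair(
          X[, i], X[, j],
          data$items$min_score[i]:data$items$max_score[i],
          data$items$min_score[j]:data$items$max_score[j],
          taus[[i]], taus[[j]])
      }
    }
    dimnames(S) <- list(colnames(X), colnames(X))
    ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8) {
      warning("polychoric matrix not positive semi-definite; ",
              "nearest-PSD repair applied", call. = FALSE)
      S <- nearest_psd(S)
      repaired <- TRUE
    }
  }
  structure(S, method = method, n = nrow(X), psd_repaired = repaired)
}

# two-step polychoric MLE for one item pair
polychoric_pair <- function(x, y, lev_x, lev_y, tau_x, tau_y) {
  counts <- table(factor(x, levels = lev_x), factor(y, levels = lev_y))
  counts <- matrix(as.numeric(counts), nrow = length(lev_x))
  # drop unobserved boundary categories (infinite thresholds are handled by
  # the CDF, but empty rows/columns carry no information)
  f <- function(rho) cpp_polychoric_negll(counts, tau_x, tau_y, rho)
  stats::optimize(f, interval = c(-0.999, 0.999), tol = 1e-7)$minimum
}

# nearest PSD correlation matrix by eigenvalue clipping
nearest_psd <- function(S, eps = 1e-8) {
  e <- eigen(S, symmetric = TRUE)
  ev <- pmax(e$values, eps)
  out <- e$vectors %*% diag(ev) %*% t(e$vectors)
  out <- stats::cov2cor(out)
  dimnames(out) <- dimnames(S)
  out
}
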