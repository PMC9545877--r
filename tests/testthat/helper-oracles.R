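# Test fixtures built in code, plus naive independent oracles the fast
# implementations are checked against.

# small symptom network from an arbitrary symmetric weights matrix
toy_net <- function(W, constructs = NULL) {
  p <- nrow(W)
  ids <- paste0("V", seq_len(p))
  if (is.null(constructs))
    constructs <- rep(c("depression", "anxiety", "loneliness"), length.out = p)
  items <- item_metadata(ids, constructs, 0L, 3L)
  dimnames(W) <- list(ids, ids)
  symptom_network(W, items)
}

# random sparse signed weights matrix
random_weights <- function(p, density = 0.4, wmax = 0.6) {
  W <- matrix(0, p, p)
  for (i in seq_len(p - 1)) {
    for (j in (i + 1):p) {
      if (stats::runif(1) < density) {
        W[i, j] <- W[j, i] <- stats::runif(1, 0.05, wmax) *
          sample(c(-1, 1), 1)
      }
    }
  }
  W
}

# --- betweenness oracle: exhaustive enumeration of all simple paths ---------
oracle_betweenness <- function(W, tie_tol = 1e-9) {
  p <- nrow(W)
  L <- 1 / abs(W)
  diag(L) <- Inf
  all_paths <- function(s, t) {
    res <- list()
    walk <- function(path, len) {
      last <- path[length(path)]
      if (last == t) {
        res[[length(res) + 1]] <<- list(path = path, len = len)
        return()
      }
      for (v in which(is.finite(L[last, ]))) {
        if (!(v %in% path)) walk(c(path, v), len + L[last, v])
      }
    }
    walk(s, 0)
    res
  }
  bc <- rep(0, p)
  for (s in seq_len(p - 1)) {
    for (t in (s + 1):p) {
      paths <- all_paths(s, t)
      if (!length(paths)) next
      lens <- vapply(paths, `[[`, 0, "len")
      geo <- which(lens <= min(lens) + tie_tol)
      for (g in geo) {
        inner <- setdiff(paths[[g]]$path, c(s, t))
        bc[inner] <- bc[inner] + 1 / length(geo)
      }
    }
  }
  bc
}

# --- clique percolation oracle: brute-force subsets + BFS chaining ----------
oracle_percolate <- function(net, k, I) {
  W <- net$weights
  ids <- net$items$item_id
  p <- nrow(W)
  subsets <- utils::combn(p, k, simplify = FALSE)
  cliques <- Filter(function(s) {
    prs <- utils::combn(s, 2)
    all(W[t(prs)] != 0)
  }, subsets)
  ints <- vapply(cliques, function(s) {
    prs <- utils::combn(s, 2)
    exp(mean(log(abs(W[t(prs)]))))
  }, 0)
  keep <- which(ints >= I)
  cliques <- cliques[keep]
  nc <- length(cliques)
  comms <- list()
  if (nc) {
    visited <- rep(FALSE, nc)
    for (s in seq_len(nc)) {
      if (visited[s]) next
      queue <- s
      visited[s] <- TRUE
      members <- integer(0)
      while (length(queue)) {
        cur <- queue[1]; queue <- queue[-1]
        members <- c(members, cur)
        for (o in seq_len(nc)) {
          if (!visited[o] &&
              length(intersect(cliques[[cur]], cliques[[o]])) == k - 1) {
            visited[o] <- TRUE
            queue <- c(queue, o)
          }
        }
      }
      comms[[length(comms) + 1]] <-
        sort(ids[unique(unlist(cliques[members]))])
    }
  }
  comms[order(-lengths(comms), vapply(comms, paste, "", collapse = "|"))]
}

# --- graphical lasso oracle: direct penalized-likelihood minimization -------
# minimizes tr(S K) - log det K + lam * sum_offdiag |K_ij| over PD K
# (p = 3, Cholesky parametrization, Nelder-Mead restarts)
oracle_glasso_support <- function(S, lam, zero_tol = 1e-4) {
  p <- nrow(S)
  obj <- function(theta) {
    Lm <- matrix(0, p, p)
    Lm[lower.tri(Lm, diag = TRUE)] <- theta
    diag(Lm) <- exp(diag(Lm))
    K <- Lm %*% t(Lm)
    sum(S * K) - 2 * sum(log(diag(Lm))) +
      lam * sum(abs(K[upper.tri(K)])) * 2
  }
  best <- NULL
  for (r in 1:6) {
    th0 <- stats::rnorm(p * (p + 1) / 2, 0, 0.3)
    fit <- stats::optim(th0, obj, method = "Nelder-Mead",
                        control = list(maxit = 5000, reltol = 1e-14))
    fit <- stats::optim(fit$par, obj, method = "Nelder-Mead",
                        control = list(maxit = 5000, reltol = 1e-14))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  Lm <- matrix(0, p, p)
  Lm[lower.tri(Lm, diag = TRUE)] <- best$par
  diag(Lm) <- exp(diag(Lm))
  K <- Lm %*% t(Lm)
  abs(K) > zero_tol & upper.tri(K)
}

# --- exhaustive BIC enumeration over all edge sets (tiny p) -----------------
oracle_all_bics <- function(S, n) {
  p <- nrow(S)
  pairs <- utils::combn(p, 2)
  m <- ncol(pairs)
  vapply(seq_len(2^m) - 1, function(code) {
    sel <- which(bitwAnd(code, 2^(seq_len(m) - 1)) > 0)
    es <- t(pairs[, sel, drop = FALSE])
    fit <- tryCatch(constrained_mle(S, es, n), error = function(e) NULL)
    if (is.null(fit)) NA_real_ else fit$bic
  }, 0)
}

# ordinal response table with independent uniform items
independent_responses <- function(n, p, seed = 1) {
  ids <- paste0("V", seq_len(p))
  items <- item_metadata(ids, rep("anxiety", p), 0L, 3L)
  X <- with_seed_test(seed, matrix(sample(0:3, n * p, replace = TRUE), n, p,
                                   dimnames = list(NULL, ids)))
  response_table(X, items)
}

with_seed_test <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}
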