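test_that("gaussian_loglik matches its closed forms", {
  p <- 4; n <- 100
  expect_equal(gaussian_loglik(diag(p), diag(p), n), -n * p / 2)

  S <- matrix(c(1, 0.6, 0.6, 1), 2)
  K <- solve(S)
  expect_equal(gaussian_loglik(S, K, n),
               (n / 2) * (-log(det(S)) - 2))
  # MLE dominance: the saturated precision maximizes the likelihood
  with_seed_test(3, {
    for (r in 1:20) {
      A <- matrix(rnorm(4), 2); Kr <- crossprod(A) + diag(2) * 0.1
      expect_lte(gaussian_loglik(S, Kr, n), gaussian_loglik(S, K, n) + 1e-9)
    }
  })
  expect_error(gaussian_loglik(S, matrix(c(1, 2, 2, 1), 2), n),
               "positive definite")
})

test_that("constrained MLE reproduces saturated and independence models", {
  with_seed_test(11, {
    X <- matrix(rnorm(300 * 4), 300, 4) %*%
      chol(matrix(0.4, 4, 4) + diag(0.6, 4))
    S <- cor(X)
  })
  full <- which(upper.tri(S), arr.ind = TRUE)
  fit <- constrained_mle(S, full, n = 300)
  expect_equal(fit$precision, solve(S), tolerance = 1e-6,
               ignore_attr = TRUE)
  d <- sqrt(diag(fit$precision))
  W_exp <- -fit$precision / outer(d, d)
  diag(W_exp) <- 0
  expect_equal(fit$weights, W_exp, tolerance = 1e-8, ignore_attr = TRUE)

  empty <- constrained_mle(S, matrix(0L, 4, 4), n = 300)
  expect_equal(empty$precision, diag(4), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_true(all(empty$weights == 0))
})

test_that("constrained MLE recovers a chain model exactly", {
  K0 <- diag(3)
  K0[1, 2] <- K0[2, 1] <- -0.4
  K0[2, 3] <- K0[3, 2] <- -0.25
  S <- cov2cor(solve(K0))
  fit <- constrained_mle(S, rbind(c(1, 2), c(2, 3)), n = 500)
  # moment conditions: implied covariance matches S on edges + diagonal,
  # and the missing edge factorizes as S12 * S23
  Sigma <- solve(fit$precision)
  expect_equal(Sigma[1, 2], S[1, 2], tolerance = 1e-7)
  expect_equal(Sigma[2, 3], S[2, 3], tolerance = 1e-7)
  expect_equal(diag(Sigma), diag(S), tolerance = 1e-7, ignore_attr = TRUE)
  expect_equal(Sigma[1, 3], S[1, 2] * S[2, 3], tolerance = 1e-7)
  expect_equal(fit$precision[1, 3], 0)
  # exact recovery of the generating chain precision up to scale
  expect_equal(cov2cor(fit$precision), cov2cor(K0), tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("glasso path endpoints are the empty and saturated graphs", {
  with_seed_test(21, {
    X <- matrix(rnorm(500 * 5), 500, 5) %*%
      chol(matrix(0.3, 5, 5) + diag(0.7, 5))
    S <- cor(X)
  })
  lmax <- max(abs(S[upper.tri(S)]))
  path <- glasso_path(S, lambdas = c(lmax * 1.001, 0))
  expect_equal(sum(path$supports[[1]]), 0)
  expect_equal(sum(path$supports[[2]] == 1), 5 * 4)
  expect_equal(path$path_edges, c(0L, 10L))
})

test_that("glasso support matches a direct penalized-likelihood oracle", {
  with_seed_test(31, {
    for (r in 1:4) {
      K0 <- diag(3)
      K0[1, 2] <- K0[2, 1] <- runif(1, 0.2, 0.45)
      S <- cov2cor(solve(K0))
      lam <- runif(1, 0.05, 0.18)
      sup <- glasso_path(S, lambdas = lam)$supports[[1]]
      oracle <- oracle_glasso_support(S, lam)
      expect_identical(sup[upper.tri(sup)] == 1, oracle[upper.tri(oracle)])
    }
  })
})

test_that("stepwise search reaches a single-edge local optimum", {
  with_seed_test(41, {
    X <- matrix(rnorm(400 * 5), 400, 5) %*%
      chol(matrix(0.35, 5, 5) + diag(0.65, 5))
    S <- cor(X)
  })
  n <- 400
  path <- glasso_path(S)
  bics <- vapply(path$edge_sets, function(A)
    constrained_mle(S, A, n)$bic, 0)
  fit <- stepwise_bic_search(S, n, path$edge_sets[[which.min(bics)]])
  # every single-edge neighbour has BIC >= the final model
  A <- fit$adjacency
  for (i in 1:4) for (j in (i + 1):5) {
    A2 <- A; A2[i, j] <- A2[j, i] <- 1 - A2[i, j]
    expect_gte(constrained_mle(S, A2, n)$bic, fit$bic - 1e-6)
  }
  # BIC bookkeeping identity
  expect_equal(fit$bic, -2 * fit$loglik + fit$n_edges * log(n),
               tolerance = 1e-9)
})

test_that("stepwise result ranks in the top tail of exhaustive enumeration", {
  # p = 4: all 64 edge sets refitted by constrained MLE, greedy result must
  # land within the top 5% of BIC values
  with_seed_test(51, {
    for (r in 1:20) {
      K0 <- diag(4)
      K0[1, 2] <- K0[2, 1] <- -0.35
      K0[3, 4] <- K0[4, 3] <- -0.3
      S0 <- cov2cor(solve(K0))
      X <- matrix(rnorm(300 * 4), 300, 4) %*% chol(S0)
      S <- cor(X)
      path <- glasso_path(S)
      bics <- vapply(path$edge_sets, function(A)
        constrained_mle(S, A, 300)$bic, 0)
      fit <- stepwise_bic_search(S, 300, path$edge_sets[[which.min(bics)]])
      all_bics <- oracle_all_bics(S, 300)
      rank_pos <- mean(all_bics <= fit$bic + 1e-9, na.rm = TRUE)
      expect_lte(rank_pos, 0.05)
    }
  })
})

test_that("estimation on independent data returns (near-)empty graphs", {
  # BIC consistency at large n: at most 1 spurious edge in >= 18/20 runs
  hits <- 0L
  for (r in 1:20) {
    d <- independent_responses(5000, 5, seed = 100 + r)
    net <- estimate_network(d)
    if (edge_count(net) <= 1) hits <- hits + 1L
  }
  expect_gte(hits, 18L)
})

test_that("refitting a fit's own edge set is a fixed point", {
  spec <- lad_generator_spec(n = 600, seed = 13)
  d <- generate_responses(spec)
  net <- estimate_network(d)
  fit <- attr(net, "fit")
  refit <- constrained_mle(fit$S, fit$adjacency, fit$n)
  expect_equal(refit$weights, fit$weights, tolerance = 1e-6)
  expect_equal(refit$bic, fit$bic, tolerance = 1e-6)
  # refitted (unregularized) likelihood dominates the penalized path fit on
  # the same support by construction; check against the saturated bound
  sat <- constrained_mle(fit$S, which(upper.tri(fit$S), arr.ind = TRUE),
                         fit$n)
  expect_lte(fit$loglik, sat$loglik + 1e-9)
})

test_that("estimation is equivariant under node permutation", {
  spec <- lad_generator_spec(n = 700, seed = 17)
  d <- generate_responses(spec)
  net1 <- estimate_network(d)
  perm <- with_seed_test(1, sample(19))
  d2 <- response_table(d$responses[, perm], d$items[perm, ])
  net2 <- estimate_network(d2)
  expect_equal(net2$weights,
               net1$weights[perm, perm], tolerance = 1e-6)
})

test_that("correlation matrices validate inputs and methods", {
  d <- independent_responses(200, 4, seed = 3)
  S <- correlation_matrix(d)
  expect_equal(attr(S, "method"), "pearson")
  Xc <- d$responses; Xc[, 1] <- 2L
  expect_error(correlation_matrix(response_table(Xc, d$items)), "constant")
  expect_equal(unclass(correlation_matrix(d, "spearman")),
               cor(d$responses, method = "spearman"), ignore_attr = TRUE)
})

test_that("polychoric correlation recovers latent correlations", {
  # copula consistency: latent rho = 0.5, 2x2 median-split items
  items <- item_metadata(c("A1", "A2"), rep("anxiety", 2), 0, 1)
  R <- matrix(c(1, 0.5, 0.5, 1), 2)
  spec <- generator_spec(items, list(A1 = 0, A2 = 0),
                         latent_correlation = R, n = 30000, seed = 5)
  d <- generate_responses(spec)
  S <- correlation_matrix(d, "polychoric")
  expect_equal(S[1, 2], 0.5, tolerance = 0.05)
  # pearson on the same data is attenuated
  expect_lt(cor(d$responses)[1, 2], S[1, 2])
  # independent ordinal columns: polychoric near zero
  d0 <- independent_responses(10000, 3, seed = 6)
  S0 <- correlation_matrix(d0, "polychoric")
  expect_lt(max(abs(S0[upper.tri(S0)])), 0.03)
})

test_that("polychoric pair likelihood agrees with an mvtnorm oracle", {
  tau1 <- c(-0.6, 0.4); tau2 <- c(-0.2, 0.9)
  rho <- 0.37
  cells <- symptomnet:::cpp_ordinal_cells(tau1, tau2, rho)
  b1 <- c(-Inf, tau1, Inf); b2 <- c(-Inf, tau2, Inf)
  for (i in 1:3) for (j in 1:3) {
    ref <- mvtnorm::pmvnorm(lower = c(b1[i], b2[j]),
                            upper = c(b1[i + 1], b2[j + 1]),
                            corr = matrix(c(1, rho, rho, 1), 2))
    expect_equal(cells[i, j], as.numeric(ref), tolerance = 1e-10)
  }
})
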