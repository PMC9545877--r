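test_that("partials_to_correlation matches direct inversion", {
  expect_equal(partials_to_correlation(matrix(0, 4, 4)), diag(4))

  P2 <- matrix(c(0, 0.5, 0.5, 0), 2)
  expect_equal(partials_to_correlation(P2)[1, 2], 0.5)

  # 3-node chain: compare against brute-force inversion of the implied
  # precision matrix
  for (ab in list(c(0.3, 0.5), c(-0.4, 0.2), c(0.6, 0.6))) {
    P <- matrix(0, 3, 3)
    P[1, 2] <- P[2, 1] <- ab[1]
    P[2, 3] <- P[3, 2] <- ab[2]
    K <- diag(3); K[1, 2] <- K[2, 1] <- -ab[1]; K[2, 3] <- K[3, 2] <- -ab[2]
    expect_equal(partials_to_correlation(P), cov2cor(solve(K)))
  }

  Pbad <- matrix(0.9, 3, 3); diag(Pbad) <- 0
  expect_error(partials_to_correlation(Pbad), "eigenvalue")
})

test_that("generation is deterministic in the seed and monotone in latents", {
  spec <- lad_generator_spec(n = 200, seed = 9)
  d1 <- generate_responses(spec)
  d2 <- generate_responses(spec)
  expect_identical(d1$responses, d2$responses)
  d3 <- generate_responses(spec, seed = 10)
  expect_false(identical(d1$responses, d3$responses))

  # discretization is monotone: sorted latent draws give sorted scores
  tau <- spec$thresholds[["PHQ1"]]
  z <- sort(rnorm(500))
  scores <- findInterval(z, tau)
  expect_true(all(diff(scores) >= 0))
})

test_that("degenerate thresholds give constant columns", {
  items <- item_metadata(paste0("A", 1:3), rep("anxiety", 3), 0, 3)
  thr <- list(A1 = c(10, 11, 12), A2 = c(-12, -11, -10), A3 = c(-1, 0, 1))
  spec <- generator_spec(items, thr, latent_correlation = diag(3), n = 100,
                         seed = 1)
  d <- generate_responses(spec)
  expect_true(all(d$responses[, "A1"] == 0L))  # all mass below first cut
  expect_true(all(d$responses[, "A2"] == 3L))  # all mass above last cut
  expect_gt(length(unique(d$responses[, "A3"])), 1L)
})

test_that("identity latent correlation yields uncorrelated items", {
  items <- item_metadata(paste0("A", 1:6), rep("anxiety", 6), 0, 3)
  thr <- setNames(rep(list(c(-0.5, 0.3, 1)), 6), items$item_id)
  spec <- generator_spec(items, thr, latent_correlation = diag(6),
                         n = 20000, seed = 4)
  d <- generate_responses(spec)
  R <- stats::cor(d$responses)
  expect_lt(max(abs(R[upper.tri(R)])), 0.03)
})

test_that("invalid generator specs are rejected", {
  items <- item_metadata(paste0("A", 1:2), rep("anxiety", 2), 0, 3)
  thr <- list(A1 = c(0, 1, 2), A2 = c(0, 1, 2))
  expect_error(generator_spec(items, thr[1], latent_correlation = diag(2)),
               "missing")
  expect_error(generator_spec(items, list(A1 = c(0, 1), A2 = c(0, 1, 2)),
                              latent_correlation = diag(2)),
               "cut-points")
  expect_error(generator_spec(items, list(A1 = c(1, 0, 2), A2 = c(0, 1, 2)),
                              latent_correlation = diag(2)),
               "increasing")
  Rbad <- matrix(c(1, 1.2, 1.2, 1), 2)
  expect_error(generator_spec(items, thr, latent_correlation = Rbad),
               "positive definite")
  expect_warning(generate_responses(
    generator_spec(items, thr, latent_correlation = diag(2), n = 2, seed = 1)),
    "ill-posed")
})

test_that("calibration reproduces the published total-score moments", {
  spec <- lad_generator_spec(n = 1041, seed = 1)
  ach <- spec$calibration$achieved
  expect_true(all(abs(ach$achieved_mean - ach$target_mean) /
                    ach$target_mean < 0.02))
  expect_true(all(abs(ach$achieved_sd - ach$target_sd) /
                    ach$target_sd < 0.10))
  # thresholds shared within construct
  expect_identical(spec$thresholds[["PHQ1"]], spec$thresholds[["PHQ9"]])
  expect_identical(spec$thresholds[["GAD1"]], spec$thresholds[["GAD7"]])
  # cross-construct factors shrink the latent blocks toward the published
  # total-score correlations
  expect_true(all(spec$calibration$factors < 1))
})

test_that("calibration round trips on its own achieved moments", {
  spec <- lad_generator_spec(n = 1041, seed = 1)
  ach <- spec$calibration$achieved
  tgt <- calibration_target(
    means = setNames(ach$achieved_mean, ach$construct),
    sds = setNames(ach$achieved_sd, ach$construct))
  spec2 <- calibrate_thresholds(default_items(), tgt, lad_network()$weights,
                                match_correlations = FALSE)
  for (g in c("Ln1", "PHQ1", "GAD1"))
    expect_equal(spec2$thresholds[[g]], spec$thresholds[[g]], tolerance = 1e-3)
})

test_that("large-sample totals track the calibration targets", {
  spec <- lad_generator_spec(n = 1041, seed = 2)
  d <- generate_responses(spec, n = 50000)
  sc <- compute_scale_scores(d)
  expect_equal(sc$summary$mean[sc$summary$construct == "loneliness"], 4.97,
               tolerance = 0.02)
  expect_equal(sc$summary$sd[sc$summary$construct == "depression"], 6.096,
               tolerance = 0.1)
  expect_equal(sc$correlations["depression", "anxiety"], 0.805,
               tolerance = 0.03)
})
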