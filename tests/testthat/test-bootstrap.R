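# The bootstrap tests run at reduced sizes (small p, fast mode, B just
# above the enforced floor) so the whole suite stays quick; the full-size
# stability analysis lives with the acceptance checks.

make_chain_data <- function(n, seed, p = 5, rho = 0.45) {
  items <- item_metadata(paste0("V", seq_len(p)), rep("anxiety", p), 0L, 3L)
  P <- matrix(0, p, p)
  for (i in seq_len(p - 1)) P[i, i + 1] <- P[i + 1, i] <- rho
  thr <- setNames(rep(list(c(-0.8, 0.2, 1.0)), p), items$item_id)
  spec <- generator_spec(items, thr, latent_partials = P, n = n, seed = seed)
  generate_responses(spec)
}

test_that("edge bootstrap is reproducible and covers the point estimates", {
  d <- make_chain_data(400, seed = 1)
  r1 <- bootstrap_edges(d, B = 60, seed = 5, fast = TRUE)
  r2 <- bootstrap_edges(d, B = 60, seed = 5, fast = TRUE)
  expect_identical(r1$draws, r2$draws)
  expect_identical(r1$edge_ci, r2$edge_ci)
  r3 <- bootstrap_edges(d, B = 60, seed = 6, fast = TRUE)
  expect_false(identical(r1$draws, r3$draws))

  ci <- r1$edge_ci
  nz <- ci[ci$estimate != 0, ]
  covered <- mean(ci$ci_lower <= ci$estimate & ci$estimate <= ci$ci_upper)
  expect_gte(covered, 0.95)
  # chain edges are strong: their CIs exclude zero
  chain <- ci[ci$edge %in% paste0("V", 1:4, "--V", 2:5), ]
  expect_true(all(chain$ci_lower > 0))
})

test_that("independent data give edge CIs that straddle zero", {
  d <- independent_responses(300, 5, seed = 9)
  r <- bootstrap_edges(d, B = 60, seed = 2, fast = TRUE)
  expect_true(all(r$edge_ci$ci_lower <= 0 & r$edge_ci$ci_upper >= 0))
})

test_that("difference tests gain power with sample size", {
  # two planted edges of similar strength: rarely distinguishable at small
  # n, clearly distinguishable at large n
  make_two_edge <- function(n, seed) {
    items <- item_metadata(paste0("V", 1:4), rep("anxiety", 4), 0L, 3L)
    P <- matrix(0, 4, 4)
    P[1, 2] <- P[2, 1] <- 0.55
    P[3, 4] <- P[4, 3] <- 0.15
    thr <- setNames(rep(list(c(-0.8, 0.2, 1.0)), 4), items$item_id)
    generate_responses(generator_spec(items, thr, latent_partials = P,
                                      n = n, seed = seed))
  }
  pick <- function(r) {
    row <- r$edge_diff[(r$edge_diff$edge1 == "V1--V2" &
                          r$edge_diff$edge2 == "V3--V4") |
                         (r$edge_diff$edge1 == "V3--V4" &
                            r$edge_diff$edge2 == "V1--V2"), ]
    row$significant
  }
  r_small <- bootstrap_edges(make_two_edge(150, 3), B = 80, seed = 1,
                             fast = TRUE)
  r_large <- bootstrap_edges(make_two_edge(8000, 3), B = 80, seed = 1,
                             fast = TRUE)
  sig_small <- pick(r_small)
  sig_large <- pick(r_large)
  expect_true(length(sig_large) == 1 && isTRUE(sig_large))
  expect_false(isTRUE(sig_small) && !isTRUE(sig_large))
})

test_that("edge CI width shrinks roughly like 1/sqrt(n)", {
  r250 <- bootstrap_edges(make_chain_data(250, seed = 4, rho = 0.55),
                          B = 100, seed = 8, fast = TRUE)
  r1000 <- bootstrap_edges(make_chain_data(1000, seed = 4, rho = 0.55),
                           B = 100, seed = 8, fast = TRUE)
  # width of the always-selected chain edges only: absent-edge widths are
  # dominated by model-selection noise, not sampling error
  chain <- paste0("V", 1:4, "--V", 2:5)
  w250 <- mean(with(r250$edge_ci, ci_upper - ci_lower)[
    r250$edge_ci$edge %in% chain])
  w1000 <- mean(with(r1000$edge_ci, ci_upper - ci_lower)[
    r1000$edge_ci$edge %in% chain])
  expect_gt(w250 / w1000, 1.6)
  expect_lt(w250 / w1000, 2.4)
})

test_that("CS coefficient follows its defining quantile rule", {
  grid <- seq(0.1, 0.7, by = 0.2)
  # all subsample correlations perfect -> grid maximum
  cors <- matrix(1, length(grid), 50)
  expect_equal(cs_coefficient(cors, grid), 0.7)
  # degrade beyond 0.3: exactly the rule's cutoff
  cors[3, ] <- c(rep(0.9, 47), rep(0.2, 3))   # 94% >= 0.7 -> fails
  cors[4, ] <- 0.2
  expect_equal(cs_coefficient(cors, grid), 0.3)
  # nothing qualifies
  expect_equal(cs_coefficient(matrix(0.1, 2, 10), c(0.1, 0.2)), 0)
  # NA replicates count against stability
  cors_na <- matrix(1, 2, 10)
  cors_na[2, 1:2] <- NA
  expect_equal(cs_coefficient(cors_na, c(0.1, 0.2)), 0.1)
})

test_that("case dropping reports reproducible curves and coefficients", {
  d <- make_chain_data(500, seed = 2)
  cs <- case_dropping(d, drop_grid = c(0.1, 0.3), B = 12, seed = 3,
                      fast = TRUE)
  cs2 <- case_dropping(d, drop_grid = c(0.1, 0.3), B = 12, seed = 3,
                       fast = TRUE)
  expect_identical(cs$cs_draws, cs2$cs_draws)
  # stored draws reproduce the reported coefficient exactly
  for (ix in names(cs$cs_coefficients)) {
    expect_equal(cs_coefficient(cs$cs_draws[, , ix], cs$drop_grid),
                 unname(cs$cs_coefficients[[ix]]))
  }
  expect_equal(names(cs$cs_curve), c("drop", "expected_influence",
                                     "closeness", "betweenness"))
  expect_true(all(cs$cs_coefficients >= 0 & cs$cs_coefficients <= 0.75))
})

test_that("a strongly determined network earns the maximal CS coefficient", {
  # n large relative to a 4-node chain: every subsample reproduces the
  # centrality ordering, so CS hits the grid maximum
  d <- make_chain_data(4000, seed = 6, p = 4, rho = 0.5)
  cs <- case_dropping(d, indices = "expected_influence",
                      drop_grid = c(0.25, 0.5, 0.75), B = 25, seed = 4,
                      fast = TRUE)
  expect_equal(unname(cs$cs_coefficients[["expected_influence"]]), 0.75)
})
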