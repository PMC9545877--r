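test_that("expected influence is the signed incident-weight sum", {
  net <- lad_network()
  ei <- expected_influence(net)
  # hand sum of the printed GAD4 row/column entries
  expect_equal(unname(ei["GAD4"]),
               0.05 + 0.16 + 0.13 - 0.11 + 0.17 + 0.13 + 0.22 + 0.45 + 0.11)
  # isolated node
  W <- matrix(0, 3, 3); W[1, 2] <- W[2, 1] <- 0.4
  expect_equal(unname(expected_influence(toy_net(W))[3]), 0)
  # linearity in the weights
  W2 <- random_weights(6)
  expect_equal(expected_influence(toy_net(W2 * 0.5)),
               0.5 * expected_influence(toy_net(W2)))
})

test_that("standardized EI reproduces the published centrality values", {
  net <- lad_network()
  z <- standardize(expected_influence(net))
  expect_equal(unname(z["GAD4"]), 2.17, tolerance = 0.1)
  expect_equal(unname(z["PHQ6"]), 1.46, tolerance = 0.1)
  expect_equal(names(which.max(z)), "GAD4")
  phq <- z[paste0("PHQ", 1:9)]
  expect_equal(names(which.max(phq)), "PHQ6")
})

test_that("node distances follow the 1/|w| convention", {
  W <- matrix(0, 2, 2); W[1, 2] <- W[2, 1] <- 0.5
  expect_equal(node_distances(toy_net(W))[1, 2], 2)
  # chain: distances add along the geodesic
  W <- matrix(0, 3, 3)
  W[1, 2] <- W[2, 1] <- 0.5
  W[2, 3] <- W[3, 2] <- -0.5   # sign is ignored
  D <- node_distances(toy_net(W))
  expect_equal(D[1, 3], 4)
  # the packaged network is connected
  Dl <- node_distances(lad_network())
  expect_true(is.finite(Dl["Ln1", "GAD7"]))
  expect_true(all(is.finite(Dl)))
})

test_that("closeness has its closed form on a star and flags components", {
  W <- matrix(0, 4, 4)
  W[1, 2:4] <- W[2:4, 1] <- 0.5   # star, spoke length 2
  cl <- closeness(toy_net(W))
  expect_equal(unname(cl[1]), 3 / 6)
  expect_equal(unname(cl[2:4]), rep(3 / 10, 3))
  # sign-flip invariance
  expect_equal(closeness(toy_net(-W)), cl)
  # disconnected: per-component closeness, flagged
  W2 <- matrix(0, 4, 4)
  W2[1, 2] <- W2[2, 1] <- 0.5
  cl2 <- closeness(toy_net(W2))
  expect_equal(unname(cl2[1]), 1 / 2)
  expect_equal(unname(cl2[3]), 0)
  expect_false(is.null(attr(cl2, "components")))
})

test_that("loneliness items hold the three lowest closeness ranks", {
  cl <- closeness(lad_network())
  expect_setequal(names(sort(cl))[1:3], c("Ln1", "Ln2", "Ln3"))
})

test_that("betweenness matches small closed forms", {
  W <- matrix(0, 3, 3)
  W[1, 2] <- W[2, 1] <- 0.5; W[2, 3] <- W[3, 2] <- 0.5
  expect_equal(unname(betweenness(toy_net(W))), c(0, 1, 0))
  # 4-cycle with equal weights: two tied geodesics for each opposite pair
  W <- matrix(0, 4, 4)
  for (e in list(c(1, 2), c(2, 3), c(3, 4), c(4, 1)))
    W[e[1], e[2]] <- W[e[2], e[1]] <- 0.5
  expect_equal(unname(betweenness(toy_net(W))), rep(0.5, 4))
})

test_that("betweenness agrees with exhaustive path enumeration and igraph", {
  with_seed_test(77, {
    for (r in 1:12) {
      p <- sample(5:8, 1)
      W <- random_weights(p, density = 0.45)
      net <- toy_net(W)
      b <- betweenness(net)
      expect_equal(unname(b), oracle_betweenness(W), tolerance = 1e-9)
      if (any(W != 0)) {
        g <- as_igraph(net)
        bi <- igraph::betweenness(g, weights = 1 / abs(igraph::E(g)$weight))
        expect_equal(unname(b[names(bi)]), unname(bi), tolerance = 1e-9)
      }
    }
  })
})

test_that("shortest-path indices are permutation-equivariant and sign-blind", {
  with_seed_test(88, {
    W <- random_weights(7, density = 0.5)
    net <- toy_net(W)
    perm <- sample(7)
    netp <- toy_net(W[perm, perm],
                    constructs = rep(c("depression", "anxiety",
                                       "loneliness"), length.out = 7)[perm])
    expect_equal(unname(betweenness(netp)), unname(betweenness(net))[perm])
    expect_equal(unname(closeness(netp)), unname(closeness(net))[perm])
    sgn <- matrix(sample(c(-1, 1), 49, replace = TRUE), 7)
    sgn <- sgn * t(sgn)          # symmetric sign pattern
    expect_equal(betweenness(toy_net(-W)), betweenness(net))
  })
})

test_that("standardize uses the sample SD and rejects constants", {
  expect_equal(standardize(c(0, 2)), c(-1, 1) / sqrt(2))
  expect_error(standardize(rep(1, 5)), "zero standard deviation")
  expect_error(standardize(3), "at least 2")
  z <- standardize(rnorm(19))
  expect_equal(mean(z), 0, tolerance = 1e-9)
  expect_equal(sd(z), 1, tolerance = 1e-9)
})

test_that("centrality_table is internally consistent", {
  net <- lad_network()
  tab <- centrality_table(net)
  expect_equal(nrow(tab), 19)
  expect_equal(tab$ei_raw, unname(expected_influence(net)))
  expect_equal(tab$ei_z, unname(standardize(expected_influence(net))))
  expect_equal(tab$node[tab$ei_rank == 1], "GAD4")
  expect_equal(mean(tab$betweenness_z), 0, tolerance = 1e-9)
  expect_equal(sd(tab$closeness_z), 1, tolerance = 1e-9)
})
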