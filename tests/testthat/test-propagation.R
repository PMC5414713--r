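test_that("normalized adjacency applies symmetric degree normalization", {
  pair <- signaling_network(data.frame(source = "A", target = "B",
                                       type = "activate"))
  W <- normalized_adjacency(pair)
  expect_equal(W["A", "B"], 1.0)
  expect_equal(W["B", "A"], 1.0)

  star <- signaling_network(data.frame(source = "HUB",
                                       target = c("L1", "L2", "L3", "L4"),
                                       type = "activate"))
  Ws <- normalized_adjacency(star)
  expect_equal(unname(Ws["HUB", c("L1", "L2", "L3", "L4")]),
               rep(1 / 2, 4))  # 1 / sqrt(4 * 1)

  empty <- signaling_network(data.frame(source = character(),
                                        target = character(),
                                        type = character()))
  expect_equal(dim(normalized_adjacency(empty)), c(0, 0))
})

test_that("trivial propagation fixed points are exact", {
  iso <- signaling_network(data.frame(source = "A", target = "B",
                                      type = "activate"), nodes = "LONE")
  cfg <- propagation_config(alpha = 0.7)
  # no seeds: zero everywhere
  h0 <- propagate(iso, character(), cfg)
  expect_equal(unname(h0), rep(0, 3), ignore_attr = TRUE)
  # isolated seeded node: heat exactly (1 - alpha)
  h <- propagate(iso, "LONE", cfg)
  expect_equal(h[["LONE"]], 0.3)
  expect_warning(propagate(iso, "ZZZ", cfg), "no seed maps")
  expect_error(propagate(signaling_network(
    data.frame(source = character(), target = character(),
               type = character())), "A"), "empty network")
})

test_that("iterative heat matches the direct linear solve on random networks", {
  cfg <- propagation_config(alpha = 0.7, tol = 1e-8)
  for (s in 1:25) {
    net <- random_net(sample(5:60, 1), runif(1, 0.03, 0.2), seed = 500 + s)
    seeds <- sample(net$nodes, sample(1:5, 1))
    W <- normalized_adjacency(net)
    y <- as.numeric(net$nodes %in% seeds)
    direct <- (1 - cfg$alpha) *
      solve(diag(length(net$nodes)) - cfg$alpha * W, y)
    iter <- propagate(net, seeds, cfg)
    expect_lt(max(abs(iter - direct)), 10 * cfg$tol)
  }
})

test_that("path network heat equals the dense 2x2 solve at alpha = 0.5", {
  pair <- signaling_network(data.frame(source = "A", target = "B",
                                       type = "activate"))
  cfg <- propagation_config(alpha = 0.5, tol = 1e-10)
  h <- propagate(pair, "A", cfg)
  direct <- 0.5 * solve(diag(2) - 0.5 * matrix(c(0, 1, 1, 0), 2), c(1, 0))
  expect_equal(unname(h), as.vector(direct), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("heat is monotone in seed mass", {
  net <- random_net(30, 0.1, seed = 77)
  cfg <- propagation_config()
  seeds <- sample(net$nodes, 3)
  extra <- sample(setdiff(net$nodes, seeds), 1)
  h1 <- propagate(net, seeds, cfg)
  h2 <- propagate(net, c(seeds, extra), cfg)
  expect_true(all(h2 >= h1 - 1e-12))
})

test_that("cohort profiles scale converged heat by the configured factor", {
  iso <- signaling_network(data.frame(source = "A", target = "B",
                                      type = "activate"), nodes = "LONE")
  cat <- structure(list(S1 = "LONE", S2 = character(), S3 = "LONE"),
                   class = "mutation_catalog")
  expect_warning(prof <- profile_cohort(iso, cat), "no in-network mutation")
  # default scale 100,000 on the 0.3 fixed point
  expect_equal(prof$scores["S1", "LONE"], 30000)
  expect_equal(unname(prof$scores["S2", ]), rep(0, 3))
  # identical mutation sets give identical rows
  expect_equal(prof$scores["S1", ], prof$scores["S3", ])
  expect_equal(prof$stage, "scaled")
})

test_that("profile normalization median-centers and scales each gene", {
  m <- rbind(S1 = c(G1 = 1, G2 = 5), S2 = c(G1 = 2, G2 = 5),
             S3 = c(G1 = 4, G2 = 5))
  prof <- structure(list(scores = m, stage = "scaled"),
                    class = "network_profiles")
  expect_warning(norm <- normalize_profiles(prof), "zero-variance")
  oracle <- (c(1, 2, 4) - 2) / sd(c(1, 2, 4))
  expect_equal(unname(norm$scores[, "G1"]), oracle)
  expect_equal(unname(norm$scores[, "G2"]), rep(0, 3))  # constant column
  expect_equal(norm$stage, "normalized")
  # centering identity: normalized columns have median 0
  expect_equal(unname(apply(norm$scores, 2, median)), c(0, 0))
  one <- structure(list(scores = m[1, , drop = FALSE], stage = "scaled"),
                   class = "network_profiles")
  expect_error(normalize_profiles(one), "at least 2 samples")
})

test_that("permuting catalog order permutes profile rows only", {
  net <- random_net(20, 0.15, seed = 31)
  cat1 <- list(S1 = net$nodes[1:2], S2 = net$nodes[3], S3 = net$nodes[c(2, 5)])
  cat2 <- cat1[c(3, 1, 2)]
  class(cat1) <- class(cat2) <- "mutation_catalog"
  p1 <- profile_cohort(net, cat1)
  p2 <- profile_cohort(net, cat2)
  expect_equal(rownames(p2$scores), c("S3", "S1", "S2"))
  expect_equal(p2$scores[rownames(p1$scores), ], p1$scores)
})
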