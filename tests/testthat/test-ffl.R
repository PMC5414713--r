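test_that("a single all-activate triad yields exactly one positive loop", {
  ffls <- enumerate_ffls(triad_net())
  expect_equal(nrow(ffls), 1)
  expect_equal(ffls$master, "A")
  expect_equal(ffls$secondary, "B")
  expect_equal(ffls$target, "C")
  expect_equal(ffls$sign_class, "positive")

  edgeless <- signaling_network(data.frame(source = character(),
                                           target = character(),
                                           type = character()),
                                nodes = c("A", "B"))
  expect_equal(nrow(enumerate_ffls(edgeless)), 0)
})

test_that("sign filter: one inhibiting edge disqualifies the positive class", {
  mixed <- triad_net(c("activate", "activate", "inhibit"))  # B->C inhibit
  expect_equal(enumerate_ffls(mixed)$sign_class, "other")
  expect_equal(nrow(enumerate_ffls(mixed, positive_only = TRUE)), 0)
  # neutral edges never satisfy positive_only either
  neut <- triad_net(c("activate", "activate", "neutral"))
  expect_equal(nrow(enumerate_ffls(neut, positive_only = TRUE)), 0)
})

test_that("complete 4-node all-activate digraph holds 24 loop instances", {
  genes <- c("A", "B", "C", "D")
  pairs <- expand.grid(source = genes, target = genes,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$source != pairs$target, ]
  pairs$type <- "activate"
  k4 <- signaling_network(pairs)
  ffls <- enumerate_ffls(k4, positive_only = TRUE)
  expect_equal(nrow(ffls), 24)  # 4 * 3 * 2 ordered triples
  expect_equal(anyDuplicated(ffls[, 1:3]), 0)
})

test_that("enumeration equals brute force over ordered triples on random graphs", {
  for (s in 1:30) {
    net <- random_net(sample(4:25, 1), runif(1, 0.05, 0.4), seed = 900 + s)
    for (po in c(FALSE, TRUE)) {
      got <- enumerate_ffls(net, positive_only = po)
      want <- brute_force_ffls(net, positive_only = po)
      expect_equal(as.data.frame(got), want)
    }
  }
})

test_that("loop count is invariant under node relabeling", {
  net <- random_net(15, 0.25, seed = 321)
  perm <- setNames(sprintf("X%02d", sample(15)), net$nodes)
  e <- net$edges
  relabeled <- signaling_network(
    data.frame(source = unname(perm[e$source]), target = unname(perm[e$target]),
               type = e$type), nodes = unname(perm))
  expect_equal(nrow(enumerate_ffls(relabeled)), nrow(enumerate_ffls(net)))
  expect_equal(table(enumerate_ffls(relabeled)$sign_class),
               table(enumerate_ffls(net)$sign_class))
})

test_that("differential expression recovers a planted shift and guards inputs", {
  grp_a <- sprintf("A%02d", 1:50)
  grp_b <- sprintf("B%02d", 1:50)
  hits <- 0
  n_seeds <- 30
  for (s in seq_len(n_seeds)) {
    set.seed(1200 + s)
    m <- matrix(rnorm(201 * 100), nrow = 201,
                dimnames = list(c("SHIFTED", sprintf("NULL%03d", 1:200)),
                                c(grp_a, grp_b)))
    m["SHIFTED", grp_a] <- m["SHIFTED", grp_a] + 3  # 3 pooled-SD shift
    deg <- differential_genes(m, grp_a, grp_b, fdr = 0.05)
    if ("SHIFTED" %in% deg) hits <- hits + 1
  }
  expect_gte(hits / n_seeds, 0.95)

  const <- matrix(5, nrow = 2, ncol = 100,
                  dimnames = list(c("G1", "G2"), c(grp_a, grp_b)))
  expect_length(differential_genes(const, grp_a, grp_b), 0)
  expect_error(differential_genes(const, grp_a[1:2], grp_b), "at least 3")
  expect_error(differential_genes(const, grp_a, c(grp_a[1], grp_b[1:9])),
               "disjoint")
})

test_that("loop filtering requires all three member genes", {
  net <- random_net(20, 0.3, seed = 55)
  ffls <- enumerate_ffls(net)
  expect_gt(nrow(ffls), 5)
  # identity when the gene set covers every node
  expect_equal(filter_ffls(ffls, net$nodes), ffls)
  expect_equal(nrow(filter_ffls(ffls, character())), 0)
  # loop with only 2 of 3 genes in the set is excluded
  one <- ffls[1, ]
  partial <- filter_ffls(one, c(one$master, one$secondary))
  expect_equal(nrow(partial), 0)
  # brute-force check of the kept set
  gene_set <- sample(net$nodes, 12)
  kept <- filter_ffls(ffls, gene_set)
  manual <- ffls[apply(ffls[, c("master", "secondary", "target")], 1,
                       function(g) all(g %in% gene_set)), ]
  rownames(manual) <- NULL
  expect_equal(as.data.frame(kept), as.data.frame(manual))
})

test_that("activity calls require all three genes above the cohort reference", {
  scores <- rbind(S1 = c(M = 2, S = 2, T = 2),
                  S2 = c(M = 2, S = 2, T = -2),
                  S3 = c(M = -2, S = -2, T = -2),
                  S4 = c(M = 0.1, S = 0.1, T = 0.1))
  prof <- structure(list(scores = scores, stage = "normalized"),
                    class = "network_profiles")
  loop <- data.frame(master = "M", secondary = "S", target = "T")
  expect_true(ffl_active(prof, loop, "S1"))
  expect_false(ffl_active(prof, loop, "S2"))  # above on only 2 of 3
  expect_false(ffl_active(prof, loop, "S3"))  # all-low profile row
  expect_error(ffl_active(prof, data.frame(master = "M", secondary = "S",
                                           target = "Z"), "S1"), "absent")
  raw <- structure(list(scores = scores, stage = "scaled"),
                   class = "network_profiles")
  expect_error(ffl_active(raw, loop, "S1"), "normalized")
})

test_that("enrichment ranks by fraction with a strict pass threshold", {
  set.seed(9)
  n <- 100
  scores <- cbind(M = c(rep(1, 71), rep(-1, 29)),
                  S = c(rep(1, 71), rep(-1, 29)),
                  T = c(rep(1, 71), rep(-1, 29)),
                  M2 = c(rep(1, 70), rep(-1, 30)),
                  S2 = c(rep(1, 70), rep(-1, 30)),
                  T2 = c(rep(1, 70), rep(-1, 30)))
  rownames(scores) <- sprintf("P%03d", 1:n)
  prof <- structure(list(scores = scores, stage = "normalized"),
                    class = "network_profiles")
  ffls <- data.frame(master = c("M", "M2"), secondary = c("S", "S2"),
                     target = c("T", "T2"), sign_class = "positive")
  enr <- enrich_ffls(prof, ffls, rownames(scores), min_fraction = 0.70)
  expect_equal(enr$n_active, c(71, 70))
  # 71/100 passes the strict > 0.70 rule; 70/100 does not
  expect_equal(enr$passes, c(TRUE, FALSE))
  expect_equal(enr$master, c("M", "M2"))  # ranked by fraction
  expect_error(enrich_ffls(prof, ffls, "P001"), "at least 2")
  expect_error(enrich_ffls(prof, ffls, c("P001", "NOPE")), "not profiled")
})

test_that("active counts over disjoint cohorts add up to their union", {
  set.seed(88)
  scores <- matrix(rnorm(60 * 3), ncol = 3,
                   dimnames = list(sprintf("P%02d", 1:60), c("M", "S", "T")))
  prof <- structure(list(scores = scores, stage = "normalized"),
                    class = "network_profiles")
  loop <- data.frame(master = "M", secondary = "S", target = "T",
                     sign_class = "positive")
  c1 <- rownames(scores)[1:30]
  c2 <- rownames(scores)[31:60]
  n1 <- enrich_ffls(prof, loop, c1)$n_active
  n2 <- enrich_ffls(prof, loop, c2)$n_active
  nu <- enrich_ffls(prof, loop, c(c1, c2))$n_active
  expect_equal(n1 + n2, nu)
  frac <- enrich_ffls(prof, loop, c(c1, c2))$fraction
  expect_true(frac >= 0 && frac <= 1)
})
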