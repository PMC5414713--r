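test_that("generators are deterministic given the master seed", {
  spec <- cohort_spec(n_samples = 40, seed = 5)
  a <- simulate_cohort(spec)
  b <- simulate_cohort(spec)
  expect_identical(a$network$edges, b$network$edges)
  expect_identical(a$evidence, b$evidence)
  expect_identical(unclass(a$catalog), unclass(b$catalog))
  expect_identical(a$expression, b$expression)
  expect_identical(a$clinical, b$clinical)
  # each generator is independently reproducible from its own offset stream
  nw1 <- simulate_network(spec)
  expect_identical(nw1$network$edges, a$network$edges)
})

test_that("planted loops exist in the generated network as positive FFLs", {
  spec <- cohort_spec(n_genes = 30, n_planted_positive_ffls = 3, seed = 2)
  nw <- simulate_network(spec)
  expect_equal(nrow(nw$truth$planted_ffls), 3)
  pos <- enumerate_ffls(nw$network, positive_only = TRUE)
  key <- function(d) paste(d$master, d$secondary, d$target)
  expect_true(all(key(nw$truth$planted_ffls) %in% key(pos)))
  expect_error(simulate_network(cohort_spec(n_genes = 10,
                                            n_planted_positive_ffls = 4)),
               "not enough genes")
})

test_that("background edge count is binomially calibrated", {
  n <- 50; p <- 0.05
  n_seeds <- 300
  counts <- vapply(seq_len(n_seeds), function(s) {
    nw <- simulate_network(cohort_spec(n_genes = n, edge_density = p,
                                       n_planted_positive_ffls = 0, seed = s))
    nrow(nw$network$edges)
  }, numeric(1))
  trials <- n * (n - 1)
  # 99% CI for the mean count over n_seeds independent graphs
  se <- sqrt(trials * p * (1 - p) / n_seeds)
  expect_lt(abs(mean(counts) - trials * p), 2.58 * se)
})

test_that("designated essential genes pass the default selection rules", {
  spec <- cohort_spec(seed = 8)
  nw <- simulate_network(spec)
  sc <- simulate_screens(spec, nw$truth)
  sel <- suppressWarnings(select_genes(sc$evidence))
  for (cl in names(sc$truth$designated)) {
    des <- sc$truth$designated[[cl]]
    expect_true(all(des$essential %in% sel$selection$gene))
    expect_true(all(des$driver %in% sel$selection$gene))
    expect_true(all(des$prolif %in% sel$selection$gene))
  }
  roles <- setNames(sel$selection$role, sel$selection$gene)
  expect_true(all(roles[sc$truth$designated$CL01$essential] == "essential"))
})

test_that("driver mutation frequency is binomially calibrated", {
  spec0 <- cohort_spec(n_samples = 50, driver_mutation_rate = 0, seed = 3)
  nw <- simulate_network(spec0)
  mu0 <- simulate_mutations(spec0, nw$truth)
  expect_false(any(vapply(mu0$catalog, function(g) "PIK3CA" %in% g,
                          logical(1))))

  n_seeds <- 200; n <- 300; rate <- 0.466
  fracs <- vapply(seq_len(n_seeds), function(s) {
    sp <- cohort_spec(n_samples = n, driver_mutation_rate = rate, seed = 40 + s)
    tw <- simulate_network(sp)
    mu <- simulate_mutations(sp, tw$truth)
    mean(vapply(mu$catalog, function(g) "PIK3CA" %in% g, logical(1)))
  }, numeric(1))
  se <- sqrt(rate * (1 - rate) / (n * n_seeds))
  expect_lt(abs(mean(fracs) - rate), 2.58 * se)
})

test_that("expression shift and survival contrast follow the spec knobs", {
  spec <- cohort_spec(n_samples = 200, expr_shift = 2, seed = 17)
  b <- simulate_cohort(spec)
  tr <- b$truth
  mut <- names(tr$driver_mutated)[tr$driver_mutated]
  non <- setdiff(tr$samples, mut)
  deg_gene <- tr$deg_genes[1]
  shift <- mean(b$expression[deg_gene, mut]) - mean(b$expression[deg_gene, non])
  expect_equal(shift, 2, tolerance = 0.5)
  # non-DEG genes are unshifted
  null_gene <- setdiff(rownames(b$expression), c(tr$deg_genes,
                                                 proliferation_genes()))[1]
  shift0 <- mean(b$expression[null_gene, mut]) - mean(b$expression[null_gene, non])
  expect_equal(shift0, 0, tolerance = 0.5)
  # with expr_shift = 0, DEG calls stay near the FDR level
  spec0 <- cohort_spec(n_samples = 200, expr_shift = 0, prolif_shift = 0,
                       seed = 18)
  b0 <- simulate_cohort(spec0)
  mut0 <- names(b0$truth$driver_mutated)[b0$truth$driver_mutated]
  deg0 <- differential_genes(b0$expression, mut0,
                             setdiff(b0$truth$samples, mut0), fdr = 0.05)
  expect_lte(length(deg0), ceiling(0.05 * nrow(b0$expression)) + 2)
})

test_that("null hazard ratio leaves the latent groups indistinguishable", {
  n_reps <- 200
  rej <- vapply(seq_len(n_reps), function(s) {
    sp <- cohort_spec(n_samples = 137, hazard_ratio = 1, seed = 2000 + s)
    nw <- simulate_network(sp)
    mu <- simulate_mutations(sp, nw$truth)
    es <- simulate_expression_survival(sp, mu$truth)
    cl <- es$clinical
    pos <- cl[es$truth$latent_pos, ]
    neg <- cl[!es$truth$latent_pos, ]
    if (nrow(pos) == 0 || nrow(neg) == 0 ||
        sum(cl$event) == 0) return(NA)
    logrank_test(pos, neg)$p_value < 0.05
  }, logical(1))
  expect_equal(mean(rej, na.rm = TRUE), 0.05, tolerance = 0.035)
})

test_that("the written bundle reads back into equivalent objects", {
  dir <- tempfile("bundle")
  spec <- cohort_spec(n_samples = 30, seed = 12)
  b <- simulate_cohort(spec, dir = dir)
  expect_true(all(file.exists(b$paths)))
  net <- read_network(b$paths[["network"]])
  expect_identical(net$edges, b$network$edges)
  cat2 <- read_mutations(b$paths[["mutations"]])
  nonempty <- names(b$catalog)[lengths(b$catalog) > 0]
  expect_identical(lapply(cat2[nonempty], identity),
                   lapply(unclass(b$catalog)[nonempty], identity))
  clin2 <- read_clinical(b$paths[["clinical"]])
  expect_equal(clin2$time, b$clinical$time, tolerance = 1e-8)
  expr2 <- read_expression(b$paths[["expression"]])
  expect_equal(expr2, b$expression, tolerance = 1e-8,
               ignore_attr = TRUE)
})
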