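# shared fixture builders; all fixtures are generated in code

triad_net <- function(types = c("activate", "activate", "activate")) {
  signaling_network(data.frame(source = c("A", "A", "B"),
                               target = c("B", "C", "C"),
                               type = types))
}

# random directed graph over n nodes at density p, random edge types
random_net <- function(n, p, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  genes <- sprintf("N%02d", seq_len(n))
  pairs <- expand.grid(source = genes, target = genes,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$source != pairs$target, ]
  keep <- runif(nrow(pairs)) < p
  e <- pairs[keep, , drop = FALSE]
  e$type <- sample(c("activate", "inhibit", "neutral"), nrow(e), replace = TRUE)
  signaling_network(e, nodes = genes)
}

# independent brute-force FFL oracle: scan all ordered triples
brute_force_ffls <- function(net, positive_only = FALSE) {
  nodes <- net$nodes
  has <- matrix(FALSE, length(nodes), length(nodes),
                dimnames = list(nodes, nodes))
  act <- has
  if (nrow(net$edges)) {
    idx <- cbind(match(net$edges$source, nodes), match(net$edges$target, nodes))
    has[idx] <- TRUE
    act[idx] <- net$edges$type == "activate"
  }
  out <- list()
  for (a in nodes) for (b in nodes) for (ch in nodes) {
    if (a == b || a == ch || b == ch) next
    if (has[a, b] && has[a, ch] && has[b, ch]) {
      pos <- act[a, b] && act[a, ch] && act[b, ch]
      if (positive_only && !pos) next
      out[[length(out) + 1]] <- data.frame(
        master = a, secondary = b, target = ch,
        sign_class = if (pos) "positive" else "other",
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(master = character(), secondary = character(),
                      target = character(), sign_class = character(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$master, res$secondary, res$target), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# vectorized independent oracle: scan every ordered triple at once
brute_force_ffls_vec <- function(net, positive_only = FALSE) {
  nodes <- net$nodes
  n <- length(nodes)
  has <- matrix(FALSE, n, n)
  act <- has
  if (nrow(net$edges)) {
    idx <- cbind(match(net$edges$source, nodes), match(net$edges$target, nodes))
    has[idx] <- TRUE
    act[idx] <- net$edges$type == "activate"
  }
  g <- expand.grid(a = seq_len(n), b = seq_len(n), c = seq_len(n))
  g <- g[g$a != g$b & g$a != g$c & g$b != g$c, , drop = FALSE]
  ok <- has[cbind(g$a, g$b)] & has[cbind(g$a, g$c)] & has[cbind(g$b, g$c)]
  g <- g[ok, , drop = FALSE]
  pos <- act[cbind(g$a, g$b)] & act[cbind(g$a, g$c)] & act[cbind(g$b, g$c)]
  if (positive_only) {
    g <- g[pos, , drop = FALSE]
    pos <- pos[pos]
  }
  res <- data.frame(master = nodes[g$a], secondary = nodes[g$b],
                    target = nodes[g$c],
                    sign_class = as.character(ifelse(pos, "positive", "other")),
                    stringsAsFactors = FALSE)
  res <- res[order(res$master, res$secondary, res$target), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# in-memory end-to-end run over a synthetic bundle; returns recovery facts
run_end_to_end <- function(spec) {
  b <- simulate_cohort(spec)
  sel <- suppressWarnings(select_genes(b$evidence))
  snet <- build_survival_network(b$network, sel)
  prof <- suppressWarnings(
    normalize_profiles(suppressWarnings(profile_cohort(snet, b$catalog))))
  cohort <- names(b$catalog)[vapply(b$catalog, function(g)
    spec$driver_gene %in% g, logical(1))]
  noncohort <- setdiff(names(b$catalog), cohort)
  deg <- differential_genes(b$expression, cohort, noncohort, fdr = 0.05)
  filtered <- filter_ffls(enumerate_ffls(snet, positive_only = TRUE), deg)
  enr <- enrich_ffls(prof, filtered, cohort, min_fraction = 0.70)
  planted <- b$truth$planted_ffls[1, ]
  top_is_planted <- nrow(enr) > 0 &&
    enr$master[1] == planted$master &&
    enr$secondary[1] == planted$secondary &&
    enr$target[1] == planted$target
  p_ffl <- NA_real_
  if (nrow(enr) > 0) {
    g <- c(enr$master[1], enr$secondary[1], enr$target[1])
    thr <- colMeans(prof$scores)
    act <- rowSums(sweep(prof$scores[cohort, g, drop = FALSE],
                         2, thr[g], ">")) == 3L
    rownames(b$clinical) <- b$clinical$sample
    pos <- b$clinical[cohort[act], ]
    neg <- b$clinical[cohort[!act], ]
    if (nrow(pos) > 0 && nrow(neg) > 0 &&
        sum(pos$event) + sum(neg$event) > 0) {
      p_ffl <- logrank_test(pos, neg)$p_value
    }
  }
  list(top_is_planted = top_is_planted, p_ffl = p_ffl,
       any_pass = nrow(enr) > 0 && any(enr$passes))
}

write_tsv_lines <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}

toy_evidence <- function(gene, rnai_p, gistic = -0.1, expr = NULL,
                         cell_line = "CL1") {
  n <- length(gene)
  if (is.null(expr)) expr <- seq(10, 10 + n - 1)
  data.frame(gene = gene, cell_line = cell_line,
             rnai_p = rep_len(rnai_p, n), garp = 0,
             gistic = rep_len(gistic, n), expr = rep_len(expr, n),
             stringsAsFactors = FALSE)
}

clin <- function(time, event, prefix = "S") {
  data.frame(sample = paste0(prefix, seq_along(time), recycle0 = TRUE),
             time = time, event = event, stringsAsFactors = FALSE)
}
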