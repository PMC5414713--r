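#' Enumerate feed-forward loops in a directed network
#'
#' A feed-forward loop (FFL) is an ordered triple of distinct genes
#' (master, secondary, target) with directed edges master -> secondary,
#' master -> target and secondary -> target all present. The positive
#' (coherent) class requires all three edges to be activating; `neutral`
#' edges never qualify, since a positive regulatory loop needs unambiguous
#' activation. Enumeration is exhaustive and duplicate-free, returned in
#' lexicographic (master, secondary, target) order.
#'
#' @param net a [signaling_network].
#' @param positive_only if `TRUE` return only all-activate loops.
#' @return data.frame of class `ffl_table` with columns `master`,
#'   `secondary`, `target`, `sign_class` (`"positive"` or `"other"`).
#' @export
enumerate_ffls <- function(net, positive_only = FALSE) {
  stopifnot(inherits(net, "signaling_network"))
  e <- net$edges
  empty <- data.frame(master = character(), secondary = character(),
                      target = character(), sign_class = character(),
                      stringsAsFactors = FALSE)
  if (nrow(e) < 3) return(structure(empty, class = c("ffl_table", "data.frame")))
  etype <- stats::setNames(e$type, paste(e$source, e$target, sep = "\r"))
  succ <- split(e$target, e$source)
  out <- vector("list", nrow(e))
  # loop over candidate (master -> secondary) edges; targets are the
  # intersection of both out-neighborhoods
  for (i in seq_len(nrow(e))) {
    a <- e$source[i]; b <- e$target[i]
    tb <- succ[[b]]
    if (is.null(tb)) next
    targets <- intersect(succ[[a]], tb)
    targets <- targets[targets != a & targets != b]
    if (!length(targets)) next
    out[[i]] <- data.frame(master = a, secondary = b, target = targets,
                           stringsAsFactors = FALSE)
  }
  ffls <- do.call(rbind, out)
  if (is.null(ffls) || nrow(ffls) == 0) {
    return(structure(empty, class = c("ffl_table", "data.frame")))
  }
  all_act <- etype[paste(ffls$master, ffls$secondary, sep = "\r")] == "activate" &
    etype[paste(ffls$master, ffls$target, sep = "\r")] == "activate" &
    etype[paste(ffls$secondary, ffls$target, sep = "\r")] == "activate"
  ffls$sign_class <- ifelse(all_act, "positive", "other")
  if (positive_only) ffls <- ffls[all_act, , drop = FALSE]
  ffls <- ffls[order(ffls$master, ffls$secondary, ffls$target), , drop = FALSE]
  rownames(ffls) <- NULL
  structure(ffls, class = c("ffl_table", "data.frame"))
}

#' Differentially expressed genes between two sample groups
#'
#' Per-gene two-sided Welch t-test between the two groups with
#' Benjamini-Hochberg adjustment; genes with adjusted p below `fdr` are
#' returned. Genes that are constant in both groups are never called
#' (p = 1 when the means agree).
#'
#' @param expr genes x samples numeric matrix.
#' @param group_a,group_b disjoint character vectors of sample (column)
#'   names, each of size >= 3.
#' @param fdr adjusted-p cutoff (default 0.05).
#' @return character vector of gene symbols, sorted.
#' @export
differential_genes <- function(expr, group_a, group_b, fdr = 0.05) {
  if (length(intersect(group_a, group_b))) {
    stop("groups must be disjoint", call. = FALSE)
  }
  if (length(group_a) < 3 || length(group_b) < 3) {
    stop("each group needs at least 3 samples", call. = FALSE)
  }
  miss <- setdiff(c(group_a, group_b), colnames(expr))
  if (length(miss)) {
    stop(sprintf("sample(s) absent from expression matrix: %s",
                 paste(utils::head(miss, 5), collapse = ", ")), call. = FALSE)
  }
  xa <- expr[, group_a, drop = FALSE]
  xb <- expr[, group_b, drop = FALSE]
  pvals <- vapply(seq_len(nrow(expr)), function(i) {
    a <- xa[i, ]; b <- xb[i, ]
    tryCatch(stats::t.test(a, b)$p.value,
             error = function(e) {
               # essentially-constant data: call only a real mean shift
               if (isTRUE(all.equal(mean(a, na.rm = TRUE), mean(b, na.rm = TRUE)))) 1 else 0
             })
  }, numeric(1))
  padj <- stats::p.adjust(pvals, method = "BH")
  sort(rownames(expr)[!is.na(padj) & padj < fdr])
}

#' Keep only loops fully contained in a gene set
#'
#' A loop survives the differential-expression funnel only if master,
#' secondary and target are all in `gene_set`.
#'
#' @param ffls an `ffl_table` from [enumerate_ffls()].
#' @param gene_set character vector of gene symbols.
#' @return filtered `ffl_table`.
#' @export
filter_ffls <- function(ffls, gene_set) {
  gene_set <- toupper(gene_set)
  keep <- ffls$master %in% gene_set & ffls$secondary %in% gene_set &
    ffls$target %in% gene_set
  out <- ffls[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

activity_reference <- function(scores, ref) {
  if (ref == "mean") colMeans(scores) else apply(scores, 2, stats::median)
}

#' Is a loop active in one sample?
#'
#' A loop is called active in a sample when the sample's normalized heat
#' score strictly exceeds the cohort reference (column mean by default,
#' median optionally) for each of master, secondary and target.
#'
#' @param profiles normalized `network_profiles`.
#' @param ffl one-row `ffl_table` (or list with `master`, `secondary`,
#'   `target`).
#' @param sample sample id (profile row).
#' @param ref `"mean"` (default) or `"median"` cohort reference.
#' @return logical scalar.
#' @export
ffl_active <- function(profiles, ffl, sample, ref = c("mean", "median")) {
  ref <- match.arg(ref)
  stopifnot(inherits(profiles, "network_profiles"))
  if (profiles$stage != "normalized") {
    stop("ffl_active needs normalized profiles", call. = FALSE)
  }
  genes <- c(ffl$master[1], ffl$secondary[1], ffl$target[1])
  miss <- setdiff(genes, colnames(profiles$scores))
  if (length(miss)) {
    stop(sprintf("gene(s) absent from profiles: %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  }
  if (!sample %in% rownames(profiles$scores)) {
    stop(sprintf("sample absent from profiles: %s", sample), call. = FALSE)
  }
  thr <- activity_reference(profiles$scores[, genes, drop = FALSE], ref)
  all(profiles$scores[sample, genes] > thr)
}

#' Rank loops by enrichment in a mutation-defined cohort
#'
#' For each loop, counts the cohort samples in which the loop is active
#' (see [ffl_active()]; the reference is computed over all profiled
#' samples) and ranks loops by active fraction, ties broken
#' lexicographically by (master, secondary, target). A loop passes when its
#' fraction strictly exceeds `min_fraction` — 0.70 by default, mirroring
#' the "more than 70% of driver-mutated tumors" enrichment rule.
#'
#' @param profiles normalized `network_profiles`.
#' @param ffls an `ffl_table`.
#' @param cohort character vector of sample ids (>= 2, all profiled).
#' @param min_fraction pass threshold on the active fraction.
#' @param ref `"mean"` or `"median"` activity reference.
#' @return data.frame of class `ffl_enrichment`: columns of `ffls` plus
#'   `n_active`, `cohort_size`, `fraction`, `passes`.
#' @export
enrich_ffls <- function(profiles, ffls, cohort, min_fraction = 0.70,
                        ref = c("mean", "median")) {
  ref <- match.arg(ref)
  stopifnot(inherits(profiles, "network_profiles"))
  if (profiles$stage != "normalized") {
    stop("enrich_ffls needs normalized profiles", call. = FALSE)
  }
  miss <- setdiff(cohort, rownames(profiles$scores))
  if (length(miss)) {
    stop(sprintf("cohort sample(s) not profiled: %s",
                 paste(utils::head(miss, 5), collapse = ", ")), call. = FALSE)
  }
  if (length(cohort) < 2) stop("cohort needs at least 2 samples", call. = FALSE)
  out <- as.data.frame(ffls, stringsAsFactors = FALSE)
  if (nrow(out) == 0) {
    out$n_active <- integer(); out$cohort_size <- integer()
    out$fraction <- numeric(); out$passes <- logical()
    return(structure(out, class = c("ffl_enrichment", "data.frame")))
  }
  thr <- activity_reference(profiles$scores, ref)
  sub <- profiles$scores[cohort, , drop = FALSE]
  above <- sweep(sub, 2, thr, ">")
  out$n_active <- vapply(seq_len(nrow(out)), function(i) {
    g <- c(out$master[i], out$secondary[i], out$target[i])
    sum(rowSums(above[, g, drop = FALSE]) == 3L)
  }, integer(1))
  out$cohort_size <- length(cohort)
  out$fraction <- out$n_active / out$cohort_size
  out$passes <- out$fraction > min_fraction
  ord <- order(-out$fraction, out$master, out$secondary, out$target)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("ffl_enrichment", "data.frame"))
}
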