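GENE_ROLES <- c("essential", "driver_regulator", "proliferation_influencing", "none")

#' Thresholds for screening-based gene selection
#'
#' Encodes the selection rules used to nominate genes for a cancer-specific
#' survival network from genome-wide RNAi screens, GISTIC copy-number scores
#' and expression:
#'
#' * cancer-essential: RNAi screening P < `p_essential`, not a housekeeping
#'   gene, and within the top `expr_pct_essential` of expressed genes in
#'   that cell line;
#' * proliferation-influencing: `p_prolif_low` < P < `p_prolif_high` and the
#'   same expression filter;
#' * driver regulator: GISTIC score > `gistic_min` (amplified), within the
#'   top `expr_pct_driver` of expressed genes, and P < `p_driver`.
#'
#' All comparisons are strict, so boundary values (e.g. GISTIC exactly 0.3)
#' do not qualify. The housekeeping exclusion list is user-supplied; the
#' default is empty, with a warning at selection time.
#'
#' @param p_essential,p_prolif_low,p_prolif_high,p_driver RNAi-screening
#'   P-value cutoffs (defaults 0.05, 0.05, 0.1, 0.4).
#' @param gistic_min GISTIC amplification cutoff (default 0.3).
#' @param expr_pct_essential,expr_pct_driver expression filters as "top"
#'   fractions (defaults 0.75 and 0.50).
#' @param housekeeping character vector of housekeeping gene symbols
#'   excluded from the essential class.
#' @return list of class `selection_thresholds`.
#' @export
selection_thresholds <- function(p_essential = 0.05,
                                 p_prolif_low = 0.05,
                                 p_prolif_high = 0.1,
                                 p_driver = 0.4,
                                 gistic_min = 0.3,
                                 expr_pct_essential = 0.75,
                                 expr_pct_driver = 0.50,
                                 housekeeping = character()) {
  stopifnot(p_essential > 0, p_essential <= p_prolif_low,
            p_prolif_low < p_prolif_high, p_prolif_high <= p_driver,
            p_driver < 1,
            expr_pct_essential > 0, expr_pct_essential < 1,
            expr_pct_driver > 0, expr_pct_driver < 1)
  structure(list(p_essential = p_essential, p_prolif_low = p_prolif_low,
                 p_prolif_high = p_prolif_high, p_driver = p_driver,
                 gistic_min = gistic_min,
                 expr_pct_essential = expr_pct_essential,
                 expr_pct_driver = expr_pct_driver,
                 housekeeping = toupper(housekeeping)),
            class = "selection_thresholds")
}

#' Expression percentile within a cell line
#'
#' Rank-based percentile in (0, 1], ties sharing the mean rank; 1 is the
#' most highly expressed gene. "Top 75% of expressed genes" then reads as
#' percentile >= 0.25.
#'
#' @param expr numeric vector of expression values for all genes measured
#'   in one cell line.
#' @return numeric vector of percentiles, same length and names as `expr`.
#' @export
expression_percentile <- function(expr) {
  r <- rank(expr, ties.method = "average", na.last = "keep")
  r / sum(!is.na(expr))
}

#' Classify a gene's role in one cell line
#'
#' Applies the selection rules of [selection_thresholds()] to per-gene
#' evidence from one cell line. When more than one rule fires, precedence is
#' essential > driver_regulator > proliferation_influencing; the role only
#' annotates the gene, it does not change survival-network membership.
#'
#' @param gene gene symbol(s).
#' @param rnai_p RNAi-screening P value(s) in \[0, 1\].
#' @param gistic GISTIC copy-number score(s); `NA` disables the driver rule.
#' @param expr_rank expression percentile(s) from [expression_percentile()].
#' @param thresholds a [selection_thresholds()].
#' @return character vector of roles in
#'   `c("essential", "driver_regulator", "proliferation_influencing", "none")`.
#' @export
classify_gene <- function(gene, rnai_p, gistic, expr_rank, thresholds = selection_thresholds()) {
  stopifnot(inherits(thresholds, "selection_thresholds"))
  n <- length(gene)
  rnai_p <- rep_len(rnai_p, n); gistic <- rep_len(gistic, n)
  expr_rank <- rep_len(expr_rank, n)
  if (any(is.na(rnai_p))) {
    stop("missing RNAi-screening P value; every selection rule needs one",
         call. = FALSE)
  }
  if (any(rnai_p < 0 | rnai_p > 1)) {
    stop("RNAi-screening P values must lie in [0, 1]", call. = FALSE)
  }
  gene <- toupper(gene)
  th <- thresholds
  expr_ok_ess <- !is.na(expr_rank) & expr_rank >= 1 - th$expr_pct_essential
  expr_ok_drv <- !is.na(expr_rank) & expr_rank >= 1 - th$expr_pct_driver
  ess <- rnai_p < th$p_essential & !(gene %in% th$housekeeping) & expr_ok_ess
  drv <- !is.na(gistic) & gistic > th$gistic_min & expr_ok_drv & rnai_p < th$p_driver
  pro <- rnai_p > th$p_prolif_low & rnai_p < th$p_prolif_high & expr_ok_ess
  ifelse(ess, "essential",
         ifelse(drv, "driver_regulator",
                ifelse(pro, "proliferation_influencing", "none")))
}

role_strength <- function(role) match(role, GENE_ROLES)

#' Select survival-network genes from multi-cell-line screening evidence
#'
#' A gene is selected if it earns a non-`none` role in at least one cell
#' line; its cohort-level role is the strongest role over lines
#' (essential > driver_regulator > proliferation_influencing). Expression
#' percentiles are computed per cell line over all genes measured in that
#' line.
#'
#' @param evidence data.frame with columns `gene`, `cell_line`, `rnai_p`,
#'   `gistic`, `expr` (a `garp` column, if present, is carried as metadata
#'   only — no GARP cutoff is applied).
#' @param thresholds a [selection_thresholds()].
#' @return list of class `gene_selection` with elements
#'   `selection` (data.frame `gene`, `role`) and `attribution` (data.frame
#'   `gene`, `cell_line`, `role`, one row per firing rule).
#' @export
select_genes <- function(evidence, thresholds = selection_thresholds()) {
  need <- c("gene", "cell_line", "rnai_p", "gistic", "expr")
  miss <- setdiff(need, names(evidence))
  if (length(miss)) {
    stop(sprintf("evidence is missing column(s): %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  }
  if (nrow(evidence) == 0) stop("no screening evidence supplied", call. = FALSE)
  if (length(thresholds$housekeeping) == 0) {
    warning("empty housekeeping list: no genes excluded from the essential class",
            call. = FALSE)
  }
  evidence$gene <- toupper(as.character(evidence$gene))
  parts <- split(evidence, evidence$cell_line)
  attribution <- do.call(rbind, lapply(names(parts), function(cl) {
    ev <- parts[[cl]]
    pct <- expression_percentile(ev$expr)
    role <- classify_gene(ev$gene, ev$rnai_p, ev$gistic, pct, thresholds)
    keep <- role != "none"
    data.frame(gene = ev$gene[keep], cell_line = cl, role = role[keep],
               stringsAsFactors = FALSE)
  }))
  if (is.null(attribution) || nrow(attribution) == 0) {
    attribution <- data.frame(gene = character(), cell_line = character(),
                              role = character(), stringsAsFactors = FALSE)
  }
  if (nrow(attribution) == 0) {
    selection <- data.frame(gene = character(), role = character(),
                            stringsAsFactors = FALSE)
  } else {
    strongest <- tapply(attribution$role, attribution$gene,
                        function(r) GENE_ROLES[min(role_strength(r))])
    selection <- data.frame(gene = names(strongest),
                            role = unname(unlist(strongest)),
                            stringsAsFactors = FALSE)
  }
  selection <- selection[order(selection$gene), , drop = FALSE]
  rownames(selection) <- NULL
  structure(list(selection = selection, attribution = attribution),
            class = "gene_selection")
}

#' @export
print.gene_selection <- function(x, ...) {
  cat(sprintf("<gene_selection> %d genes (%s)\n", nrow(x$selection),
              paste(sprintf("%s: %d", names(table(x$selection$role)),
                            table(x$selection$role)), collapse = ", ")))
  invisible(x)
}

#' Extract a cancer-specific survival network as an induced subgraph
#'
#' Restricts a parent signaling network to the selected genes and every
#' parent edge whose two endpoints are both selected. Selected genes absent
#' from the parent network are reported in `unmapped`, not silently dropped.
#'
#' @param net parent [signaling_network].
#' @param selected character vector of selected gene symbols, or a
#'   `gene_selection` from [select_genes()].
#' @return A `survival_network` (subclass of `signaling_network`) with
#'   fields `roles` (named character vector, `"unannotated"` when `selected`
#'   was a bare vector) and `unmapped` (genes not in the parent network).
#' @export
build_survival_network <- function(net, selected) {
  stopifnot(inherits(net, "signaling_network"))
  roles <- NULL
  if (inherits(selected, "gene_selection")) {
    roles <- stats::setNames(selected$selection$role, selected$selection$gene)
    selected <- selected$selection$gene
  }
  selected <- unique(toupper(as.character(selected)))
  keep_nodes <- intersect(selected, net$nodes)
  unmapped <- sort(setdiff(selected, net$nodes))
  e <- net$edges
  keep <- e$source %in% keep_nodes & e$target %in% keep_nodes
  sub <- signaling_network(e[keep, , drop = FALSE], nodes = keep_nodes)
  if (is.null(roles)) {
    roles <- stats::setNames(rep("unannotated", length(sub$nodes)), sub$nodes)
  } else {
    roles <- roles[sub$nodes]
    names(roles) <- sub$nodes
  }
  structure(list(nodes = sub$nodes, edges = sub$edges,
                 roles = roles, unmapped = unmapped),
            class = c("survival_network", "signaling_network"))
}

jaccard_index <- function(a, b) {
  u <- union(a, b)
  if (length(u) == 0) return(1)
  length(intersect(a, b)) / length(u)
}

#' Re-derive the survival network under alternative threshold sets
#'
#' Sensitivity analysis for the selection cutoffs: the network is rebuilt
#' under each threshold variant and node-set agreement is summarized as a
#' pairwise Jaccard matrix.
#'
#' @param evidence as in [select_genes()].
#' @param net parent [signaling_network].
#' @param variants non-empty list of [selection_thresholds()] objects;
#'   names are used as labels.
#' @return list with `networks` (list of `survival_network`) and `jaccard`
#'   (numeric matrix of pairwise node-set Jaccard indices).
#' @export
sensitivity_rerun <- function(evidence, net, variants) {
  if (!length(variants)) stop("need at least one threshold variant", call. = FALSE)
  if (is.null(names(variants)) || any(!nzchar(names(variants)))) {
    names(variants) <- paste0("variant", seq_along(variants))
  }
  networks <- lapply(variants, function(th) {
    build_survival_network(net, select_genes(evidence, th))
  })
  k <- length(networks)
  jac <- matrix(1, k, k, dimnames = list(names(variants), names(variants)))
  if (k > 1) {
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      jac[i, j] <- jac[j, i] <- jaccard_index(networks[[i]]$nodes,
                                              networks[[j]]$nodes)
    }
  }
  list(networks = networks, jaccard = jac)
}
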