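#' The 11-gene PAM50 proliferation set
#'
#' The proliferation subset of the PAM50 panel used for the proliferation
#' index: MKI67, CDC20, BIRC5, CCNB1, CDCA1, CEP55, KNTC2, PTTG1, UBE2C,
#' RRM2 and TYMS. Lower mean expression of these genes indicates a slower
#' proliferating tumor. (CDCA1 and KNTC2 are the legacy aliases of
#' NUF2/NDC80 used by the panel; symbols are kept as published.)
#'
#' @return character vector of 11 gene symbols.
#' @export
proliferation_genes <- function() {
  c("MKI67", "CDC20", "BIRC5", "CCNB1", "CDCA1", "CEP55",
    "KNTC2", "PTTG1", "UBE2C", "RRM2", "TYMS")
}

check_records <- function(records, what = "records") {
  need <- c("sample", "time", "event")
  if (!is.data.frame(records) || !all(need %in% names(records))) {
    stop(sprintf("%s must be a data.frame with columns sample, time, event", what),
         call. = FALSE)
  }
  if (nrow(records) == 0) stop(sprintf("%s is empty", what), call. = FALSE)
  validate_clinical(records[, need])
}

#' Kaplan-Meier survival curve
#'
#' Product-limit estimator over a set of clinical records; censored times
#' reduce the risk set without producing steps. The curve starts at 1 and
#' is reported at observed event times only.
#'
#' @param records data.frame with columns `sample`, `time`, `event`.
#' @return list of class `km_curve`: `time` (event times), `surv`
#'   (survival probability after each event time), `n_risk` (at-risk count
#'   just before each event time), `n_event`, and `n` (cohort size).
#' @export
km_estimate <- function(records) {
  records <- check_records(records)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = records)
  keep <- fit$n.event > 0
  structure(list(time = fit$time[keep], surv = fit$surv[keep],
                 n_risk = fit$n.risk[keep], n_event = fit$n.event[keep],
                 n = nrow(records)),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("<km_curve> n = %d, %d event time(s)%s\n", x$n, length(x$time),
              if (length(x$time)) sprintf(", final S = %.3f", min(x$surv)) else ""))
  invisible(x)
}

#' Two-group log-rank test
#'
#' Standard log-rank statistic with hypergeometric variance and pooled
#' ties; p from the chi-square distribution with 1 degree of freedom.
#'
#' @param a,b data.frames of clinical records (columns `sample`, `time`,
#'   `event`), both non-empty, with at least one event overall.
#' @return list of class `logrank_result`: `chi_square`, `p_value`,
#'   `observed` and `expected` per-group event counts, `n` per group.
#' @export
logrank_test <- function(a, b) {
  a <- check_records(a, "group a"); b <- check_records(b, "group b")
  if (sum(a$event) + sum(b$event) == 0) {
    stop("log-rank statistic undefined: no events in either group", call. = FALSE)
  }
  df <- rbind(cbind(a, group = "a"), cbind(b, group = "b"))
  fit <- survival::survdiff(survival::Surv(time, event) ~ group, data = df)
  chi <- unname(fit$chisq)
  structure(list(chi_square = chi,
                 p_value = stats::pchisq(chi, df = 1, lower.tail = FALSE),
                 observed = stats::setNames(as.vector(fit$obs), c("a", "b")),
                 expected = stats::setNames(as.vector(fit$exp), c("a", "b")),
                 n = c(a = nrow(a), b = nrow(b))),
            class = "logrank_result")
}

#' @export
print.logrank_result <- function(x, ...) {
  cat(sprintf("<logrank_result> chi-square = %.3f, p = %.4g (n = %d vs %d)\n",
              x$chi_square, x$p_value, x$n[["a"]], x$n[["b"]]))
  invisible(x)
}

#' Per-sample proliferation index
#'
#' Unweighted mean expression over the proliferation gene set (the 11-gene
#' PAM50 subset by default) for each requested sample. Set genes absent
#' from the matrix are warned about; scores are flagged undefined (`NA`
#' with attribute `undefined = TRUE`) when more than half of the set is
#' missing, and it is an error when no set gene is present at all. Raw
#' expression means are used; `standardize = TRUE` z-scores each gene
#' across the requested samples first.
#'
#' @param expr genes x samples numeric matrix.
#' @param samples sample (column) names; defaults to all columns.
#' @param gene_set character vector of set genes.
#' @param standardize z-score each set gene across samples before averaging.
#' @return named numeric vector of per-sample scores, with attributes
#'   `genes_used` and `undefined`.
#' @export
proliferation_index <- function(expr, samples = colnames(expr),
                                gene_set = proliferation_genes(),
                                standardize = FALSE) {
  if (!length(gene_set)) stop("gene set is empty", call. = FALSE)
  gene_set <- toupper(gene_set)
  present <- intersect(gene_set, rownames(expr))
  if (!length(present)) {
    stop("no proliferation-set gene present in the expression matrix",
         call. = FALSE)
  }
  absent <- setdiff(gene_set, present)
  if (length(absent)) {
    warning(sprintf("proliferation gene(s) missing from matrix: %s",
                    paste(absent, collapse = ", ")), call. = FALSE)
  }
  undefined <- length(present) < length(gene_set) / 2
  sub <- expr[present, samples, drop = FALSE]
  if (standardize) {
    sub <- t(scale(t(sub)))
    sub[is.nan(sub)] <- 0
  }
  scores <- colMeans(sub, na.rm = TRUE)
  if (undefined) scores[] <- NA_real_
  attr(scores, "genes_used") <- present
  attr(scores, "undefined") <- undefined
  scores
}

#' Compare proliferation scores between two groups
#'
#' Two-sided Welch t-test on per-sample scores.
#'
#' @param scores_a,scores_b numeric vectors, each of length >= 3.
#' @return list with `t`, `p_value`, `mean_a`, `mean_b`, `n`.
#' @export
compare_groups <- function(scores_a, scores_b) {
  scores_a <- scores_a[!is.na(scores_a)]
  scores_b <- scores_b[!is.na(scores_b)]
  if (length(scores_a) < 3 || length(scores_b) < 3) {
    stop("each group needs at least 3 non-missing scores", call. = FALSE)
  }
  if (stats::sd(scores_a) == 0 && stats::sd(scores_b) == 0) {
    same <- isTRUE(all.equal(mean(scores_a), mean(scores_b)))
    return(list(t = if (same) 0 else Inf, p_value = if (same) 1 else 0,
                mean_a = mean(scores_a), mean_b = mean(scores_b),
                n = c(length(scores_a), length(scores_b))))
  }
  tt <- stats::t.test(scores_a, scores_b)
  list(t = unname(tt$statistic), p_value = tt$p.value,
       mean_a = mean(scores_a), mean_b = mean(scores_b),
       n = c(length(scores_a), length(scores_b)))
}
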