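#' @keywords internal
"_PACKAGE"

EDGE_TYPES <- c("activate", "inhibit", "neutral")

check_gene_symbols <- function(genes, what = "gene") {
  bad <- is.na(genes) | !nzchar(genes) | grepl("[[:space:]]", genes)
  if (any(bad)) {
    stop(sprintf("invalid %s symbol(s): %s", what,
                 paste(utils::head(unique(genes[bad]), 5), collapse = ", ")),
         call. = FALSE)
  }
  invisible(genes)
}

#' Construct a signed directed signaling network
#'
#' The basic container for a literature-curated signaling network: a set of
#' gene-symbol nodes and directed edges typed as `activate`, `inhibit` or
#' `neutral` (the latter encoding non-directional relations such as complex
#' membership). Gene symbols are uppercased so that mutation, expression and
#' network namespaces join cleanly. Self-loops are dropped and duplicate
#' (source, target) pairs collapsed to the first occurrence, each with a
#' warning.
#'
#' @param edges data.frame with character columns `source`, `target`, `type`
#'   (`type` one of `"activate"`, `"inhibit"`, `"neutral"`).
#' @param nodes optional character vector of additional (possibly isolated)
#'   node symbols.
#' @return An object of class `signaling_network`: a list with `nodes`
#'   (sorted character vector) and `edges` (data.frame `source`, `target`,
#'   `type`).
#' @examples
#' net <- signaling_network(data.frame(
#'   source = c("A", "A", "B"), target = c("B", "C", "C"),
#'   type = "activate"))
#' net$nodes
#' @export
signaling_network <- function(edges, nodes = NULL) {
  if (!is.data.frame(edges) ||
      !all(c("source", "target", "type") %in% names(edges))) {
    stop("edges must be a data.frame with columns source, target, type",
         call. = FALSE)
  }
  edges <- data.frame(source = toupper(as.character(edges$source)),
                      target = toupper(as.character(edges$target)),
                      type   = as.character(edges$type),
                      stringsAsFactors = FALSE)
  if (nrow(edges) > 0) {
    check_gene_symbols(edges$source, "source")
    check_gene_symbols(edges$target, "target")
    bad_type <- !edges$type %in% EDGE_TYPES
    if (any(bad_type)) {
      stop(sprintf("unknown edge type(s): %s",
                   paste(unique(edges$type[bad_type]), collapse = ", ")),
           call. = FALSE)
    }
    self <- edges$source == edges$target
    if (any(self)) {
      warning(sprintf("dropped %d self-loop edge(s): %s", sum(self),
                      paste(utils::head(edges$source[self], 5), collapse = ", ")),
              call. = FALSE)
      edges <- edges[!self, , drop = FALSE]
    }
    key <- paste(edges$source, edges$target, sep = "\r")
    dup <- duplicated(key)
    if (any(dup)) {
      warning(sprintf("collapsed %d duplicate edge(s)", sum(dup)), call. = FALSE)
      edges <- edges[!dup, , drop = FALSE]
    }
  }
  nodes <- sort(unique(c(toupper(as.character(nodes)),
                         edges$source, edges$target)))
  if (length(nodes)) check_gene_symbols(nodes, "node")
  edges <- edges[order(edges$source, edges$target), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges), class = "signaling_network")
}

#' @export
print.signaling_network <- function(x, ...) {
  cat(sprintf("<%s> %d nodes, %d edges (%d activate, %d inhibit, %d neutral)\n",
              class(x)[1], length(x$nodes), nrow(x$edges),
              sum(x$edges$type == "activate"),
              sum(x$edges$type == "inhibit"),
              sum(x$edges$type == "neutral")))
  invisible(x)
}

#' Read a signaling network from disk
#'
#' Native dialect is a TSV with header `source  target  type` and
#' `type` in `{activate, inhibit, neutral}`. The `v7_csv` dialect is a
#' best-effort mapping for curated-network CSV exports whose column layout
#' is not formally documented: the first two columns are taken as source and
#' target genes; a third column is matched against "activ"/"inhib" and any
#' other relation code (e.g. complex membership) is coerced to `neutral` and
#' mirrored as a reverse edge, since complexes are not directional.
#'
#' @param path file path.
#' @param dialect `"native"` (TSV) or `"v7_csv"` (CSV export).
#' @return A [signaling_network].
#' @export
read_network <- function(path, dialect = c("native", "v7_csv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  if (dialect == "native") {
    nf <- utils::count.fields(path, sep = "\t", quote = "")
    bad <- which(nf != 3L)
    if (length(bad)) {
      stop(sprintf("malformed row at line %d of %s: expected 3 tab-separated fields",
                   bad[1], path), call. = FALSE)
    }
    df <- utils::read.delim(path, colClasses = "character", quote = "")
    if (!identical(names(df), c("source", "target", "type"))) {
      stop(sprintf("bad header in %s: expected 'source\ttarget\ttype'", path),
           call. = FALSE)
    }
    signaling_network(df)
  } else {
    df <- utils::read.csv(path, colClasses = "character")
    if (ncol(df) < 2) stop(sprintf("v7_csv file %s needs >= 2 columns", path),
                           call. = FALSE)
    rel <- if (ncol(df) >= 3) tolower(df[[3]]) else rep("", nrow(df))
    type <- ifelse(grepl("activ", rel), "activate",
                   ifelse(grepl("inhib", rel), "inhibit", "neutral"))
    edges <- data.frame(source = df[[1]], target = df[[2]], type = type,
                        stringsAsFactors = FALSE)
    mirror <- edges[edges$type == "neutral", c("target", "source", "type")]
    names(mirror) <- c("source", "target", "type")
    signaling_network(rbind(edges, mirror))
  }
}

#' Write a signaling network in the native TSV dialect
#'
#' Edges are written in canonical order (sorted by source then target) so
#' that `write_network(read_network(f))` reproduces canonical files byte for
#' byte.
#'
#' @param net a [signaling_network].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path) {
  stopifnot(inherits(net, "signaling_network"))
  e <- net$edges[order(net$edges$source, net$edges$target), , drop = FALSE]
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c("source\ttarget\ttype",
               if (nrow(e)) paste(e$source, e$target, e$type, sep = "\t")),
             con, sep = "\n")
  invisible(path)
}

#' Read a missense mutation catalog from a MAF-like table
#'
#' Expects a TSV with columns `sample`, `gene` and `variant_classification`.
#' Only rows classified `Missense_Mutation` (case-insensitive) are kept:
#' missense variants are the "functionally mutated gene" criterion used to
#' seed network propagation. Every sample id seen in the file appears in the
#' catalog, possibly with an empty gene set; genes are uppercased and
#' deduplicated per sample.
#'
#' @param path file path to the MAF-like TSV.
#' @return A named list mapping sample id to a character vector of mutated
#'   gene symbols, of class `mutation_catalog`.
#' @export
read_mutations <- function(path) {
  df <- utils::read.delim(path, colClasses = "character", quote = "")
  need <- c("sample", "gene", "variant_classification")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop(sprintf("mutation table %s is missing column(s): %s", path,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  mutation_catalog_from_table(df)
}

# shared by the reader and the synthetic generator
mutation_catalog_from_table <- function(df) {
  keep <- tolower(df$variant_classification) == "missense_mutation"
  samples <- unique(df$sample)
  sub <- df[keep, , drop = FALSE]
  cat_list <- lapply(samples, function(s) {
    sort(unique(toupper(sub$gene[sub$sample == s])))
  })
  names(cat_list) <- samples
  structure(cat_list, class = "mutation_catalog")
}

#' @export
print.mutation_catalog <- function(x, ...) {
  cat(sprintf("<mutation_catalog> %d samples, %.1f mutated genes/sample (mean)\n",
              length(x), if (length(x)) mean(lengths(x)) else 0))
  invisible(x)
}

#' Read a clinical outcome table
#'
#' Expects a TSV with columns `sample`, `time` (non-negative follow-up, in
#' months) and `event` (1 = death/recurrence, 0 = censored). The event
#' semantics (overall survival vs recurrence) are those of the input data.
#'
#' @param path file path.
#' @return data.frame with columns `sample`, `time`, `event`.
#' @export
read_clinical <- function(path) {
  df <- utils::read.delim(path, quote = "")
  need <- c("sample", "time", "event")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop(sprintf("clinical table %s is missing column(s): %s", path,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  df$sample <- as.character(df$sample)
  df$time <- suppressWarnings(as.numeric(df$time))
  validate_clinical(df[, need])
}

validate_clinical <- function(df) {
  if (anyDuplicated(df$sample)) {
    stop("duplicate sample id(s) in clinical table", call. = FALSE)
  }
  if (any(is.na(df$time)) || any(df$time < 0)) {
    stop("clinical time must be numeric and >= 0", call. = FALSE)
  }
  if (!all(df$event %in% c(0L, 1L))) {
    stop("clinical event must be 0 (censored) or 1 (event)", call. = FALSE)
  }
  df$event <- as.integer(df$event)
  rownames(df) <- NULL
  df
}

#' Read an expression (or copy-number) matrix
#'
#' Genes as rows, samples as columns, first column holding gene symbols.
#' Duplicate gene or sample labels are an error; missing values are
#' permitted and their count is attached as attribute `n_missing`.
#'
#' @param path file path to a TSV matrix.
#' @return numeric matrix (genes x samples) with uppercased rownames.
#' @export
read_expression <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, quote = "")
  genes <- toupper(as.character(df[[1]]))
  if (anyDuplicated(genes)) {
    stop(sprintf("duplicate gene label(s) in %s: %s", path,
                 paste(utils::head(genes[duplicated(genes)], 3), collapse = ", ")),
         call. = FALSE)
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- genes
  if (anyDuplicated(colnames(m))) {
    stop(sprintf("duplicate sample label(s) in %s", path), call. = FALSE)
  }
  attr(m, "n_missing") <- sum(is.na(m))
  m
}

#' Write an expression-style matrix as TSV
#'
#' @param m numeric matrix with row and column names.
#' @param path output path.
#' @param label header name for the gene column.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(m, path, label = "gene") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- label
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
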