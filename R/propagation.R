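#' Network propagation settings
#'
#' Parameters of the insulated-diffusion (random-walk-with-restart) heat
#' propagation used to turn a sample's mutated genes into a network profile.
#' The fixed point solved is `F = alpha * W' F + (1 - alpha) * Y`, with `W'`
#' the symmetrically degree-normalized adjacency and `Y` the 0/1 seed
#' indicator. `scale` multiplies converged heat scores before normalization
#' (default 100,000), keeping tiny diffusion values on a readable scale.
#'
#' @param alpha weight on the network term, in (0, 1); higher spreads heat
#'   further from the seeds (default 0.7).
#' @param tol convergence threshold on the maximum absolute change per
#'   iteration (default 1e-6).
#' @param max_iter iteration cap; non-convergence is warned about.
#' @param scale post-convergence multiplier applied to heat scores.
#' @param seed_norm `"binary"` (0/1 indicator, default) or `"sum1"`
#'   (indicator rescaled to sum to one).
#' @return list of class `propagation_config`.
#' @export
propagation_config <- function(alpha = 0.7, tol = 1e-6, max_iter = 1000L,
                               scale = 1e5, seed_norm = c("binary", "sum1")) {
  stopifnot(alpha > 0, alpha < 1, tol > 0, max_iter >= 1, scale > 0)
  structure(list(alpha = alpha, tol = tol, max_iter = as.integer(max_iter),
                 scale = scale, seed_norm = match.arg(seed_norm)),
            class = "propagation_config")
}

#' Symmetrically normalized adjacency of a network
#'
#' `W' = D^(-1/2) A D^(-1/2)` where `A` is the unweighted adjacency of the
#' network treated as undirected (diffusion ignores edge direction and
#' sign; those matter only to motif analysis) and `D` the degree matrix.
#' Isolated nodes get zero rows and columns.
#'
#' @param net a [signaling_network].
#' @return numeric matrix with dimnames `net$nodes` x `net$nodes`.
#' @export
normalized_adjacency <- function(net) {
  stopifnot(inherits(net, "signaling_network"))
  n <- length(net$nodes)
  A <- matrix(0, n, n, dimnames = list(net$nodes, net$nodes))
  if (nrow(net$edges)) {
    idx <- cbind(match(net$edges$source, net$nodes),
                 match(net$edges$target, net$nodes))
    A[idx] <- 1
    A[idx[, c(2, 1), drop = FALSE]] <- 1
  }
  deg <- rowSums(A)
  d <- ifelse(deg > 0, 1 / sqrt(deg), 0)
  A * outer(d, d)
}

#' Propagate seed heat over a network
#'
#' Iterates `F <- alpha * W' F + (1 - alpha) * Y` from `F = Y` until the
#' maximum absolute change drops below `cfg$tol` (or `cfg$max_iter`, with a
#' warning). The fixed point equals the direct linear solve
#' `(1 - alpha) (I - alpha W')^(-1) Y`. Seeds outside the network are
#' counted and warned about; if no seed maps into the network the heat is
#' identically zero.
#'
#' @param net a [signaling_network] (typically a survival network).
#' @param seeds character vector of seed (mutated) gene symbols.
#' @param cfg a [propagation_config()].
#' @param W optional precomputed [normalized_adjacency()] of `net`.
#' @return named numeric vector of raw (unscaled) heat scores over
#'   `net$nodes`.
#' @export
propagate <- function(net, seeds, cfg = propagation_config(), W = NULL) {
  stopifnot(inherits(net, "signaling_network"))
  if (length(net$nodes) == 0) stop("cannot propagate over an empty network",
                                   call. = FALSE)
  if (is.null(W)) W <- normalized_adjacency(net)
  seeds <- unique(toupper(seeds))
  inside <- intersect(seeds, net$nodes)
  n_out <- length(seeds) - length(inside)
  if (length(seeds) && !length(inside)) {
    warning("no seed maps into the network; heat is identically zero",
            call. = FALSE)
  }
  y <- as.numeric(net$nodes %in% inside)
  if (cfg$seed_norm == "sum1" && sum(y) > 0) y <- y / sum(y)
  f <- y
  restart <- (1 - cfg$alpha) * y
  converged <- FALSE
  for (i in seq_len(cfg$max_iter)) {
    f_new <- cfg$alpha * as.vector(W %*% f) + restart
    if (max(abs(f_new - f)) < cfg$tol) {
      f <- f_new
      converged <- TRUE
      break
    }
    f <- f_new
  }
  if (!converged && sum(y) > 0) {
    warning(sprintf("propagation did not converge in %d iterations", cfg$max_iter),
            call. = FALSE)
  }
  names(f) <- net$nodes
  attr(f, "n_out_of_network_seeds") <- n_out
  f
}

new_network_profiles <- function(m, stage) {
  structure(list(scores = m, stage = stage), class = "network_profiles")
}

#' @export
print.network_profiles <- function(x, ...) {
  cat(sprintf("<network_profiles> %d samples x %d genes, stage = %s\n",
              nrow(x$scores), ncol(x$scores), x$stage))
  invisible(x)
}

#' Compute scaled network profiles for a mutation cohort
#'
#' Runs one propagation per sample, seeding with that sample's missense
#' mutations, and multiplies the converged heat by `cfg$scale`. Rows follow
#' catalog order; columns are the survival-network genes. Samples with no
#' in-network mutation get an all-zero row with a warning.
#'
#' @param net a [signaling_network].
#' @param catalog a `mutation_catalog` from [read_mutations()].
#' @param cfg a [propagation_config()].
#' @return A `network_profiles` object (samples x genes, stage `"scaled"`).
#' @export
profile_cohort <- function(net, catalog, cfg = propagation_config()) {
  if (length(catalog) == 0) stop("mutation catalog is empty", call. = FALSE)
  W <- normalized_adjacency(net)
  empty <- character()
  rows <- lapply(names(catalog), function(s) {
    seeds <- intersect(toupper(catalog[[s]]), net$nodes)
    if (!length(seeds)) {
      empty <<- c(empty, s)
      return(stats::setNames(numeric(length(net$nodes)), net$nodes))
    }
    propagate(net, seeds, cfg, W = W)
  })
  if (length(empty)) {
    warning(sprintf("%d sample(s) have no in-network mutation (all-zero profile): %s",
                    length(empty), paste(utils::head(empty, 5), collapse = ", ")),
            call. = FALSE)
  }
  m <- do.call(rbind, rows) * cfg$scale
  rownames(m) <- names(catalog)
  new_network_profiles(m, "scaled")
}

#' Normalize network profiles across samples
#'
#' Per gene (column): subtract the cross-sample median, then divide by the
#' cross-sample standard deviation. Zero-variance columns become all-zero
#' with a warning. This puts every gene's heat on a comparable
#' between-sample scale before motif-activity calls.
#'
#' @param profiles a `network_profiles` with stage `"scaled"` (or `"raw"`).
#' @return A `network_profiles` with stage `"normalized"`.
#' @export
normalize_profiles <- function(profiles) {
  stopifnot(inherits(profiles, "network_profiles"))
  if (profiles$stage == "normalized") {
    stop("profiles are already normalized", call. = FALSE)
  }
  m <- profiles$scores
  if (nrow(m) < 2) stop("normalization needs at least 2 samples", call. = FALSE)
  med <- apply(m, 2, stats::median)
  sdv <- apply(m, 2, stats::sd)
  flat <- sdv == 0 | is.na(sdv)
  if (any(flat)) {
    warning(sprintf("%d zero-variance gene column(s) set to zero", sum(flat)),
            call. = FALSE)
  }
  sdv[flat] <- 1
  z <- sweep(sweep(m, 2, med, "-"), 2, sdv, "/")
  z[, flat] <- 0
  new_network_profiles(z, "normalized")
}
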