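#' Fit a copy number phylogeny under the ZCNT model
#'
#' The main entry point: infers a phylogeny and ancestral copy number
#' profiles for a matrix of single-cell copy number profiles by (approximate)
#' ZCNT large parsimony. The pipeline computes the pairwise ZCNT distance
#' matrix, builds a neighbor-joining starting tree, improves it by NNI hill
#' climbing scored with the fast unbalanced small-parsimony relaxation, and
#' finally reconstructs balanced ancestral profiles with the 2-approximation
#' (or the exact ILP). With \code{root_at_diploid} a pseudo-leaf carrying
#' the diploid profile is attached before the search, pinning the root
#' state.
#'
#' @param cnm a [cn_matrix()] (or an integer matrix, converted with default
#'   bins) with at least 3 cells.
#' @param config a [search_config()].
#' @param baseline baseline ploidy (default 2).
#' @return An object of class \code{zcnt_phylo} with components
#'   \code{tree} (rooted \code{phylo}, including the \code{"diploid"}
#'   pseudo-leaf when used), \code{fit} (the final \code{zcnt_parsimony}
#'   result), \code{ancestral_cn} (copy-number-space labeling matrix),
#'   \code{nj_tree}, \code{search} (score trace), \code{data},
#'   \code{config}, and \code{call}.
#' @examples
#' sim <- simulate_evolution(simulate_topology(6, seed = 1),
#'                           simulation_config(n_bins = 20), seed = 1)
#' fit <- zcnt_phylo(sim$matrix, search_config(max_rounds = 2))
#' fit
#' @export
zcnt_phylo <- function(cnm, config = search_config(), baseline = 2L) {
  cl <- match.call()
  if (!inherits(cnm, "cn_matrix")) cnm <- cn_matrix(cnm)
  if (nrow(cnm$X) < 3L) stop("need at least 3 cells")
  work <- cnm
  if (config$root_at_diploid) {
    if ("diploid" %in% rownames(cnm$X)) stop("'diploid' is a reserved cell id")
    X <- rbind(work$X, diploid = rep(as.integer(baseline), ncol(work$X)))
    work <- cn_matrix(X, work$bins)
  }
  D <- zcnt_distance_matrix(work, baseline)
  nj <- nj_tree(D)
  hc <- hill_climb(nj, work, config, baseline)
  tree <- hc$tree
  if (config$root_at_diploid)
    tree <- .prep_tree(ape::root(ape::unroot(tree), outgroup = "diploid",
                                 resolve.root = TRUE))
  fit <- switch(config$final_scorer,
                "two-approx" = two_approx_small_parsimony(tree, work, baseline),
                "ilp" = exact_small_parsimony_ilp(tree, work, baseline))
  anc <- labeling_to_cn(fit$labeling, work$bins, baseline)
  structure(list(tree = fit$tree, fit = fit, ancestral_cn = anc,
                 nj_tree = nj, search = hc[c("score_l1", "trace")],
                 data = cnm, config = config, baseline = baseline,
                 call = cl),
            class = "zcnt_phylo")
}

#' @export
print.zcnt_phylo <- function(x, ...) {
  cat("ZCNT copy number phylogeny\n")
  cat("  cells:", nrow(x$data$X), " bins:", ncol(x$data$X),
      " chromosomes:", length(unique(x$data$bins$chrom)), "\n")
  cat(sprintf("  parsimony score: %g events (L1 %g), method %s\n",
              x$fit$score_events, x$fit$score_l1, x$fit$method))
  cat(sprintf("  search: NJ start %g -> final %g (unbalanced L1)\n",
              x$search$trace[1L], x$search$score_l1))
  invisible(x)
}

#' @export
summary.zcnt_phylo <- function(object, ...) {
  viol <- cnt_violation_stats(object$tree, object$ancestral_cn,
                              object$data$bins, object$baseline)
  out <- list(fit = object$fit, search = object$search, violations = viol)
  class(out) <- "summary.zcnt_phylo"
  out
}

#' @export
print.summary.zcnt_phylo <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  accepted-score trace: %s\n",
              paste(x$search$trace, collapse = " -> ")))
  v <- x$violations
  cat(sprintf(paste0("  CNT violations: %d negative stretch(es) ",
                     "(%.3f/edge), min ancestral copy %g,\n",
                     "    %d zero-amplification(s) (%.3f/edge), ",
                     "%.1f%% of score\n"),
              v$negative_stretches, v$negative_stretches_per_edge,
              v$min_ancestral_entry, v$zero_amplifications,
              v$zero_amplifications_per_edge,
              100 * v$violating_score_fraction))
  invisible(x)
}

#' @export
plot.zcnt_phylo <- function(x, ...) {
  ape::plot.phylo(x$tree, ...)
  invisible(x)
}

#' Ancestral copy number profiles of a fit
#'
#' @param fit a [zcnt_phylo()] object.
#' @return Matrix of copy number profiles, one row per tree vertex
#'   (tips first, in \code{tree$tip.label} order, then internal vertices in
#'   \pkg{ape} numbering).
#' @export
ancestral_profiles <- function(fit) {
  stopifnot(inherits(fit, "zcnt_phylo"))
  fit$ancestral_cn
}

#' Simulate new copy number matrices on a fitted phylogeny
#'
#' Parametric resampling: re-runs the CNT event simulator down the fitted
#' topology, with the per-edge event rate estimated from the fitted
#' parsimony score.
#'
#' @param object a [zcnt_phylo()] fit.
#' @param nsim number of replicates.
#' @param seed RNG seed.
#' @param ... unused.
#' @return List of \code{sim_result} objects.
#' @export
simulate.zcnt_phylo <- function(object, nsim = 1L, seed = 0L, ...) {
  tree <- object$tree
  if ("diploid" %in% tree$tip.label) tree <- ape::drop.tip(tree, "diploid")
  tree <- .prep_tree(tree)
  rate <- object$fit$score_events / nrow(tree$edge)
  bins <- object$data$bins
  cfg <- simulation_config(
    n_bins = as.integer(table(bins$chrom)[unique(bins$chrom)[1L]]),
    n_chromosomes = length(unique(bins$chrom)),
    events_per_edge_mean = rate, baseline = object$baseline)
  lapply(seq_len(nsim), function(i)
    simulate_evolution(tree, cfg, seed = seed + i - 1L))
}
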