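#' Simulation configuration
#'
#' Parameters of the ground-truth generator: a diploid root evolves down a
#' random binary tree by interval copy number events applied, by default,
#' under the CNT semantics (zero-copy loci are skipped), so simulated data
#' never violates the CNT model and both models can be compared on it.
#'
#' @param n_bins bins per chromosome.
#' @param n_chromosomes number of chromosomes.
#' @param events_per_edge_mean Poisson mean of the number of events per
#'   tree edge.
#' @param amplification_probability probability an event is an
#'   amplification (+1) rather than a deletion (-1).
#' @param length_distribution \code{"uniform"} (both interval endpoints
#'   uniform over bins) or \code{"geometric"} (geometric interval length,
#'   mimicking focal events).
#' @param geometric_mean_length mean interval length under the geometric
#'   option.
#' @param max_copy_cap optional maximum copy number; events that would
#'   exceed it are rejected (skipped).
#' @param semantics event semantics, \code{"CNT"} (default) or
#'   \code{"ZCNT"}.
#' @param baseline root ploidy.
#' @return A list of class \code{sim_config}.
#' @export
simulation_config <- function(n_bins = 30L, n_chromosomes = 1L,
                              events_per_edge_mean = 3,
                              amplification_probability = 0.5,
                              length_distribution = c("uniform", "geometric"),
                              geometric_mean_length = 5,
                              max_copy_cap = NULL,
                              semantics = c("CNT", "ZCNT"),
                              baseline = 2L) {
  stopifnot(events_per_edge_mean >= 0,
            amplification_probability >= 0, amplification_probability <= 1,
            n_bins >= 1L, n_chromosomes >= 1L)
  structure(list(n_bins = as.integer(n_bins),
                 n_chromosomes = as.integer(n_chromosomes),
                 events_per_edge_mean = events_per_edge_mean,
                 amplification_probability = amplification_probability,
                 length_distribution = match.arg(length_distribution),
                 geometric_mean_length = geometric_mean_length,
                 max_copy_cap = max_copy_cap,
                 semantics = match.arg(semantics),
                 baseline = as.integer(baseline)),
            class = "sim_config")
}

#' Random binary tree topology
#'
#' Builds a rooted binary tree with \code{n} leaves by iterative random
#' pair-joining of lineages, reproducible from a single seed.
#'
#' @param n number of leaves (>= 2).
#' @param seed RNG seed.
#' @param labels optional tip labels, default \code{cell1..celln}.
#' @return A rooted binary \code{phylo} with \code{2n - 2} edges.
#' @export
simulate_topology <- function(n, seed = 0L, labels = paste0("cell", seq_len(n))) {
  if (n < 2L) stop("need at least 2 leaves")
  set.seed(seed)
  clusters <- as.list(labels)
  while (length(clusters) > 1L) {
    pick <- sample.int(length(clusters), 2L)
    merged <- paste0("(", clusters[[pick[1L]]], ",", clusters[[pick[2L]]], ")")
    clusters <- c(clusters[-pick], merged)
  }
  ape::read.tree(text = paste0(clusters[[1L]], ";"))
}

#' Simulate copy number evolution on a tree
#'
#' Starting from an all-diploid root profile, draws a Poisson number of
#' interval events on every edge (uniform chromosome, random interval,
#' amplification with the configured probability) and applies them under
#' the configured semantics. Returns the leaf matrix, the true ancestral
#' profiles, and the event log; replaying the log down the tree reproduces
#' every vertex profile exactly.
#'
#' @param tree a rooted binary \code{phylo} (e.g. from
#'   [simulate_topology()]).
#' @param config a [simulation_config()].
#' @param seed RNG seed.
#' @return List of class \code{sim_result}: \code{matrix} (a
#'   [cn_matrix()] over the leaves), \code{tree}, \code{true_labeling}
#'   (copy-number-space matrix over all vertices), \code{event_log}
#'   (data.frame: edge, parent, child, chrom, s, t, b, applied), and
#'   \code{config}.
#' @export
simulate_evolution <- function(tree, config = simulation_config(), seed = 0L) {
  stopifnot(inherits(tree, "phylo"), ape::is.rooted(tree))
  set.seed(seed)
  m <- config$n_bins * config$n_chromosomes
  bins <- cn_bins(rep(paste0("chr", seq_len(config$n_chromosomes)),
                      each = config$n_bins),
                  rep(seq_len(config$n_bins) - 1L, config$n_chromosomes),
                  rep(seq_len(config$n_bins), config$n_chromosomes))
  ntip <- ape::Ntip(tree)
  N <- ntip + tree$Nnode
  prof <- matrix(NA_integer_, N, m)
  root <- ntip + 1L
  prof[root, ] <- config$baseline
  E <- stats::reorder(tree, "cladewise")$edge   # parents before children
  log <- list()
  for (k in seq_len(nrow(E))) {
    u <- E[k, 1L]; v <- E[k, 2L]
    p <- prof[u, ]
    nev <- stats::rpois(1L, config$events_per_edge_mean)
    for (j in seq_len(nev)) {
      cc <- paste0("chr", sample.int(config$n_chromosomes, 1L))
      if (config$length_distribution == "uniform") {
        st <- sort(sample.int(config$n_bins, 2L, replace = TRUE))
      } else {
        s0 <- sample.int(config$n_bins, 1L)
        len <- 1L + stats::rgeom(1L, 1 / config$geometric_mean_length)
        st <- c(s0, min(config$n_bins, s0 + len - 1L))
      }
      b <- if (stats::runif(1L) < config$amplification_probability) 1L else -1L
      ev <- event_record(cc, st[1L], st[2L], b)
      cand <- if (config$semantics == "CNT") apply_cnt_event(p, ev, bins)
              else apply_zcnt_event(p, ev, bins)
      applied <- TRUE
      if (!is.null(config$max_copy_cap) && max(cand) > config$max_copy_cap)
        applied <- FALSE
      if (config$semantics == "ZCNT" && min(cand) < 0L) applied <- FALSE
      if (applied) p <- cand
      log[[length(log) + 1L]] <- data.frame(
        edge = k, parent = u, child = v, chrom = cc,
        s = st[1L], t = st[2L], b = b, applied = applied)
    }
    prof[v, ] <- p
  }
  X <- prof[seq_len(ntip), , drop = FALSE]
  rownames(X) <- tree$tip.label
  structure(list(matrix = cn_matrix(X, bins), tree = tree,
                 true_labeling = prof,
                 event_log = if (length(log)) do.call(rbind, log) else
                   data.frame(edge = integer(), parent = integer(),
                              child = integer(), chrom = character(),
                              s = integer(), t = integer(), b = integer(),
                              applied = logical()),
                 config = config, seed = seed),
            class = "sim_result")
}

#' Enumerate all copy number profiles at toy scale
#'
#' Lexicographic, duplicate-free enumeration of all \code{(B+1)^m} profiles
#' of \code{m} loci with entries \code{0..B}; oracle support for exhaustive
#' tests.
#'
#' @param m number of loci.
#' @param B maximum copy number.
#' @return Integer matrix with \code{(B+1)^m} rows.
#' @export
enumerate_profiles <- function(m, B) {
  if ((B + 1)^m > 1e6) stop("enumeration guard exceeded: (B+1)^m > 1e6")
  r <- 0:((B + 1)^m - 1)
  out <- vapply(seq_len(m),
                function(j) (r %/% (B + 1)^(m - j)) %% (B + 1),
                numeric(length(r)))
  matrix(as.integer(out), ncol = m)
}
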