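# ---- neighbor joining -------------------------------------------------------

#' Neighbor joining on a distance matrix
#'
#' Standard Saitou-Nei neighbor joining (via \pkg{ape}), with input
#' validation: the matrix must be symmetric with a zero diagonal.
#'
#' @param D symmetric distance matrix with labels as dimnames (e.g. from
#'   [zcnt_distance_matrix()]).
#' @return An unrooted \code{phylo}.
#' @export
nj_tree <- function(D) {
  D <- as.matrix(D)
  if (nrow(D) < 3L) stop("neighbor joining needs at least 3 taxa")
  if (any(abs(D - t(D)) > 1e-9)) stop("distance matrix is not symmetric")
  if (any(abs(diag(D)) > 1e-9)) stop("distance matrix has nonzero diagonal")
  ape::nj(D)
}

# ---- NNI moves --------------------------------------------------------------

#' Internal edges of a tree
#'
#' Works on the unrooted representation (a rooted input is unrooted
#' first), where every edge between two internal vertices is a genuine
#' internal edge; an unrooted binary tree with \code{n} leaves has
#' \code{n - 3} of them.
#'
#' @param tree a \code{phylo}.
#' @return Integer vector of row indices into \code{ape::unroot(tree)$edge}
#'   whose child endpoint is an internal vertex.
#' @export
internal_edges <- function(tree) {
  tree <- ape::unroot(tree)
  which(tree$edge[, 2L] > ape::Ntip(tree))
}

#' Nearest-neighbor-interchange neighbors across one internal edge
#'
#' Returns the two alternative topologies obtained by swapping one subtree
#' pair across the given internal edge. Applying the same move twice
#' returns the original topology; an unrooted binary tree with \code{n}
#' leaves has \code{n - 3} internal edges and hence \code{2(n - 3)} NNI
#' neighbors.
#'
#' @param tree a binary \code{phylo}; a rooted input is unrooted first.
#' @param edge row index into \code{ape::unroot(tree)$edge}, as returned by
#'   [internal_edges()]; must be an internal edge.
#' @return List of two unrooted \code{phylo} trees.
#' @export
nni_neighbors <- function(tree, edge) {
  tree <- ape::unroot(tree)
  ntip <- ape::Ntip(tree)
  E <- tree$edge
  p <- E[edge, 1L]; ch <- E[edge, 2L]
  if (ch <= ntip) stop("pendant edge: NNI requires an internal edge")
  kids <- which(E[, 1L] == ch)             # edges ch -> c1, c2
  sibs <- setdiff(which(E[, 1L] == p), edge)
  if (length(sibs) == 0L) stop("edge has no sibling subtree to exchange")
  s <- sibs[1L]                            # one fixed subtree on p's side
  lapply(kids[1:2], function(k) {
    t2 <- tree
    t2$edge[k, 1L] <- p                    # child subtree moves up to p
    t2$edge[s, 1L] <- ch                   # sibling subtree moves down
    t2 <- stats::reorder(t2, "cladewise")
    t2
  })
}

#' All NNI neighbors of a tree
#'
#' @param tree a binary \code{phylo}.
#' @return List of \code{phylo} trees (two per internal edge).
#' @export
all_nni_neighbors <- function(tree) {
  unlist(lapply(internal_edges(tree), function(e) nni_neighbors(tree, e)),
         recursive = FALSE)
}

# ---- hill climbing ----------------------------------------------------------

#' Search configuration for large parsimony
#'
#' @param seed RNG seed driving perturbations.
#' @param max_rounds number of perturb-and-reclimb rounds after the first
#'   climb converges.
#' @param perturbation_strength random-walk length as a fraction of the
#'   leaf count.
#' @param improvement \code{"best"} (evaluate the whole NNI neighborhood,
#'   take the best improving move) or \code{"first"} (take the first
#'   improving move).
#' @param root_at_diploid pin the root label to the diploid profile by
#'   attaching a \code{"diploid"} pseudo-leaf before search.
#' @param final_scorer method for the final ancestral labeling:
#'   \code{"two-approx"} or \code{"ilp"}.
#' @return A list of class \code{search_config}.
#' @export
search_config <- function(seed = 0L, max_rounds = 50L,
                          perturbation_strength = 0.2,
                          improvement = c("best", "first"),
                          root_at_diploid = FALSE,
                          final_scorer = c("two-approx", "ilp")) {
  stopifnot(perturbation_strength >= 0, perturbation_strength <= 1,
            max_rounds >= 0)
  structure(list(seed = as.integer(seed), max_rounds = as.integer(max_rounds),
                 perturbation_strength = perturbation_strength,
                 improvement = match.arg(improvement),
                 root_at_diploid = root_at_diploid,
                 final_scorer = match.arg(final_scorer)),
            class = "search_config")
}

.climb_once <- function(tree, cnm, baseline, improvement) {
  cur <- tree
  cur_score <- unbalanced_small_parsimony(cur, cnm, baseline)$score_l1
  trace <- cur_score
  repeat {
    improved <- FALSE
    best_tree <- NULL; best_score <- cur_score
    for (e in internal_edges(cur)) {
      for (t2 in nni_neighbors(cur, e)) {
        s2 <- unbalanced_small_parsimony(t2, cnm, baseline)$score_l1
        if (s2 < best_score - 1e-9) {
          best_score <- s2; best_tree <- t2; improved <- TRUE
          if (improvement == "first") break
        }
      }
      if (improved && improvement == "first") break
    }
    if (!improved) break
    cur <- best_tree; cur_score <- best_score
    trace <- c(trace, cur_score)
  }
  list(tree = cur, score = cur_score, trace = trace)
}

.random_walk <- function(tree, steps) {
  for (i in seq_len(steps)) {
    ie <- internal_edges(tree)
    if (length(ie) == 0L) break
    e <- ie[sample.int(length(ie), 1L)]
    nb <- nni_neighbors(tree, e)
    tree <- nb[[sample.int(2L, 1L)]]
  }
  tree
}

#' NNI hill climbing with stochastic restarts
#'
#' Iteratively applies improving nearest-neighbor interchanges, scored by
#' the fast unbalanced small-parsimony relaxation, until no improving move
#' exists; then repeatedly perturbs the best tree by a short random NNI
#' walk and re-climbs, keeping the best tree seen. The accepted-score trace
#' is non-increasing and the whole search is reproducible from the
#' configuration seed.
#'
#' @param tree starting \code{phylo} over the matrix cells (e.g. an NJ
#'   tree).
#' @param cnm a [cn_matrix()].
#' @param config a [search_config()].
#' @param baseline baseline ploidy.
#' @return List with \code{tree}, \code{score_l1}, and \code{trace} (the
#'   accepted unbalanced L1 scores, including the starting tree's).
#' @export
hill_climb <- function(tree, cnm, config = search_config(), baseline = 2L) {
  set.seed(config$seed)
  tree <- ape::unroot(tree)
  res <- .climb_once(tree, cnm, baseline, config$improvement)
  best <- res; trace <- res$trace
  steps <- ceiling(config$perturbation_strength * ape::Ntip(tree))
  if (steps > 0L) {
    for (r in seq_len(config$max_rounds)) {
      pert <- .random_walk(best$tree, steps)
      res <- .climb_once(pert, cnm, baseline, config$improvement)
      if (res$score < best$score - 1e-9) {
        best <- res
        trace <- c(trace, res$score)
      }
    }
  }
  list(tree = best$tree, score_l1 = best$score, trace = trace)
}
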