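# ---- tree helpers -----------------------------------------------------------

# A rooted, binary working copy of a tree: polytomies are resolved
# deterministically (this never increases the unbalanced optimum) and
# unrooted trees are rooted by the resolution.
.prep_tree <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (!ape::is.binary(tree) || !ape::is.rooted(tree))
    tree <- ape::multi2di(tree, random = FALSE)
  if (ape::Ntip(tree) < 2L) stop("tree must have at least two leaves")
  tree
}

.leaf_delta <- function(tree, cnm, baseline) {
  Q <- delta_transform(cnm, baseline)
  miss <- setdiff(tree$tip.label, rownames(Q))
  if (length(miss)) stop("leaf without data: ", paste(miss, collapse = ", "))
  Q[match(tree$tip.label, rownames(Q)), , drop = FALSE]
}

.parsimony_result <- function(method, tree, labeling, score_l1,
                              extra = list()) {
  structure(c(list(method = method, tree = tree, labeling = labeling,
                   score_l1 = score_l1, score_events = score_l1 / 2),
              extra),
            class = "zcnt_parsimony")
}

#' @export
print.zcnt_parsimony <- function(x, ...) {
  cat(sprintf("ZCNT small parsimony [%s]: %g events (L1 score %g) on %d leaves\n",
              x$method, x$score_events, x$score_l1, ape::Ntip(x$tree)))
  invisible(x)
}

# ---- unbalanced relaxation --------------------------------------------------

#' Small parsimony without the balancing condition
#'
#' Solves the ZCNT small parsimony problem exactly when the balancing
#' condition on ancestral delta profiles is dropped. Coordinates decouple,
#' and each per-coordinate problem is an L1 labeling on the tree solved by
#' interval message passing: bottom up, a vertex's minimizer interval is
#' the intersection of its children's intervals when they overlap and
#' otherwise the gap between them, whose length is added to the cost; top
#' down, each vertex takes the interval value nearest its parent's
#' assignment (the root takes the value nearest zero, i.e. nearest the
#' diploid delta). Runs in O(mn) up to sorting factors.
#'
#' The returned labeling is integer but its internal vertices need not be
#' balanced; its score is a lower bound on the balanced optimum.
#'
#' @param tree a rooted or unrooted \code{phylo}; polytomies are resolved
#'   deterministically (the returned result carries the resolved tree).
#' @param cnm a [cn_matrix()] whose cell ids cover the tree's tip labels.
#' @param baseline baseline ploidy.
#' @return A \code{zcnt_parsimony} result: method tag, resolved tree,
#'   delta-space labeling matrix (rows indexed by tree vertex id), and the
#'   score in L1 and event units.
#' @export
unbalanced_small_parsimony <- function(tree, cnm, baseline = 2L) {
  tree <- .prep_tree(tree)
  Q <- .leaf_delta(tree, cnm, baseline)
  lay <- .seg_layout(cnm$bins)
  ntip <- ape::Ntip(tree)
  N <- ntip + tree$Nnode
  D <- ncol(Q)
  lo <- hi <- matrix(NA_real_, N, D)
  lo[seq_len(ntip), ] <- hi[seq_len(ntip), ] <- Q
  po <- stats::reorder(tree, "postorder")$edge
  cost <- numeric(D)
  # parents in order of last occurrence: all subtree edges precede it
  for (v in po[, 1L][!duplicated(po[, 1L], fromLast = TRUE)]) {
    ch <- po[po[, 1L] == v, 2L]
    if (length(ch) != 2L) stop("internal error: tree not binary")
    a <- pmax(lo[ch[1L], ], lo[ch[2L], ])
    b <- pmin(hi[ch[1L], ], hi[ch[2L], ])
    cost <- cost + pmax(a - b, 0)
    lo[v, ] <- pmin(a, b)
    hi[v, ] <- pmax(a, b)
  }
  x <- matrix(NA_real_, N, D)
  root <- ntip + 1L
  x[root, ] <- pmin(pmax(0, lo[root, ]), hi[root, ])
  for (k in rev(seq_len(nrow(po)))) {        # parents before children
    v <- po[k, 1L]; ch <- po[k, 2L]
    x[ch, ] <- pmin(pmax(x[v, ], lo[ch, ]), hi[ch, ])
  }
  lab <- structure(x, seg = lay$seg, space = "delta")
  .parsimony_result("unbalanced", tree, lab, sum(cost))
}

# ---- scoring, discrepancy, repair ------------------------------------------

#' Score a vertex labeling
#'
#' Sums the per-edge L1 distances of a delta-space labeling over the tree,
#' and reports the total-discrepancy lower bound: any labeling that agrees
#' with the leaves has L1 score at least the summed absolute vertex
#' discrepancies.
#'
#' @param tree a \code{phylo} whose vertex ids index the labeling rows.
#' @param labeling matrix of delta vectors, one row per tree vertex, with a
#'   \code{"seg"} attribute as produced by the solvers.
#' @return A \code{zcnt_parsimony} result with an extra element
#'   \code{lower_bound_disc}.
#' @export
parsimony_score <- function(tree, labeling) {
  e <- tree$edge
  score <- sum(abs(labeling[e[, 1L], , drop = FALSE] -
                     labeling[e[, 2L], , drop = FALSE]))
  lbd <- sum(abs(vertex_discrepancy(labeling)))
  .parsimony_result("rescore", tree, labeling, score,
                    list(lower_bound_disc = lbd))
}

#' Per-vertex, per-chromosome discrepancy of a labeling
#'
#' The discrepancy of a delta vector is the sum of its entries within a
#' chromosome segment; it is zero exactly when the segment is balanced.
#' Leaf labels are delta maps of observed profiles and always have zero
#' discrepancy.
#'
#' @param labeling delta-space labeling matrix with a \code{"seg"} attribute.
#' @return Matrix: vertices x chromosomes of discrepancies.
#' @export
vertex_discrepancy <- function(labeling) {
  seg <- attr(labeling, "seg")
  if (is.null(seg)) stop("labeling lacks a 'seg' attribute")
  chroms <- unique(seg)
  out <- sapply(chroms, function(cc)
    rowSums(labeling[, seg == cc, drop = FALSE]))
  out <- matrix(out, nrow = nrow(labeling),
                dimnames = list(NULL, chroms))
  out
}

#' Repair an unbalanced labeling
#'
#' Restores the balancing condition at every vertex by subtracting each
#' vertex's per-chromosome discrepancy from the final (right telomere)
#' delta coordinate of that chromosome. The per-edge cost increase is at
#' most \eqn{|disc(u) - disc(v)| \le \lVert \ell(u)-\ell(v)\rVert_1}, so
#' the repaired cost is at most twice the input cost. Already-balanced
#' vertices (all leaves in particular) are unchanged.
#'
#' @param labeling delta-space labeling matrix with a \code{"seg"} attribute.
#' @return The balanced labeling matrix.
#' @export
repair_balancing <- function(labeling) {
  seg <- attr(labeling, "seg")
  if (is.null(seg)) stop("labeling lacks a 'seg' attribute")
  for (cc in unique(seg)) {
    idx <- which(seg == cc)
    last <- idx[length(idx)]
    labeling[, last] <- labeling[, last] -
      rowSums(labeling[, idx, drop = FALSE])
  }
  labeling
}

#' Linear-time 2-approximation for ZCNT small parsimony
#'
#' Runs the unbalanced relaxation and repairs its labeling to satisfy the
#' balancing condition. Since the unbalanced optimum lower-bounds the
#' balanced optimum and the repair at most doubles the cost, the returned
#' feasible labeling scores within a factor 2 of the optimum.
#'
#' @inheritParams unbalanced_small_parsimony
#' @return A \code{zcnt_parsimony} result (method \code{"two-approx"}) with
#'   extra element \code{unbalanced_score_l1}.
#' @export
two_approx_small_parsimony <- function(tree, cnm, baseline = 2L) {
  ub <- unbalanced_small_parsimony(tree, cnm, baseline)
  lab <- repair_balancing(ub$labeling)
  sc <- parsimony_score(ub$tree, lab)
  .parsimony_result("two-approx", ub$tree, lab, sc$score_l1,
                    list(unbalanced_score_l1 = ub$score_l1))
}

# ---- event decomposition and CNT-violation accounting -----------------------

#' Canonical minimum-length event decomposition of an edge
#'
#' Produces exactly \code{zcnt_distance(parent, child)} interval events
#' whose composition transforms the parent profile into the child profile.
#' Per chromosome the difference of delta profiles is expanded into unit
#' charges; positive and negative charges are paired left to right in
#' position order, each pair emitting an amplification when the positive
#' charge comes first and a deletion otherwise. Amplifications are
#' scheduled before deletions, which guarantees no intermediate profile
#' dips below the running minimum unnecessarily.
#'
#' @param parent,child copy number profiles on the same bins.
#' @param bins shared bin table.
#' @param baseline baseline ploidy.
#' @return data.frame with columns \code{chrom, s, t, b} (amplifications
#'   first); zero rows when the profiles are equal.
#' @export
canonical_event_decomposition <- function(parent, child,
                                          bins = uniform_bins(length(parent)),
                                          baseline = 2L) {
  if (length(parent) != length(child)) stop("profiles have mismatched bins")
  lay <- .seg_layout(bins)
  w <- delta_map(child, bins, baseline) - delta_map(parent, bins, baseline)
  out <- list()
  for (i in seq_along(lay$chroms)) {
    wc <- w[lay$d_start[i] + seq_len(lay$d_per_chrom[i]) - 1L]
    plus <- rep(which(wc > 0), wc[wc > 0])
    minus <- rep(which(wc < 0), -wc[wc < 0])
    if (length(plus) == 0L) next
    amp <- plus < minus
    out[[i]] <- data.frame(
      chrom = lay$chroms[i],
      s = ifelse(amp, plus, minus),
      t = ifelse(amp, minus, plus) - 1L,
      b = ifelse(amp, 1L, -1L))
  }
  ev <- if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(), s = integer(), t = integer(),
               b = integer())
  ev[order(-ev$b), , drop = FALSE]
}

#' CNT-violation statistics of an ancestral labeling
#'
#' Quantifies how far a ZCNT ancestral labeling strays from the stricter
#' CNT model: (a) the number of negative stretches (maximal runs of
#' consecutive negative entries within a chromosome) across ancestral
#' profiles, normalized by the number of edges; (b) the minimum ancestral
#' copy number; (c) the number of amplification events in the canonical
#' per-edge decomposition (amplifications replayed first) that cover at
#' least one locus whose current value is at most zero, normalized by the
#' number of edges; (d) the fraction of the parsimony score attributable to
#' those violating events.
#'
#' @param tree a \code{phylo} whose vertex ids index the labeling rows.
#' @param labeling_cn copy-number-space labeling matrix (rows = tree
#'   vertices, columns = bins); delta labelings must be inverted first via
#'   [inverse_delta_map()].
#' @param bins bin table.
#' @param baseline baseline ploidy.
#' @return List with elements \code{negative_stretches},
#'   \code{negative_stretches_per_edge}, \code{min_ancestral_entry},
#'   \code{zero_amplifications}, \code{zero_amplifications_per_edge},
#'   \code{violating_score_fraction}, \code{total_events}.
#' @export
cnt_violation_stats <- function(tree, labeling_cn,
                                bins = uniform_bins(ncol(labeling_cn)),
                                baseline = 2L) {
  ntip <- ape::Ntip(tree)
  N <- ntip + tree$Nnode
  stopifnot(nrow(labeling_cn) == N)
  internal <- (ntip + 1L):N
  neg_stretch <- 0L
  for (v in internal) {
    for (cc in unique(bins$chrom)) {
      r <- rle(labeling_cn[v, bins$chrom == cc] < 0)
      neg_stretch <- neg_stretch + sum(r$values)
    }
  }
  nE <- nrow(tree$edge)
  zero_amp <- 0L; total_ev <- 0L
  for (k in seq_len(nE)) {
    u <- tree$edge[k, 1L]; v <- tree$edge[k, 2L]
    ev <- canonical_event_decomposition(labeling_cn[u, ], labeling_cn[v, ],
                                        bins, baseline)
    total_ev <- total_ev + nrow(ev)
    cur <- labeling_cn[u, ]
    for (j in seq_len(nrow(ev))) {
      e <- event_record(ev$chrom[j], ev$s[j], ev$t[j], ev$b[j])
      if (e$b > 0L && any(cur[.event_global_idx(e, bins)] <= 0)) {
        zero_amp <- zero_amp + 1L
      }
      cur <- apply_zcnt_event(cur, e, bins)
    }
  }
  list(negative_stretches = neg_stretch,
       negative_stretches_per_edge = neg_stretch / nE,
       min_ancestral_entry = min(labeling_cn[internal, , drop = FALSE]),
       zero_amplifications = zero_amp,
       zero_amplifications_per_edge = zero_amp / nE,
       violating_score_fraction = if (total_ev > 0) zero_amp / total_ev else 0,
       total_events = total_ev)
}

#' Invert a delta-space labeling to copy number space
#'
#' @param labeling delta-space labeling matrix with a \code{"seg"} attribute.
#' @param bins bin table matching the segment layout.
#' @param baseline baseline ploidy.
#' @return Matrix of copy number profiles, one row per vertex.
#' @export
labeling_to_cn <- function(labeling, bins, baseline = 2L) {
  t(apply(labeling, 1L, inverse_delta_map, bins = bins, baseline = baseline))
}
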