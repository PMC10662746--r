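# non-trivial unrooted splits of a tree, as canonical label-set keys
.tree_splits <- function(tree, drop = "diploid") {
  drop <- intersect(drop, tree$tip.label)
  if (length(drop)) tree <- ape::drop.tip(tree, drop)
  tips <- sort(tree$tip.label)
  ntip <- ape::Ntip(tree)
  if (ntip < 4L) return(character(0))
  ref <- tips[1L]
  po <- stats::reorder(tree, "postorder")$edge
  below <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(ntip)) below[[i]] <- tree$tip.label[i]
  keys <- character(0)
  for (k in seq_len(nrow(po))) {
    v <- po[k, 2L]
    if (v > ntip) {
      ch <- po[po[, 1L] == v, 2L]
      below[[v]] <- unlist(below[ch])
    }
    side <- below[[po[k, 2L]]]
    if (length(side) >= 2L && length(side) <= ntip - 2L) {
      if (ref %in% side) side <- setdiff(tips, side)
      keys <- c(keys, paste(sort(side), collapse = "|"))
    }
  }
  unique(keys)
}

#' Robinson-Foulds distance between two trees
#'
#' Counts the non-trivial unrooted splits present in exactly one of the two
#' trees. The normalized form divides by the total number of non-trivial
#' splits in both trees, so partially unresolved (multifurcating) trees
#' normalize correctly and the value lies in \code{[0, 1]}. Rooted inputs
#' are compared unrooted; a tip named \code{"diploid"} (the rooting
#' pseudo-leaf) is dropped first.
#'
#' @param t1,t2 \code{phylo} trees on the same leaf set.
#' @param normalized return the normalized distance?
#' @param drop tip labels to drop before comparison.
#' @return A number: the split count, or the normalized distance.
#' @export
rf_distance <- function(t1, t2, normalized = FALSE, drop = "diploid") {
  l1 <- setdiff(t1$tip.label, drop); l2 <- setdiff(t2$tip.label, drop)
  if (!setequal(l1, l2)) stop("trees have different leaf sets")
  s1 <- .tree_splits(t1, drop); s2 <- .tree_splits(t2, drop)
  raw <- length(setdiff(s1, s2)) + length(setdiff(s2, s1))
  if (!normalized) return(raw)
  denom <- length(s1) + length(s2)
  if (denom == 0L) 0 else raw / denom
}

#' Sibling dissimilarity of leaf pairs
#'
#' Over all unordered pairs of leaf children sharing a parent (all pairs
#' under polytomies), the Hamming distance between the two cells' copy
#' number profiles divided by the number of bins. Low values indicate that
#' the tree places nearly identical cells together.
#'
#' @param tree a \code{phylo}; a \code{"diploid"} pseudo-leaf is ignored.
#' @param cnm a [cn_matrix()] covering the tree's tips.
#' @return List with \code{mean} and \code{per_pair} (data.frame of sibling
#'   pairs and their normalized Hamming distances); zero-row result with
#'   \code{mean = NA} when the tree has no sibling leaf pair.
#' @export
sibling_dissimilarity <- function(tree, cnm) {
  stopifnot(inherits(cnm, "cn_matrix"))
  ntip <- ape::Ntip(tree)
  m <- ncol(cnm$X)
  pairs <- list()
  for (v in (ntip + 1L):(ntip + tree$Nnode)) {
    ch <- tree$edge[tree$edge[, 1L] == v, 2L]
    kids <- ch[ch <= ntip]
    kids <- kids[tree$tip.label[kids] != "diploid"]
    if (length(kids) >= 2L) {
      cmb <- utils::combn(kids, 2L)
      for (j in seq_len(ncol(cmb))) {
        a <- tree$tip.label[cmb[1L, j]]; b <- tree$tip.label[cmb[2L, j]]
        pairs[[length(pairs) + 1L]] <- data.frame(
          cell1 = a, cell2 = b,
          dissimilarity = mean(cnm$X[a, ] != cnm$X[b, ]))
      }
    }
  }
  if (length(pairs) == 0L)
    return(list(mean = NA_real_,
                per_pair = data.frame(cell1 = character(),
                                      cell2 = character(),
                                      dissimilarity = numeric())))
  pp <- do.call(rbind, pairs)
  list(mean = mean(pp$dissimilarity), per_pair = pp)
}

#' Clonal discordance of a tree with respect to clone labels
#'
#' The minimum number of clone-label changes over the edges of the tree:
#' single multi-state character parsimony, computed with the Hartigan
#' bottom-up procedure, which is exact on arbitrary (including
#' multifurcating) trees. When every clone forms a clade the score attains
#' its minimum \code{k - 1} for \code{k} distinct labels.
#'
#' @param tree a \code{phylo}; a \code{"diploid"} pseudo-leaf is dropped.
#' @param clones named character vector mapping every cell (tip label) to a
#'   clone label.
#' @return Integer discordance score.
#' @export
clonal_discordance <- function(tree, clones) {
  if ("diploid" %in% tree$tip.label && !("diploid" %in% names(clones)))
    tree <- ape::drop.tip(tree, "diploid")
  miss <- setdiff(tree$tip.label, names(clones))
  if (length(miss)) stop("unlabeled leaf: ", paste(miss, collapse = ", "))
  states <- sort(unique(as.character(clones[tree$tip.label])))
  ntip <- ape::Ntip(tree)
  N <- ntip + tree$Nnode
  topset <- vector("list", N)
  for (i in seq_len(ntip))
    topset[[i]] <- as.character(clones[tree$tip.label[i]])
  po <- stats::reorder(tree, "postorder")$edge
  cost <- 0L
  for (v in po[, 1L][!duplicated(po[, 1L], fromLast = TRUE)]) {
    ch <- po[po[, 1L] == v, 2L]
    # Hartigan: each child whose top set misses the chosen state costs one
    # change; the best states are those appearing in most children's sets
    votes <- vapply(states, function(s)
      sum(vapply(ch, function(c0) s %in% topset[[c0]], logical(1))),
      integer(1))
    best <- max(votes)
    topset[[v]] <- states[votes == best]
    cost <- cost + length(ch) - best
  }
  cost
}
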