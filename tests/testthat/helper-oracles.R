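# Independent brute-force oracles used across the test suite. These
# deliberately avoid the package's solver code paths: enumeration plus
# naive minimization only.

# random copy number profile
rand_profile <- function(m, B) sample(0:B, m, replace = TRUE)

# exact unbalanced small-parsimony optimum by per-coordinate enumeration of
# all integer internal labels within the coordinate-wise leaf range
bf_unbalanced_score <- function(tree, Qleaf) {
  ntip <- ape::Ntip(tree)
  N <- ntip + tree$Nnode
  internal <- (ntip + 1L):N
  E <- tree$edge
  total <- 0
  for (j in seq_len(ncol(Qleaf))) {
    vals <- seq(min(Qleaf[, j]), max(Qleaf[, j]))
    grid <- as.matrix(expand.grid(rep(list(vals), length(internal))))
    lab <- numeric(N)
    lab[seq_len(ntip)] <- Qleaf[, j]
    best <- Inf
    for (g in seq_len(nrow(grid))) {
      lab[internal] <- grid[g, ]
      best <- min(best, sum(abs(lab[E[, 1L]] - lab[E[, 2L]])))
    }
    total <- total + best
  }
  total
}

# all balanced integer delta vectors of length L with entries in [lo, hi]
balanced_states <- function(L, lo, hi) {
  g <- as.matrix(expand.grid(rep(list(lo:hi), L - 1L)))
  last <- -rowSums(g)
  keep <- last >= lo & last <= hi
  unname(cbind(g[keep, , drop = FALSE], last[keep]))
}

# exact balanced small-parsimony optimum by Sankoff DP over an explicit
# finite state space of balanced delta vectors (single chromosome)
bf_balanced_score <- function(tree, Qleaf, lo = -4L, hi = 4L) {
  S <- balanced_states(ncol(Qleaf), lo, hi)
  Dmat <- as.matrix(dist(S, method = "manhattan"))
  ntip <- ape::Ntip(tree)
  key <- apply(S, 1L, paste, collapse = ",")
  leaf_state <- match(apply(Qleaf, 1L, paste, collapse = ","), key)
  stopifnot(!any(is.na(leaf_state)))
  N <- ntip + tree$Nnode
  cost <- matrix(Inf, N, nrow(S))
  for (i in seq_len(ntip)) {
    cost[i, ] <- Inf
    cost[i, leaf_state[i]] <- 0
  }
  po <- reorder(tree, "postorder")$edge
  for (v in po[, 1L][!duplicated(po[, 1L], fromLast = TRUE)]) {
    ch <- po[po[, 1L] == v, 2L]
    acc <- 0
    for (c0 in ch) {
      # min over child state of (cost + transition)
      acc <- acc + apply(sweep(Dmat, 1L, cost[c0, ], "+"), 2L, min)
    }
    cost[v, ] <- acc
  }
  min(cost[ntip + 1L, ])
}

# brute-force ZCNT median over balanced delta vectors in a box
bf_median_events <- function(X, lo, hi, baseline = 2L) {
  Q <- t(apply(X, 1L, zcnt::delta_map, baseline = baseline))
  S <- balanced_states(ncol(Q), lo, hi)
  tot <- apply(S, 1L, function(s) sum(abs(sweep(Q, 2L, s))))
  min(tot) / 2
}

# brute-force clonal discordance: minimize label changes over all internal
# label assignments
bf_discordance <- function(tree, clones) {
  states <- unique(as.character(clones))
  ntip <- ape::Ntip(tree)
  N <- ntip + tree$Nnode
  internal <- (ntip + 1L):N
  E <- tree$edge
  lab <- character(N)
  lab[seq_len(ntip)] <- as.character(clones[tree$tip.label])
  grid <- expand.grid(rep(list(states), length(internal)),
                      stringsAsFactors = FALSE)
  best <- Inf
  for (g in seq_len(nrow(grid))) {
    lab[internal] <- unlist(grid[g, ])
    best <- min(best, sum(lab[E[, 1L]] != lab[E[, 2L]]))
  }
  best
}

# all rooted binary topologies over the given tip labels (tiny n only),
# via recursive enumeration of sibling pairs
all_topologies <- function(tips) {
  if (length(tips) == 1L) return(tips)
  out <- character(0)
  n <- length(tips)
  # enumerate by splitting the tip set into two non-empty halves, first tip
  # always in the left half to avoid double counting
  idx <- seq_len(n - 1L) + 1L
  for (k in seq_len(n - 1L)) {
    for (right in utils::combn(idx, k, simplify = FALSE)) {
      left <- setdiff(seq_len(n), right)
      lsub <- all_topologies(tips[left])
      rsub <- all_topologies(tips[right])
      for (a in lsub) for (b in rsub)
        out <- c(out, paste0("(", a, ",", b, ")"))
    }
  }
  out
}

rooted_topologies <- function(tips) {
  unique(paste0(all_topologies(tips), ";"))
}
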