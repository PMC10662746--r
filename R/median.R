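#' ZCNT median of a set of copy number profiles
#'
#' Finds a profile minimizing the total ZCNT distance to \code{n} input
#' profiles, by dynamic programming in delta space. Per chromosome the
#' table \code{A[j, k]} holds the minimal summed L1 cost of a length-j
#' delta prefix with discrepancy (entry sum) \code{k}; the recurrence
#' ranges the next entry over \code{-B..B} (B the maximum input copy
#' number, widened to cover the leaf delta range) and the answer is
#' \code{A[L, 0]}, the balanced completion. Boundary: \code{A[0, 0] = 0}
#' and \code{A[0, k] = Inf} otherwise — the empty prefix has discrepancy
#' zero. Ties among entries are broken toward the value nearest zero
#' (nearest the diploid delta). Runs in O(n m^2 B^2) per chromosome.
#'
#' For two profiles the minimum equals their pairwise ZCNT distance and is
#' attained by either input.
#'
#' @param profiles a [cn_matrix()], or a list of integer profile vectors on
#'   shared bins.
#' @param bins bin table (ignored when \code{profiles} is a
#'   \code{cn_matrix}).
#' @param baseline baseline ploidy.
#' @return List with \code{median} (copy number profile),
#'   \code{total_distance_events} (sum of ZCNT distances from the median to
#'   all inputs), and \code{total_distance_l1} (twice that).
#' @export
zcnt_median <- function(profiles, bins = NULL, baseline = 2L) {
  if (inherits(profiles, "cn_matrix")) {
    bins <- profiles$bins
    X <- profiles$X
  } else {
    if (length(profiles) < 1L) stop("need at least one profile")
    X <- do.call(rbind, lapply(profiles, as.numeric))
    if (is.null(bins)) bins <- uniform_bins(ncol(X))
  }
  lay <- .seg_layout(bins)
  n <- nrow(X)
  Q <- t(apply(X, 1L, delta_map, bins = bins, baseline = baseline))
  if (n == 1L) Q <- matrix(Q, nrow = 1L)
  B <- max(abs(Q), max(X), 1)
  med_q <- numeric(lay$D)
  total <- 0
  brange <- seq(-B, B)
  bord <- brange[order(abs(brange), brange)]   # ties toward zero
  for (i in seq_along(lay$chroms)) {
    cols <- lay$d_start[i] + seq_len(lay$d_per_chrom[i]) - 1L
    Qc <- Q[, cols, drop = FALSE]
    L <- length(cols)
    koff <- B * L + 1L                          # k index offset: k in -BL..BL
    nk <- 2L * B * L + 1L
    A <- rep(Inf, nk); A[koff] <- 0
    choice <- matrix(NA_integer_, L, nk)
    for (j in seq_len(L)) {
      cost_b <- vapply(bord, function(b) sum(abs(b - Qc[, j])), numeric(1))
      Anew <- rep(Inf, nk)
      for (bi in seq_along(bord)) {
        b <- bord[bi]
        # A[j, k] candidate from A[j-1, k - b]
        ks <- seq_len(nk)
        prev <- ks - b
        valid <- prev >= 1L & prev <= nk
        cand <- rep(Inf, nk)
        cand[valid] <- A[prev[valid]] + cost_b[bi]
        better <- cand < Anew
        Anew[better] <- cand[better]
        choice[j, better] <- b
      }
      A <- Anew
    }
    if (!is.finite(A[koff])) stop("median DP failed to reach a balanced state")
    total <- total + A[koff]
    k <- koff
    for (j in rev(seq_len(L))) {
      b <- choice[j, k]
      med_q[cols[j]] <- b
      k <- k - b
    }
  }
  med <- inverse_delta_map(med_q, bins, baseline)
  list(median = med, total_distance_events = total / 2,
       total_distance_l1 = total)
}
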