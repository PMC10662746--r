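#' ZCNT distance between two copy number profiles
#'
#' The zero-agnostic copy number transformation (ZCNT) distance is the
#' minimum number of interval events (amplifications/deletions that also
#' alter zero-copy loci) transforming one profile into the other. It has
#' the closed form
#' \deqn{d(p, p') = \tfrac{1}{2} \lVert \Delta(p) - \Delta(p') \rVert_1,}
#' summed over chromosomes, where \eqn{\Delta} is the delta map. The
#' distance is a metric and always a non-negative integer.
#'
#' @param p,p2 copy number profiles (integer vectors on the same bins).
#' @param bins shared bin table; default single chromosome.
#' @param baseline baseline ploidy (default 2).
#' @return Non-negative integer distance.
#' @export
zcnt_distance <- function(p, p2, bins = uniform_bins(length(p)),
                          baseline = 2L) {
  if (length(p) != length(p2)) stop("profiles have mismatched bins")
  sum(abs(delta_map(p, bins, baseline) - delta_map(p2, bins, baseline))) / 2
}

#' Pairwise ZCNT distance matrix
#'
#' @param cnm a [cn_matrix()].
#' @param baseline baseline ploidy.
#' @return Symmetric matrix of pairwise ZCNT distances with zero diagonal,
#'   labeled by cell id.
#' @export
zcnt_distance_matrix <- function(cnm, baseline = 2L) {
  stopifnot(inherits(cnm, "cn_matrix"))
  Q <- delta_transform(cnm, baseline)
  D <- as.matrix(stats::dist(Q, method = "manhattan")) / 2
  dimnames(D) <- list(rownames(cnm$X), rownames(cnm$X))
  D
}

# All (s, t, b) interval events on a single chromosome of m bins.
.all_events <- function(m) {
  st <- which(upper.tri(matrix(0, m, m), diag = TRUE), arr.ind = TRUE)
  data.frame(s = st[, 1L], t = st[, 2L],
             b = rep(c(1L, -1L), each = nrow(st)))
}

.state_key <- function(X) do.call(paste, c(as.data.frame(X), sep = ","))

#' Breadth-first search over event applications (toy-scale oracle)
#'
#' Explores all profiles reachable from \code{p} by interval events under
#' either the CNT semantics (zero entries are skipped; states stay
#' non-negative) or the ZCNT semantics (all entries shift; states range over
#' a bounded integer box), recording the minimum number of events to each
#' reachable state. Intended as an exhaustive oracle at toy scale only and
#' guarded accordingly.
#'
#' @param p source profile, a single-chromosome integer vector.
#' @param semantics \code{"ZCNT"} or \code{"CNT"}.
#' @param max_events search depth limit.
#' @return Named integer vector: minimum event counts keyed by the
#'   comma-separated profile string.
#' @export
bfs_event_distances <- function(p, semantics = c("ZCNT", "CNT"),
                                max_events = 12L) {
  semantics <- match.arg(semantics)
  m <- length(p)
  B <- max(p, 0L)
  if (m > 6L || B > 5L || max_events > 12L)
    stop("oracle scale exceeded: need m <= 6, entries <= 5, max_events <= 12")
  ev <- .all_events(m)
  lo <- if (semantics == "CNT") 0L else -max_events
  hi <- B + max_events
  dist <- stats::setNames(0L, .state_key(matrix(p, 1L)))
  frontier <- matrix(as.integer(p), 1L)
  for (d in seq_len(max_events)) {
    nxt <- vector("list", nrow(ev))
    for (k in seq_len(nrow(ev))) {
      idx <- ev$s[k]:ev$t[k]
      new <- frontier
      if (semantics == "CNT") {
        seg <- new[, idx, drop = FALSE]
        seg[seg != 0L] <- seg[seg != 0L] + ev$b[k]
        new[, idx] <- seg
      } else {
        new[, idx] <- new[, idx, drop = FALSE] + ev$b[k]
      }
      keep <- rowSums(new < lo | new > hi) == 0L
      nxt[[k]] <- new[keep, , drop = FALSE]
    }
    cand <- unique(do.call(rbind, nxt))
    if (nrow(cand) == 0L) break
    keys <- .state_key(cand)
    fresh <- !(keys %in% names(dist))
    if (!any(fresh)) break
    dist <- c(dist, stats::setNames(rep(d, sum(fresh)), keys[fresh]))
    frontier <- cand[fresh, , drop = FALSE]
  }
  dist
}

#' Minimum event count between two profiles by exhaustive search
#'
#' BFS oracle for the minimum number of events transforming \code{p} into
#' \code{p2} under CNT or ZCNT semantics. Under CNT a transformation may
#' not exist (a lost locus cannot be regained); \code{Inf} is returned when
#' no transformation of at most \code{max_events} events exists.
#'
#' @inheritParams bfs_event_distances
#' @param p2 target profile.
#' @return Integer event count, or \code{Inf} if infeasible within
#'   \code{max_events}.
#' @export
bfs_min_events <- function(p, p2, semantics = c("ZCNT", "CNT"),
                           max_events = 12L) {
  semantics <- match.arg(semantics)
  if (length(p) != length(p2)) stop("profiles have mismatched bins")
  if (max(p2, 0L) > 5L)
    stop("oracle scale exceeded: need m <= 6, entries <= 5, max_events <= 12")
  dmap <- bfs_event_distances(p, semantics, max_events)
  d <- dmap[.state_key(matrix(as.integer(p2), 1L))]
  if (is.na(d)) Inf else as.numeric(d)
}

#' Compare CNT and ZCNT distances over profile pairs
#'
#' For each pair computes the ZCNT distance (closed form) and the
#' symmetrized CNT distance \eqn{\sigma'(u,v) = (\sigma(u,v) +
#' \sigma(v,u))/2} (by the BFS oracle unless supplied), and summarizes the
#' relative differences \eqn{|d_{CNT}/d_{ZCNT} - 1|}. Pairs with zero ZCNT
#' distance or an infeasible CNT transformation are excluded and counted.
#'
#' @param pairs list of 2-element lists/pairs of profiles.
#' @param cnt_distances optional numeric vector of precomputed symmetrized
#'   CNT distances (one per pair), bypassing the toy-scale oracle.
#' @param max_events BFS depth limit for the oracle.
#' @return List with \code{per_pair} (data.frame of distances and relative
#'   differences), \code{median}, \code{quartiles}, and \code{n_excluded}.
#' @export
cnt_zcnt_comparison <- function(pairs, cnt_distances = NULL,
                                max_events = 12L) {
  n <- length(pairs)
  d_z <- d_c <- numeric(n)
  for (i in seq_len(n)) {
    p <- pairs[[i]][[1L]]; p2 <- pairs[[i]][[2L]]
    d_z[i] <- zcnt_distance(p, p2)
    d_c[i] <- if (!is.null(cnt_distances)) cnt_distances[i] else
      (bfs_min_events(p, p2, "CNT", max_events) +
         bfs_min_events(p2, p, "CNT", max_events)) / 2
  }
  ok <- d_z > 0 & is.finite(d_c)
  if (!any(ok)) stop("all pairs excluded (zero ZCNT distance or infeasible CNT)")
  rel <- abs(d_c[ok] / d_z[ok] - 1)
  list(per_pair = data.frame(pair = which(ok), d_cnt = d_c[ok],
                             d_zcnt = d_z[ok], rel_diff = rel),
       median = stats::median(rel),
       quartiles = stats::quantile(rel, c(0.25, 0.5, 0.75), names = FALSE),
       n_excluded = sum(!ok))
}
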