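#' Genomic bin table
#'
#' Construct and validate the bin metadata shared by all copy number profiles:
#' one row per genomic bin with chromosome, start and end coordinates.
#' Coordinates are 0-based half-open \code{[start, end)}; bins within a
#' chromosome must be sorted and non-overlapping.
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer vectors of bin boundaries, \code{start < end}.
#' @return A \code{data.frame} with columns \code{chrom}, \code{start},
#'   \code{end}, chromosomes kept in order of first appearance.
#' @export
cn_bins <- function(chrom, start, end) {
  if (length(chrom) != length(start) || length(start) != length(end))
    stop("chrom, start, end must have equal length")
  start <- as.integer(start); end <- as.integer(end)
  if (any(is.na(start)) || any(is.na(end))) stop("non-integer bin coordinates")
  if (any(start >= end)) stop("bin start must be < end")
  chrom <- as.character(chrom)
  bins <- data.frame(chrom = chrom, start = start, end = end,
                     stringsAsFactors = FALSE)
  # preserve order of first appearance, sort bins within chromosome
  lev <- unique(chrom)
  ord <- order(match(bins$chrom, lev), bins$start)
  bins <- bins[ord, , drop = FALSE]
  rownames(bins) <- NULL
  for (cc in lev) {
    b <- bins[bins$chrom == cc, , drop = FALSE]
    if (nrow(b) > 1 && any(b$start[-1] < b$end[-nrow(b)]))
      stop("overlapping bins on chromosome ", cc)
  }
  bins
}

#' Uniform single-chromosome bins
#'
#' Convenience constructor for \code{m} unit-width bins on one chromosome,
#' used for simulated data and small examples.
#'
#' @param m number of bins.
#' @param chrom chromosome name.
#' @return A bin table as from [cn_bins()].
#' @export
uniform_bins <- function(m, chrom = "chr1") {
  cn_bins(rep(chrom, m), seq_len(m) - 1L, seq_len(m))
}

.check_bins <- function(bins) {
  stopifnot(is.data.frame(bins),
            all(c("chrom", "start", "end") %in% names(bins)))
  bins
}

#' Copy number matrix
#'
#' Bundle an \code{n} cells by \code{m} bins matrix of non-negative integer
#' copy numbers with its bin metadata.
#'
#' @param X integer matrix, rows are cells (rownames used as cell ids).
#' @param bins bin table from [cn_bins()]; defaults to unit bins on one
#'   chromosome.
#' @return An object of class \code{cn_matrix}: a list with elements
#'   \code{X} and \code{bins}.
#' @export
cn_matrix <- function(X, bins = uniform_bins(ncol(X))) {
  X <- as.matrix(X)
  storage.mode(X) <- "integer"
  .check_bins(bins)
  if (ncol(X) != nrow(bins)) stop("ncol(X) must equal nrow(bins)")
  if (any(is.na(X))) stop("missing copy numbers")
  if (any(X < 0L)) stop("copy numbers must be non-negative")
  if (is.null(rownames(X))) rownames(X) <- paste0("cell", seq_len(nrow(X)))
  if (anyDuplicated(rownames(X))) stop("duplicated cell identifiers")
  structure(list(X = X, bins = bins), class = "cn_matrix")
}

#' @export
print.cn_matrix <- function(x, ...) {
  cat("Copy number matrix:", nrow(x$X), "cells x", ncol(x$X), "bins (",
      length(unique(x$bins$chrom)), "chromosome(s) ), max copy number",
      max(x$X), "\n")
  invisible(x)
}

#' @export
dim.cn_matrix <- function(x) dim(x$X)

# Per-chromosome layout of the delta representation. For a chromosome with
# m_c bins the delta segment has m_c + 1 coordinates; segments are
# concatenated in chromosome order. Returns, for each delta coordinate, the
# chromosome id, plus index bookkeeping used throughout.
.seg_layout <- function(bins) {
  .check_bins(bins)
  chroms <- unique(bins$chrom)
  mc <- vapply(chroms, function(cc) sum(bins$chrom == cc), integer(1))
  dlen <- mc + 1L
  dstart <- cumsum(c(1L, dlen[-length(dlen)]))
  bstart <- cumsum(c(1L, mc[-length(mc)]))
  list(chroms = chroms, m_per_chrom = mc, d_per_chrom = dlen,
       d_start = dstart, b_start = bstart,
       seg = rep(chroms, dlen), D = sum(dlen), m = sum(mc))
}

#' Delta map: adjacent-locus differences of a copy number profile
#'
#' Maps a copy number profile to its delta profile: per chromosome, the
#' vector of differences between adjacent loci after padding both
#' chromosome ends with the baseline (diploid) copy number. A chromosome
#' with \code{m_c} bins yields \code{m_c + 1} delta coordinates; each
#' per-chromosome segment sums to zero (the balancing condition).
#'
#' @param p integer vector of copy numbers (one entry per bin).
#' @param bins bin table; default single chromosome of unit bins.
#' @param baseline baseline ploidy appended at chromosome ends (default 2).
#' @return Integer vector of length \code{m + n_chromosomes} with attribute
#'   \code{"seg"} giving the chromosome of each delta coordinate.
#' @seealso [inverse_delta_map()]
#' @export
delta_map <- function(p, bins = uniform_bins(length(p)), baseline = 2L) {
  lay <- .seg_layout(bins)
  if (length(p) != lay$m) stop("profile length does not match bins")
  q <- numeric(lay$D)
  for (i in seq_along(lay$chroms)) {
    pc <- p[lay$b_start[i] + seq_len(lay$m_per_chrom[i]) - 1L]
    q[lay$d_start[i] + seq_len(lay$d_per_chrom[i]) - 1L] <-
      diff(c(baseline, pc, baseline))
  }
  structure(q, seg = lay$seg)
}

#' Inverse delta map
#'
#' Reconstructs the unique copy number profile whose delta profile is
#' \code{q}, by cumulative summation from the baseline. Each per-chromosome
#' segment of \code{q} must satisfy the balancing condition (sum to zero);
#' an unbalanced segment is rejected.
#'
#' @param q delta vector (length \code{m + n_chromosomes}).
#' @param bins bin table; default single chromosome.
#' @param baseline baseline ploidy (default 2).
#' @return Integer vector of copy numbers, one per bin.
#' @export
inverse_delta_map <- function(q, bins = NULL, baseline = 2L) {
  if (is.null(bins)) bins <- uniform_bins(length(q) - 1L)
  lay <- .seg_layout(bins)
  if (length(q) != lay$D) stop("delta length does not match bins")
  p <- numeric(lay$m)
  for (i in seq_along(lay$chroms)) {
    qc <- q[lay$d_start[i] + seq_len(lay$d_per_chrom[i]) - 1L]
    if (abs(sum(qc)) > 1e-9)
      stop("balancing violation: delta segment for chromosome ",
           lay$chroms[i], " sums to ", sum(qc))
    p[lay$b_start[i] + seq_len(lay$m_per_chrom[i]) - 1L] <-
      baseline + cumsum(qc[-length(qc)])
  }
  p
}

#' Delta representation of a copy number matrix
#'
#' @param cnm a [cn_matrix()].
#' @param baseline baseline ploidy.
#' @return Numeric matrix, one row per cell, columns the concatenated
#'   per-chromosome delta segments; attribute \code{"seg"} as in
#'   [delta_map()].
#' @export
delta_transform <- function(cnm, baseline = 2L) {
  stopifnot(inherits(cnm, "cn_matrix"))
  lay <- .seg_layout(cnm$bins)
  Q <- t(apply(cnm$X, 1L, delta_map, bins = cnm$bins, baseline = baseline))
  dimnames(Q) <- list(rownames(cnm$X), NULL)
  structure(Q, seg = lay$seg)
}

#' Copy number event record
#'
#' A single interval event: amplification (\code{b = +1}) or deletion
#' (\code{b = -1}) of bins \code{s..t} (1-based, within the chromosome).
#'
#' @param chrom chromosome name.
#' @param s,t first and last affected bin index, \code{s <= t}.
#' @param b event sign, +1 or -1.
#' @return A list of class \code{event_record}.
#' @export
event_record <- function(chrom, s, t, b) {
  s <- as.integer(s); t <- as.integer(t); b <- as.integer(b)
  if (s > t) stop("event requires s <= t")
  if (!b %in% c(-1L, 1L)) stop("event sign must be +1 or -1")
  structure(list(chrom = as.character(chrom), s = s, t = t, b = b),
            class = "event_record")
}

#' @export
print.event_record <- function(x, ...) {
  cat(sprintf("%s event on %s bins [%d, %d]\n",
              if (x$b > 0) "amplification" else "deletion", x$chrom, x$s, x$t))
  invisible(x)
}

# global bin indices of an event
.event_global_idx <- function(event, bins) {
  idx <- which(bins$chrom == event$chrom)
  if (length(idx) == 0L) stop("unknown chromosome ", event$chrom)
  if (event$t > length(idx)) stop("event interval outside chromosome")
  idx[event$s:event$t]
}

#' Apply an event under the CNT model
#'
#' Under the copy number transformation (CNT) model an event adds \code{b}
#' to every \emph{non-zero} entry in its interval: zero-copy loci are
#' skipped, so a lost locus can never be regained.
#'
#' @param p copy number profile (integer vector).
#' @param event an [event_record()].
#' @param bins bin table; default single chromosome.
#' @return The transformed profile.
#' @export
apply_cnt_event <- function(p, event, bins = uniform_bins(length(p))) {
  idx <- .event_global_idx(event, bins)
  hit <- idx[p[idx] != 0]
  p[hit] <- p[hit] + event$b
  p
}

#' Apply an event under the zero-agnostic (ZCNT) model
#'
#' Adds \code{b} to every entry in the interval, including zeros and
#' negative values; the domain is all integer vectors.
#'
#' @inheritParams apply_cnt_event
#' @return The transformed vector.
#' @export
apply_zcnt_event <- function(p, event, bins = uniform_bins(length(p))) {
  idx <- .event_global_idx(event, bins)
  p[idx] <- p[idx] + event$b
  p
}

#' Apply an event in delta space
#'
#' A ZCNT event on bins \code{s..t} alters exactly two adjacent-locus
#' differences: it adds \code{b} to delta coordinate \code{s} and subtracts
#' \code{b} from coordinate \code{t + 1} of the same chromosome segment,
#' preserving the balancing condition.
#'
#' @param q delta vector (with the layout of [delta_map()]).
#' @param event an [event_record()].
#' @param bins bin table; default single chromosome inferred from length.
#' @return The transformed delta vector.
#' @export
apply_delta_event <- function(q, event, bins = NULL) {
  if (is.null(bins)) bins <- uniform_bins(length(q) - 1L)
  lay <- .seg_layout(bins)
  i <- match(event$chrom, lay$chroms)
  if (is.na(i)) stop("unknown chromosome ", event$chrom)
  if (event$t + 1L > lay$d_per_chrom[i]) stop("event interval outside chromosome")
  off <- lay$d_start[i] - 1L
  q[off + event$s] <- q[off + event$s] + event$b
  q[off + event$t + 1L] <- q[off + event$t + 1L] - event$b
  q
}
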