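#' Read a copy number table
#'
#' Reads a TSV/CSV copy number table in either of two dialects, auto-detected
#' from the header: long format with columns \code{cell_id, chrom, start,
#' end, copy_number}, or wide format with one row per cell and bin columns
#' named \code{"chrom:start-end"}. The delimiter (tab or comma) is sniffed
#' from the header line.
#'
#' @param path file path.
#' @return A [cn_matrix()].
#' @export
read_copy_number_table <- function(path) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  cols <- names(df)
  if (all(c("cell_id", "chrom", "start", "end", "copy_number") %in% cols)) {
    return(.cn_from_long(df))
  }
  bin_cols <- grep("^[^:]+:[0-9]+-[0-9]+$", cols, value = TRUE)
  if (length(bin_cols) > 0L) return(.cn_from_wide(df, bin_cols))
  stop("unrecognized copy number table layout: need long columns ",
       "(cell_id, chrom, start, end, copy_number) or wide 'chrom:start-end' ",
       "bin columns")
}

.cn_from_long <- function(df) {
  if (any(df$copy_number < 0)) stop("negative copy number in input")
  if (any(df$copy_number != round(df$copy_number)))
    stop("non-integer copy number in input")
  key <- paste(df$chrom, df$start, df$end, sep = ":")
  if (anyDuplicated(paste(df$cell_id, key)))
    stop("duplicate (cell, bin) pairs in input")
  ub <- !duplicated(key)
  bins <- cn_bins(df$chrom[ub], df$start[ub], df$end[ub])
  bkey <- paste(bins$chrom, bins$start, bins$end, sep = ":")
  cells <- unique(df$cell_id)
  X <- matrix(NA_integer_, length(cells), nrow(bins),
              dimnames = list(cells, NULL))
  X[cbind(match(df$cell_id, cells), match(key, bkey))] <-
    as.integer(df$copy_number)
  if (any(is.na(X))) stop("missing (cell, bin) combinations in input")
  cn_matrix(X, bins)
}

.cn_from_wide <- function(df, bin_cols) {
  idcol <- setdiff(names(df), bin_cols)
  cells <- if (length(idcol) >= 1L) as.character(df[[idcol[1L]]])
           else paste0("cell", seq_len(nrow(df)))
  parts <- regmatches(bin_cols, regexec("^([^:]+):([0-9]+)-([0-9]+)$", bin_cols))
  bins <- cn_bins(vapply(parts, `[`, "", 2L),
                  as.integer(vapply(parts, `[`, "", 3L)),
                  as.integer(vapply(parts, `[`, "", 4L)))
  # cn_bins may reorder; map columns to sorted bin order
  key <- paste(vapply(parts, `[`, "", 2L),
               vapply(parts, `[`, "", 3L), sep = ":")
  bkey <- paste(bins$chrom, bins$start, sep = ":")
  X <- as.matrix(df[, bin_cols, drop = FALSE])[, match(bkey, key), drop = FALSE]
  if (any(X < 0)) stop("negative copy number in input")
  rownames(X) <- cells
  colnames(X) <- NULL
  cn_matrix(X, bins)
}

#' Write a copy number table
#'
#' @param cnm a [cn_matrix()].
#' @param path output path.
#' @param format \code{"long"} (default) or \code{"wide"}; see
#'   [read_copy_number_table()].
#' @param sep field delimiter, tab by default.
#' @return Invisibly, \code{path}.
#' @export
write_copy_number_table <- function(cnm, path, format = c("long", "wide"),
                                    sep = "\t") {
  stopifnot(inherits(cnm, "cn_matrix"))
  format <- match.arg(format)
  if (format == "long") {
    df <- data.frame(
      cell_id = rep(rownames(cnm$X), each = ncol(cnm$X)),
      chrom = rep(cnm$bins$chrom, nrow(cnm$X)),
      start = rep(cnm$bins$start, nrow(cnm$X)),
      end = rep(cnm$bins$end, nrow(cnm$X)),
      copy_number = as.integer(t(cnm$X)))
  } else {
    df <- data.frame(cell_id = rownames(cnm$X), check.names = FALSE)
    df[paste0(cnm$bins$chrom, ":", cnm$bins$start, "-", cnm$bins$end)] <-
      as.data.frame(cnm$X)
  }
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write trees in newick format
#'
#' Thin wrappers over \pkg{ape} that validate the parse and preserve
#' topology and leaf names on round trip.
#'
#' @param path file path.
#' @return \code{read_newick}: an \pkg{ape} \code{phylo} tree.
#' @export
read_newick <- function(path) {
  tree <- tryCatch(ape::read.tree(path),
                   error = function(e) stop("unparseable newick: ",
                                            conditionMessage(e)))
  if (is.null(tree)) stop("unparseable newick file: ", path)
  tree
}

#' @rdname read_newick
#' @param tree a \code{phylo} object.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
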