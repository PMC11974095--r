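#' Segment tables
#'
#' A segment table describes the `L` genomic segments on which copy numbers
#' are defined: one row per segment with a chromosome, BED-style 0-based
#' half-open coordinates, and a 1-based genome-ordered index. Segments of one
#' chromosome form a single contiguous index run, so interval CNA events can
#' be constrained to a chromosome by index arithmetic alone.
#'
#' @param chrom character vector of chromosome identifiers, one per segment,
#'   grouped (all segments of a chromosome must be consecutive).
#' @param start,end integer genomic coordinates (0-based half-open);
#'   `start < end` and segments within a chromosome must be sorted and
#'   non-overlapping.
#' @param n_bins optional integer vector giving how many fixed-size bins each
#'   segment covers; used to weight bin-level evaluation metrics. Defaults
#'   to 1 per segment.
#' @return An object of class `evocn_segments`: a data.frame with columns
#'   `chrom`, `start`, `end`, `index`, `n_bins`.
#' @examples
#' segment_table(rep("chr1", 4), start = c(0, 10, 20, 30) * 1e5,
#'               end = c(10, 20, 30, 40) * 1e5)
#' @export
segment_table <- function(chrom, start, end, n_bins = NULL) {
  chrom <- as.character(chrom)
  start <- as.numeric(start)
  end <- as.numeric(end)
  L <- length(chrom)
  if (length(start) != L || length(end) != L)
    stopf("segment table: chrom/start/end lengths differ")
  if (L == 0L) stopf("segment table: empty")
  if (any(start >= end)) stopf("segment table: start must be < end for every segment")
  r <- rle(chrom)
  if (anyDuplicated(r$values))
    stopf("segment table: segments of one chromosome must be contiguous")
  idx_by_chrom <- split(seq_len(L), factor(chrom, levels = r$values))
  for (ii in idx_by_chrom) {
    if (length(ii) > 1L) {
      if (any(diff(start[ii]) <= 0) || any(start[ii][-1] < end[ii][-length(ii)]))
        stopf("segment table: segments within a chromosome must be sorted and non-overlapping")
    }
  }
  if (is.null(n_bins)) n_bins <- rep(1L, L)
  df <- data.frame(chrom = chrom, start = start, end = end,
                   index = seq_len(L), n_bins = as.integer(n_bins),
                   stringsAsFactors = FALSE)
  class(df) <- c("evocn_segments", "data.frame")
  df
}

n_segments <- function(segments) nrow(segments)

## Integer chromosome-block id per segment (1, 2, ... in genome order).
chrom_block <- function(segments) {
  r <- rle(segments$chrom)
  rep(seq_along(r$lengths), r$lengths)
}

## Last segment index of the chromosome containing each segment.
block_end_index <- function(segments) {
  blk <- chrom_block(segments)
  ave(segments$index, blk, FUN = max)
}

same_chromosome <- function(segments, i, j) {
  segments$chrom[i] == segments$chrom[j]
}

#' Read a segment table from a BED-style TSV
#'
#' @param path TSV with columns `chrom`, `start`, `end` and optionally
#'   `n_bins` (header required).
#' @return `evocn_segments` object.
#' @export
read_segments <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end")
  if (!all(need %in% names(df)))
    stopf("segment table %s: missing columns %s", path,
          paste(setdiff(need, names(df)), collapse = ", "))
  segment_table(df$chrom, df$start, df$end,
                n_bins = if ("n_bins" %in% names(df)) df$n_bins else NULL)
}

#' @export
write_segments <- function(segments, path) {
  utils::write.table(segments[, c("chrom", "start", "end", "n_bins")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

segment_labels <- function(segments) {
  sprintf("%s:%d-%d", segments$chrom, as.integer(segments$start),
          as.integer(segments$end))
}
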