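# Genomic intervals use the BED convention throughout the package:
# 0-based starts, half-open ends.  GTF input is converted on read.

#' Construct a genomic interval
#'
#' Intervals are plain data frames with columns `chrom`, `start`, `end` and
#' `strand`, using 0-based half-open coordinates. Empty intervals
#' (`start >= end`) are rejected.
#'
#' @param chrom Chromosome name(s), non-empty strings.
#' @param start 0-based start position(s).
#' @param end Exclusive end position(s); must exceed `start`.
#' @param strand One of `"+"`, `"-"` or `"*"` (unstranded).
#' @return A data frame with one row per interval.
#' @examples
#' genomic_interval("chr1", 1000, 2000)
#' @export
genomic_interval <- function(chrom, start, end, strand = "*") {
  df <- data.frame(
    chrom = as.character(chrom),
    start = as.numeric(start),
    end = as.numeric(end),
    strand = as.character(strand),
    stringsAsFactors = FALSE
  )
  validate_intervals(df)
  df
}

validate_intervals <- function(df, what = "interval") {
  if (!all(c("chrom", "start", "end") %in% names(df))) {
    stop(what, " table must have columns chrom, start, end", call. = FALSE)
  }
  if (any(is.na(df$chrom) | !nzchar(df$chrom))) {
    stop(what, ": chromosome names must be non-empty", call. = FALSE)
  }
  bad <- which(!is.finite(df$start) | !is.finite(df$end) |
                 df$start < 0 | df$start >= df$end)
  if (length(bad)) {
    stop(what, " row ", bad[1], ": requires 0 <= start < end (got start=",
         df$start[bad[1]], ", end=", df$end[bad[1]], ")", call. = FALSE)
  }
  if ("strand" %in% names(df) &&
      !all(df$strand %in% c("+", "-", "*", "."))) {
    stop(what, ": strand must be one of +, -, *", call. = FALSE)
  }
  invisible(df)
}

#' Gap distance between genomic intervals
#'
#' The number of bases strictly separating two intervals: 0 if they overlap
#' or abut, `Inf` if they lie on different chromosomes. This is the distance
#' notion used by every windowed test in the pipeline (replication within
#' 10 kb, control proximity, gene assignment within 2 kb).
#'
#' @param a,b Data frames with columns `chrom`, `start`, `end`
#'   (0-based half-open). Rows are recycled to a common length.
#' @return Numeric vector of gap distances in bp (`Inf` across chromosomes).
#' @examples
#' gap_distance(genomic_interval("chr1", 0, 100), genomic_interval("chr1", 150, 250))
#' @export
gap_distance <- function(a, b) {
  n <- max(nrow(a), nrow(b))
  ai <- rep_len(seq_len(nrow(a)), n)
  bi <- rep_len(seq_len(nrow(b)), n)
  d <- pmax(0, b$start[bi] - a$end[ai], a$start[ai] - b$end[bi])
  d[a$chrom[ai] != b$chrom[bi]] <- Inf
  d
}

# Internal: 0-based half-open data frame -> GRanges (1-based closed).
as_granges0 <- function(df) {
  strand <- if ("strand" %in% names(df)) {
    s <- df$strand
    s[is.na(s) | s == "."] <- "*"
    s
  } else "*"
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = strand
  )
}

# Internal: midpoint of a 0-based half-open interval (floor of the center).
interval_midpoint <- function(df) {
  floor((df$start + df$end) / 2)
}
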