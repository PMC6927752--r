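#' Construct a table of genomic intervals
#'
#' All coordinates in this package are 0-based half-open `[start, end)`.
#' Intervals are plain data frames with columns `contig`, `start`, `end`
#' and `strand`; any extra columns supplied via `...` are carried along.
#'
#' @param contig Character vector of contig identifiers (non-empty).
#' @param start Integer vector, 0-based inclusive start.
#' @param end Integer vector, exclusive end; must satisfy `start < end`.
#' @param strand Character vector in `c("+", "-", "*")`; `"*"` means
#'   unstranded. Recycled to length.
#' @param ... Further columns (recycled by `data.frame()`).
#' @return A data frame with class `c("genomic_intervals", "data.frame")`.
#' @export
gintervals <- function(contig, start, end, strand = "*", ...) {
  strand <- rep(as.character(strand), length.out = length(contig))
  df <- data.frame(
    contig = as.character(contig),
    start  = as.numeric(start),
    end    = as.numeric(end),
    strand = as.character(strand),
    ...,
    stringsAsFactors = FALSE
  )
  validate_gintervals(df)
  class(df) <- c("genomic_intervals", "data.frame")
  df
}

validate_gintervals <- function(df) {
  stopifnot(all(c("contig", "start", "end") %in% names(df)))
  if (nrow(df) == 0L) return(invisible(df))
  if (any(is.na(df$contig) | !nzchar(df$contig)))
    stop("interval contigs must be non-empty")
  if (any(df$start < 0))
    stop("interval starts must be >= 0")
  if (any(df$start >= df$end))
    stop("intervals must satisfy start < end (0-based half-open)")
  invisible(df)
}

#' Merge overlapping intervals
#'
#' Collapses intervals that overlap by at least 1 bp into single regions,
#' per contig, discarding strand. Abutting intervals (`[a,b)` and `[b,c)`)
#' are deliberately *not* merged: coverage is unchanged either way, but
#' keeping them separate makes interval counts deterministic.
#'
#' @param intervals A data frame with `contig`, `start`, `end` columns.
#' @return A `genomic_intervals` data frame sorted by `(contig, start)`,
#'   with no two rows overlapping.
#' @export
merge_intervals <- function(intervals) {
  if (nrow(intervals) == 0L)
    return(gintervals(character(), integer(), integer()))
  ord <- order(intervals$contig, intervals$start, intervals$end)
  ctg <- intervals$contig[ord]
  s <- intervals$start[ord]
  e <- intervals$end[ord]
  out_c <- character(0); out_s <- numeric(0); out_e <- numeric(0)
  cur_c <- ctg[1L]; cur_s <- s[1L]; cur_e <- e[1L]
  for (i in seq_along(s)[-1L]) {
    if (ctg[i] == cur_c && s[i] < cur_e) {
      # strict overlap: abutting (s[i] == cur_e) starts a new region
      cur_e <- max(cur_e, e[i])
    } else {
      out_c <- c(out_c, cur_c); out_s <- c(out_s, cur_s); out_e <- c(out_e, cur_e)
      cur_c <- ctg[i]; cur_s <- s[i]; cur_e <- e[i]
    }
  }
  out_c <- c(out_c, cur_c); out_s <- c(out_s, cur_s); out_e <- c(out_e, cur_e)
  gintervals(out_c, out_s, out_e)
}

#' Base-pair overlap between two intervals
#'
#' @param a,b Single intervals given as lists/data-frame rows with
#'   `contig`, `start`, `end`.
#' @return `max(0, min(a$end, b$end) - max(a$start, b$start))` if the
#'   contigs match, else 0.
#' @export
overlap_bp <- function(a, b) {
  if (as.character(a$contig) != as.character(b$contig)) return(0)
  max(0, min(a$end, b$end) - max(a$start, b$start))
}

# Vectorised overlap of one interval table against a single window.
overlap_bp_vec <- function(intervals, contig, start, end) {
  ov <- pmin(intervals$end, end) - pmax(intervals$start, start)
  ov[intervals$contig != contig] <- 0
  pmax(0, ov)
}

#' Fraction of a genome covered by merged intervals
#'
#' @param merged_intervals Output of [merge_intervals()]; all contigs must
#'   exist in `genome`.
#' @param genome A `genome_sequence` (see [parse_fasta()]) or a named
#'   numeric vector of contig lengths.
#' @return Covered bases divided by total genome size, in `[0, 1]`.
#' @export
genome_fraction <- function(merged_intervals, genome) {
  lens <- contig_lengths(genome)
  if (nrow(merged_intervals) == 0L) return(0)
  unknown <- setdiff(unique(merged_intervals$contig), names(lens))
  if (length(unknown) > 0L)
    stop("intervals on contigs absent from genome: ",
         paste(unknown, collapse = ", "))
  sum(merged_intervals$end - merged_intervals$start) / sum(lens)
}

#' Contig lengths of a genome or length vector
#'
#' @param genome A `genome_sequence` or a named numeric vector of lengths.
#' @return Named numeric vector of contig lengths.
#' @export
contig_lengths <- function(genome) {
  if (inherits(genome, "genome_sequence")) {
    vapply(genome$contigs, nchar, numeric(1))
  } else if (is.numeric(genome) && !is.null(names(genome))) {
    genome
  } else {
    stop("genome must be a genome_sequence or a named numeric length vector")
  }
}
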