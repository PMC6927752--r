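# IUPAC nucleotide ambiguity sets over the base alphabet A,C,G,T.
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

IUPAC_COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A",
  R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
  B = "V", D = "H", H = "D", V = "B", N = "N"
)

#' Reverse complement of an IUPAC string
#'
#' @param motif_string IUPAC nucleotide string.
#' @return The reverse-complemented IUPAC string.
#' @export
revcomp_iupac <- function(motif_string) {
  chars <- strsplit(toupper(motif_string), "")[[1L]]
  bad <- which(!chars %in% names(IUPAC_COMPLEMENT))
  if (length(bad) > 0L)
    stop("illegal IUPAC character '", chars[bad[1L]],
         "' at position ", bad[1L])
  paste(rev(unname(IUPAC_COMPLEMENT[chars])), collapse = "")
}

#' Compile an IUPAC motif into per-position allowed-base sets
#'
#' The default motif is the degenerate heat-shock element (HSE),
#' `NGAANNTTCNNGAAN`: three nGAAn-type units in alternating orientation,
#' the sequence bound by trimeric HSF-1.
#'
#' @param motif_string IUPAC nucleotide string.
#' @return A `motif_pattern`: list with `motif_string`, `length`,
#'   `allowed` (4 x L logical matrix, rows A,C,G,T, forward strand),
#'   `revcomp_string` and `allowed_rc` (same for the reverse complement).
#' @export
compile_iupac_pattern <- function(motif_string = "NGAANNTTCNNGAAN") {
  motif_string <- toupper(motif_string)
  chars <- strsplit(motif_string, "")[[1L]]
  bad <- which(!chars %in% names(IUPAC_SETS))
  if (length(bad) > 0L)
    stop("illegal IUPAC character '", chars[bad[1L]],
         "' at position ", bad[1L])
  bases <- c("A", "C", "G", "T")
  to_matrix <- function(cs) {
    m <- vapply(cs, function(ch) bases %in% IUPAC_SETS[[ch]], logical(4))
    rownames(m) <- bases
    m
  }
  rc <- revcomp_iupac(motif_string)
  structure(
    list(
      motif_string = motif_string,
      length = length(chars),
      allowed = to_matrix(chars),
      revcomp_string = rc,
      allowed_rc = to_matrix(strsplit(rc, "")[[1L]])
    ),
    class = "motif_pattern"
  )
}

#' @export
print.motif_pattern <- function(x, ...) {
  cat("motif_pattern:", x$motif_string, "(", x$length, "bp ), revcomp",
      x$revcomp_string, "\n")
  invisible(x)
}

#' Scan a genome for a degenerate motif on both strands
#'
#' Every start position is tested independently, so overlapping
#' occurrences are all reported (tandem HSEs overlap one another; a plain
#' regex `findall` would miss them). A window can match on both strands
#' and then yields two records. An `N` in the genome matches nothing.
#'
#' @param genome A `genome_sequence`.
#' @param pattern A `motif_pattern` from [compile_iupac_pattern()], or an
#'   IUPAC string.
#' @param strands `"both"` (default), `"plus"` or `"minus"`.
#' @return A `genomic_intervals` data frame of matches with 0-based
#'   half-open `start`/`end`, `strand`, and `matched_seq` as read on the
#'   plus strand, sorted by (contig, start, strand).
#' @export
scan_genome <- function(genome, pattern = compile_iupac_pattern(),
                        strands = c("both", "plus", "minus")) {
  strands <- match.arg(strands)
  if (is.character(pattern)) pattern <- compile_iupac_pattern(pattern)
  stopifnot(inherits(genome, "genome_sequence"))
  L <- pattern$length
  res <- vector("list", length(genome$contigs))
  for (ci in seq_along(genome$contigs)) {
    ctg <- names(genome$contigs)[ci]
    seq <- genome$contigs[[ci]]
    n <- nchar(seq) - L + 1L
    if (n < 1L) next
    code <- BASE_CODE[utf8ToInt(seq)]
    hit_p <- if (strands %in% c("both", "plus"))
      scan_positions(code, pattern$allowed, n) else integer(0)
    hit_m <- if (strands %in% c("both", "minus"))
      scan_positions(code, pattern$allowed_rc, n) else integer(0)
    starts <- c(hit_p, hit_m)
    if (length(starts) == 0L) next
    df <- data.frame(
      contig = ctg,
      start = starts - 1,                       # to 0-based
      end = starts - 1 + L,
      strand = c(rep("+", length(hit_p)), rep("-", length(hit_m))),
      matched_seq = substring(seq, starts, starts + L - 1L),
      stringsAsFactors = FALSE
    )
    res[[ci]] <- df[order(df$start, df$strand), , drop = FALSE]
  }
  res <- res[!vapply(res, is.null, logical(1))]
  if (length(res) == 0L)
    return(gintervals(character(), integer(), integer(),
                      matched_seq = character()))
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  class(out) <- c("genomic_intervals", "data.frame")
  out
}

# ASCII -> base index (A=1, C=2, G=3, T=4, anything else NA).
BASE_CODE <- local({
  v <- rep(NA_integer_, 128L)
  v[utf8ToInt("A")] <- 1L; v[utf8ToInt("C")] <- 2L
  v[utf8ToInt("G")] <- 3L; v[utf8ToInt("T")] <- 4L
  v
})

# Positions (1-based) where every pattern column admits the genome base.
scan_positions <- function(code, allowed, n) {
  L <- ncol(allowed)
  ok <- rep(TRUE, n)
  for (j in seq_len(L)) {
    v <- allowed[, j][code[j:(j + n - 1L)]]
    v[is.na(v)] <- FALSE                        # N in genome fails
    ok <- ok & v
  }
  which(ok)
}

#' Write motif matches as BED6
#'
#' Name column carries the matched sequence; score is 0.
#'
#' @param matches Output of [scan_genome()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_matches_bed <- function(matches, path) {
  matches$name <- matches$matched_seq
  matches$score <- 0L
  write_bed(matches, path)
}
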