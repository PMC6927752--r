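#' Read a genome FASTA file
#'
#' Sequences are uppercased, `U` is mapped to `T`, and any character
#' outside `{A,C,G,T,N}` is replaced by `N` with a warning. Contig order
#' is preserved.
#'
#' @param path Path to a plain (uncompressed or gzipped) FASTA file.
#' @return A `genome_sequence`: a list with `contigs` (named character
#'   vector of sequences, in file order) and `total_size` (sum of contig
#'   lengths in bp).
#' @export
parse_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L)
    stop("FASTA file contains no sequences: ", path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids))
    stop("duplicate contig id in FASTA: ",
         ids[duplicated(ids)][1L])
  seqs <- toupper(as.character(set))
  seqs <- gsub("U", "T", seqs, fixed = TRUE)
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    warning("non-ACGTN characters replaced by N in contig(s): ",
            paste(ids[bad], collapse = ", "))
    seqs <- gsub("[^ACGTN]", "N", seqs)
  }
  names(seqs) <- ids
  genome_sequence(seqs)
}

#' Build a genome_sequence from named character sequences
#'
#' @param contigs Named character vector of uppercase A/C/G/T/N sequences.
#' @return A `genome_sequence` list with `contigs` and `total_size`.
#' @export
genome_sequence <- function(contigs) {
  stopifnot(is.character(contigs), !is.null(names(contigs)),
            all(nzchar(names(contigs))))
  structure(
    list(contigs = contigs, total_size = sum(nchar(contigs))),
    class = "genome_sequence"
  )
}

#' @export
print.genome_sequence <- function(x, ...) {
  cat("genome_sequence:", length(x$contigs), "contig(s),",
      format(x$total_size, big.mark = ","), "bp total\n")
  invisible(x)
}

#' Read repeat annotations from RepeatMasker .out or BED
#'
#' RepeatMasker `.out` files (3 header lines, whitespace columns, 1-based
#' inclusive coordinates) are converted to 0-based half-open. A 6-column
#' BED is accepted as an alternative (already 0-based half-open; repeat
#' name taken from column 4, class from column 7 when present). The
#' keyword filter is a case-insensitive substring match against the
#' repeat name and class.
#'
#' @param path Path to the annotation file.
#' @param keyword Filter keyword, e.g. `"helitron"`; `NULL` keeps all rows.
#' @return A `genomic_intervals` data frame with extra columns
#'   `repeat_name` and `repeat_class`, in file order.
#' @export
parse_repeatmasker <- function(path, keyword = "helitron") {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L)
    return(gintervals(character(), integer(), integer(),
                      repeat_name = character(), repeat_class = character()))
  is_bed <- !grepl("^\\s*(SW|score)\\b", lines[1L]) &&
    length(strsplit(trimws(lines[1L]), "\\s+")[[1L]]) <= 8L &&
    !grepl("perc", lines[1L])
  if (is_bed) {
    recs <- parse_rm_bed(lines)
  } else {
    recs <- parse_rm_out(lines)
  }
  if (!is.null(keyword)) {
    hit <- grepl(keyword, recs$repeat_name, ignore.case = TRUE) |
      grepl(keyword, recs$repeat_class, ignore.case = TRUE)
    recs <- recs[hit, , drop = FALSE]
  }
  rownames(recs) <- NULL
  class(recs) <- c("genomic_intervals", "data.frame")
  recs
}

parse_rm_out <- function(lines) {
  # skip the 2 banner lines + blank separator if present
  body <- grep("^\\s*\\d", lines, value = FALSE)
  if (length(body) == 0L)
    return(gintervals(character(), integer(), integer(),
                      repeat_name = character(), repeat_class = character()))
  rows <- lapply(body, function(i) {
    f <- strsplit(trimws(lines[i]), "\\s+")[[1L]]
    if (length(f) < 11L)
      stop("unparseable RepeatMasker line ", i, ": ", lines[i])
    # cols: 5 query, 6 begin (1-based), 7 end (inclusive), 10 name, 11 class
    s <- suppressWarnings(as.numeric(f[6L]))
    e <- suppressWarnings(as.numeric(f[7L]))
    if (is.na(s) || is.na(e))
      stop("unparseable coordinates on RepeatMasker line ", i, ": ", lines[i])
    data.frame(contig = f[5L], start = s - 1, end = e,
               repeat_name = f[10L], repeat_class = f[11L],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$strand <- "*"
  out[, c("contig", "start", "end", "strand", "repeat_name", "repeat_class")]
}

parse_rm_bed <- function(lines) {
  lines <- lines[!grepl("^(track|browser|#)", lines)]
  rows <- lapply(seq_along(lines), function(i) {
    f <- strsplit(trimws(lines[i]), "\\s+")[[1L]]
    if (length(f) < 3L)
      stop("unparseable BED line ", i, ": ", lines[i])
    data.frame(
      contig = f[1L],
      start = as.numeric(f[2L]),
      end = as.numeric(f[3L]),
      strand = if (length(f) >= 6L) f[6L] else "*",
      repeat_name = if (length(f) >= 4L) f[4L] else ".",
      repeat_class = if (length(f) >= 7L) f[7L] else ".",
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Read a BED3/BED6 file as intervals
#'
#' @param path Path to a BED file (0-based half-open).
#' @return A `genomic_intervals` data frame; `name` and `score` columns
#'   are included when present.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !grepl("^(track|browser|#)", lines)]
  if (length(lines) == 0L)
    return(gintervals(character(), integer(), integer()))
  f <- strsplit(lines, "\t")
  ncol <- min(lengths(f))
  get <- function(k) vapply(f, `[[`, character(1), k)
  gintervals(
    contig = get(1L),
    start = as.numeric(get(2L)),
    end = as.numeric(get(3L)),
    strand = if (ncol >= 6L) get(6L) else "*",
    name = if (ncol >= 4L) get(4L) else ".",
    score = if (ncol >= 5L) get(5L) else "0"
  )
}

#' Write intervals to BED6
#'
#' @param intervals Interval data frame; optional `name`, `score`,
#'   `strand` columns are used when present.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_bed <- function(intervals, path) {
  n <- nrow(intervals)
  name <- if ("name" %in% names(intervals)) intervals$name else rep(".", n)
  score <- if ("score" %in% names(intervals)) intervals$score else rep(0L, n)
  strand <- if ("strand" %in% names(intervals)) intervals$strand else rep(".", n)
  strand[strand == "*"] <- "."
  lines <- sprintf("%s\t%d\t%d\t%s\t%s\t%s",
                   intervals$contig, as.integer(intervals$start),
                   as.integer(intervals$end), name, score, strand)
  writeLines(lines, path)
  invisible(path)
}

#' Read a gene model table
#'
#' Accepts a tab-separated table with columns `gene_id`, `contig`,
#' `start`, `end`, `strand` (header required), or GFF3 where `gene`
#' lines are used (`gene_id` from the `ID=` attribute). The TSS is
#' `start` for `+` genes and `end - 1` for `-` genes.
#'
#' @param path Path to the table.
#' @return Data frame with columns `gene_id`, `contig`, `start`, `end`,
#'   `strand`, `tss`.
#' @export
read_gene_table <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("^##gff", first) || length(strsplit(first, "\t")[[1L]]) == 9L) {
    df <- read_genes_gff3(path)
  } else {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("gene_id", "contig", "start", "end", "strand")
    miss <- setdiff(need, names(df))
    if (length(miss) > 0L)
      stop("gene table missing column(s): ", paste(miss, collapse = ", "))
  }
  stopifnot(all(df$strand %in% c("+", "-")))
  df$tss <- ifelse(df$strand == "+", df$start, df$end - 1)
  df
}

read_genes_gff3 <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  f <- strsplit(lines, "\t")
  keep <- vapply(f, function(x) length(x) == 9L && x[3L] == "gene", logical(1))
  f <- f[keep]
  if (length(f) == 0L) stop("no gene lines in GFF3: ", path)
  data.frame(
    gene_id = vapply(f, function(x)
      sub("^.*ID=([^;]+).*$", "\\1", x[9L]), character(1)),
    contig = vapply(f, `[[`, character(1), 1L),
    start = as.numeric(vapply(f, `[[`, character(1), 4L)) - 1,  # GFF 1-based
    end = as.numeric(vapply(f, `[[`, character(1), 5L)),
    strand = vapply(f, `[[`, character(1), 7L),
    stringsAsFactors = FALSE
  )
}

#' Read a differential-expression table
#'
#' Tab-separated with header; needs columns `gene_id`, `fold_change`,
#' `padj` (a DESeq2-style export can be mapped via `col_map`, e.g.
#' `c(fold_change = "log2FoldChange")` with `log2 = TRUE`).
#'
#' @param path Path to the TSV.
#' @param col_map Optional named character vector mapping required names
#'   to columns present in the file.
#' @param log2 If `TRUE`, the mapped fold-change column holds log2 values
#'   and is exponentiated.
#' @return Data frame with `gene_id`, `fold_change`, `padj`.
#' @export
read_expression_table <- function(path, col_map = NULL, log2 = FALSE) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  for (nm in names(col_map)) {
    if (!col_map[[nm]] %in% names(df))
      stop("mapped column not found: ", col_map[[nm]])
    df[[nm]] <- df[[col_map[[nm]]]]
  }
  miss <- setdiff(c("gene_id", "fold_change", "padj"), names(df))
  if (length(miss) > 0L)
    stop("expression table missing column(s): ", paste(miss, collapse = ", "))
  if (log2) df$fold_change <- 2^df$fold_change
  df[, c("gene_id", "fold_change", "padj")]
}

#' Read ortholog pairs
#'
#' @param path Two-column TSV (`gene_a`, `gene_b`), header optional.
#' @return Data frame with columns `gene_a`, `gene_b`.
#' @export
read_ortholog_pairs <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (identical(tolower(df[1L, 1L]), "gene_a")) df <- df[-1L, , drop = FALSE]
  stopifnot(ncol(df) >= 2L)
  data.frame(gene_a = df[[1L]], gene_b = df[[2L]], stringsAsFactors = FALSE)
}

#' Read a minimal VCF (biallelic SNPs with GT)
#'
#' Parses CHROM, POS, REF, ALT and the GT subfield only. Non-biallelic
#' or non-SNP records are skipped with a warning. Genotypes are
#' decomposed into haplotypes (phase ignored); `.` alleles become `NA`.
#'
#' @param path Path to an uncompressed VCF.
#' @return List with `contig`, `pos` (1-based), `ref`, `alt` vectors and
#'   `gt`, an integer matrix of 0/1/NA with one row per site and one
#'   column per haplotype.
#' @export
parse_vcf_minimal <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  body <- lines[!grepl("^#", lines)]
  if (length(body) == 0L)
    return(list(contig = character(0), pos = integer(0),
                ref = character(0), alt = character(0),
                gt = matrix(integer(0), nrow = 0)))
  f <- strsplit(body, "\t")
  keep <- rep(TRUE, length(f))
  gt_rows <- vector("list", length(f))
  for (i in seq_along(f)) {
    x <- f[[i]]
    if (length(x) < 10L) stop("VCF record with no samples at line: ", body[i])
    ref <- x[4L]; alt <- x[5L]
    if (nchar(ref) != 1L || nchar(alt) != 1L || grepl(",", alt) ||
        !ref %in% c("A", "C", "G", "T") || !alt %in% c("A", "C", "G", "T")) {
      warning("skipping non-biallelic/non-SNP record at ", x[1L], ":", x[2L])
      keep[i] <- FALSE
      next
    }
    fmt <- strsplit(x[9L], ":")[[1L]]
    gt_idx <- match("GT", fmt)
    if (is.na(gt_idx)) stop("no GT in FORMAT at ", x[1L], ":", x[2L])
    calls <- vapply(x[10:length(x)], function(smp)
      strsplit(smp, ":")[[1L]][gt_idx], character(1), USE.NAMES = FALSE)
    alleles <- unlist(strsplit(calls, "[/|]"))
    al <- suppressWarnings(as.integer(alleles))
    al[alleles == "."] <- NA_integer_
    gt_rows[[i]] <- al
  }
  f <- f[keep]
  gt_rows <- gt_rows[keep]
  nh <- unique(lengths(gt_rows))
  if (length(nh) > 1L) stop("inconsistent ploidy across VCF records")
  list(
    contig = vapply(f, `[[`, character(1), 1L),
    pos = as.integer(vapply(f, `[[`, character(1), 2L)),
    ref = vapply(f, `[[`, character(1), 4L),
    alt = vapply(f, `[[`, character(1), 5L),
    gt = do.call(rbind, gt_rows)
  )
}
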