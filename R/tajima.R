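#' Tajima's D normalising constants
#'
#' Standard constants for `n` sequences: `a1 = sum 1/i`, `a2 = sum
#' 1/i^2` (i = 1..n-1), `b1 = (n+1)/(3(n-1))`, `b2 =
#' 2(n^2+n+3)/(9n(n-1))`, `c1 = b1 - 1/a1`, `c2 = b2 - (n+2)/(a1 n) +
#' a2/a1^2`, `e1 = c1/a1`, `e2 = c2/(a1^2 + a2)`.
#'
#' @param n Number of sequences (haplotypes), `>= 2`.
#' @return Named list of the constants.
#' @export
tajima_constants <- function(n) {
  stopifnot(n >= 2)
  i <- seq_len(n - 1)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2,
       e1 = e1, e2 = e2)
}

#' Tajima's D from summary statistics
#'
#' `D = (pi - S/a1) / sqrt(e1 S + e2 S (S - 1))`; undefined (`NA`) when
#' `S = 0` or `n < 3`.
#'
#' @param S Number of segregating sites.
#' @param pi Mean pairwise difference (summed over sites).
#' @param n Number of haplotypes.
#' @return Tajima's D, or `NA`.
#' @export
tajima_d <- function(S, pi, n) {
  if (S == 0 || n < 3) return(NA_real_)
  k <- tajima_constants(n)
  (pi - S / k$a1) / sqrt(k$e1 * S + k$e2 * S * (S - 1))
}

#' Sliding-window Tajima's D from biallelic SNP genotypes
#'
#' Windows of `window_bp` advanced by `step_bp` across each contig
#' (full windows only; a contig shorter than one window forms a single
#' window spanning it). Sites with any missing genotype are dropped
#' from both `S` and `pi` (complete-case). `pi` is the average number
#' of pairwise differences across all haplotype pairs, summed over the
#' window's sites; with `j` alternate alleles among `n` haplotypes a
#' site contributes `j (n - j) / choose(n, 2)`.
#'
#' @param variants Parsed VCF from [parse_vcf_minimal()].
#' @param contig_lens Named vector of contig lengths (or a
#'   `genome_sequence`).
#' @param window_bp Window size (default 10000).
#' @param step_bp Step size (default 100).
#' @return Data frame with `contig`, `start`, `end`, `n`, `S`, `pi`,
#'   `D` (`NA` where undefined).
#' @export
sliding_tajima <- function(variants, contig_lens, window_bp = 10000L,
                           step_bp = 100L) {
  lens <- contig_lengths(contig_lens)
  gt <- variants$gt
  n_hap <- if (nrow(gt) > 0L) ncol(gt) else 0L
  complete <- if (nrow(gt) > 0L) rowSums(is.na(gt)) == 0L else logical(0)
  j_alt <- if (nrow(gt) > 0L) rowSums(gt == 1L, na.rm = TRUE) else integer(0)
  seg <- complete & j_alt > 0L & j_alt < n_hap
  pos0 <- variants$pos - 1L                     # to 0-based
  npairs <- if (n_hap >= 2L) n_hap * (n_hap - 1) / 2 else NA_real_
  out <- list()
  for (ctg in names(lens)) {
    L <- lens[[ctg]]
    w_starts <- if (L <= window_bp) 0
    else seq(0, L - window_bp, by = step_bp)
    on_ctg <- variants$contig == ctg & seg
    p <- pos0[on_ctg]
    contrib <- j_alt[on_ctg] * (n_hap - j_alt[on_ctg]) / npairs
    ord <- order(p)
    p <- p[ord]; contrib <- contrib[ord]
    cum <- c(0, cumsum(contrib))
    S_w <- pi_w <- numeric(length(w_starts))
    for (k in seq_along(w_starts)) {
      lo <- findInterval(w_starts[k] - 0.5, p)
      hi <- findInterval(w_starts[k] + window_bp - 0.5, p)
      S_w[k] <- hi - lo
      pi_w[k] <- cum[hi + 1L] - cum[lo + 1L]
    }
    D_w <- vapply(seq_along(w_starts), function(k)
      tajima_d(S_w[k], pi_w[k], n_hap), numeric(1))
    out[[ctg]] <- data.frame(
      contig = ctg, start = w_starts,
      end = pmin(w_starts + window_bp, L),
      n = n_hap, S = S_w, pi = pi_w, D = D_w,
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
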