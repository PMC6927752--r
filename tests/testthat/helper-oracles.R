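# Independent oracles used across test files. These deliberately take a
# different computational route than the package functions they check.

# IUPAC -> regex character class, for a regex-engine-based scan oracle.
iupac_regex <- function(motif) {
  map <- c(A = "A", C = "C", G = "G", T = "T",
           R = "[AG]", Y = "[CT]", S = "[CG]", W = "[AT]",
           K = "[GT]", M = "[AC]", B = "[CGT]", D = "[AGT]",
           H = "[ACT]", V = "[ACG]", N = "[ACGT]")
  paste(map[strsplit(toupper(motif), "")[[1L]]], collapse = "")
}

# Independent reverse complement on plain ACGTN strings.
revcomp_plain <- function(s) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1L]]), collapse = "")
}

# All start positions (1-based) of overlapping matches via regex lookahead.
regex_scan_starts <- function(seq, motif) {
  rx <- paste0("(?=", iupac_regex(motif), ")")
  m <- gregexpr(rx, seq, perl = TRUE)[[1L]]
  if (m[1L] == -1L) integer(0) else as.integer(m)
}

# Oracle scanner: forward and reverse-complement pattern, both via regex.
oracle_scan <- function(seq, motif) {
  rc <- {
    comp <- c(A = "T", C = "G", G = "C", T = "A",
              R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
              B = "V", D = "H", H = "D", V = "B", N = "N")
    paste(rev(comp[strsplit(toupper(motif), "")[[1L]]]), collapse = "")
  }
  list(plus = regex_scan_starts(seq, motif),
       minus = regex_scan_starts(seq, rc))
}

# Covered-base count of an interval set via per-base boolean masks.
mask_coverage <- function(intervals, lens) {
  total <- 0
  for (ctg in names(lens)) {
    mask <- logical(lens[[ctg]])
    sub <- intervals[intervals$contig == ctg, , drop = FALSE]
    for (i in seq_len(nrow(sub)))
      mask[(sub$start[i] + 1):sub$end[i]] <- TRUE
    total <- total + sum(mask)
  }
  total
}

# Exact Binomial(n, p) pmf by repeated convolution (no dbinom/pbinom).
binom_pmf_convolve <- function(n, p) {
  pmf <- 1
  for (i in seq_len(n)) pmf <- c(pmf * (1 - p), 0) + c(0, pmf * p)
  pmf   # pmf[k + 1] = P(X = k)
}

# 2x2 table probability with fixed margins, from binomial coefficients.
table_prob_2x2 <- function(a, r1, r2, c1) {
  # P(top-left = a | margins r1, r2, c1)
  choose(r1, a) * choose(r2, c1 - a) / choose(r1 + r2, c1)
}

# Two-sided Fisher p by enumerating all tables with the fixed margins.
fisher_enum_p <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  a_obs <- tab[1, 1]
  as <- max(0, c1 - r2):min(r1, c1)
  probs <- vapply(as, table_prob_2x2, numeric(1), r1 = r1, r2 = r2, c1 = c1)
  p_obs <- table_prob_2x2(a_obs, r1, r2, c1)
  sum(probs[probs <= p_obs * (1 + 1e-07)])
}

# Upper-tail hypergeometric by direct summation of binomial coefficients.
hyper_enum_p <- function(k, a, b, N) {
  ks <- k:min(a, b)
  sum(choose(a, ks) * choose(N - a, b - ks)) / choose(N, b)
}

# Tajima's D from a haplotype 0/1 matrix by brute-force pairwise Hamming
# distances and independently coded constants.
tajima_oracle <- function(gt) {
  n <- ncol(gt)
  seg <- apply(gt, 1, function(x) length(unique(x)) == 2)
  S <- sum(seg)
  if (S == 0 || n < 3) return(NA_real_)
  pairs <- utils::combn(n, 2)
  diffs <- apply(pairs, 2, function(p) sum(gt[, p[1]] != gt[, p[2]]))
  pi <- mean(diffs)
  i <- 1:(n - 1)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1; e2 <- c2 / (a1^2 + a2)
  (pi - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# Random ACGT sequence.
rand_seq <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# Random interval set on the given contig lengths.
rand_intervals <- function(n, lens, max_len = 500) {
  ci <- sample(length(lens), n, replace = TRUE)
  len <- sample(max_len, n, replace = TRUE)
  start <- vapply(seq_len(n), function(i)
    sample(max(1, lens[[ci[i]]] - len[i]), 1) - 1, numeric(1))
  gintervals(names(lens)[ci], start, pmin(start + len, lens[ci]))
}
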