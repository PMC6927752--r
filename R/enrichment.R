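#' Enrichment test result
#'
#' Lightweight container shared by all four significance tests.
#'
#' @param observed Observed count.
#' @param expected Expected (real) count under the null.
#' @param total Total count.
#' @param statistic Test statistic.
#' @param p_value P-value in `[0, 1]`.
#' @param test_name Identifier of the test.
#' @return An `enrichment_result` list.
#' @export
enrichment_result <- function(observed, expected, total, statistic,
                              p_value, test_name) {
  stopifnot(p_value >= 0, p_value <= 1 + 1e-12)
  structure(
    list(observed = observed, expected = expected, total = total,
         statistic = statistic, p_value = min(p_value, 1), test_name = test_name),
    class = "enrichment_result"
  )
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("%s: observed=%s expected=%s total=%s statistic=%.4g p=%.4g\n",
              x$test_name, format(x$observed), format(x$expected),
              format(x$total), x$statistic, x$p_value))
  invisible(x)
}

#' Cumulative binomial overlap enrichment test
#'
#' One-sided (enrichment) test of whether `n_inside` of `n_total` sites
#' falling in a region covering `genome_fraction` of the genome exceeds
#' chance: `p = P(X >= n_inside)` for `X ~ Binomial(n_total,
#' genome_fraction)`, computed with the stable upper-tail routine.
#'
#' @param n_inside Number of sites inside the region class.
#' @param n_total Total number of sites.
#' @param genome_fraction Fraction of the genome covered, in (0, 1).
#' @return An `enrichment_result` (`statistic` is `n_inside`).
#' @export
binomial_overlap_test <- function(n_inside, n_total, genome_fraction) {
  stopifnot(n_inside >= 0, n_inside <= n_total)
  if (genome_fraction <= 0 || genome_fraction >= 1)
    stop("genome_fraction must lie strictly inside (0, 1)")
  p <- stats::pbinom(n_inside - 1, n_total, genome_fraction,
                     lower.tail = FALSE)
  enrichment_result(
    observed = n_inside,
    expected = n_total * genome_fraction,
    total = n_total,
    statistic = n_inside,
    p_value = p,
    test_name = "binomial_overlap"
  )
}

#' Two-cell chi-squared goodness-of-fit proximity test
#'
#' Compares an observed count against a background expectation out of a
#' fixed total: `chi2 = (O-E)^2/E + ((T-O)-(T-E))^2/(T-E)` on 1 df,
#' without continuity correction. This construction reproduces the
#' printed enrichment p-values for upstream-proximity counts (e.g.
#' 60 observed vs 28 expected of 1462 gives p ~ 1e-9).
#'
#' @param observed Observed count (integer, `<= total`).
#' @param expected Expected real count under the null, in (0, total).
#' @param total Total number of trials (genes).
#' @return An `enrichment_result` (`statistic` is the chi-squared value).
#' @export
chi2_proximity_test <- function(observed, expected, total) {
  if (expected <= 0 || expected >= total)
    stop("expected must lie strictly between 0 and total")
  stopifnot(observed >= 0, observed <= total)
  chi2 <- (observed - expected)^2 / expected +
    ((total - observed) - (total - expected))^2 / (total - expected)
  p <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  enrichment_result(
    observed = observed, expected = expected, total = total,
    statistic = chi2, p_value = p, test_name = "chi2_proximity"
  )
}

#' Fisher's exact test on a 2x2 table
#'
#' Two-sided, summing hypergeometric probabilities of tables (with the
#' observed margins) at most as probable as the observed one — the
#' convention of [stats::fisher.test()].
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return An `enrichment_result` (`statistic` is the odds ratio
#'   estimate; `observed` is cell `[1,1]`, `total` the table sum).
#' @export
fisher_exact_2x2 <- function(table) {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == c(2L, 2L)), all(table >= 0))
  if (sum(table) == 0) stop("all-zero 2x2 table")
  ft <- stats::fisher.test(table)
  n <- sum(table)
  enrichment_result(
    observed = table[1L, 1L],
    expected = sum(table[1L, ]) * sum(table[, 1L]) / n,
    total = n,
    statistic = unname(ft$estimate),
    p_value = ft$p.value,
    test_name = "fisher_exact"
  )
}

#' Hypergeometric overlap test
#'
#' Upper-tail probability that two sets of sizes `set_a` and `set_b`
#' drawn from a universe of size `universe` share at least `k_overlap`
#' elements: `p = P(X >= k_overlap)`,
#' `X ~ Hypergeometric(universe, set_a, set_b)`.
#'
#' @param k_overlap Observed overlap.
#' @param set_a,set_b Set sizes.
#' @param universe Universe size.
#' @return An `enrichment_result` (`statistic` is `k_overlap`).
#' @export
hypergeometric_overlap_test <- function(k_overlap, set_a, set_b, universe) {
  if (k_overlap > min(set_a, set_b) || set_a > universe || set_b > universe ||
      k_overlap < 0)
    stop("inconsistent counts for hypergeometric test")
  p <- stats::phyper(k_overlap - 1, set_a, universe - set_a, set_b,
                     lower.tail = FALSE)
  enrichment_result(
    observed = k_overlap,
    expected = set_a * set_b / universe,
    total = universe,
    statistic = k_overlap,
    p_value = p,
    test_name = "hypergeometric_overlap"
  )
}
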