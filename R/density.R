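# Run code with a locally seeded RNG, restoring the caller's stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Per-window site counts across a genome
#'
#' Counts sites in windows of `window_bp` advanced by `step_bp`, on all
#' contigs strictly longer than `window_bp`. A site is assigned to a
#' window when its *start* lies in `[w_start, w_start + window_bp)`, so
#' for tiling windows (`step_bp == window_bp`) every site on an included
#' contig is counted exactly once. The trailing partial window at the
#' contig end is included.
#'
#' @param matches Site intervals (only `contig` and `start` are used).
#' @param genome A `genome_sequence` or named vector of contig lengths.
#' @param window_bp Window size in bp (default 1000).
#' @param step_bp Step size in bp (default 1000); must be `<= window_bp`.
#' @return A `density_profile`: list with `window_bp`, `step_bp`,
#'   `windows` (data frame `contig`, `window_start`, `count`), `counts`
#'   (convenience numeric vector) and `n_windows`.
#' @export
window_counts <- function(matches, genome, window_bp = 1000L,
                          step_bp = 1000L) {
  stopifnot(step_bp >= 1L, step_bp <= window_bp)
  lens <- contig_lengths(genome)
  lens <- lens[lens > window_bp]
  out <- vector("list", length(lens))
  for (ci in seq_along(lens)) {
    ctg <- names(lens)[ci]
    L <- lens[[ci]]
    w_starts <- seq(0, L - 1, by = step_bp)
    s <- sort(matches$start[matches$contig == ctg])
    cnt <- findInterval(w_starts + window_bp - 0.5, s) -
      findInterval(w_starts - 0.5, s)
    out[[ci]] <- data.frame(contig = ctg, window_start = w_starts,
                            count = cnt, stringsAsFactors = FALSE)
  }
  windows <- if (length(out) > 0L) do.call(rbind, out)
  else data.frame(contig = character(0), window_start = numeric(0),
                  count = numeric(0))
  rownames(windows) <- NULL
  structure(
    list(window_bp = window_bp, step_bp = step_bp, windows = windows,
         counts = windows$count, n_windows = nrow(windows)),
    class = "density_profile"
  )
}

#' @export
print.density_profile <- function(x, ...) {
  cat("density_profile:", x$n_windows, "windows of", x$window_bp,
      "bp (step", x$step_bp, "bp ), max count", max(c(0, x$counts)), "\n")
  invisible(x)
}

#' Cumulative window-count distribution
#'
#' For each `k` in `1..k_max`, the number of windows holding at least
#' `k` sites — the cumulative curve used to compare HSE pile-up across
#' genomes.
#'
#' @param profile A `density_profile` from [window_counts()].
#' @param k_max Largest threshold (default 100).
#' @return Data frame with columns `k` and `n_windows_ge_k`
#'   (non-increasing in `k`).
#' @export
cumulative_bins <- function(profile, k_max = 100L) {
  stopifnot(k_max >= 1L)
  ks <- seq_len(k_max)
  data.frame(
    k = ks,
    n_windows_ge_k = vapply(ks, function(k) sum(profile$counts >= k),
                            numeric(1))
  )
}

#' Sample random k-mer start positions uniformly over a genome
#'
#' Positions are drawn with replacement, uniformly over all starts that
#' admit a full `site_len_bp`-mer on a contig; contigs are weighted by
#' their number of valid starts.
#'
#' @param n_sites Number of positions to draw.
#' @param site_len_bp Site length in bp.
#' @param genome A `genome_sequence` or named vector of contig lengths.
#' @return Interval data frame of the sampled sites (0-based).
#' @export
sample_kmer_starts <- function(n_sites, site_len_bp, genome) {
  lens <- contig_lengths(genome)
  valid <- lens - site_len_bp + 1
  valid[valid < 0] <- 0
  if (sum(valid) == 0)
    stop("no contig admits a full ", site_len_bp, "-mer")
  lens <- lens[valid > 0]
  valid <- valid[valid > 0]
  ci <- sample.int(length(valid), n_sites, replace = TRUE,
                   prob = valid / sum(valid))
  pos <- floor(stats::runif(n_sites) * valid[ci])
  gintervals(names(valid)[ci], pos, pos + site_len_bp)
}

#' Permutation test for HSE clustering in 1-kb windows
#'
#' Draws `n_sites` random `site_len_bp`-mer positions, bins them into
#' windows, and counts windows holding strictly more than `threshold`
#' sites. The observed count of such high-density windows is compared
#' to the sampled count with Fisher's exact test over the common window
#' universe.
#'
#' @param n_sites Number of random sites (match the observed site count).
#' @param site_len_bp Site length (15 for the HSE motif).
#' @param genome A `genome_sequence` or named vector of contig lengths.
#' @param threshold Strict count threshold (default 10: high-density
#'   means >= 11 sites).
#' @param observed_high_bins Observed number of high-density windows.
#' @param seed Integer seed for the draw (reproducibility).
#' @param window_bp Window size (default 1000, tiling).
#' @return List with `sampled_high_bins`, `n_windows`, `profile`
#'   (sampled-site `density_profile`) and `result` (Fisher
#'   `enrichment_result`).
#' @export
permutation_cluster_test <- function(n_sites, site_len_bp, genome,
                                     threshold = 10L, observed_high_bins,
                                     seed = NULL, window_bp = 1000L) {
  stopifnot(n_sites >= 1L)
  sites <- with_seed(seed, sample_kmer_starts(n_sites, site_len_bp, genome))
  prof <- window_counts(sites, genome, window_bp = window_bp,
                        step_bp = window_bp)
  sampled_high <- sum(prof$counts > threshold)
  nw <- prof$n_windows
  tab <- rbind(
    c(observed_high_bins, nw - observed_high_bins),
    c(sampled_high, nw - sampled_high)
  )
  list(
    sampled_high_bins = sampled_high,
    n_windows = nw,
    profile = prof,
    result = fisher_exact_2x2(tab)
  )
}
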