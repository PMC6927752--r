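#' Classify HSEs as Helitron-acquired (Hac) or Helitron-independent (Hin)
#'
#' An HSE is Hac when its interval lies entirely within one merged
#' Helitron region (`start >= h.start` and `end <= h.end`); everything
#' else is Hin. Containment is tested against *merged* regions so a
#' motif spanning two overlapping annotations still counts as Hac. The
#' `host_repeat` is taken from the original (unmerged) annotation with
#' maximal overlap, ties broken by file order.
#'
#' @param matches Motif matches from [scan_genome()].
#' @param merged_helitrons Merged Helitron intervals
#'   ([merge_intervals()] output).
#' @param annotations Optional unmerged [parse_repeatmasker()] records
#'   used to name the host repeat of each Hac HSE.
#' @return `matches` with extra columns `category` (`"Hac"`/`"Hin"`) and
#'   `host_repeat` (`NA` for Hin).
#' @export
classify_hses <- function(matches, merged_helitrons, annotations = NULL) {
  n <- nrow(matches)
  category <- rep("Hin", n)
  host <- rep(NA_character_, n)
  if (n > 0L && nrow(merged_helitrons) > 0L) {
    for (ctg in unique(matches$contig)) {
      mi <- which(matches$contig == ctg)
      h <- merged_helitrons[merged_helitrons$contig == ctg, , drop = FALSE]
      if (nrow(h) == 0L) next
      h <- h[order(h$start), , drop = FALSE]
      idx <- findInterval(matches$start[mi], h$start)
      inside <- idx >= 1L & matches$end[mi] <= h$end[pmax(idx, 1L)]
      category[mi[inside]] <- "Hac"
    }
  }
  if (!is.null(annotations) && any(category == "Hac")) {
    for (i in which(category == "Hac")) {
      ov <- overlap_bp_vec(annotations, matches$contig[i],
                           matches$start[i], matches$end[i])
      if (any(ov > 0))
        host[i] <- annotations$repeat_name[which.max(ov)]  # first max = file order
    }
  }
  out <- matches
  out$category <- category
  out$host_repeat <- host
  out
}

#' Select HSF-1-bound HSEs from ChIP peak summits
#'
#' A match is "bound" when it overlaps a single summit window by at
#' least `min_overlap_bp`. Each summit position `s` (single bp) anchors
#' a centred window `[s - (w-1)/2, s + (w-1)/2 + 1)` of odd width `w`.
#'
#' @param matches Motif matches from [scan_genome()].
#' @param summits Either an interval data frame of single-bp summits
#'   (`end = start + 1`) or a list with `contig` and `pos` vectors
#'   (0-based positions).
#' @param window_bp Window width in bp; must be odd (default 101).
#' @param min_overlap_bp Minimum overlap with one window (default 14).
#' @return The subset of `matches` that is bound, each row once.
#' @export
bound_hses_from_summits <- function(matches, summits, window_bp = 101L,
                                    min_overlap_bp = 14L) {
  if (window_bp %% 2L == 0L)
    stop("window_bp must be odd so the summit has a unique centre")
  half <- (window_bp - 1L) / 2L
  if (is.data.frame(summits)) {
    s_ctg <- summits$contig
    s_pos <- summits$start
  } else {
    s_ctg <- summits$contig
    s_pos <- summits$pos
  }
  n <- nrow(matches)
  bound <- logical(n)
  for (ctg in unique(matches$contig)) {
    mi <- which(matches$contig == ctg)
    sp <- s_pos[s_ctg == ctg]
    if (length(sp) == 0L) next
    w_start <- sp - half
    w_end <- sp + half + 1
    for (i in mi) {
      ov <- pmin(matches$end[i], w_end) - pmax(matches$start[i], w_start)
      if (any(ov >= min_overlap_bp)) bound[i] <- TRUE
    }
  }
  matches[bound, , drop = FALSE]
}

#' Per-genome HSE/Helitron overlap summary
#'
#' Composes the scan, classification, binomial overlap test and window
#' density count into the per-species summary row used to compare
#' genomes: total HSEs, HSEs inside Helitrons, merged Helitron genome
#' fraction, cumulative binomial p, and the number of 1-kb windows with
#' strictly more than `density_threshold` HSEs.
#'
#' @param genome A `genome_sequence`.
#' @param helitron_annotations Repeat annotations
#'   ([parse_repeatmasker()] output, already keyword-filtered).
#' @param pattern Motif ([compile_iupac_pattern()] output or IUPAC
#'   string).
#' @param window_bp Density window size (default 1000).
#' @param density_threshold Strict HSE-count threshold (default 10,
#'   i.e. windows with >= 11 HSEs are counted).
#' @return A one-row data frame with columns `n_hse_total`,
#'   `n_hse_in_helitron`, `helitron_fraction`, `binomial_p`,
#'   `n_windows_gt10`.
#' @export
species_overlap_summary <- function(genome, helitron_annotations,
                                    pattern = compile_iupac_pattern(),
                                    window_bp = 1000L,
                                    density_threshold = 10L) {
  matches <- scan_genome(genome, pattern)
  merged <- merge_intervals(helitron_annotations)
  cls <- classify_hses(matches, merged)
  n_total <- nrow(matches)
  n_in <- sum(cls$category == "Hac")
  if (nrow(merged) == 0L) {
    warning("no Helitron annotations: overlap fraction undefined, p set to 1")
    frac <- 0
    p <- 1
  } else {
    frac <- genome_fraction(merged, genome)
    p <- if (n_total > 0L)
      binomial_overlap_test(n_in, n_total, frac)$p_value else 1
  }
  prof <- window_counts(matches, genome, window_bp = window_bp,
                        step_bp = window_bp)
  data.frame(
    n_hse_total = n_total,
    n_hse_in_helitron = n_in,
    helitron_fraction = frac,
    binomial_p = p,
    n_windows_gt10 = sum(prof$counts > density_threshold)
  )
}
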