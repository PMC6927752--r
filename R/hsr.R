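#' Call heat-shock up-regulated genes from an expression table
#'
#' Both thresholds are strict: `fold_change > fc_min` and
#' `padj < padj_max` (defaults 2 and 0.01, i.e. log2 fold change > 1).
#'
#' @param expression_table Data frame with `gene_id`, `fold_change`,
#'   `padj` columns (see [read_expression_table()]).
#' @param fc_min Fold-change threshold (strict).
#' @param padj_max Adjusted-p threshold (strict).
#' @return Character vector of up-regulated gene ids.
#' @export
call_up_genes <- function(expression_table, fc_min = 2, padj_max = 0.01) {
  miss <- setdiff(c("gene_id", "fold_change", "padj"),
                  names(expression_table))
  if (length(miss) > 0L)
    stop("expression table missing column(s): ", paste(miss, collapse = ", "))
  keep <- expression_table$fold_change > fc_min &
    expression_table$padj < padj_max
  keep[is.na(keep)] <- FALSE
  expression_table$gene_id[keep]
}

#' Strand-aware upstream distance from a TSS to a site
#'
#' Distance from the gene's TSS to the nearest base of the site, looking
#' upstream of the gene: for `+` genes the site must not start past the
#' TSS (`distance = tss - (site_end - 1)`), for `-` genes mirrored
#' (`distance = site_start - tss`). A site overlapping the TSS base has
#' distance 0; a site strictly downstream (or on another contig) yields
#' `NA`.
#'
#' @param gene One gene-model row (`contig`, `strand`, `tss`).
#' @param site One interval (`contig`, `start`, `end`).
#' @return Non-negative distance in bp, or `NA`.
#' @export
upstream_distance <- function(gene, site) {
  if (as.character(gene$contig) != as.character(site$contig))
    return(NA_real_)
  if (gene$strand == "+") {
    if (site$start > gene$tss) return(NA_real_)
    max(0, gene$tss - (site$end - 1))
  } else {
    if (site$end - 1 < gene$tss) return(NA_real_)
    max(0, site$start - gene$tss)
  }
}

# Per-gene minimum upstream distance to any site; NA when none upstream.
min_upstream_distances <- function(genes, sites) {
  n <- nrow(genes)
  out <- rep(NA_real_, n)
  for (ctg in unique(genes$contig)) {
    gi <- which(genes$contig == ctg)
    s <- sites[sites$contig == ctg, , drop = FALSE]
    if (nrow(s) == 0L) next
    for (i in gi) {
      if (genes$strand[i] == "+") {
        d <- genes$tss[i] - (s$end - 1)
        d <- d[s$start <= genes$tss[i]]
      } else {
        d <- s$start - genes$tss[i]
        d <- d[s$end - 1 >= genes$tss[i]]
      }
      if (length(d) > 0L) out[i] <- max(0, min(d))
    }
  }
  out
}

#' Upstream-proximity profile of up-regulated genes with sampled background
#'
#' Each gene contributes to the 500-bp bin of its *minimum* upstream
#' distance to any site (genes with no upstream site within `max_bp`
#' contribute nothing). The background samples `|up_genes|` genes
#' uniformly without replacement from `all_genes`, recomputes the bins,
#' and averages over `n_reps` replicates. Enrichment within
#' `cutoff_bp` is tested with the two-cell chi-squared test against the
#' (unrounded) background mean.
#'
#' @param up_genes Character vector of up-regulated gene ids (subset of
#'   `all_genes$gene_id`).
#' @param all_genes Gene-model data frame ([read_gene_table()] layout).
#' @param sites Site intervals (e.g. bound HSEs).
#' @param bin_bp Bin width (default 500).
#' @param max_bp Profile reach upstream (default 10000).
#' @param cutoff_bp Enrichment cutoff, strict `<` (default 2500).
#' @param n_reps Background replicates (default 100).
#' @param seed Integer seed for background sampling.
#' @return A `proximity_profile`: list with `bins` (data frame
#'   `bin_start`, `observed`, `background_mean`), `observed_within`,
#'   `expected_within`, `n_up`, and `enrichment`
#'   (an `enrichment_result`, or `NULL` when the background is
#'   degenerate).
#' @export
proximity_profile <- function(up_genes, all_genes, sites, bin_bp = 500L,
                              max_bp = 10000L, cutoff_bp = 2500L,
                              n_reps = 100L, seed = NULL) {
  up_genes <- unique(up_genes)
  if (length(up_genes) > nrow(all_genes))
    stop("more up-regulated genes than genes in the universe")
  if (!all(up_genes %in% all_genes$gene_id))
    stop("up_genes must be a subset of all_genes$gene_id")
  dmin <- min_upstream_distances(all_genes, sites)
  breaks <- seq(0, max_bp, by = bin_bp)
  bin_counts <- function(d) {
    d <- d[!is.na(d) & d < max_bp]
    tabulate(floor(d / bin_bp) + 1L, nbins = length(breaks) - 1L)
  }
  is_up <- all_genes$gene_id %in% up_genes
  observed <- bin_counts(dmin[is_up])
  observed_within <- sum(dmin[is_up] < cutoff_bp, na.rm = TRUE)
  n_up <- sum(is_up)
  bg <- with_seed(seed, {
    mat <- matrix(0, nrow = n_reps, ncol = length(breaks) - 1L)
    within <- numeric(n_reps)
    for (r in seq_len(n_reps)) {
      idx <- sample.int(nrow(all_genes), n_up, replace = FALSE)
      mat[r, ] <- bin_counts(dmin[idx])
      within[r] <- sum(dmin[idx] < cutoff_bp, na.rm = TRUE)
    }
    list(mean = colMeans(mat), within = mean(within))
  })
  enr <- if (bg$within > 0 && bg$within < n_up)
    chi2_proximity_test(observed_within, bg$within, n_up)
  else {
    warning("degenerate background (all or none within cutoff); ",
            "no enrichment test")
    NULL
  }
  structure(
    list(
      bin_bp = bin_bp, max_bp = max_bp, cutoff_bp = cutoff_bp,
      n_reps = n_reps, n_up = n_up,
      bins = data.frame(bin_start = breaks[-length(breaks)],
                        observed = observed,
                        background_mean = bg$mean),
      observed_within = observed_within,
      expected_within = bg$within,
      enrichment = enr
    ),
    class = "proximity_profile"
  )
}

#' @export
print.proximity_profile <- function(x, ...) {
  cat(sprintf(
    "proximity_profile: %d up genes; %d observed vs %.2f expected within %d bp\n",
    x$n_up, x$observed_within, x$expected_within, x$cutoff_bp))
  if (!is.null(x$enrichment)) print(x$enrichment)
  invisible(x)
}

#' Call heat-shock-response (HSR) genes
#'
#' An HSR gene is an up-regulated gene whose minimum strand-aware
#' upstream distance to a qualifying site (normally an HSF-1-bound HSE)
#' is strictly less than `cutoff_bp`.
#'
#' @param genes Gene-model data frame.
#' @param up_genes Character vector of up-regulated gene ids.
#' @param bound_hses Site intervals (e.g. from
#'   [bound_hses_from_summits()]).
#' @param cutoff_bp Strict upstream cutoff in bp (default 2500).
#' @return Character vector of HSR gene ids.
#' @export
call_hsr_genes <- function(genes, up_genes, bound_hses, cutoff_bp = 2500L) {
  sub <- genes[genes$gene_id %in% up_genes, , drop = FALSE]
  if (nrow(sub) == 0L) return(character(0))
  d <- min_upstream_distances(sub, bound_hses)
  sub$gene_id[!is.na(d) & d < cutoff_bp]
}

#' Count HSEs upstream of one gene
#'
#' @param gene One gene-model row.
#' @param hse_matches Motif match intervals.
#' @param cutoff_bp Strict upstream cutoff (default 2500).
#' @return Number of matches with upstream distance `< cutoff_bp`.
#' @export
count_upstream_hses <- function(gene, hse_matches, cutoff_bp = 2500L) {
  if (nrow(hse_matches) == 0L) return(0L)
  d <- vapply(seq_len(nrow(hse_matches)), function(i)
    upstream_distance(gene, hse_matches[i, ]), numeric(1))
  sum(!is.na(d) & d < cutoff_bp)
}

#' Partition orthologous up-regulated genes into shared and unique sets
#'
#' A pair qualifies in species A when its A-side gene is up-regulated
#' and has a qualifying upstream HSE (`up_a` and `has_hse_a`), and
#' analogously in B. `shared` pairs qualify in both species, `unique_a`
#' / `unique_b` in exactly one. The overlap of the two qualifying sets
#' is tested with the hypergeometric test over the ortholog-pair
#' universe.
#'
#' @param up_a,up_b Character vectors of up-regulated gene ids per
#'   species.
#' @param has_hse_a,has_hse_b Character vectors of gene ids with
#'   qualifying upstream HSEs per species.
#' @param ortholog_pairs Data frame with `gene_a`, `gene_b`.
#' @param known_a,known_b Optional gene universes; pairs mentioning
#'   genes outside them are skipped with a warning.
#' @return List with `shared`, `unique_a`, `unique_b` (data frames of
#'   pairs) and `test` (an `enrichment_result`).
#' @export
partition_orthologs <- function(up_a, up_b, has_hse_a, has_hse_b,
                                ortholog_pairs,
                                known_a = NULL, known_b = NULL) {
  pairs <- ortholog_pairs
  if (!is.null(known_a) || !is.null(known_b)) {
    ok <- rep(TRUE, nrow(pairs))
    if (!is.null(known_a)) ok <- ok & pairs$gene_a %in% known_a
    if (!is.null(known_b)) ok <- ok & pairs$gene_b %in% known_b
    if (any(!ok)) {
      warning(sum(!ok), " ortholog pair(s) with unknown genes skipped")
      pairs <- pairs[ok, , drop = FALSE]
    }
  }
  qual_a <- pairs$gene_a %in% up_a & pairs$gene_a %in% has_hse_a
  qual_b <- pairs$gene_b %in% up_b & pairs$gene_b %in% has_hse_b
  list(
    shared = pairs[qual_a & qual_b, , drop = FALSE],
    unique_a = pairs[qual_a & !qual_b, , drop = FALSE],
    unique_b = pairs[!qual_a & qual_b, , drop = FALSE],
    test = hypergeometric_overlap_test(
      k_overlap = sum(qual_a & qual_b),
      set_a = sum(qual_a),
      set_b = sum(qual_b),
      universe = nrow(pairs)
    )
  )
}
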