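#' Configuration for the synthetic-data generator
#'
#' Defaults describe a small worm-like genome: 5 Mb of i.i.d. sequence
#' at 36% GC carrying ~300 non-overlapping Helitron copies (200-3000
#' bp), of which ~19% contain a cluster of embedded HSEs (geometric
#' with mean 5, plus a 2% heavy-tail chance of 20-120 copies,
#' mimicking the rare massively amplified elements), 150 scattered
#' Helitron-independent HSEs, ChIP summits at 30% of HSEs, 2000 genes
#' of which those with a bound HSE within 2.5 kb upstream are
#' up-regulated with probability 0.7 (background rate 0.05), and
#' biallelic SNPs across 20 diploid samples at Watterson theta 0.001
#' per bp.
#'
#' @param seed Integer seed; the whole bundle is a deterministic
#'   function of it.
#' @param genome_bp Total genome size in bp.
#' @param n_contigs Number of (near-)equal contigs.
#' @param gc GC fraction of the background sequence.
#' @param n_helitrons Number of Helitron copies.
#' @param helitron_len Length range (min, max) in bp.
#' @param frac_helitrons_with_hses Fraction of Helitrons carrying an
#'   HSE cluster.
#' @param hse_per_helitron_mean Mean cluster size (geometric).
#' @param hse_heavy_tail_p Probability a cluster is heavy-tailed.
#' @param hse_heavy_tail_range Heavy-tail cluster size range.
#' @param cluster_gap_bp Gap range between clustered HSEs in bp.
#' @param n_hin_hses Number of Helitron-independent HSEs.
#' @param frac_hses_with_summit Fraction of planted HSEs given a ChIP
#'   summit (these become "bound").
#' @param n_genes Number of genes.
#' @param frac_genes_proximal Target fraction of genes deliberately
#'   placed with a bound HSE < 2.5 kb upstream.
#' @param p_up_given_proximal Up-regulation probability for proximal
#'   genes.
#' @param p_up_background Up-regulation probability otherwise.
#' @param log2fc_signal_mean,log2fc_signal_sd Normal log2 fold-change
#'   model for up-regulated genes.
#' @param log2fc_null_sd Normal(0, sd) log2 fold change for the rest.
#' @param n_variant_samples Number of diploid samples in the VCF.
#' @param theta_per_bp Watterson theta per bp for SNP density.
#' @param motif IUPAC motif planted and scanned.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       genome_bp = 5e6,
                       n_contigs = 5L,
                       gc = 0.36,
                       n_helitrons = 300L,
                       helitron_len = c(200L, 3000L),
                       frac_helitrons_with_hses = 0.19,
                       hse_per_helitron_mean = 5,
                       hse_heavy_tail_p = 0.02,
                       hse_heavy_tail_range = c(20L, 120L),
                       cluster_gap_bp = c(1L, 30L),
                       n_hin_hses = 150L,
                       frac_hses_with_summit = 0.3,
                       n_genes = 2000L,
                       frac_genes_proximal = 0.05,
                       p_up_given_proximal = 0.7,
                       p_up_background = 0.05,
                       log2fc_signal_mean = 3,
                       log2fc_signal_sd = 1,
                       log2fc_null_sd = 0.5,
                       n_variant_samples = 20L,
                       theta_per_bp = 0.001,
                       motif = "NGAANNTTCNNGAAN") {
  cfg <- as.list(environment())
  fracs <- c(cfg$gc, cfg$frac_helitrons_with_hses, cfg$frac_hses_with_summit,
             cfg$frac_genes_proximal, cfg$p_up_given_proximal,
             cfg$p_up_background, cfg$hse_heavy_tail_p)
  stopifnot(all(fracs >= 0 & fracs <= 1), cfg$genome_bp > 0,
            cfg$helitron_len[1L] <= cfg$helitron_len[2L])
  structure(cfg, class = "sim_config")
}

REPEAT_NAMES <- c("Helitron1_CE", "HelitronY1_CE", "HelitronY1A_CE",
                  "HelitronY4_CE", "Helitron2_CE")

# Draw one concrete instance (plus-strand bases) of an allowed-set matrix.
instantiate_motif <- function(allowed) {
  bases <- rownames(allowed)
  vapply(seq_len(ncol(allowed)), function(j) {
    ok <- bases[allowed[, j]]
    ok[sample.int(length(ok), 1L)]
  }, character(1))
}

#' Generate a ground-truth-labelled synthetic input bundle
#'
#' Builds a genome with planted Helitrons, clustered Helitron-acquired
#' (Hac) HSEs, scattered Helitron-independent (Hin) HSEs, ChIP summits
#' over a subset of HSEs, genes whose proximity to bound HSEs drives
#' up-regulation, a DESeq2-style expression table, and a biallelic-SNP
#' VCF — everything the analysis pipeline consumes, with truth labels.
#'
#' @param config A [sim_config()].
#' @param out_dir Optional directory; when given, the bundle is written
#'   as `genome.fa`, `helitrons.out`, `helitrons.bed`, `summits.bed`,
#'   `genes.tsv`, `expression.tsv`, `variants.vcf`, `truth_hse.tsv`,
#'   `truth_genes.tsv`.
#' @return A list with in-memory versions of all of the above
#'   (`genome`, `helitrons`, `summits`, `genes`, `expression`,
#'   `variants`, `truth_hse`, `truth_genes`, `config`).
#' @export
simulate_bundle <- function(config = sim_config(), out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  exp_hel_total <- config$n_helitrons * mean(config$helitron_len)
  if (exp_hel_total > 0.5 * config$genome_bp)
    stop("infeasible packing: expected Helitron bases exceed half the genome")
  bundle <- with_seed(config$seed, simulate_bundle_impl(config))
  if (!is.null(out_dir)) write_bundle(bundle, out_dir)
  bundle
}

simulate_bundle_impl <- function(cfg) {
  pat <- compile_iupac_pattern(cfg$motif)
  L_mot <- pat$length
  base_len <- floor(cfg$genome_bp / cfg$n_contigs)
  lens <- rep(base_len, cfg$n_contigs)
  lens[cfg$n_contigs] <- cfg$genome_bp - base_len * (cfg$n_contigs - 1L)
  names(lens) <- paste0("ctg", seq_len(cfg$n_contigs))
  p_base <- c(A = (1 - cfg$gc) / 2, C = cfg$gc / 2,
              G = cfg$gc / 2, T = (1 - cfg$gc) / 2)
  seqs <- lapply(lens, function(L)
    sample(names(p_base), L, replace = TRUE, prob = p_base))

  ## --- Helitrons: non-overlapping placement by rejection -----------------
  hel <- place_helitrons(cfg, lens)

  ## --- HSEs ---------------------------------------------------------------
  hse <- plant_hses(cfg, pat, hel, lens)
  for (i in seq_len(nrow(hse))) {
    inst <- strsplit(hse$seq_plus[i], "")[[1L]]
    seqs[[hse$contig[i]]][(hse$start[i] + 1L):(hse$start[i] + L_mot)] <- inst
  }

  ## --- Summits over a subset of HSEs -------------------------------------
  n_hse <- nrow(hse)
  n_summit <- round(cfg$frac_hses_with_summit * n_hse)
  bound_idx <- if (n_summit > 0L) sort(sample.int(n_hse, n_summit)) else integer(0)
  hse$bound <- seq_len(n_hse) %in% bound_idx
  summits <- if (length(bound_idx) > 0L) {
    ctr <- floor((hse$start[bound_idx] + hse$end[bound_idx]) / 2)
    gintervals(hse$contig[bound_idx], ctr, ctr + 1)
  } else gintervals(character(0), integer(0), integer(0))

  ## --- Genes --------------------------------------------------------------
  genes <- place_genes(cfg, hse, lens)

  ## --- Expression ---------------------------------------------------------
  bound_sites <- hse[hse$bound, , drop = FALSE]
  dmin <- min_upstream_distances(genes, bound_sites)
  proximal <- !is.na(dmin) & dmin < 2500
  p_up <- ifelse(proximal, cfg$p_up_given_proximal, cfg$p_up_background)
  designated_up <- stats::runif(nrow(genes)) < p_up
  log2fc <- ifelse(designated_up,
                   stats::rnorm(nrow(genes), cfg$log2fc_signal_mean,
                                cfg$log2fc_signal_sd),
                   stats::rnorm(nrow(genes), 0, cfg$log2fc_null_sd))
  padj <- ifelse(designated_up, 1e-6, stats::runif(nrow(genes)))
  expression <- data.frame(
    gene_id = genes$gene_id,
    fold_change = 2^log2fc,
    padj = padj,
    stringsAsFactors = FALSE
  )
  is_up <- expression$fold_change > 2 & expression$padj < 0.01
  truth_genes <- data.frame(
    gene_id = genes$gene_id,
    proximal_bound_hse = proximal,
    min_upstream_bp = dmin,
    designated_up = designated_up,
    is_up = is_up,
    is_hsr = is_up & proximal,
    stringsAsFactors = FALSE
  )

  ## --- Variants -----------------------------------------------------------
  variants <- simulate_variants(cfg, lens, seqs)

  genome <- genome_sequence(vapply(seqs, paste, character(1), collapse = ""))
  list(
    genome = genome,
    helitrons = hel,
    summits = summits,
    genes = genes,
    expression = expression,
    variants = variants,
    truth_hse = hse,
    truth_genes = truth_genes,
    config = cfg
  )
}

place_helitrons <- function(cfg, lens) {
  ctg <- character(0); s <- numeric(0); e <- numeric(0)
  tries <- 0L
  while (length(s) < cfg$n_helitrons && tries < 50L * cfg$n_helitrons) {
    tries <- tries + 1L
    ci <- sample.int(length(lens), 1L, prob = lens / sum(lens))
    len <- sample(cfg$helitron_len[1L]:cfg$helitron_len[2L], 1L)
    if (lens[ci] <= len + 1) next
    st <- sample.int(lens[ci] - len, 1L) - 1L
    same <- ctg == names(lens)[ci]
    if (any(same & s < st + len & st < e)) next   # overlap: reject
    ctg <- c(ctg, names(lens)[ci]); s <- c(s, st); e <- c(e, st + len)
  }
  if (length(s) < cfg$n_helitrons)
    stop("could not place ", cfg$n_helitrons, " non-overlapping Helitrons")
  gintervals(ctg, s, e,
             repeat_name = sample(REPEAT_NAMES, length(s), replace = TRUE),
             repeat_class = "DNA/Helitron")
}

plant_hses <- function(cfg, pat, hel, lens) {
  L_mot <- pat$length
  rows <- list()
  with_hse <- stats::runif(nrow(hel)) < cfg$frac_helitrons_with_hses
  for (h in which(with_hse)) {
    hel_len <- hel$end[h] - hel$start[h]
    n_want <- if (stats::runif(1) < cfg$hse_heavy_tail_p)
      sample(cfg$hse_heavy_tail_range[1L]:cfg$hse_heavy_tail_range[2L], 1L)
    else stats::rgeom(1L, 1 / cfg$hse_per_helitron_mean) + 1L
    gaps <- sample(cfg$cluster_gap_bp[1L]:cfg$cluster_gap_bp[2L], n_want,
                   replace = TRUE)
    # cap cluster size by what fits with 1 bp of slack on both sides
    offs <- cumsum(c(0, (L_mot + gaps)[-n_want]))
    fits <- offs + L_mot <= hel_len - 2
    n <- sum(fits)
    if (n == 0L) next
    span <- offs[n] + L_mot
    cl_start <- hel$start[h] + 1 +
      sample.int(max(1, hel_len - 2 - span + 1), 1L) - 1L
    strands <- sample(c("+", "-"), n, replace = TRUE)
    for (k in seq_len(n)) {
      allowed <- if (strands[k] == "+") pat$allowed else pat$allowed_rc
      rows[[length(rows) + 1L]] <- data.frame(
        contig = hel$contig[h],
        start = cl_start + offs[k],
        end = cl_start + offs[k] + L_mot,
        strand = strands[k],
        label = "Hac",
        helitron = hel$repeat_name[h],
        seq_plus = paste(instantiate_motif(allowed), collapse = ""),
        stringsAsFactors = FALSE
      )
    }
  }
  hac <- if (length(rows) > 0L) do.call(rbind, rows)
  else data.frame(contig = character(0), start = numeric(0),
                  end = numeric(0), strand = character(0),
                  label = character(0), helitron = character(0),
                  seq_plus = character(0), stringsAsFactors = FALSE)

  # Hin: uniform placement outside Helitrons, non-overlapping with
  # anything planted so far
  occupied <- rbind(
    data.frame(contig = hel$contig, start = hel$start, end = hel$end),
    hac[, c("contig", "start", "end")]
  )
  hin_rows <- list()
  tries <- 0L
  while (length(hin_rows) < cfg$n_hin_hses && tries < 200L * cfg$n_hin_hses) {
    tries <- tries + 1L
    ci <- sample.int(length(lens), 1L, prob = lens / sum(lens))
    st <- sample.int(lens[ci] - L_mot, 1L) - 1L
    ctg <- names(lens)[ci]
    clash <- occupied$contig == ctg & occupied$start < st + L_mot &
      st < occupied$end
    if (any(clash)) next
    strand <- sample(c("+", "-"), 1L)
    allowed <- if (strand == "+") pat$allowed else pat$allowed_rc
    hin_rows[[length(hin_rows) + 1L]] <- data.frame(
      contig = ctg, start = st, end = st + L_mot, strand = strand,
      label = "Hin", helitron = NA_character_,
      seq_plus = paste(instantiate_motif(allowed), collapse = ""),
      stringsAsFactors = FALSE
    )
    occupied <- rbind(occupied,
                     data.frame(contig = ctg, start = st, end = st + L_mot))
  }
  if (length(hin_rows) < cfg$n_hin_hses)
    stop("could not place the requested number of Hin HSEs")
  out <- rbind(hac, do.call(rbind, hin_rows))
  rownames(out) <- NULL
  out
}

place_genes <- function(cfg, hse, lens) {
  L_gene <- 1000L
  bound <- hse[hse$bound, , drop = FALSE]
  n_prox <- min(nrow(bound), round(cfg$frac_genes_proximal * cfg$n_genes))
  pick <- if (n_prox > 0L) sample.int(nrow(bound), n_prox) else integer(0)
  g_ctg <- character(0); g_s <- numeric(0); g_e <- numeric(0)
  g_strand <- character(0)
  for (i in pick) {
    d <- sample(100:2400, 1L)
    strand <- sample(c("+", "-"), 1L)
    if (strand == "+") {
      tss <- bound$end[i] - 1 + d
      s <- tss; e <- tss + L_gene
    } else {
      tss <- bound$start[i] - d
      s <- tss - L_gene + 1; e <- tss + 1
    }
    if (s < 0 || e > lens[[bound$contig[i]]]) next
    g_ctg <- c(g_ctg, bound$contig[i]); g_s <- c(g_s, s); g_e <- c(g_e, e)
    g_strand <- c(g_strand, strand)
  }
  n_rest <- cfg$n_genes - length(g_s)
  ci <- sample.int(length(lens), n_rest, replace = TRUE,
                   prob = lens / sum(lens))
  pos <- vapply(ci, function(k)
    sample.int(lens[k] - L_gene, 1L) - 1L, numeric(1))
  g_ctg <- c(g_ctg, names(lens)[ci])
  g_s <- c(g_s, pos); g_e <- c(g_e, pos + L_gene)
  g_strand <- c(g_strand, sample(c("+", "-"), n_rest, replace = TRUE))
  ord <- order(g_ctg, g_s)
  genes <- data.frame(
    gene_id = sprintf("gene%04d", seq_along(g_s)),
    contig = g_ctg[ord], start = g_s[ord], end = g_e[ord],
    strand = g_strand[ord],
    stringsAsFactors = FALSE
  )
  genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1)
  genes
}

simulate_variants <- function(cfg, lens, seqs) {
  n_hap <- 2L * cfg$n_variant_samples
  k <- tajima_constants(n_hap)
  n_sites <- stats::rpois(1L, cfg$theta_per_bp * k$a1 * sum(lens))
  ci <- sample.int(length(lens), n_sites, replace = TRUE,
                   prob = lens / sum(lens))
  pos <- vapply(ci, function(j) sample.int(lens[j], 1L), numeric(1))
  contig <- names(lens)[ci]
  dup <- duplicated(paste(contig, pos))
  contig <- contig[!dup]; pos <- pos[!dup]
  ord <- order(contig, pos)
  contig <- contig[ord]; pos <- pos[ord]
  n_sites <- length(pos)
  # neutral frequency spectrum: derived count i with prob proportional to 1/i
  i_probs <- (1 / seq_len(n_hap - 1)) / k$a1
  jalt <- sample.int(n_hap - 1L, n_sites, replace = TRUE, prob = i_probs)
  gt <- matrix(0L, nrow = n_sites, ncol = n_hap)
  for (s in seq_len(n_sites))
    gt[s, sample.int(n_hap, jalt[s])] <- 1L
  ref <- vapply(seq_len(n_sites), function(s)
    seqs[[contig[s]]][pos[s]], character(1))
  alts <- c("A", "C", "G", "T")
  alt <- vapply(ref, function(r)
    sample(setdiff(alts, r), 1L), character(1), USE.NAMES = FALSE)
  list(contig = contig, pos = as.integer(pos), ref = ref, alt = alt, gt = gt)
}

write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(f) file.path(out_dir, f)
  write_fasta(bundle$genome, fp("genome.fa"))
  write_repeatmasker_out(bundle$helitrons, fp("helitrons.out"))
  hb <- bundle$helitrons
  hb$name <- hb$repeat_name
  write_bed(hb, fp("helitrons.bed"))
  write_bed(bundle$summits, fp("summits.bed"))
  utils::write.table(
    bundle$genes[, c("gene_id", "contig", "start", "end", "strand")],
    fp("genes.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(bundle$expression, fp("expression.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_vcf_minimal(bundle$variants, bundle$config$n_variant_samples,
                    fp("variants.vcf"))
  utils::write.table(bundle$truth_hse, fp("truth_hse.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(bundle$truth_genes, fp("truth_genes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(out_dir)
}

#' Write a genome_sequence as FASTA
#'
#' @param genome A `genome_sequence`.
#' @param path Output path.
#' @param width Line-wrap width (default 70).
#' @return The path, invisibly.
#' @export
write_fasta <- function(genome, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (ctg in names(genome$contigs)) {
    writeLines(paste0(">", ctg), con)
    s <- genome$contigs[[ctg]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

write_repeatmasker_out <- function(hel, path) {
  hdr <- c(
    "   SW   perc perc perc  query     position in query    matching repeat",
    "score   div. del. ins.  sequence  begin end   (left)   repeat class/family  begin end (left) ID",
    ""
  )
  lines <- sprintf(
    " 1000   10.0  0.0  0.0  %s %d %d (0) + %s %s 1 %d (0) %d",
    hel$contig, as.integer(hel$start) + 1L, as.integer(hel$end),
    hel$repeat_name, hel$repeat_class,
    as.integer(hel$end - hel$start), seq_len(nrow(hel)))
  writeLines(c(hdr, lines), path)
  invisible(path)
}

write_vcf_minimal <- function(variants, n_samples, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sprintf("S%03d", seq_len(n_samples))), collapse = "\t")
  ), con)
  if (length(variants$pos) > 0L) {
    gt <- variants$gt
    gts <- matrix("", nrow = nrow(gt), ncol = n_samples)
    for (s in seq_len(n_samples))
      gts[, s] <- paste(gt[, 2L * s - 1L], gt[, 2L * s], sep = "/")
    lines <- paste(
      variants$contig, variants$pos, ".", variants$ref, variants$alt,
      ".", "PASS", ".", "GT",
      apply(gts, 1L, paste, collapse = "\t"),
      sep = "\t")
    writeLines(lines, con)
  }
  invisible(path)
}
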