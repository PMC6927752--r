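toy_genes <- function() {
  data.frame(
    gene_id = c("g1", "g2", "g3"),
    contig = "c1",
    start = c(5000, 2000, 8000),
    end = c(6000, 3000, 9000),
    strand = c("+", "-", "+"),
    tss = c(5000, 2999, 8000),
    stringsAsFactors = FALSE
  )
}

test_that("call_up_genes applies strict thresholds", {
  tab <- data.frame(
    gene_id = paste0("g", 1:6),
    fold_change = c(2.0, 21, 3, 1.5, 2.5, 10),
    padj = c(0.001, 1e-6, 0.01, 1e-4, 0.005, 0.5)
  )
  up <- call_up_genes(tab)
  # hand filter: fc > 2 strictly AND padj < 0.01 strictly
  expect_setequal(up, c("g2", "g5"))
  expect_false("g1" %in% up)   # fc exactly 2 excluded
  expect_false("g3" %in% up)   # padj exactly 0.01 excluded
  expect_error(call_up_genes(tab[, 1:2]), "missing")
})

test_that("upstream_distance is strand-aware and measured to nearest base", {
  g <- list(contig = "c1", strand = "+", tss = 5000)
  expect_equal(upstream_distance(g, list(contig = "c1", start = 2400,
                                         end = 2415)), 2586)
  # overlap of the TSS base is distance 0
  expect_equal(upstream_distance(g, list(contig = "c1", start = 4995,
                                         end = 5010)), 0)
  # strictly downstream: absent
  expect_true(is.na(upstream_distance(g, list(contig = "c1", start = 6000,
                                              end = 6015))))
  expect_true(is.na(upstream_distance(g, list(contig = "c2", start = 2400,
                                              end = 2415))))
  # minus-strand mirror
  gm <- list(contig = "c1", strand = "-", tss = 5000)
  expect_equal(upstream_distance(gm, list(contig = "c1", start = 7000,
                                          end = 7015)), 2000)
  expect_equal(upstream_distance(gm, list(contig = "c1", start = 4995,
                                          end = 5010)), 0)
  expect_true(is.na(upstream_distance(gm, list(contig = "c1", start = 3000,
                                               end = 3015))))
})

test_that("count_upstream_hses equals a brute-force distance filter", {
  set.seed(19)
  gene <- list(contig = "c1", strand = "+", tss = 5000)
  sites <- gintervals("c1", s <- sample(0:9985, 200), s + 15)
  d <- vapply(seq_len(200), function(i)
    upstream_distance(gene, sites[i, ]), numeric(1))
  expect_equal(count_upstream_hses(gene, sites),
               sum(!is.na(d) & d < 2500))
  expect_equal(count_upstream_hses(gene, sites[0, ]), 0)
  # a planted cluster of 10 upstream HSEs is counted in full
  cl <- gintervals("c1", 3000 + 30 * (0:9), 3000 + 30 * (0:9) + 15)
  expect_equal(count_upstream_hses(gene, cl), 10)
})

test_that("proximity_profile: up = all genes means observed == background", {
  genes <- toy_genes()
  sites <- gintervals("c1", c(4000, 2500), c(4015, 2515))
  pp <- proximity_profile(genes$gene_id, genes, sites, n_reps = 10, seed = 1)
  expect_equal(pp$bins$observed, pp$bins$background_mean)
  expect_equal(pp$observed_within, pp$expected_within)
})

test_that("proximity_profile counts each gene once, in its minimum bin", {
  genes <- toy_genes()
  # g1 (+, tss 5000): sites at 4000-4015 (d = 986) and 2500-2515 (d = 2486)
  sites <- gintervals("c1", c(4000, 2500), c(4015, 2515))
  pp <- suppressWarnings(
    proximity_profile("g1", genes, sites, n_reps = 5, seed = 2))
  expect_equal(sum(pp$bins$observed), 1)
  expect_equal(pp$bins$observed[floor(986 / 500) + 1], 1)
  expect_error(proximity_profile(c("g1", "gX"), genes, sites), "subset")
})

test_that("proximity_profile is reproducible under a fixed seed", {
  set.seed(1)
  genes <- data.frame(
    gene_id = sprintf("g%03d", 1:200), contig = "c1",
    start = s <- sample(0:99000, 200), end = s + 1000,
    strand = sample(c("+", "-"), 200, TRUE), stringsAsFactors = FALSE
  )
  genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1)
  sites <- gintervals("c1", ss <- sample(0:99985, 40), ss + 15)
  up <- sample(genes$gene_id, 50)
  p1 <- proximity_profile(up, genes, sites, n_reps = 20, seed = 33)
  p2 <- proximity_profile(up, genes, sites, n_reps = 20, seed = 33)
  expect_identical(p1$bins, p2$bins)
  expect_identical(p1$enrichment$p_value, p2$enrichment$p_value)
})

test_that("background means converge to the all-gene bin frequencies", {
  set.seed(50)
  genes <- data.frame(
    gene_id = sprintf("g%03d", 1:300), contig = "c1",
    start = s <- sample(0:99000, 300), end = s + 1000,
    strand = sample(c("+", "-"), 300, TRUE), stringsAsFactors = FALSE
  )
  genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1)
  sites <- gintervals("c1", ss <- sample(0:99985, 60), ss + 15)
  up <- sample(genes$gene_id, 60)
  pp <- proximity_profile(up, genes, sites, n_reps = 400, seed = 8)
  # expectation per bin: 60/300 of the full-universe bin counts
  full <- proximity_profile(genes$gene_id, genes, sites, n_reps = 1,
                            seed = 1)
  expected <- full$bins$observed * 60 / 300
  se <- sqrt(pmax(expected * (1 - 60 / 300), 1e-9) / 400)
  expect_true(all(abs(pp$bins$background_mean - expected) <=
                    3 * se + 1e-09))
})

test_that("call_hsr_genes uses the strict 2.5-kb upstream rule", {
  genes <- toy_genes()
  # g1 tss 5000, +: site end 2516 -> nearest base 2515, distance 2485
  site_2485 <- gintervals("c1", 2501, 2516)
  expect_equal(call_hsr_genes(genes, "g1", site_2485), "g1")
  # distance exactly 2500 is excluded
  site_2500 <- gintervals("c1", 2486, 2501)
  expect_equal(upstream_distance(list(contig = "c1", strand = "+",
                                      tss = 5000), site_2500[1, ]), 2500)
  expect_equal(length(call_hsr_genes(genes, "g1", site_2500)), 0)
  # distance 2499 is included; monotone in the cutoff
  site_2499 <- gintervals("c1", 2487, 2502)
  expect_equal(call_hsr_genes(genes, "g1", site_2499), "g1")
  expect_equal(length(call_hsr_genes(genes, "g1", site_2499,
                                     cutoff_bp = 2499)), 0)
  for (cut in c(500, 1000, 2500, 5000)) {
    small <- call_hsr_genes(genes, genes$gene_id, site_2485, cutoff_bp = cut)
    big <- call_hsr_genes(genes, genes$gene_id, site_2485,
                          cutoff_bp = cut + 500)
    expect_true(all(small %in% big))
  }
})

test_that("partition_orthologs splits pairs and tests the overlap", {
  pairs <- data.frame(gene_a = paste0("a", 1:10),
                      gene_b = paste0("b", 1:10))
  # hand-assigned qualification: a-side pairs 1-4, b-side pairs 3-6
  up_a <- paste0("a", 1:4); hse_a <- paste0("a", 1:10)
  up_b <- paste0("b", 3:6); hse_b <- paste0("b", 1:10)
  part <- partition_orthologs(up_a, up_b, hse_a, hse_b, pairs)
  expect_equal(part$shared$gene_a, c("a3", "a4"))
  expect_equal(part$unique_a$gene_a, c("a1", "a2"))
  expect_equal(part$unique_b$gene_b, c("b5", "b6"))
  expect_equal(part$test$p_value, hyper_enum_p(2, 4, 4, 10),
               tolerance = 1e-12)

  # disjoint up sets: nothing shared
  p2 <- partition_orthologs("a1", "b9", hse_a, hse_b, pairs)
  expect_equal(nrow(p2$shared), 0)
  # identical qualification on a 1:1 map: everything shared
  p3 <- partition_orthologs(paste0("a", 1:10), paste0("b", 1:10),
                            hse_a, hse_b, pairs)
  expect_equal(nrow(p3$shared), 10)
  expect_equal(nrow(p3$unique_a), 0)
  # unknown genes are skipped with a warning
  expect_warning(
    p4 <- partition_orthologs(up_a, up_b, hse_a, hse_b,
                              rbind(pairs, data.frame(gene_a = "aX",
                                                      gene_b = "bX")),
                              known_a = paste0("a", 1:10)),
    "skipped")
  expect_equal(p4$test$total, 10)
})
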