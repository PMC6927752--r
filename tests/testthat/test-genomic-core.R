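test_that("parse_fasta normalizes case, U and unknown characters", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">c1", "ACGT"), f)
  g <- parse_fasta(f)
  expect_s3_class(g, "genome_sequence")
  expect_equal(names(g$contigs), "c1")
  expect_equal(nchar(g$contigs[["c1"]]), 4)
  expect_equal(g$total_size, 4)

  writeLines(c(">c1", "acgu"), f)
  expect_equal(parse_fasta(f)$contigs[["c1"]], "ACGT")

  writeLines(c(">c1", "ACXT"), f)
  expect_warning(g <- parse_fasta(f), "non-ACGTN")
  expect_equal(g$contigs[["c1"]], "ACNT")
})

test_that("parse_fasta sums contig lengths and preserves order", {
  set.seed(11)
  f <- withr::local_tempfile(fileext = ".fa")
  s1 <- rand_seq(1000); s2 <- rand_seq(500)
  writeLines(c(">big", s1, ">small", s2), f)
  g <- parse_fasta(f)
  # independent length oracle: characters on sequence lines
  expected <- sum(nchar(c(s1, s2)))
  expect_equal(g$total_size, expected)
  expect_equal(names(g$contigs), c("big", "small"))
})

test_that("parse_fasta rejects empty files and duplicate contigs", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(character(0), f)
  expect_error(parse_fasta(f))
  writeLines(c(">c1", "ACGT", ">c1", "GGGG"), f)
  expect_error(parse_fasta(f), "duplicate")
})

rm_fixture <- c(
  "   SW   perc perc perc  query  position in query  matching repeat",
  "score   div. del. ins.  sequence begin end (left) repeat class/family begin end (left) ID",
  "",
  "  463   10.5  0.0  0.0  chrI 1001 1100 (0) + HelitronY1_CE DNA/Helitron 1 100 (0) 1",
  "  270   20.1  0.0  0.0  chrI 5001 5400 (0) + CELE14B LINE/CR1 1 400 (0) 2",
  "  463    9.9  0.0  0.0  chrII 201 800 (0) C Helitron2_CE DNA/Helitron 1 600 (0) 3",
  "  120   15.0  0.0  0.0  chrII 2001 2200 (0) + CeRep55 Satellite 1 200 (0) 4",
  "  463   11.0  0.0  0.0  chrIII 1 250 (0) + HelitronY4_CE DNA/Helitron 1 250 (0) 5"
)

test_that("parse_repeatmasker filters by keyword and converts coordinates", {
  f <- withr::local_tempfile(fileext = ".out")
  writeLines(rm_fixture, f)
  hel <- parse_repeatmasker(f, "helitron")
  expect_equal(nrow(hel), 3)                     # manual count of fixture rows
  expect_equal(hel$contig[1], "chrI")
  expect_equal(hel$start[1], 1000)               # 1-based 1001 -> 0-based 1000
  expect_equal(hel$end[1], 1100)
  expect_equal(hel$repeat_name, c("HelitronY1_CE", "Helitron2_CE",
                                  "HelitronY4_CE"))
  expect_equal(nrow(parse_repeatmasker(f, "LINE")), 1)
  expect_equal(nrow(parse_repeatmasker(f, "nosuchfamily")), 0)
  expect_equal(nrow(parse_repeatmasker(f, NULL)), 5)
})

test_that("parse_repeatmasker accepts BED input", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chrI\t1000\t1100\tHelitronY1_CE\t0\t+",
               "chrI\t5000\t5400\tCELE14B\t0\t+"), f)
  hel <- parse_repeatmasker(f, "helitron")
  expect_equal(nrow(hel), 1)
  expect_equal(hel$start, 1000)
  expect_equal(hel$end, 1100)
})

test_that("merge_intervals merges overlaps but not abutting intervals", {
  m <- merge_intervals(gintervals(c("c1", "c1"), c(0, 5), c(10, 20)))
  expect_equal(m$start, 0)
  expect_equal(m$end, 20)

  m2 <- merge_intervals(gintervals(c("c1", "c2"), c(0, 0), c(10, 10)))
  expect_equal(nrow(m2), 2)
  expect_equal(m2$contig, c("c1", "c2"))

  # abutting [0,10) + [10,20) stay separate
  m3 <- merge_intervals(gintervals(c("c1", "c1"), c(0, 10), c(10, 20)))
  expect_equal(nrow(m3), 2)
})

test_that("merge_intervals preserves covered bases and is idempotent", {
  lens <- c(a = 8000, b = 10000)
  for (seed in 1:5) {
    set.seed(seed)
    x <- rand_intervals(100, lens)
    m <- merge_intervals(x)
    expect_equal(sum(m$end - m$start), mask_coverage(x, lens))
    expect_equal(merge_intervals(m), m)
    # no two outputs overlap, sorted by (contig, start)
    expect_true(all(diff(order(m$contig, m$start)) == 1))
    by_ctg <- split(m, m$contig)
    for (sub in by_ctg)
      if (nrow(sub) > 1)
        expect_true(all(sub$start[-1] >= sub$end[-nrow(sub)]))
  }
})

test_that("overlap_bp handles overlap, containment and disjoint contigs", {
  gi <- function(c, s, e) list(contig = c, start = s, end = e)
  expect_equal(overlap_bp(gi("c1", 0, 10), gi("c1", 5, 20)), 5)
  expect_equal(overlap_bp(gi("c1", 0, 10), gi("c2", 0, 10)), 0)
  expect_equal(overlap_bp(gi("c1", 100, 115), gi("c1", 90, 200)), 15)
  # symmetric and bounded by the shorter interval
  set.seed(3)
  for (i in 1:20) {
    a <- gi("c1", s <- sample(100, 1), s + sample(50, 1))
    b <- gi("c1", s2 <- sample(100, 1), s2 + sample(50, 1))
    expect_equal(overlap_bp(a, b), overlap_bp(b, a))
    expect_lte(overlap_bp(a, b), min(a$end - a$start, b$end - b$start))
  }
})

test_that("genome_fraction matches mask coverage and handles edge cases", {
  expect_equal(
    genome_fraction(merge_intervals(gintervals(character(0), integer(0),
                                               integer(0))),
                    c(c1 = 100)),
    0)
  expect_equal(
    genome_fraction(gintervals("c1", 0, 100), c(c1 = 100)), 1)
  # the worked proportion: 1.68 Mb Helitron on a 100.27 Mb genome is 1.7%
  frac <- genome_fraction(gintervals("chr", 0, 1.68e6), c(chr = 100.27e6))
  expect_equal(round(100 * frac, 1), 1.7)
  expect_error(genome_fraction(gintervals("nope", 0, 10), c(c1 = 100)),
               "absent")
  # mask oracle on random sets
  lens <- c(u = 5000, v = 3000)
  set.seed(9)
  x <- rand_intervals(60, lens)
  m <- merge_intervals(x)
  expect_equal(genome_fraction(m, lens), mask_coverage(x, lens) / sum(lens))
})
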