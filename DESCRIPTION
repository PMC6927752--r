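Package: hsescan
Title: Heat-Shock Element Scanning and Helitron Co-Localization Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for locating degenerate heat-shock element (HSE) motifs
    in genome sequences and quantifying their association with Helitron
    transposons. Provides an IUPAC motif scanner that reports overlapping
    matches on both strands, interval algebra on 0-based half-open
    coordinates, readers for FASTA, RepeatMasker .out, BED and minimal VCF,
    enrichment statistics (cumulative binomial overlap, two-cell chi-squared
    proximity, Fisher's exact, hypergeometric), 1-kb window density profiles
    with a random k-mer permutation null, classification of
    Helitron-acquired versus Helitron-independent HSEs, strand-aware
    upstream-proximity analysis of heat-shock up-regulated genes with
    sampled backgrounds, sliding-window Tajima's D, and a ground-truth
    labelled synthetic data generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
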