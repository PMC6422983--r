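Package: nucleoamp
Title: Nucleosome-Guided cfDNA Fragmentation Analysis for Amplicon Panel Design
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing cell-free DNA (cfDNA) fragmentation patterns
    to guide the design of amplicon-based liquid-biopsy panels. Builds
    per-base fragmentation coverage tracks and nucleosome maps from
    paired-end fragment records (length filter, dyad trimming, square-pulse
    smoothing, kernel-density peak calling), computes four per-amplicon
    fragmentation features (spanning-fragment count, depth range, boundary
    depth change, depth shape), performs GC-band median normalization of
    amplicon read counts with regression and ANOVA diagnostics linking
    amplicon length, GC content, coverage depth and inter-sample coverage
    uniformity, ranks features with RReliefF and predicts coverage
    depth/uniformity classes with an RBF-kernel support vector machine under
    stratified cross-validation, and provides variant filtering,
    paired allele-frequency and fragment-length enrichment statistics for
    comparing amplicon panels. Includes a synthetic cfDNA simulator with
    known ground truth (nucleosome landscapes, mono/di-nucleosome fragment
    populations, amplicon panels, per-sample count matrices) so the whole
    pipeline is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    e1071
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
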