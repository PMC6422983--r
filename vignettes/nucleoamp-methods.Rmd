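---
title: "Nucleosome-guided cfDNA fragmentation analysis: models and methods"
author: "nucleoamp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nucleosome-guided cfDNA fragmentation analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nucleoamp)
```

## The problem

Plasma cell-free DNA (cfDNA) is not randomly fragmented. Apoptotic
nucleases spare DNA wrapped around nucleosomes, so the surviving fragments
concentrate on nucleosome-protected intervals: the length distribution has
a dominant mononucleosome mode near 167 bp, a minor dinucleosome mode near
350 bp, and the genomic placement of fragments tracks nucleosome dyads.
For amplicon-based liquid-biopsy panels this matters twice. First, an
amplicon can only be amplified from fragments long enough to carry both
primer sites, so amplification efficiency collapses once amplicon length
outgrows the mononucleosome mode. Second, amplicons that straddle poorly
positioned or unstable nucleosomes sit over fewer spanning templates and
show larger coverage variation between samples.

`nucleoamp` implements the full analysis chain for studying these effects
and exploiting them in panel design: fragment-map construction from
paired-end records, four per-amplicon fragmentation features, GC-band
normalization with a regression/ANOVA suite, RReliefF feature ranking with
RBF-SVM prediction of coverage depth and uniformity classes, and the
variant-level statistics used to compare two panels. A synthetic-data
module generates nucleosome landscapes, fragment populations, panels and
count matrices with known ground truth, so every stage is testable without
sequencing data.

## The fragment-processing chain

The fragment map is built in a fixed order, each step exposed as its own
function:

1. `fragments_from_pairs()` — a fragment is the outer span
   `[min start, max end)` of its two read intervals; pairs on different
   contigs or with a degenerate span are dropped and counted.
2. `filter_by_length(min_len = 80, max_len = 250)` — inclusive bounds;
   retains the mononucleosome population and excludes dinucleosome
   fragments.
3. `trim_to_dyad_window(window = 40)` — each fragment is replaced by the
   40 bp window centered on its midpoint (the dyad proxy). We read
   "trimmed around dyads" as *keep the central window*: it is the only
   reading that yields a set of equal-length fragments. The dyad of an
   even-length fragment is the floor midpoint, a deterministic tie-break.
4. `position_overlap_counts()` — per-base counts of overlapping fragments
   over a region (0-based half-open coordinates everywhere, BED
   conventions on disk).
5. `square_pulse_smooth(width = 21)` — centered moving average. At the
   region edges the window is truncated and renormalized by its actual
   size rather than zero-padded: zero-padding would artificially depress
   coverage exactly where amplicons sit. The filter is linear and
   conserves interior window means; it is deliberately not idempotent.

`call_nucleosome_peaks()` smooths the dyad positions with a Gaussian
kernel (default bandwidth 30 bp) and reports strict local maxima. Each
peak's *stringency* is its density divided by the mean density over a
flanking background window (default 1000 bp total, excluding the
bandwidth around the peak). Under uniform dyad scatter, peak stringencies
sit slightly above 1 — local maxima are selected for being above their
surroundings — while genuinely positioned nucleosomes score several-fold
higher. The kernel bandwidth and background window are exposed; there is
no single convention for these parameters in kernel-density nucleosome
mapping.

`interception_test()` asks whether amplicons intercept nucleosome peaks
more (or less) often than chance: the statistic is the number of amplicons
containing at least one peak position, and the null is built by circularly
shifting the whole panel by uniform random offsets,
`p = (1 + #(null >= observed)) / (n_perm + 1)`. Interception means
point-in-interval containment of a peak. Because the statistic is a small
integer count, ties with the null make the p-value conservative for small
panels; it is never anti-conservative.

## The four amplicon features

For each amplicon (outer coordinates, primer footprints included):

* **Feature A**, `spanning_fragment_count()` — fragments that fully
  contain the outer interval, i.e. in-silico PCR templates carrying both
  primers. Computed on length-filtered, untrimmed fragments: a trimmed
  fragment can no longer span anything.
* **Feature B**, `depth_range()` — max minus min of the smoothed track
  over the amplicon.
* **Feature C**, `depth_change()` — absolute difference between the
  track values at the amplicon's two boundaries. "Signal change at the
  boundaries" admits several formalizations; we chose the boundary-value
  difference because it is the simplest reading
  that is zero on symmetric signal and equals Feature B on monotone
  signal. The choice is isolated in one small function and easy to swap.
* **Feature D**, `depth_shape()` — the summed absolute area between the
  track and the straight line joining its boundary values; zero for
  linear signal, invariant under adding constants, *not* invariant under
  adding general affine functions.

B–D are computed on the smoothed (width 21) track by default, matching
the order of the processing chain; the functions accept any track, so raw
signal can be used instead.
`feature_robustness()` summarizes cross-sample stability as the average
over amplicons of the per-amplicon coefficient of variation (sample SD
over mean), skipping and counting zero-mean amplicons.

## GC normalization and the regression suite

`gc_normalize()` implements per-sample median scaling in fixed 5% GC
bands anchored at 0: `r_i * m / m_GC`, with `m` the sample's overall
median and `m_GC` the median of the amplicon's band. It is idempotent and
preserves within-band rank order.

Two practical points we established on null simulations (no length
effect built in, 200–400 replicates) shape how the regression suite is
meant to be used:

* **Average, then normalize.** Normalizing each sample separately and
  averaging afterwards leaves each band's factor carrying per-sample
  median noise shared by every amplicon in the band. Ordinary least
  squares then treats those correlated residuals as independent and the
  restricted length regression rejected its true null in roughly a third
  of replicates. Normalizing the across-sample mean vector is calibrated.
* **Estimate factors from the analysis set.** Band medians computed on
  the full panel are dragged by amplicons outside the analysis subset
  (e.g. long, template-limited amplicons), which again injects shared
  band-level errors. Passing the subset under analysis to
  `gc_normalize()` restores calibration (5–6% type-I at the 5% level).

`length_coverage_regression()` is ordinary least squares of mean
normalized coverage on amplicon length with the two-sided slope t-test,
optionally restricted to a maximum length; `broken_stick_regression()`
fits the two segments around a fixed breakpoint, 170 bp by default — the
breakpoint is asserted, not estimated, though a grid search would be easy
to add. `polynomial_gc_regression()` (degree 2),
`equal_frequency_discretize()` (ties to the lower group, deterministic)
and `anova_between_groups()` (one-way fixed effects) complete the suite.
`coverage_uniformity()` defines an amplicon's uniformity as the
coefficient of inter-sample variation of its counts, with the n−1 sample
SD.

## Feature ranking and class prediction

`rrelieff_rank()` implements the regression form of the Relief family:
for sampled instances and their `k` nearest neighbours (Manhattan
distance on min-max scaled features, `k = 10` by default), it accumulates
the probability mass of "feature differs" split by "prediction differs",
and scores each feature as the difference between the two conditional
probabilities. Constant features get weight 0 with a warning; duplicated
features get identical weights by construction; the whole procedure is
deterministic given a seed.

`define_target_classes()` reuses the equal-frequency discretizer to form
tertiles: *depth* mode labels the lowest tertile positive (amplicons at
risk of poor coverage), *uniformity* mode the highest tertile (amplicons
with unstable coverage). `train_eval_svm_rbf()` evaluates an RBF-kernel
SVM (`e1071::svm`, i.e. libsvm) under stratified k-fold cross-validation
(3 folds by default): features are standardized with training-fold
statistics only, out-of-fold decision scores are pooled, AUROC is the
rank statistic, and the 95% CI is a percentile bootstrap over amplicons
of the pooled scores (1000 resamples). A CI over cross-validation
repetitions is a common alternative and gives much tighter intervals;
bootstrap-over-amplicons is the default because it reflects
panel-to-panel uncertainty. We default to `C = 1` and
`gamma = 1/n_features` on standardized features, the standard RBF
heuristic, both exposed.
Precision is evaluated at decision threshold 0.

`compare_feature_sets()` runs the evaluator on two feature sets with
shared fold assignments per replicate and reports the mean AUROC
difference. With identical sets the difference is exactly zero; adding a
pure-noise feature moves it by less than ±0.02 in our checks.

## The synthetic-data generator

The generator is first-class, tested code. Its defaults are the study
conditions used throughout the tests and the acceptance script, chosen
once:

* **Landscape** — dyads at mean spacing 190 bp (jitter SD 20), occupancy
  weights uniform in [0.5, 1], per-dyad positional SD uniform in
  [0, 30] bp. Positional SD is the generative notion of nucleosome
  instability.
* **Fragments** — mononucleosome fraction 0.85; lengths are discretized
  normals, modes 167 bp (SD 20) and 350 bp (SD 35), truncated at 1 bp.
  Mono fragments center on one dyad (chosen proportionally to occupancy),
  di fragments on the midpoint of two adjacent dyads; centers are
  jittered by the dyad's positional SD. A `tumor_length_shift` parameter
  (default 0) shortens both modes to emulate tumor-derived cfDNA.
* **Counts** — expected count = `baseline_depth` × quadratic GC factor ×
  availability, with availability `min(1, S(len)/0.4)` where `S` is the
  survival function of the fragment-length mixture. The saturation form
  models PCR as template-limited only when spanning templates are scarce:
  coverage is flat for amplicons comfortably below the mononucleosome
  mode and collapses above it, which is the regime the length–coverage
  regressions probe. The GC factor defaults to `-4·gc² + 4·gc + 0.2`
  (peaked at GC 0.5). Per-sample noise is unit-mean lognormal with SD
  `0.3 · (0.2 + 0.8·instability) · (1 + 4·(gc − 0.5)²)`, where an
  amplicon's instability is the scaled mean positional SD of the dyads
  whose ±73 bp footprint overlaps it. Noise is centered to unit mean so
  that expected depth is independent of instability — inter-sample
  uniformity, not depth, carries the nucleosome signal.

What the generator does *not* emulate: real genome sequence and mappability,
base-level sequencing error, library-size differences between samples,
tumor clonal structure, and chromatin heterogeneity between tissues.
Passing tests therefore demonstrate that the pipeline recovers the
modelled dependencies (length-driven availability, GC bias, instability-
driven uniformity), not that it would recover them at a given effect size
in patient data.

## Problem sizes and numerical choices

The test suite and acceptance script run on a 200 kb synthetic contig,
50,000 fragments, panels of 200 amplicons (100–200 bp) and 10 samples,
with 20 seeded replicates for the stochastic recovery checks — sizes at
which every check completes in seconds while keeping at least ~20
amplicons per occupied GC band, which the normalization needs for stable
medians. Degenerate inputs error early and explicitly: empty landscapes
or panels, fragments shorter than the trim window (offending rows are
listed), even smoothing widths, bands with all-zero medians (named),
single-sample CVs, single-class folds. Wilcoxon tests drop zero
differences and switch from the exact null to the normal approximation
above 25 informative pairs; the Poisson screen's homopolymer multiplier
table (doubling per base beyond 3, capped at 16×, indels ×4) is a
package default, fully overridable, since no canonical table exists.

## Known limitations

* Feature C's definition is one of several defensible readings of a
  schematic description.
* The interception test's p-value is conservative for small panels
  (discrete statistic).
* Median-based GC-band normalization requires adequately occupied bands;
  with fewer than ~10 amplicons per band its factors are noisy and
  downstream OLS p-values become anti-conservative (see the calibration
  notes above).
* The broken-stick breakpoint is fixed, not estimated.
* RReliefF uses uniform neighbour weights rather than rank-exponential
  weighting; with `k = 10` the difference is negligible in our checks.
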