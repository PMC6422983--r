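# nucleoamp

Nucleosome-guided cfDNA fragmentation analysis for amplicon panel design.

## What it is for

Plasma cell-free DNA (cfDNA) is fragmented along nucleosome boundaries: a
dominant mononucleosome mode near 167 bp, a minor dinucleosome mode near
350 bp, and fragment placement that tracks nucleosome dyads. For
amplicon-based liquid-biopsy panels this creates two design constraints:
an amplicon can only be amplified from fragments long enough to span both
primers, and amplicons sitting over unstable nucleosomes show high
inter-sample coverage variation. `nucleoamp` is for panel designers and
method developers who want to quantify these effects and use them to
choose amplicon positions and lengths.

The package implements, end to end:

* **Fragment maps** — paired reads → fragments (outer span) → inclusive
  80–250 bp length filter → 40 bp dyad trimming → per-base overlap counts
  → square-pulse smoothing (width 21); Gaussian-kernel nucleosome peak
  calling with positional stringency scores; a circular-shift permutation
  test for peak/amplicon interception.
* **Four amplicon features** — spanning-fragment count (A, the in-silico
  PCR template count), depth range (B), boundary depth change (C), depth
  shape (D: area between the signal and its linear approximation), plus
  cross-sample feature robustness (averaged coefficients of variation).
* **Coverage statistics** — GC-band median normalization
  `r_i · m / m_GC` in fixed 5% bands; OLS length–coverage regression with
  slope t-test and a 170 bp broken-stick fit; degree-2 polynomial GC
  regressions (R²); equal-frequency discretization and one-way ANOVA;
  per-amplicon coverage uniformity (CV across samples).
* **Prediction** — RReliefF feature ranking for continuous targets;
  tertile class definitions (lowest-depth / highest-CV tertile positive);
  RBF-kernel SVM under stratified 3-fold cross-validation with pooled
  out-of-fold AUROC, bootstrap CI and precision; paired comparison of
  GC-only vs combined feature sets.
* **Panel comparison** — variant classification (COSMIC ≥ 10 somatic,
  population MAF ≥ 0.05 germline), read-support filters (total < 20,
  alt < 4), allele frequencies with bootstrap depth normalization,
  Wilcoxon signed-rank (exact for ≤ 25 pairs) and Pearson statistics,
  geometric mean ratio with t-interval, fragment-length enrichment ratios
  for deletion alleles, and a Poisson hotspot screen with
  homopolymer-dependent error rates.
* **Synthetic data** — nucleosome landscapes, cfDNA fragment populations,
  amplicon panels and per-sample count matrices with known ground truth
  (GC factor, template availability, nucleosome instability), so the whole
  chain runs and is tested without any sequencing download.

## Worked example

```r
library(nucleoamp)

# simulate a cfDNA population over a synthetic nucleosome landscape
landscape <- generate_nucleosome_landscape(2e5, mean_spacing = 190,
                                           spacing_jitter_sd = 20, seed = 1)
cfg <- simulation_config(n_fragments = 50000, n_samples = 10, seed = 2)
fragments <- sample_fragments(landscape, cfg)
table(cut(fragment_lengths(fragments), c(0, 250, 500)))
#>   (0,250] (250,500]
#>     42396      7592        # ~85% mononucleosome fragments

# fragment map: filter -> trim -> count -> smooth -> call peaks
kept    <- filter_by_length(fragments, 80, 250)
trimmed <- trim_to_dyad_window(kept, 40)
dyads   <- (trimmed$start + trimmed$end) %/% 2
call_nucleosome_peaks(dyads, bandwidth = 30, min_stringency = 1.5)
#> <nucleosome_map> 981 peaks (bandwidth 30 bp)

# amplicon panel, counts, and the length/GC analyses
panel <- simulate_panel(landscape, 200, seed = 3)
sim   <- simulate_amplicon_counts(panel, landscape, cfg)
len      <- panel$outer_end - panel$outer_start
mean_cov <- rowMeans(sim$counts)
full  <- length_coverage_regression(len, gc_normalize(mean_cov, panel$gc_fraction))
sub   <- len <= 170
restr <- length_coverage_regression(len[sub],
           gc_normalize(mean_cov[sub], panel$gc_fraction[sub]))
sprintf("full-range slope %.2f (p = %.2g); <=170 bp slope p = %.2f",
        full$slope, full$p_value, restr$p_value)
#> "full-range slope -3.55 (p = 1.8e-21); <=170 bp slope p = 0.77"

# predict high coverage variation: GC alone vs GC + nucleosome instability
cv <- coverage_uniformity(sim$counts)
y  <- define_target_classes(cv, "uniformity")
cmp <- compare_feature_sets(matrix(panel$gc_fraction, ncol = 1),
                            cbind(gc = panel$gc_fraction,
                                  inst = sim$truth$instability),
                            y, replicates = 5, seed = 4)
sprintf("AUROC gain from nucleosome features: %+.2f (%d/%d replicates)",
        cmp$mean_delta, sum(cmp$deltas > 0), length(cmp$deltas))
#> "AUROC gain from nucleosome features: +0.29 (5/5 replicates)"
```

Reading the output: coverage is independent of amplicon length up to the
mononucleosome mode (restricted slope p = 0.77) and collapses above it
(full-range negative slope, p ≈ 1e-21), so panels should stay at or below
~170 bp but gain nothing from going shorter. Amplicons over unstable
nucleosomes have high inter-sample CV, and adding the nucleosome feature
to a GC-only classifier raises out-of-fold AUROC by ~0.29 on this
simulation — nucleosome maps carry panel-design signal that GC content
does not.

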