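# Variant filtering and classification rules, paired allele-frequency
# statistics between two amplicon panels, fragment-length enrichment
# ratios, and the Poisson hotspot screen.

#' Classify a variant as confidently somatic, germline, or unclassified
#'
#' Hotspot rule first: variants seen in 10 or more COSMIC samples are
#' confidently somatic. Otherwise a population minor allele frequency of
#' 5% or more makes the variant confidently germline. Everything else is
#' unclassified and excluded from downstream comparison.
#'
#' @param cosmic_sample_count Integer vector of COSMIC sample counts.
#' @param population_maf Numeric vector of population MAFs in `[0, 1]`.
#' @return Factor with levels `confidently_somatic`, `confidently_germline`,
#'   `unclassified`.
#' @export
classify_variant <- function(cosmic_sample_count, population_maf) {
  if (any(population_maf < 0 | population_maf > 1)) {
    stop("`population_maf` must lie in [0, 1]", call. = FALSE)
  }
  out <- ifelse(cosmic_sample_count >= 10L, "confidently_somatic",
                ifelse(population_maf >= 0.05, "confidently_germline",
                       "unclassified"))
  factor(out, levels = c("confidently_somatic", "confidently_germline",
                         "unclassified"))
}

#' Read-support filters for variant observations
#'
#' Variants with fewer than 20 total reads are dropped (`low_total`);
#' variants with fewer than 4 alternative-allele reads are dropped
#' (`low_alt`); the rest are kept.
#'
#' @param total_reads,alt_reads Integer vectors, `alt_reads <= total_reads`.
#' @return Factor with levels `keep`, `drop_low_total`, `drop_low_alt`.
#' @export
apply_read_filters <- function(total_reads, alt_reads) {
  if (any(alt_reads > total_reads)) {
    stop("`alt_reads` must not exceed `total_reads`", call. = FALSE)
  }
  out <- ifelse(total_reads < 20L, "drop_low_total",
                ifelse(alt_reads < 4L, "drop_low_alt", "keep"))
  factor(out, levels = c("keep", "drop_low_total", "drop_low_alt"))
}

#' Variant allele frequency
#'
#' Ratio of reads supporting the mutation to the total qualified reads
#' covering the site.
#'
#' @inheritParams apply_read_filters
#' @return Numeric vector of allele frequencies in `[0, 1]`.
#' @export
allele_frequency <- function(alt_reads, total_reads) {
  if (any(total_reads < 1L)) stop("`total_reads` must be >= 1", call. = FALSE)
  if (any(alt_reads > total_reads | alt_reads < 0L)) {
    stop("need 0 <= alt_reads <= total_reads", call. = FALSE)
  }
  alt_reads / total_reads
}

#' Bootstrap normalization of an allele frequency to a target depth
#'
#' Resamples `target_depth` reads with replacement from the observed pool
#' of `alt_reads` mutant and `total_reads - alt_reads` wild-type reads,
#' `n_boot` times, to express the allele frequency at a common coverage.
#'
#' @inheritParams apply_read_filters
#' @param target_depth Depth to normalize to (>= 1).
#' @param n_boot Number of bootstrap resamples.
#' @param seed Integer seed.
#' @return A list with `af` (mean resampled AF), `ci` (2.5/97.5 percentile
#'   interval) and `af_observed`.
#' @export
bootstrap_af_normalize <- function(alt_reads, total_reads, target_depth,
                                   n_boot = 1000L, seed = 1L) {
  if (total_reads < 1L) stop("`total_reads` must be >= 1", call. = FALSE)
  if (target_depth < 1L) stop("`target_depth` must be >= 1", call. = FALSE)
  p <- allele_frequency(alt_reads, total_reads)
  draws <- local_seed(seed, {
    stats::rbinom(n_boot, target_depth, p) / target_depth
  })
  list(af = mean(draws),
       ci = unname(stats::quantile(draws, c(0.025, 0.975))),
       af_observed = p)
}

#' Paired allele-frequency comparison between two panels
#'
#' Two-sided Wilcoxon signed-rank test on the paired differences (zero
#' differences dropped; exact null for 25 or fewer informative pairs,
#' normal approximation above) and Pearson correlation with its t-based
#' p-value.
#'
#' @param af1,af2 Paired allele frequencies from the two panels.
#' @return A list with `wilcoxon_p`, `pearson_r`, `pearson_p`, and
#'   `n_pairs` (informative, non-tied pairs).
#' @export
paired_af_comparison <- function(af1, af2) {
  if (length(af1) != length(af2)) {
    stop("`af1` and `af2` must be paired", call. = FALSE)
  }
  d <- af1 - af2
  nz <- sum(d != 0)
  if (nz == 0L) {
    warning("all paired differences are zero; Wilcoxon p = 1")
    wp <- 1
  } else {
    wt <- suppressWarnings(
      stats::wilcox.test(af1, af2, paired = TRUE, exact = nz <= 25L,
                         correct = TRUE)
    )
    wp <- wt$p.value
  }
  if (stats::sd(af1) == 0 || stats::sd(af2) == 0) {
    stop("Pearson correlation undefined for constant allele frequencies",
         call. = FALSE)
  }
  ct <- stats::cor.test(af1, af2, method = "pearson")
  list(wilcoxon_p = wp, pearson_r = unname(ct$estimate),
       pearson_p = ct$p.value, n_pairs = nz)
}

#' Geometric mean ratio of paired allele frequencies
#'
#' `exp(mean(log(af1 / af2)))` with a 95% CI from the t-interval on the
#' log ratios.
#'
#' @param af1,af2 Paired, strictly positive allele frequencies.
#' @return A list with `ratio` and `ci`.
#' @export
geometric_mean_ratio <- function(af1, af2) {
  if (length(af1) != length(af2)) {
    stop("`af1` and `af2` must be paired", call. = FALSE)
  }
  if (any(af1 <= 0 | af2 <= 0)) {
    stop("allele frequencies must be strictly positive", call. = FALSE)
  }
  lr <- log(af1 / af2)
  if (length(lr) < 2L) {
    stop("need >= 2 pairs for the confidence interval", call. = FALSE)
  }
  if (stats::sd(lr) == 0) {
    return(list(ratio = exp(mean(lr)), ci = exp(c(mean(lr), mean(lr)))))
  }
  tt <- stats::t.test(lr)
  list(ratio = exp(mean(lr)), ci = exp(as.vector(tt$conf.int)))
}

#' Construct a fragment-length distribution
#'
#' @param support Positive fragment lengths in bp (strictly increasing).
#' @param mass Nonnegative probabilities summing to 1.
#' @return An object of class `length_distribution`.
#' @export
length_distribution <- function(support, mass) {
  if (length(support) != length(mass)) {
    stop("`support` and `mass` must have equal length", call. = FALSE)
  }
  if (any(support <= 0)) stop("`support` must be positive", call. = FALSE)
  if (is.unsorted(support, strictly = TRUE)) {
    stop("`support` must be strictly increasing", call. = FALSE)
  }
  if (any(mass < 0) || abs(sum(mass) - 1) > 1e-9) {
    stop("`mass` must be nonnegative and sum to 1", call. = FALSE)
  }
  structure(list(support = support, mass = mass),
            class = "length_distribution")
}

#' Empirical length distribution of a fragment set
#'
#' @param fragments A fragment-record `data.frame`.
#' @return A `length_distribution` over the observed lengths.
#' @export
empirical_length_distribution <- function(fragments) {
  len <- fragment_lengths(fragments)
  tab <- table(len)
  length_distribution(as.integer(names(tab)),
                      as.numeric(tab) / sum(tab))
}

#' Expected mutant:wild-type amplification enrichment ratio
#'
#' A deletion of `deletion_len` bp shortens the template an amplicon needs,
#' so more cfDNA fragments can span it. The enrichment ratio is the
#' tail-mass ratio `P(L >= amplicon_len - deletion_len) / P(L >= amplicon_len)`
#' under the fragment-length distribution; it is always >= 1.
#'
#' @param dist A `length_distribution`.
#' @param amplicon_len Amplicon length in bp, primers included.
#' @param deletion_len Deletion length in bp (`0 <= deletion_len <
#'   amplicon_len`).
#' @return The enrichment ratio (scalar >= 1).
#' @export
enrichment_ratio <- function(dist, amplicon_len, deletion_len) {
  if (deletion_len < 0 || amplicon_len <= deletion_len) {
    stop("need amplicon_len > deletion_len >= 0", call. = FALSE)
  }
  tail_mass <- function(x) sum(dist$mass[dist$support >= x])
  denom <- tail_mass(amplicon_len)
  if (denom == 0) {
    stop("no fragment is long enough to amplify the wild-type amplicon",
         call. = FALSE)
  }
  tail_mass(amplicon_len - deletion_len) / denom
}

# Default context multiplier: 1 for homopolymers up to 3 bp, doubling per
# extra base capped at 16x; indels are 4x more error-prone.
default_context_multiplier <- function(context_complexity, variant_class) {
  hp <- pmin(2^pmax(0, context_complexity - 3), 16)
  hp * ifelse(variant_class == "indel", 4, 1)
}

#' Poisson hotspot screen for low-frequency variants
#'
#' Models the alternative-allele read count at an error-only site as
#' Poisson with expectation `lambda = total_reads * e(context)`, where the
#' per-read error probability `e(context) = base_error * multiplier` grows
#' with homopolymer length and is larger for indels. Returns the upper
#' tail probability `P(Poisson(lambda) >= alt_reads)`.
#'
#' @inheritParams apply_read_filters
#' @param base_error Base per-read error probability in `(0, 1)`.
#' @param context_complexity Homopolymer length at the site in bp.
#' @param variant_class `"SNV"` or `"indel"`.
#' @param multiplier Function `(context_complexity, variant_class) ->
#'   multiplier`, non-decreasing in homopolymer length; the default table
#'   doubles per homopolymer base beyond 3 (capped at 16x) and multiplies
#'   indels by 4.
#' @return Numeric vector of p-values.
#' @export
poisson_hotspot_screen <- function(total_reads, alt_reads, base_error,
                                   context_complexity = 1L,
                                   variant_class = "SNV",
                                   multiplier = default_context_multiplier) {
  if (any(base_error <= 0 | base_error >= 1)) {
    stop("`base_error` must lie in (0, 1)", call. = FALSE)
  }
  if (any(total_reads < 1L)) stop("`total_reads` must be >= 1", call. = FALSE)
  lambda <- total_reads * base_error *
    multiplier(context_complexity, variant_class)
  stats::ppois(alt_reads - 1, lambda, lower.tail = FALSE)
}
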