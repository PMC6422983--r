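#' Generate a synthetic nucleosome landscape
#'
#' Lays nucleosome dyads along a synthetic contig at roughly regular spacing
#' with Gaussian jitter. Each dyad carries an occupancy weight (how often a
#' nucleosome sits there across the cell population, hence how many cfDNA
#' fragments it protects) and a positional standard deviation (how "fuzzy"
#' its placement is; well-positioned nucleosomes have small values).
#'
#' @param contig_length Contig length in bp; must exceed `mean_spacing`.
#' @param mean_spacing Mean dyad-to-dyad distance in bp (default 190,
#'   a typical nucleosome repeat length).
#' @param spacing_jitter_sd SD of the spacing jitter in bp; 0 gives a
#'   perfectly regular array.
#' @param occupancy_range Length-2 numeric range in `[0, 1]` from which
#'   occupancy weights are drawn uniformly.
#' @param positional_sd_range Length-2 nonnegative range (bp) from which each
#'   dyad's positional SD is drawn uniformly.
#' @param contig_name Name of the synthetic contig.
#' @param seed Integer seed; identical seeds give identical landscapes.
#' @return An object of class `nucleosome_landscape`: a list with
#'   `contig`, `contig_length`, and a `dyads` data.frame
#'   (`position`, `occupancy`, `positional_sd`), positions strictly
#'   increasing in `[0, contig_length)`.
#' @examples
#' gl <- generate_nucleosome_landscape(10000, mean_spacing = 200,
#'                                     spacing_jitter_sd = 0, seed = 1)
#' head(gl$dyads)
#' @export
generate_nucleosome_landscape <- function(contig_length,
                                          mean_spacing = 190,
                                          spacing_jitter_sd = 20,
                                          occupancy_range = c(0.5, 1),
                                          positional_sd_range = c(0, 30),
                                          contig_name = "sim1",
                                          seed = NULL) {
  stop_if_not_scalar_number(contig_length, "contig_length")
  stop_if_not_scalar_number(mean_spacing, "mean_spacing")
  if (contig_length <= 0 || mean_spacing <= 0) {
    stop("`contig_length` and `mean_spacing` must be positive", call. = FALSE)
  }
  if (contig_length <= mean_spacing) {
    stop("`contig_length` must exceed `mean_spacing`", call. = FALSE)
  }
  if (spacing_jitter_sd < 0) {
    stop("`spacing_jitter_sd` must be nonnegative", call. = FALSE)
  }
  if (any(occupancy_range < 0) || any(occupancy_range > 1)) {
    stop("`occupancy_range` must lie within [0, 1]", call. = FALSE)
  }
  if (any(positional_sd_range < 0)) {
    stop("`positional_sd_range` must be nonnegative", call. = FALSE)
  }
  local_seed(seed, {
    n_max <- ceiling(contig_length / mean_spacing) + 10L
    gaps <- stats::rnorm(n_max, mean_spacing, spacing_jitter_sd)
    gaps <- pmax(gaps, 1)
    pos <- round(mean_spacing / 2 + cumsum(c(0, gaps[-n_max])))
    pos <- pos[pos >= 0 & pos < contig_length]
    pos <- pos[c(TRUE, diff(pos) > 0)]
    n <- length(pos)
    occ <- stats::runif(n, occupancy_range[1], occupancy_range[2])
    psd <- stats::runif(n, positional_sd_range[1], positional_sd_range[2])
    structure(
      list(contig = contig_name,
           contig_length = as.integer(contig_length),
           dyads = data.frame(position = as.integer(pos),
                              occupancy = occ,
                              positional_sd = psd)),
      class = "nucleosome_landscape"
    )
  })
}

#' @export
print.nucleosome_landscape <- function(x, ...) {
  cat(sprintf("<nucleosome_landscape> %s (%d bp), %d dyads\n",
              x$contig, x$contig_length, nrow(x$dyads)))
  invisible(x)
}

#' Simulation configuration for synthetic cfDNA data
#'
#' Bundles the parameters of the cfDNA fragment-length law, the sampling
#' depth, and the amplicon count model. Defaults reflect healthy-plasma
#' cfDNA: a dominant mononucleosome mode at 167 bp (~85% of fragments) and
#' a minor dinucleosome mode at 350 bp.
#'
#' @param n_fragments Number of fragments to draw.
#' @param mono_fraction Fraction of fragments from the mononucleosome mode.
#' @param mono_length_mode,mono_length_sd Mononucleosome length mode and SD
#'   in bp.
#' @param di_length_mode,di_length_sd Dinucleosome length mode and SD in bp.
#' @param tumor_length_shift Optional shift (bp) subtracted from both modes
#'   to emulate the shorter fragments of tumor-derived cfDNA; default 0 (off).
#' @param dyad_protection_halfwidth Half-width in bp of the nucleosome
#'   footprint used when matching amplicons to dyads (default 73, half the
#'   147 bp core-particle protection).
#' @param n_samples Number of samples for the count matrix.
#' @param gc_bias_coefficients Numeric length 3, descending order
#'   (quadratic, linear, constant): the amplification-efficiency factor as a
#'   polynomial in GC fraction. `c(0, 0, c0)` gives a flat factor `c0`.
#' @param occupancy_noise_sd Scale of the per-sample lognormal noise on
#'   amplicon counts; 0 makes counts identical across samples.
#' @param gc_uniformity_coef Strength of the extra GC-driven inter-sample
#'   variability (multiplier `1 + coef * (gc - 0.5)^2` on the noise SD).
#' @param baseline_depth Expected count of a bias-free amplicon.
#' @param template_saturation_tail Survival-probability threshold below
#'   which amplification becomes template-limited; amplicons short enough
#'   that at least this fraction of fragments can span them amplify at full
#'   efficiency. See the package vignette.
#' @param seed Integer seed controlling all randomness.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_fragments = 20000L,
                              mono_fraction = 0.85,
                              mono_length_mode = 167,
                              mono_length_sd = 20,
                              di_length_mode = 350,
                              di_length_sd = 35,
                              tumor_length_shift = 0,
                              dyad_protection_halfwidth = 73,
                              n_samples = 10L,
                              gc_bias_coefficients = c(-4, 4, 0.2),
                              occupancy_noise_sd = 0.3,
                              gc_uniformity_coef = 4,
                              baseline_depth = 1000,
                              template_saturation_tail = 0.4,
                              seed = 1L) {
  if (mono_fraction < 0 || mono_fraction > 1) {
    stop("`mono_fraction` must lie in [0, 1]", call. = FALSE)
  }
  if (n_fragments < 0) stop("`n_fragments` must be >= 0", call. = FALSE)
  if (any(c(mono_length_mode, mono_length_sd, di_length_mode,
            di_length_sd) < 0)) {
    stop("length modes and SDs must be nonnegative", call. = FALSE)
  }
  if (length(gc_bias_coefficients) != 3L) {
    stop("`gc_bias_coefficients` must have length 3 (quadratic, linear, constant)",
         call. = FALSE)
  }
  if (occupancy_noise_sd < 0) {
    stop("`occupancy_noise_sd` must be nonnegative", call. = FALSE)
  }
  if (template_saturation_tail <= 0 || template_saturation_tail > 1) {
    stop("`template_saturation_tail` must lie in (0, 1]", call. = FALSE)
  }
  structure(
    list(n_fragments = as.integer(n_fragments),
         mono_fraction = mono_fraction,
         mono_length_mode = mono_length_mode - tumor_length_shift,
         mono_length_sd = mono_length_sd,
         di_length_mode = di_length_mode - tumor_length_shift,
         di_length_sd = di_length_sd,
         dyad_protection_halfwidth = dyad_protection_halfwidth,
         n_samples = as.integer(n_samples),
         gc_bias_coefficients = as.numeric(gc_bias_coefficients),
         occupancy_noise_sd = occupancy_noise_sd,
         gc_uniformity_coef = gc_uniformity_coef,
         baseline_depth = baseline_depth,
         template_saturation_tail = template_saturation_tail,
         seed = as.integer(seed)),
    class = "simulation_config"
  )
}

#' Sample cfDNA fragments from a nucleosome landscape
#'
#' Draws fragments whose centers sit on nucleosome dyads: mononucleosome
#' fragments are centered on a single dyad chosen proportionally to its
#' occupancy weight; dinucleosome fragments are centered between two
#' adjacent dyads. Centers are jittered by each dyad's positional SD, and
#' lengths are drawn from discretized normal laws around the mono/di modes
#' (truncated at 1 bp). Fragments extending past the contig are discarded.
#'
#' @param landscape A `nucleosome_landscape`.
#' @param cfg A `simulation_config`; `cfg$seed` makes the draw reproducible.
#' @return A fragment-record `data.frame` with `sample_id` cycling over
#'   `cfg$n_samples` samples (`S01`, `S02`, ...).
#' @export
sample_fragments <- function(landscape, cfg) {
  if (!inherits(landscape, "nucleosome_landscape")) {
    stop("`landscape` must be a nucleosome_landscape", call. = FALSE)
  }
  dy <- landscape$dyads
  if (nrow(dy) == 0L) stop("landscape has no dyads", call. = FALSE)
  if (cfg$mono_fraction < 0 || cfg$mono_fraction > 1) {
    stop("`mono_fraction` must lie in [0, 1]", call. = FALSE)
  }
  n <- cfg$n_fragments
  empty <- fragment_records(character(), integer(), integer() + 1L,
                            character())[0, ]
  if (n == 0L) return(empty)
  local_seed(cfg$seed, {
    is_mono <- stats::runif(n) < cfg$mono_fraction
    if (nrow(dy) < 2L) is_mono[] <- TRUE
    center <- numeric(n)
    n_mono <- sum(is_mono)
    if (n_mono > 0L) {
      i <- sample.int(nrow(dy), n_mono, replace = TRUE, prob = dy$occupancy)
      center[is_mono] <- dy$position[i] +
        stats::rnorm(n_mono, 0, dy$positional_sd[i])
    }
    n_di <- n - n_mono
    if (n_di > 0L) {
      pw <- (dy$occupancy[-nrow(dy)] + dy$occupancy[-1]) / 2
      j <- sample.int(nrow(dy) - 1L, n_di, replace = TRUE, prob = pw)
      mid <- (dy$position[j] + dy$position[j + 1L]) / 2
      sdj <- (dy$positional_sd[j] + dy$positional_sd[j + 1L]) / 2
      center[!is_mono] <- mid + stats::rnorm(n_di, 0, sdj)
    }
    len <- integer(n)
    len[is_mono] <- pmax(1L, as.integer(round(
      stats::rnorm(n_mono, cfg$mono_length_mode, cfg$mono_length_sd))))
    len[!is_mono] <- pmax(1L, as.integer(round(
      stats::rnorm(n_di, cfg$di_length_mode, cfg$di_length_sd))))
    start <- as.integer(round(center)) - len %/% 2L
    end <- start + len
    sample_id <- sprintf("S%02d", 1L + (seq_len(n) - 1L) %% cfg$n_samples)
    keep <- start >= 0L & end <= landscape$contig_length
    out <- data.frame(contig = landscape$contig, start = start, end = end,
                      sample_id = sample_id, stringsAsFactors = FALSE)
    out <- out[keep, , drop = FALSE]
    rownames(out) <- NULL
    out
  })
}

#' Simulate an amplicon panel on a synthetic contig
#'
#' Places amplicons uniformly at random with lengths and GC fractions drawn
#' from the given ranges; primer lengths are drawn uniformly per end.
#'
#' @param landscape A `nucleosome_landscape` providing the contig.
#' @param n_amplicons Number of amplicons.
#' @param length_range Integer range of outer amplicon lengths in bp
#'   (default 100-200, the span typical of cfDNA panels).
#' @param primer_len_range Integer range of per-primer lengths in bp.
#' @param gc_range Range of GC fractions drawn uniformly.
#' @param seed Integer seed.
#' @return An amplicon panel `data.frame` (see [amplicon_panel()]).
#' @export
simulate_panel <- function(landscape, n_amplicons = 200L,
                           length_range = c(100L, 200L),
                           primer_len_range = c(18L, 27L),
                           gc_range = c(0.3, 0.7),
                           seed = NULL) {
  if (n_amplicons < 1L) stop("`n_amplicons` must be >= 1", call. = FALSE)
  local_seed(seed, {
    len <- sample(length_range[1]:length_range[2], n_amplicons, replace = TRUE)
    start <- vapply(len, function(l) {
      sample.int(landscape$contig_length - l, 1L) - 1L
    }, integer(1))
    amplicon_panel(
      contig = landscape$contig,
      outer_start = start,
      outer_end = start + len,
      name = sprintf("amp%04d", seq_len(n_amplicons)),
      fwd_primer_len = sample(primer_len_range[1]:primer_len_range[2],
                              n_amplicons, replace = TRUE),
      rev_primer_len = sample(primer_len_range[1]:primer_len_range[2],
                              n_amplicons, replace = TRUE),
      gc_fraction = stats::runif(n_amplicons, gc_range[1], gc_range[2])
    )
  })
}

# Survival function of the simulated fragment-length mixture.
fragment_length_survival <- function(x, cfg) {
  cfg$mono_fraction *
    stats::pnorm(x, cfg$mono_length_mode, cfg$mono_length_sd,
                 lower.tail = FALSE) +
    (1 - cfg$mono_fraction) *
    stats::pnorm(x, cfg$di_length_mode, cfg$di_length_sd, lower.tail = FALSE)
}

# Per-amplicon nucleosome instability in [0, 1]: mean positional SD of the
# dyads whose footprint (dyad +/- halfwidth) overlaps the amplicon, scaled
# by the landscape's maximum positional SD. Falls back to the nearest dyad
# when none overlaps.
amplicon_instability <- function(panel, landscape, halfwidth) {
  dy <- landscape$dyads
  sd_max <- max(dy$positional_sd)
  vapply(seq_len(nrow(panel)), function(i) {
    s <- panel$outer_start[i]
    e <- panel$outer_end[i]
    hit <- dy$position + halfwidth > s & dy$position - halfwidth < e
    psd <- if (any(hit)) {
      mean(dy$positional_sd[hit])
    } else {
      mid <- (s + e) / 2
      dy$positional_sd[which.min(abs(dy$position - mid))]
    }
    if (sd_max == 0) 0 else min(1, psd / sd_max)
  }, numeric(1))
}

#' Simulate per-sample amplicon count matrices with known ground truth
#'
#' The expected count of each amplicon is
#' `baseline_depth * g(GC) * availability(length)`, where `g` is the
#' quadratic GC-efficiency polynomial and the availability factor is
#' `min(1, S(len) / s_sat)` with `S` the survival function of the simulated
#' fragment-length mixture: amplification runs at full efficiency while
#' spanning templates are abundant and collapses once amplicon length
#' outgrows the mononucleosome mode. Per-sample counts multiply the
#' expectation by lognormal noise whose SD grows with the nucleosome
#' instability of the overlapping dyads (and mildly with extreme GC), so
#' inter-sample coverage uniformity is driven by nucleosome-occupancy
#' stability plus GC.
#'
#' @param panel An amplicon panel `data.frame`.
#' @param landscape A `nucleosome_landscape`.
#' @param cfg A `simulation_config`.
#' @return A list with `counts` (matrix, amplicons x samples), and `truth`
#'   (data.frame of the generative labels per amplicon: `gc_factor`,
#'   `availability`, `instability`, `expected`).
#' @export
simulate_amplicon_counts <- function(panel, landscape, cfg) {
  if (is.null(panel) || nrow(panel) == 0L) {
    stop("`panel` must contain at least one amplicon", call. = FALSE)
  }
  gc <- panel$gc_fraction
  cf <- cfg$gc_bias_coefficients
  gc_factor <- cf[1] * gc^2 + cf[2] * gc + cf[3]
  if (any(gc_factor <= 0)) {
    stop("`gc_bias_coefficients` yield a non-positive efficiency factor",
         call. = FALSE)
  }
  len <- panel$outer_end - panel$outer_start
  avail <- pmin(1, fragment_length_survival(len, cfg) /
                  cfg$template_saturation_tail)
  instab <- amplicon_instability(panel, landscape,
                                 cfg$dyad_protection_halfwidth)
  expected <- cfg$baseline_depth * gc_factor * avail
  noise_sd <- cfg$occupancy_noise_sd * (0.2 + 0.8 * instab) *
    (1 + cfg$gc_uniformity_coef * (gc - 0.5)^2)
  counts <- local_seed(cfg$seed, {
    eps <- matrix(stats::rnorm(nrow(panel) * cfg$n_samples), nrow(panel))
    # unit-mean lognormal noise: variability without biasing expected depth
    expected * exp(eps * noise_sd - noise_sd^2 / 2)
  })
  dimnames(counts) <- list(panel$name,
                           sprintf("S%02d", seq_len(cfg$n_samples)))
  list(
    counts = counts,
    truth = data.frame(name = panel$name, gc = gc, length = len,
                       gc_factor = gc_factor, availability = avail,
                       instability = instab, expected = expected,
                       noise_sd = noise_sd, stringsAsFactors = FALSE)
  )
}
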