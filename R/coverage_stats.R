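# GC-band median normalization of amplicon counts and the regression/ANOVA
# suite linking amplicon length, GC content, coverage depth and uniformity.

gc_band_index <- function(gc_fraction, band_width = 5) {
  pct <- gc_fraction * 100
  n_bands <- ceiling(100 / band_width)
  pmin(floor(pct / band_width), n_bands - 1L)
}

#' GC-band median normalization of an amplicon count matrix
#'
#' Scales each amplicon's read count by `m / m_GC`, where `m` is the
#' sample's overall median count and `m_GC` the median count of all
#' amplicons in the same GC band. Bands are fixed-width half-open bins of
#' `band_width` GC percent anchored at 0 (the last bin absorbs 100%).
#' Normalization is per sample.
#'
#' Normalization factors are estimated from the amplicon set passed in;
#' when an analysis targets a subset of the panel (e.g. a restricted length
#' range), pass that subset so the factors reflect the amplicons under
#' analysis.
#'
#' @param counts Numeric matrix (rows = amplicons, columns = samples) or a
#'   numeric vector of per-amplicon counts (e.g. means across samples).
#' @param gc_fraction Numeric vector of per-amplicon GC fractions in
#'   `[0, 1]`, one per row of `counts`.
#' @param band_width Band width in GC percent (default 5).
#' @return The normalized matrix (or vector, matching the input), with the
#'   band assignment attached as attribute `gc_band`.
#' @export
gc_normalize <- function(counts, gc_fraction, band_width = 5) {
  vector_in <- is.null(dim(counts))
  counts <- as.matrix(counts)
  if (length(gc_fraction) != nrow(counts)) {
    stop("`gc_fraction` must have one value per amplicon row", call. = FALSE)
  }
  if (any(gc_fraction < 0 | gc_fraction > 1)) {
    stop("`gc_fraction` must lie in [0, 1]", call. = FALSE)
  }
  if (any(counts < 0)) stop("`counts` must be nonnegative", call. = FALSE)
  band <- gc_band_index(gc_fraction, band_width)
  out <- counts
  for (j in seq_len(ncol(counts))) {
    r <- counts[, j]
    m <- stats::median(r)
    for (b in unique(band)) {
      sel <- band == b
      m_gc <- stats::median(r[sel])
      if (m_gc == 0) {
        stop(sprintf("GC band [%g%%, %g%%) has an all-zero median in sample %s",
                     b * band_width, (b + 1) * band_width,
                     colnames(counts)[j] %||% as.character(j)), call. = FALSE)
      }
      out[sel, j] <- r[sel] * m / m_gc
    }
  }
  if (vector_in) out <- out[, 1]
  attr(out, "gc_band") <- band
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Ordinary least-squares regression of coverage on amplicon length
#'
#' @param lengths Amplicon lengths in bp.
#' @param coverage Per-amplicon mean (normalized) coverage.
#' @param max_length Optional restriction: only amplicons with
#'   `length <= max_length` enter the fit.
#' @return A list with `slope`, `se`, `p_value` (two-sided slope t-test),
#'   `intercept` and `n`.
#' @export
length_coverage_regression <- function(lengths, coverage, max_length = NULL) {
  if (!is.null(max_length)) {
    keep <- lengths <= max_length
    lengths <- lengths[keep]
    coverage <- coverage[keep]
  }
  if (length(lengths) < 3L) {
    stop("need >= 3 amplicons after restriction", call. = FALSE)
  }
  if (length(unique(lengths)) < 2L) {
    stop("all amplicon lengths identical; slope undefined", call. = FALSE)
  }
  fit <- stats::lm(coverage ~ lengths)
  cf <- summary(fit)$coefficients
  list(slope = cf[2, 1], se = cf[2, 2], p_value = cf[2, 4],
       intercept = cf[1, 1], n = length(lengths))
}

#' Broken-stick regression with a fixed breakpoint
#'
#' Fits independent OLS regressions of coverage on length for amplicons
#' with `length <= breakpoint` and `length > breakpoint`.
#'
#' @inheritParams length_coverage_regression
#' @param breakpoint Breakpoint in bp (default 170).
#' @return A list with elements `below` and `above`, each as in
#'   [length_coverage_regression()].
#' @export
broken_stick_regression <- function(lengths, coverage, breakpoint = 170) {
  lo <- lengths <= breakpoint
  if (sum(lo) < 3L || sum(!lo) < 3L) {
    stop(sprintf("each segment needs >= 3 points (got %d below, %d above the %g bp breakpoint)",
                 sum(lo), sum(!lo), breakpoint), call. = FALSE)
  }
  list(
    below = length_coverage_regression(lengths[lo], coverage[lo]),
    above = length_coverage_regression(lengths[!lo], coverage[!lo]),
    breakpoint = breakpoint
  )
}

#' Polynomial regression of a response on GC content
#'
#' Least-squares polynomial fit (default degree 2) with the coefficient of
#' determination `R^2 = 1 - SSE / SST`.
#'
#' @param gc GC fractions.
#' @param y Response (e.g. mean coverage or its CV).
#' @param degree Polynomial degree.
#' @return A list with `coefficients` (intercept first, ascending powers)
#'   and `r_squared`.
#' @export
polynomial_gc_regression <- function(gc, y, degree = 2L) {
  if (length(gc) < degree + 2L) {
    stop("need at least degree + 2 points", call. = FALSE)
  }
  if (length(unique(gc)) <= degree) {
    stop("degenerate design: too few distinct GC values", call. = FALSE)
  }
  fit <- stats::lm(y ~ stats::poly(gc, degree, raw = TRUE))
  list(coefficients = unname(stats::coef(fit)),
       r_squared = summary(fit)$r.squared)
}

#' Equal-frequency discretization
#'
#' Splits values into `k` groups at empirical quantiles. Tied values take
#' the group of their minimum rank (deterministically assigned to the
#' lower group). With distinct values, group sizes differ by at most 1.
#'
#' @param values Numeric vector (`length >= k`).
#' @param k Number of groups (>= 2).
#' @return Integer group labels in `1..k` (1 = lowest values).
#' @export
equal_frequency_discretize <- function(values, k) {
  k <- as.integer(k)
  if (k < 2L) stop("`k` must be >= 2", call. = FALSE)
  n <- length(values)
  if (n < k) stop("need at least `k` values", call. = FALSE)
  r <- rank(values, ties.method = "min")
  g <- as.integer(floor((r - 1) * k / n)) + 1L
  if (length(unique(g)) < k) {
    stop(sprintf("ties prevent forming %d nonempty equal-frequency groups", k),
         call. = FALSE)
  }
  g
}

#' One-way fixed-effects analysis of variance
#'
#' @param y Numeric response.
#' @param labels Group labels (>= 2 groups, each with >= 2 members).
#' @return A list with `f_statistic`, `p_value`, `df_between`, `df_within`.
#' @export
anova_between_groups <- function(y, labels) {
  labels <- factor(labels)
  sizes <- table(labels)
  if (length(sizes) < 2L) stop("need >= 2 groups", call. = FALSE)
  if (any(sizes < 2L)) {
    stop("every group needs >= 2 members", call. = FALSE)
  }
  tab <- stats::anova(stats::lm(y ~ labels))
  list(f_statistic = tab$`F value`[1], p_value = tab$`Pr(>F)`[1],
       df_between = tab$Df[1], df_within = tab$Df[2])
}

#' Per-amplicon coverage uniformity (coefficient of variation)
#'
#' The uniformity of an amplicon's coverage is the coefficient of
#' inter-sample variation of its read count: sample SD (n-1) over mean
#' across samples. High CV means poor uniformity. Zero-mean amplicons
#' yield `NA` and are flagged.
#'
#' @param counts Numeric matrix, rows = amplicons, columns = samples
#'   (>= 2).
#' @return Named numeric vector of CVs with attribute `n_zero_mean`.
#' @export
coverage_uniformity <- function(counts) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2L) {
    stop("coverage uniformity requires >= 2 samples", call. = FALSE)
  }
  cv <- apply(counts, 1L, cv_sample)
  attr(cv, "n_zero_mean") <- sum(is.na(cv))
  cv
}
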