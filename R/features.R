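# Per-amplicon fragmentation features: spanning-fragment count (A), depth
# range (B), boundary depth change (C) and depth shape (D), plus their
# cross-sample robustness.

track_slice <- function(track, start, end) {
  i1 <- start - track$origin + 1L
  i2 <- end - track$origin
  if (i1 < 1L || i2 > length(track$values) || i2 < i1) {
    stop(sprintf("coverage track [%d,%d) does not cover [%d,%d)",
                 track$origin, track$origin + length(track$values),
                 start, end), call. = FALSE)
  }
  track$values[i1:i2]
}

#' Feature A: count of fragments spanning the whole amplicon
#'
#' Counts the cfDNA fragments that fully contain the amplicon's outer
#' interval, i.e. that carry both primer sites and can serve as PCR
#' template (in-silico primer matching).
#'
#' @param amplicon A single-row amplicon panel `data.frame`.
#' @param fragments A fragment-record `data.frame`; fragments on other
#'   contigs are ignored.
#' @return Integer count.
#' @export
spanning_fragment_count <- function(amplicon, fragments) {
  sum(fragments$contig == amplicon$contig &
        fragments$start <= amplicon$outer_start &
        fragments$end >= amplicon$outer_end)
}

#' Feature B: depth range (signal amplitude) within the amplicon
#'
#' @param track A (smoothed) `coverage_track` covering the amplicon.
#' @param amplicon A single-row amplicon panel `data.frame`.
#' @return `max - min` of the track over the amplicon's outer interval.
#' @export
depth_range <- function(track, amplicon) {
  v <- track_slice(track, amplicon$outer_start, amplicon$outer_end)
  max(v) - min(v)
}

#' Feature C: depth change between the amplicon boundaries
#'
#' Absolute difference between the track values at the last and first base
#' of the amplicon. Equals Feature B on monotone signals and 0 when the
#' two boundary depths agree.
#'
#' @inheritParams depth_range
#' @return Nonnegative boundary depth change.
#' @export
depth_change <- function(track, amplicon) {
  v <- track_slice(track, amplicon$outer_start, amplicon$outer_end)
  abs(v[length(v)] - v[1])
}

#' Feature D: depth shape (area between signal and its linear approximation)
#'
#' Sum over amplicon positions of the absolute difference between the track
#' and the straight segment joining its values at the two amplicon
#' boundaries. Zero for exactly linear signal; insensitive to adding a
#' constant.
#'
#' @inheritParams depth_range
#' @return Nonnegative area.
#' @export
depth_shape <- function(track, amplicon) {
  v <- track_slice(track, amplicon$outer_start, amplicon$outer_end)
  n <- length(v)
  if (n < 2L) stop("amplicon must span at least 2 bp", call. = FALSE)
  line <- seq(v[1], v[n], length.out = n)
  sum(abs(v - line))
}

#' Compute the per-amplicon feature table across samples
#'
#' Runs the fragment-processing chain per sample (length filter, dyad trim,
#' overlap counts, square-pulse smoothing) and evaluates features A-D for
#' every amplicon. Feature A is computed on the length-filtered, untrimmed
#' fragments (a trimmed fragment can no longer span an amplicon); B-D are
#' computed on the smoothed dyad-trimmed coverage track.
#'
#' @param fragments A fragment-record `data.frame` with a `sample_id`
#'   column.
#' @param panel An amplicon panel `data.frame`.
#' @param min_len,max_len Length-filter bounds in bp (inclusive).
#' @param trim Dyad trim window in bp.
#' @param kernel_width Square-pulse kernel width in bp.
#' @param margin Extra track margin in bp on each side of the panel span.
#' @return A long-format `data.frame`: `amplicon`, `sample`, `A`, `B`, `C`,
#'   `D`, `gc`.
#' @export
amplicon_feature_table <- function(fragments, panel, min_len = 80L,
                                   max_len = 250L, trim = 40L,
                                   kernel_width = 21L, margin = 500L) {
  samples <- sort(unique(fragments$sample_id))
  if (length(samples) == 0L) stop("no fragments supplied", call. = FALSE)
  contig <- panel$contig[1]
  region_start <- max(0L, min(panel$outer_start) - margin)
  region_end <- max(panel$outer_end) + margin
  res <- lapply(samples, function(s) {
    f <- fragments[fragments$sample_id == s, , drop = FALSE]
    f <- filter_by_length(f, min_len, max_len)
    a <- vapply(seq_len(nrow(panel)), function(i) {
      spanning_fragment_count(panel[i, ], f)
    }, numeric(1))
    trimmed <- trim_to_dyad_window(f, trim)
    track <- position_overlap_counts(trimmed, contig, region_start,
                                     region_end)
    track <- square_pulse_smooth(track, kernel_width)
    b <- vapply(seq_len(nrow(panel)), function(i) {
      depth_range(track, panel[i, ])
    }, numeric(1))
    cc <- vapply(seq_len(nrow(panel)), function(i) {
      depth_change(track, panel[i, ])
    }, numeric(1))
    d <- vapply(seq_len(nrow(panel)), function(i) {
      depth_shape(track, panel[i, ])
    }, numeric(1))
    data.frame(amplicon = panel$name, sample = s, A = a, B = b, C = cc,
               D = d, gc = panel$gc_fraction, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Cross-sample robustness of the fragmentation features
#'
#' For each feature, computes the coefficient of variation (sample SD over
#' mean) across samples per amplicon, then averages over amplicons.
#' Amplicons with zero mean for a feature are skipped and counted.
#'
#' @param feature_table Long-format table from [amplicon_feature_table()].
#' @param features Feature columns to evaluate.
#' @return A list with `mean_cv` (named per-feature average CV) and
#'   `n_skipped` (named count of zero-mean amplicons per feature).
#' @export
feature_robustness <- function(feature_table,
                               features = c("A", "B", "C", "D")) {
  n_samples <- length(unique(feature_table$sample))
  if (n_samples < 2L) {
    stop("feature robustness requires >= 2 samples", call. = FALSE)
  }
  amps <- unique(feature_table$amplicon)
  mean_cv <- numeric(0)
  n_skipped <- integer(0)
  for (f in features) {
    cvs <- vapply(amps, function(a) {
      cv_sample(feature_table[[f]][feature_table$amplicon == a])
    }, numeric(1))
    n_skipped[f] <- sum(is.na(cvs))
    mean_cv[f] <- mean(cvs, na.rm = TRUE)
  }
  list(mean_cv = mean_cv, n_skipped = n_skipped)
}
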