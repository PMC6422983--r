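#' Reconstruct cfDNA fragments from paired read intervals
#'
#' Paired-end sequencing captures both ends of a cfDNA molecule even when
#' the molecule is longer than a read; the fragment is the outer span of
#' the two read intervals, `[min start, max end)`. Pairs whose reads map to
#' different contigs, or whose outer span is degenerate, are dropped and
#' counted.
#'
#' @param pairs A `data.frame` with columns `contig1`, `start1`, `end1`,
#'   `contig2`, `start2`, `end2`, and optionally `sample_id`.
#' @return A fragment-record `data.frame`; the number of dropped pairs is
#'   attached as attribute `n_dropped`.
#' @examples
#' p <- data.frame(contig1 = "chr1", start1 = 100, end1 = 201,
#'                 contig2 = "chr1", start2 = 150, end2 = 251)
#' fragments_from_pairs(p)  # fragment [100, 251)
#' @export
fragments_from_pairs <- function(pairs) {
  if (nrow(pairs) == 0L) {
    out <- fragment_records(character(), integer(), integer() + 1L,
                            character())[0, ]
    attr(out, "n_dropped") <- 0L
    return(out)
  }
  sample_id <- if ("sample_id" %in% names(pairs)) pairs$sample_id else "S1"
  start <- pmin(pairs$start1, pairs$start2)
  end <- pmax(pairs$end1, pairs$end2)
  ok <- pairs$contig1 == pairs$contig2 & end > start
  out <- fragment_records(pairs$contig1[ok], start[ok], end[ok],
                          rep_len(sample_id, nrow(pairs))[ok])
  attr(out, "n_dropped") <- sum(!ok)
  out
}

#' Filter fragments by length
#'
#' Keeps fragments whose length lies in `[min_len, max_len]` (both bounds
#' inclusive). The 80-250 bp default window retains the mononucleosome
#' population and excludes dinucleosome fragments.
#'
#' @param fragments A fragment-record `data.frame`.
#' @param min_len,max_len Inclusive length bounds in bp.
#' @return The surviving fragments, input order preserved.
#' @export
filter_by_length <- function(fragments, min_len = 80L, max_len = 250L) {
  if (min_len > max_len) {
    stop("`min_len` must not exceed `max_len`", call. = FALSE)
  }
  len <- fragments$end - fragments$start
  out <- fragments[len >= min_len & len <= max_len, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Trim fragments to a fixed window around their dyads
#'
#' Replaces each fragment by the `window`-bp interval centered on its
#' midpoint (the dyad proxy), producing a set of equal-length fragments
#' that sharpens the nucleosome positioning signal. The dyad of an
#' even-length fragment is the floor midpoint.
#'
#' @param fragments A fragment-record `data.frame`; every fragment must be
#'   at least `window` bp long.
#' @param window Even window width in bp (default 40, i.e. dyad +/- 20).
#' @return Fragments of identical length `window`, one per input fragment.
#' @export
trim_to_dyad_window <- function(fragments, window = 40L) {
  window <- as.integer(window)
  if (window < 2L || window %% 2L != 0L) {
    stop("`window` must be an even integer >= 2", call. = FALSE)
  }
  len <- fragments$end - fragments$start
  short <- which(len < window)
  if (length(short) > 0L) {
    stop(sprintf("%d fragment(s) shorter than the %d bp trim window (rows: %s)",
                 length(short), window,
                 paste(utils::head(short, 10L), collapse = ", ")),
         call. = FALSE)
  }
  dyad <- (fragments$start + fragments$end) %/% 2L
  out <- fragments
  out$start <- dyad - window %/% 2L
  out$end <- dyad + window %/% 2L
  out
}

#' Per-base fragment overlap counts over a region
#'
#' For every base position `p` in `[region_start, region_end)`, counts the
#' fragments with `start <= p < end`.
#'
#' @param fragments A fragment-record `data.frame`.
#' @param contig Contig of the region; fragments on other contigs are
#'   ignored.
#' @param region_start,region_end 0-based half-open region bounds.
#' @return A `coverage_track` object: list with `contig`, `origin`
#'   (= `region_start`), per-base `values`, `smoothed` flag and
#'   `kernel_width`.
#' @export
position_overlap_counts <- function(fragments, contig, region_start,
                                    region_end) {
  region_start <- as.integer(region_start)
  region_end <- as.integer(region_end)
  if (region_end <= region_start) {
    stop("region must be non-empty (region_end > region_start)", call. = FALSE)
  }
  len <- region_end - region_start
  delta <- numeric(len + 1L)
  f <- fragments[fragments$contig == contig, , drop = FALSE]
  if (nrow(f) > 0L) {
    a <- pmax(f$start, region_start) - region_start
    b <- pmin(f$end, region_end) - region_start
    keep <- a < b
    a <- a[keep]
    b <- b[keep]
    if (length(a) > 0L) {
      inc <- tabulate(a + 1L, nbins = len + 1L)
      dec <- tabulate(b + 1L, nbins = len + 1L)
      delta <- inc - dec
    }
  }
  structure(
    list(contig = contig, origin = region_start,
         values = cumsum(delta)[seq_len(len)],
         smoothed = FALSE, kernel_width = NULL),
    class = "coverage_track"
  )
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf("<coverage_track> %s:[%d,%d) %s\n", x$contig, x$origin,
              x$origin + length(x$values),
              if (x$smoothed) sprintf("smoothed (width %d)", x$kernel_width)
              else "raw"))
  invisible(x)
}

#' Square-pulse (moving-average) low-pass filter
#'
#' Smooths a coverage track with a centered square-pulse kernel of odd
#' width. At the track edges the window is truncated to the available
#' positions and renormalized by its actual size, so constant tracks stay
#' constant everywhere.
#'
#' @param track A `coverage_track`.
#' @param width Odd kernel width in bp (default 21).
#' @return The smoothed `coverage_track` (`smoothed = TRUE`,
#'   `kernel_width = width`).
#' @export
square_pulse_smooth <- function(track, width = 21L) {
  width <- as.integer(width)
  n <- length(track$values)
  if (width < 1L || width %% 2L == 0L) {
    stop("`width` must be an odd integer >= 1", call. = FALSE)
  }
  if (width > n) {
    stop("`width` must not exceed the track length", call. = FALSE)
  }
  h <- (width - 1L) %/% 2L
  cs <- c(0, cumsum(track$values))
  idx <- seq_len(n)
  lo <- pmax(idx - h, 1L)
  hi <- pmin(idx + h, n)
  track$values <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  track$smoothed <- TRUE
  track$kernel_width <- width
  track
}

#' Call nucleosome peaks from dyad positions
#'
#' Smooths the dyad-position density with a Gaussian kernel and reports
#' strict local maxima as nucleosome peaks. Each peak's positional
#' stringency is its density divided by the mean density over the flanking
#' background window (positions within `background_window / 2` of the peak
#' but farther than `bandwidth` from it); sharply positioned nucleosomes
#' score high, diffuse placement scores near 1.
#'
#' @param dyads Integer vector of dyad positions (e.g. midpoints of trimmed
#'   fragments).
#' @param bandwidth Gaussian kernel SD in bp (default 30).
#' @param background_window Total width in bp of the flanking background
#'   region per peak (default 1000).
#' @param min_stringency Peaks below this stringency are dropped
#'   (default 0, keep all).
#' @return A `nucleosome_map` object: list with a `peaks` data.frame
#'   (`position`, `stringency`), `bandwidth` and `background_window`.
#' @export
call_nucleosome_peaks <- function(dyads, bandwidth = 30, background_window = 1000,
                                  min_stringency = 0) {
  if (length(dyads) == 0L) stop("no dyads supplied", call. = FALSE)
  if (bandwidth <= 0) stop("`bandwidth` must be positive", call. = FALSE)
  dyads <- as.integer(round(dyads))
  pad <- as.integer(ceiling(4 * bandwidth))
  g1 <- min(dyads) - pad
  g2 <- max(dyads) + pad
  len <- g2 - g1 + 1L
  cnt <- tabulate(dyads - g1 + 1L, nbins = len)
  off <- seq(-pad, pad)
  kern <- exp(-off^2 / (2 * bandwidth^2))
  dens <- as.numeric(stats::convolve(cnt, rev(kern), type = "open"))
  dens <- dens[(pad + 1L):(pad + len)]
  is_peak <- c(FALSE, dens[2:(len - 1L)] > dens[1:(len - 2L)] &
                 dens[2:(len - 1L)] > dens[3:len], FALSE)
  peak_idx <- which(is_peak)
  pos <- g1 + peak_idx - 1L
  half_bg <- background_window / 2
  stringency <- vapply(peak_idx, function(i) {
    d <- abs(seq_len(len) - i)
    bg <- d > bandwidth & d <= half_bg
    mu <- if (any(bg)) mean(dens[bg]) else 0
    if (mu == 0) Inf else dens[i] / mu
  }, numeric(1))
  keep <- stringency >= min_stringency
  structure(
    list(peaks = data.frame(position = pos[keep],
                            stringency = stringency[keep]),
         bandwidth = bandwidth, background_window = background_window),
    class = "nucleosome_map"
  )
}

#' @export
print.nucleosome_map <- function(x, ...) {
  cat(sprintf("<nucleosome_map> %d peaks (bandwidth %g bp)\n",
              nrow(x$peaks), x$bandwidth))
  invisible(x)
}

#' Permutation test for nucleosome-peak / amplicon interception
#'
#' The observed statistic is the number of amplicons whose interval
#' contains at least one nucleosome peak. The null distribution is built
#' by circularly shifting the whole panel by uniform random offsets within
#' the mapped region `n_perm` times; the p-value is
#' `(1 + #(null >= observed)) / (n_perm + 1)`.
#'
#' @param map A `nucleosome_map`.
#' @param panel An amplicon panel `data.frame`.
#' @param region_length Length of the mapped region used for circular
#'   shifts; defaults to the maximum coordinate seen in peaks or amplicons.
#' @param n_perm Number of permutations (>= 100).
#' @param seed Integer seed.
#' @return A list with `p_value`, `observed`, `n_perm` and the null counts.
#' @export
interception_test <- function(map, panel, region_length = NULL,
                              n_perm = 999L, seed = 1L) {
  if (nrow(map$peaks) == 0L) stop("nucleosome map has no peaks", call. = FALSE)
  if (is.null(panel) || nrow(panel) == 0L) {
    stop("`panel` must contain at least one amplicon", call. = FALSE)
  }
  if (n_perm < 100L) stop("`n_perm` must be >= 100", call. = FALSE)
  peaks <- sort(map$peaks$position)
  if (is.null(region_length)) {
    region_length <- max(max(panel$outer_end), max(peaks) + 1L)
  }
  count_hits <- function(starts, ends) {
    # number of amplicons containing >= 1 peak (point-in-interval)
    hi <- findInterval(ends - 1L, peaks)
    lo <- findInterval(starts - 1L, peaks)
    sum(hi > lo)
  }
  # circular interception count for a panel shifted by `offset`
  count_shifted <- function(offset) {
    s <- (panel$outer_start + offset) %% region_length
    e <- s + (panel$outer_end - panel$outer_start)
    wrap <- e > region_length
    n_plain <- if (any(!wrap)) count_hits(s[!wrap], e[!wrap]) else 0L
    n_wrap <- 0L
    if (any(wrap)) {
      sw <- s[wrap]
      ew <- e[wrap]
      hit1 <- findInterval(rep(region_length - 1L, sum(wrap)), peaks) >
        findInterval(sw - 1L, peaks)
      hit2 <- findInterval(ew - region_length - 1L, peaks) > 0L
      n_wrap <- sum(hit1 | hit2)
    }
    n_plain + n_wrap
  }
  observed <- count_hits(panel$outer_start, panel$outer_end)
  null_counts <- local_seed(seed, {
    offsets <- floor(stats::runif(n_perm) * region_length)
    vapply(offsets, count_shifted, numeric(1))
  })
  p <- (1 + sum(null_counts >= observed)) / (n_perm + 1)
  list(p_value = p, observed = observed, n_perm = n_perm,
       null_counts = null_counts)
}
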