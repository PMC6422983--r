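# Shared fixtures built in code.

small_landscape <- function(seed = 1L, contig_length = 1e5, ...) {
  generate_nucleosome_landscape(contig_length, mean_spacing = 190,
                                spacing_jitter_sd = 20, seed = seed, ...)
}

random_fragments <- function(n, contig = "chr1", max_pos = 10000L,
                             max_len = 300L, seed = NULL) {
  local({
    if (!is.null(seed)) set.seed(seed)
    start <- sample.int(max_pos, n, replace = TRUE) - 1L
    len <- sample.int(max_len, n, replace = TRUE)
    fragment_records(contig, start, start + len)
  })
}

# Brute-force per-position overlap scan, the oracle for
# position_overlap_counts().
overlap_scan_oracle <- function(fragments, contig, region_start, region_end) {
  pos <- region_start:(region_end - 1L)
  f <- fragments[fragments$contig == contig, , drop = FALSE]
  vapply(pos, function(p) sum(f$start <= p & p < f$end), numeric(1))
}

# Direct windowed-mean oracle for square_pulse_smooth().
windowed_mean_oracle <- function(values, width) {
  h <- (width - 1L) %/% 2L
  n <- length(values)
  vapply(seq_len(n), function(i) {
    w <- values[max(1L, i - h):min(n, i + h)]
    mean(w)
  }, numeric(1))
}

# Two-pass CV oracle (n-1 sd / mean).
cv_oracle <- function(x) {
  m <- sum(x) / length(x)
  if (m == 0) return(NA_real_)
  sqrt(sum((x - m)^2) / (length(x) - 1)) / m
}
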