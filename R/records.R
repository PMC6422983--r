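#' Construct a table of cfDNA fragment records
#'
#' A fragment record is one cfDNA molecule as a genomic interval in 0-based
#' half-open coordinates (BED convention): `start` is the first covered base,
#' `end` is one past the last. Fragment length is `end - start`.
#'
#' @param contig Character vector of contig names (recycled).
#' @param start Integer vector, 0-based inclusive start positions.
#' @param end Integer vector, exclusive end positions; must satisfy
#'   `end > start`.
#' @param sample_id Character vector of sample identifiers (recycled).
#' @return A `data.frame` with columns `contig`, `start`, `end`, `sample_id`.
#' @examples
#' fragment_records("chr1", c(99, 150), c(200, 317))
#' @export
fragment_records <- function(contig, start, end, sample_id = "S1") {
  start <- as.integer(start)
  end <- as.integer(end)
  if (length(start) != length(end)) {
    stop("`start` and `end` must have equal length", call. = FALSE)
  }
  if (any(end <= start)) {
    stop("all fragments must satisfy end > start", call. = FALSE)
  }
  data.frame(
    contig = as.character(rep_len(contig, length(start))),
    start = start,
    end = end,
    sample_id = as.character(rep_len(sample_id, length(start))),
    stringsAsFactors = FALSE
  )
}

#' Fragment lengths of a fragment-record table
#'
#' @param fragments A fragment-record `data.frame` (see [fragment_records()]).
#' @return Integer vector of lengths `end - start`.
#' @export
fragment_lengths <- function(fragments) {
  fragments$end - fragments$start
}

#' Construct an amplicon panel definition table
#'
#' Each amplicon is described by its outer coordinates (primer footprints
#' included, 0-based half-open), the two primer lengths, and its GC fraction.
#'
#' @param contig Character vector of contig names (recycled).
#' @param outer_start,outer_end Integer vectors, 0-based half-open outer
#'   coordinates including both primers.
#' @param name Character vector of unique amplicon names.
#' @param fwd_primer_len,rev_primer_len Integer primer lengths in bp.
#' @param gc_fraction Numeric GC fraction of the amplicon in `[0, 1]`.
#' @return A `data.frame` with one row per amplicon.
#' @export
amplicon_panel <- function(contig, outer_start, outer_end, name,
                           fwd_primer_len = 20L, rev_primer_len = 20L,
                           gc_fraction = 0.5) {
  n <- length(outer_start)
  outer_start <- as.integer(outer_start)
  outer_end <- as.integer(outer_end)
  fwd_primer_len <- as.integer(rep_len(fwd_primer_len, n))
  rev_primer_len <- as.integer(rep_len(rev_primer_len, n))
  gc_fraction <- rep_len(as.numeric(gc_fraction), n)
  if (any(outer_end - outer_start <= fwd_primer_len + rev_primer_len)) {
    stop("amplicon outer length must exceed the summed primer lengths",
         call. = FALSE)
  }
  if (any(gc_fraction < 0 | gc_fraction > 1)) {
    stop("`gc_fraction` must lie in [0, 1]", call. = FALSE)
  }
  name <- as.character(name)
  if (anyDuplicated(name)) stop("amplicon names must be unique", call. = FALSE)
  data.frame(
    contig = as.character(rep_len(contig, n)),
    outer_start = outer_start,
    outer_end = outer_end,
    name = name,
    fwd_primer_len = fwd_primer_len,
    rev_primer_len = rev_primer_len,
    gc_fraction = gc_fraction,
    stringsAsFactors = FALSE
  )
}
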