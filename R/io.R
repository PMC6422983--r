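# Plain-text readers/writers for fragments, panels and count matrices.
# All genomic coordinates on disk follow BED conventions (0-based half-open,
# tab-separated, no header for interval files).

read_tsv_checked <- function(path, n_fields, what) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(list())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < n_fields)
  if (length(bad) > 0L) {
    stop(sprintf("malformed %s line %d in '%s': expected %d tab-separated fields",
                 what, bad[1], path, n_fields), call. = FALSE)
  }
  parts
}

parse_int_field <- function(x, line_idx, path, what) {
  v <- suppressWarnings(as.integer(x))
  if (anyNA(v)) {
    stop(sprintf("malformed %s line %d in '%s': non-integer coordinate",
                 what, line_idx[which(is.na(v))[1]], path), call. = FALSE)
  }
  v
}

#' Write and read fragment records
#'
#' Fragments are stored as 4-column BED-like TSV (`contig`, `start`, `end`,
#' `sample_id`; 0-based half-open, no header), or as BEDPE where each line
#' carries the two read intervals of a pair and the fragment is the outer
#' span.
#'
#' @param fragments A fragment-record `data.frame`.
#' @param path File path.
#' @param format `"bed"` (default) or `"bedpe"`.
#' @return `read_fragments()` returns a fragment-record `data.frame`;
#'   `write_fragments()` returns `path` invisibly.
#' @export
write_fragments <- function(fragments, path, format = c("bed", "bedpe")) {
  format <- match.arg(format)
  if (format == "bed") {
    df <- fragments[, c("contig", "start", "end", "sample_id")]
  } else {
    # degenerate pairs: both "reads" are the fragment's terminal halves
    mid <- (fragments$start + fragments$end) %/% 2L
    df <- data.frame(fragments$contig, fragments$start, mid,
                     fragments$contig, mid, fragments$end,
                     fragments$sample_id)
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_fragments
#' @export
read_fragments <- function(path, format = c("bed", "bedpe")) {
  format <- match.arg(format)
  n_fields <- if (format == "bed") 4L else 7L
  parts <- read_tsv_checked(path, n_fields, "fragment")
  if (length(parts) == 0L) {
    return(fragment_records(character(), integer(), integer() + 1L,
                            character())[0, ])
  }
  idx <- seq_along(parts)
  if (format == "bed") {
    out <- fragment_records(
      contig = vapply(parts, `[[`, "", 1L),
      start = parse_int_field(vapply(parts, `[[`, "", 2L), idx, path, "fragment"),
      end = parse_int_field(vapply(parts, `[[`, "", 3L), idx, path, "fragment"),
      sample_id = vapply(parts, `[[`, "", 4L)
    )
  } else {
    pairs <- data.frame(
      contig1 = vapply(parts, `[[`, "", 1L),
      start1 = parse_int_field(vapply(parts, `[[`, "", 2L), idx, path, "fragment"),
      end1 = parse_int_field(vapply(parts, `[[`, "", 3L), idx, path, "fragment"),
      contig2 = vapply(parts, `[[`, "", 4L),
      start2 = parse_int_field(vapply(parts, `[[`, "", 5L), idx, path, "fragment"),
      end2 = parse_int_field(vapply(parts, `[[`, "", 6L), idx, path, "fragment"),
      sample_id = vapply(parts, `[[`, "", 7L),
      stringsAsFactors = FALSE
    )
    out <- fragments_from_pairs(pairs)
  }
  out
}

#' Write and read amplicon panel definitions
#'
#' BED-like TSV with header: `contig`, `outer_start`, `outer_end`, `name`,
#' `fwd_primer_len`, `rev_primer_len`, `gc_fraction`.
#'
#' @param panel An amplicon panel `data.frame`.
#' @param path File path.
#' @return `read_panel()` returns the panel `data.frame`; `write_panel()`
#'   returns `path` invisibly.
#' @export
write_panel <- function(panel, path) {
  utils::write.table(panel, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_panel
#' @export
read_panel <- function(path) {
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) {
    return(amplicon_panel(character(), integer(), integer() + 100L,
                          character())[0, ])
  }
  df <- tryCatch(
    utils::read.table(path, sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE),
    error = function(e) {
      stop(sprintf("malformed panel file '%s': %s", path, conditionMessage(e)),
           call. = FALSE)
    }
  )
  required <- c("contig", "outer_start", "outer_end", "name",
                "fwd_primer_len", "rev_primer_len", "gc_fraction")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop(sprintf("panel file '%s' lacks columns: %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  amplicon_panel(df$contig, df$outer_start, df$outer_end, df$name,
                 df$fwd_primer_len, df$rev_primer_len, df$gc_fraction)
}

#' Write and read amplicon count matrices
#'
#' TSV matrix with amplicon names in the first column (`amplicon`) and one
#' column per sample.
#'
#' @param counts Numeric matrix, rows = amplicons, columns = samples.
#' @param path File path.
#' @return `read_counts()` returns the matrix; `write_counts()` returns
#'   `path` invisibly.
#' @export
write_counts <- function(counts, path) {
  df <- data.frame(amplicon = rownames(counts), counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_counts
#' @export
read_counts <- function(path) {
  df <- tryCatch(
    utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                      stringsAsFactors = FALSE),
    error = function(e) {
      stop(sprintf("malformed counts file '%s': %s", path,
                   conditionMessage(e)), call. = FALSE)
    }
  )
  if (names(df)[1] != "amplicon") {
    stop(sprintf("counts file '%s' must start with an 'amplicon' column",
                 path), call. = FALSE)
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$amplicon
  if (!is.numeric(m)) {
    stop(sprintf("counts file '%s' contains non-numeric entries", path),
         call. = FALSE)
  }
  m
}
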