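# Peak container and validation.
#
# A peak set is a plain data.frame with the columns below; every function in
# the package that consumes or produces peaks goes through new_peaks() /
# validate_peaks() so the coordinate conventions stay uniform:
#   * start: 0-based inclusive
#   * end:   0-based exclusive (BED-style half-open)
#   * summit: ABSOLUTE 0-based genomic position, start <= summit < end

PEAK_COLUMNS <- c("id", "chrom", "start", "end", "summit", "score", "source")

#' Construct a peak data frame
#'
#' Builds the canonical peak container used across the package: one row per
#' peak, BED-style 0-based half-open `start`/`end` and an absolute 0-based
#' `summit` position inside the interval.
#'
#' @param chrom Character vector of chromosome names.
#' @param start,end Integer vectors; `0 <= start < end`, half-open.
#' @param summit Integer vector of absolute summit positions
#'   (`start <= summit < end`). Defaults to the interval midpoint.
#' @param score Numeric caller score (e.g. -log10 p). Defaults to 0.
#' @param id Character peak identifiers; generated if missing.
#' @param source Character label of the originating caller.
#' @return A `data.frame` with columns `id, chrom, start, end, summit,
#'   score, source`.
#' @examples
#' new_peaks(chrom = "chr1", start = 100, end = 200)
#' @export
new_peaks <- function(chrom, start, end, summit = NULL, score = NULL,
                      id = NULL, source = "unknown") {
  start <- as.integer(start)
  end <- as.integer(end)
  n <- length(start)
  chrom <- rep_len(as.character(chrom), n)
  if (is.null(summit)) summit <- (start + end) %/% 2L
  summit <- as.integer(summit)
  if (is.null(score)) score <- rep(0, n)
  if (is.null(id)) id <- sprintf("peak_%05d", seq_len(n))
  source <- rep_len(as.character(source), n)
  df <- data.frame(
    id = as.character(id), chrom = as.character(chrom),
    start = start, end = end, summit = summit,
    score = as.numeric(score), source = source,
    stringsAsFactors = FALSE
  )
  validate_peaks(df)
}

#' Validate a peak data frame
#'
#' Checks the container invariants: required columns, `0 <= start < end`,
#' `start <= summit < end`, non-empty chromosome names, unique ids.
#'
#' @param peaks A peak `data.frame` (see [new_peaks()]).
#' @return The input, invisibly unchanged, or an error describing the first
#'   violated invariant.
#' @export
validate_peaks <- function(peaks) {
  if (!is.data.frame(peaks)) stop("peaks must be a data.frame", call. = FALSE)
  missing_cols <- setdiff(PEAK_COLUMNS, names(peaks))
  if (length(missing_cols)) {
    stop("peak data frame lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(peaks) == 0L) return(peaks)
  if (any(is.na(peaks$start)) || any(is.na(peaks$end))) {
    stop("peak coordinates contain NA", call. = FALSE)
  }
  bad <- which(peaks$start < 0L | peaks$start >= peaks$end)
  if (length(bad)) {
    stop(sprintf("invalid interval (need 0 <= start < end) for peak '%s'",
                 peaks$id[bad[1L]]), call. = FALSE)
  }
  bad <- which(peaks$summit < peaks$start | peaks$summit >= peaks$end)
  if (length(bad)) {
    stop(sprintf("summit outside [start, end) for peak '%s'",
                 peaks$id[bad[1L]]), call. = FALSE)
  }
  if (any(!nzchar(peaks$chrom) | is.na(peaks$chrom))) {
    stop("empty chromosome name", call. = FALSE)
  }
  if (anyDuplicated(peaks$id)) {
    stop("duplicated peak id: ", peaks$id[duplicated(peaks$id)][1L],
         call. = FALSE)
  }
  peaks
}

# GRanges view of a peak data.frame (1-based closed coordinates).
peaks_to_granges <- function(peaks) {
  GenomicRanges::GRanges(
    seqnames = peaks$chrom,
    ranges = IRanges::IRanges(start = peaks$start + 1L, end = peaks$end)
  )
}
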