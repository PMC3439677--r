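# peak_pool: candidate pool as the union of several callers' peak sets.

#' Do two peaks overlap?
#'
#' Two peaks overlap iff they are on the same chromosome and share at least
#' one base pair under the half-open convention: `a$start < b$end` and
#' `b$start < a$end`.
#'
#' @param a,b Single-row peak data frames (or lists with `chrom`, `start`,
#'   `end`).
#' @return `TRUE` or `FALSE`.
#' @export
overlaps <- function(a, b) {
  a$chrom == b$chrom && a$start < b$end && b$start < a$end
}

#' Pool peak sets from several callers into merged candidates
#'
#' Takes the union of all input peak sets and transitively merges peaks that
#' share at least one base pair on the same chromosome. Each merged
#' candidate spans `min(start) .. max(end)` of its contributors; its summit
#' is the summit of the highest-scoring contributor (score ties broken by
#' the leftmost summit), its score is that contributor's score, and its
#' `source` is the comma-joined sorted set of contributing caller labels.
#'
#' @param peak_sets A list of peak data frames (one per caller), or a single
#'   peak data frame.
#' @return An object of class `"candidate_pool"`: a list with
#'   \describe{
#'     \item{peaks}{merged candidate peak `data.frame`, ordered by
#'       chromosome then start, ids `cand_00001 ...`}
#'     \item{provenance}{named list mapping each candidate id to a
#'       `data.frame` of contributing `(source, id)` pairs}
#'   }
#' @examples
#' a <- new_peaks("chr1", 100, 200, source = "macs")
#' b <- new_peaks("chr1", 150, 250, source = "tpic")
#' union_peaks(list(a, b))$peaks
#' @export
union_peaks <- function(peak_sets) {
  if (is.data.frame(peak_sets)) peak_sets <- list(peak_sets)
  peak_sets <- lapply(peak_sets, validate_peaks)
  all <- do.call(rbind, peak_sets)
  if (is.null(all) || nrow(all) == 0L) {
    empty <- new_peaks(character(), integer(), integer())
    return(structure(list(peaks = empty, provenance = list()),
                     class = "candidate_pool"))
  }
  gr <- peaks_to_granges(all)
  # min.gapwidth = 0: merge on >= 1 shared bp; abutting half-open intervals
  # (gap 0) stay separate.
  merged <- GenomicRanges::reduce(gr, min.gapwidth = 0L)
  hit <- GenomicRanges::findOverlaps(gr, merged)
  stopifnot(length(hit) == nrow(all))  # every original peak in exactly one candidate
  member <- S4Vectors::subjectHits(hit)[order(S4Vectors::queryHits(hit))]

  ord <- order(as.character(GenomicRanges::seqnames(merged)),
               GenomicRanges::start(merged))
  rank_of <- integer(length(merged)); rank_of[ord] <- seq_along(ord)
  member <- rank_of[member]
  merged <- merged[ord]

  n <- length(merged)
  ids <- sprintf("cand_%05d", seq_len(n))
  summit <- integer(n); score <- numeric(n); src <- character(n)
  prov <- stats::setNames(vector("list", n), ids)
  for (i in seq_len(n)) {
    rows <- all[member == i, , drop = FALSE]
    best <- which(rows$score == max(rows$score))
    best <- best[which.min(rows$summit[best])]  # ties: leftmost summit
    summit[i] <- rows$summit[best]
    score[i] <- rows$score[best]
    src[i] <- paste(sort(unique(rows$source)), collapse = ",")
    prov[[i]] <- data.frame(source = rows$source, id = rows$id,
                            stringsAsFactors = FALSE)
  }
  peaks <- new_peaks(
    chrom = as.character(GenomicRanges::seqnames(merged)),
    start = GenomicRanges::start(merged) - 1L,
    end = GenomicRanges::end(merged),
    summit = summit, score = score, id = ids, source = src
  )
  structure(list(peaks = peaks, provenance = prov), class = "candidate_pool")
}

#' @export
print.candidate_pool <- function(x, ...) {
  cat(sprintf("Candidate pool: %d merged candidates from %d original peaks\n",
              nrow(x$peaks), sum(vapply(x$provenance, nrow, 0L))))
  srcs <- sort(unique(unlist(lapply(x$provenance, function(p) p$source))))
  if (length(srcs)) cat("  callers:", paste(srcs, collapse = ", "), "\n")
  invisible(x)
}

#' Venn-style overlap accounting across named peak sets
#'
#' Merges the union of all sets into candidates (same rule as
#' [union_peaks()]) and counts, for every non-empty subset of set names,
#' the candidates supported by exactly that subset.
#'
#' @param pools Named list (>= 2 elements) of peak data frames.
#' @return `data.frame` with columns `subset` (set names joined by `&`,
#'   sorted) and `count`; one row per non-empty subset, including zero
#'   counts. Counts sum to the total number of merged candidates.
#' @export
intersect_counts <- function(pools) {
  if (length(pools) < 2L || is.null(names(pools)) || any(!nzchar(names(pools)))) {
    stop("intersect_counts() needs >= 2 named peak sets", call. = FALSE)
  }
  nm <- names(pools)
  tagged <- lapply(nm, function(s) {
    p <- pools[[s]]
    if (nrow(p)) p$source <- s
    p$id <- paste0(s, ":", p$id)
    p
  })
  pool <- union_peaks(tagged)
  sig <- vapply(pool$provenance, function(p) {
    paste(sort(unique(p$source)), collapse = "&")
  }, "")
  subsets <- unlist(lapply(seq_along(nm), function(k) {
    apply(utils::combn(sort(nm), k), 2L, paste, collapse = "&")
  }))
  counts <- vapply(subsets, function(s) sum(sig == s), 0L)
  data.frame(subset = subsets, count = as.integer(counts),
             row.names = NULL, stringsAsFactors = FALSE)
}
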