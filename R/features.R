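# features: the 67-dimensional binary encoding of a candidate peak.
#
# Layout (fixed):
#   columns  1..64  tri_AAA ... tri_TTT   trigram presence, lexicographic
#                                         over A < C < G < T, forward strand
#   column   65     occ                   mean predicted nucleosome occupancy
#                                         over summit +/- occ_flank > threshold
#   column   66     er_overlap            >= 1 bp overlap with a primary-TF
#                                         (ERalpha) peak
#   column   67     sensitive_gene        nearest-TSS gene is co-regulator-
#                                         sensitive

#' Names of the 64 trigrams in lexicographic order
#' @return Character vector `c("AAA", "AAC", ..., "TTT")`.
#' @export
trigram_names <- function() {
  b <- c("A", "C", "G", "T")
  as.vector(t(outer(as.vector(t(outer(b, b, paste0))), b, paste0)))
}

#' Feature-extraction configuration
#'
#' @param seq_flank Half-width (bp) of the summit-centered sequence window
#'   used for trigram presence; default 300 (a 600 bp window).
#' @param occ_flank Half-width (bp) of the occupancy window; default 50
#'   (roughly one nucleosome), inclusive of both endpoints (101 positions).
#' @param occ_threshold Occupancy bit is 1 iff the window mean is strictly
#'   greater than this; default 0.75.
#' @param gene_max_distance Maximum summit-to-TSS distance (bp) for gene
#'   mapping, or `Inf` (default) for nearest-TSS with no cap.
#' @param both_strands Scan trigrams on both strands; default `FALSE`
#'   (forward only).
#' @return A list of class `"feature_config"`.
#' @export
feature_config <- function(seq_flank = 300L, occ_flank = 50L,
                           occ_threshold = 0.75, gene_max_distance = Inf,
                           both_strands = FALSE) {
  stopifnot(seq_flank > 0L, occ_flank > 0L,
            occ_threshold > 0, occ_threshold < 1)
  structure(list(seq_flank = as.integer(seq_flank),
                 occ_flank = as.integer(occ_flank),
                 occ_threshold = occ_threshold,
                 gene_max_distance = gene_max_distance,
                 both_strands = isTRUE(both_strands)),
            class = "feature_config")
}

#' Extract the summit-centered sequence window
#'
#' Returns the substring covering positions
#' `[max(0, summit - flank), min(len, summit + flank))` — clamped at the
#' chromosome edges, never padded, so the result has length at most
#' `2 * flank`.
#'
#' @param genome Named character vector from [read_fasta()].
#' @param chrom Chromosome name.
#' @param summit Absolute 0-based summit position (must lie on the
#'   chromosome).
#' @param flank Half-width in bp.
#' @return A DNA string of length `<= 2 * flank`.
#' @export
extract_window <- function(genome, chrom, summit, flank = 300L) {
  if (!chrom %in% names(genome)) {
    stop("chromosome not in genome: ", chrom, call. = FALSE)
  }
  len <- nchar(genome[[chrom]])
  if (summit < 0L || summit >= len) {
    stop(sprintf("summit %d outside chromosome %s (length %d)",
                 summit, chrom, len), call. = FALSE)
  }
  lo <- max(0L, summit - flank)          # 0-based inclusive
  hi <- min(len, summit + flank)         # 0-based exclusive
  substr(genome[[chrom]], lo + 1L, hi)
}

#' Trigram presence/absence in a sequence window
#'
#' Scans all overlapping length-3 substrings of `seq` (forward strand;
#' optionally also the reverse complement) and reports, for each of the 64
#' trigrams in lexicographic order, whether it occurs at least once.
#' Windows containing `N` match no trigram. Sequences shorter than 3 give
#' all zeros.
#'
#' @param seq A DNA string over `{A,C,G,T,N}`.
#' @param both_strands Also scan the reverse complement; default `FALSE`.
#' @return Named integer vector of length 64 with values in `{0, 1}`.
#' @export
trigram_presence <- function(seq, both_strands = FALSE) {
  out <- stats::setNames(integer(64L), paste0("tri_", trigram_names()))
  scan1 <- function(s) {
    L <- nchar(s)
    if (L < 3L) return(integer(0))
    code <- dna_codes(s)
    idx <- 16L * code[1:(L - 2L)] + 4L * code[2:(L - 1L)] + code[3:L] - 20L
    idx[!is.na(idx)]
  }
  idx <- scan1(seq)
  if (isTRUE(both_strands)) idx <- c(idx, scan1(revcomp_chr(seq)))
  out[unique(idx)] <- 1L
  out
}

#' Nucleosome-occupancy bit for a peak summit
#'
#' Takes the mean occupancy over the window `[summit - flank,
#' summit + flank]` (inclusive of both endpoints; 101 positions at the
#' default flank of 50), clamped at the chromosome edges, and returns 1 iff
#' that mean is strictly greater than `threshold`. Positions without
#' occupancy data contribute 0.
#'
#' @param track Occupancy track from [read_occupancy()].
#' @param chrom Chromosome name.
#' @param summit Absolute 0-based summit position.
#' @param flank Half-width in bp (default 50).
#' @param threshold Strict lower bound on the mean (default 0.75).
#' @param chrom_length Optional chromosome length used to clamp the window;
#'   when `NULL` the window is clamped only at 0.
#' @return `0L` or `1L`.
#' @export
occupancy_bit <- function(track, chrom, summit, flank = 50L,
                          threshold = 0.75, chrom_length = NULL) {
  lo <- max(0L, summit - flank)
  hi <- summit + flank                                  # inclusive
  if (!is.null(chrom_length)) hi <- min(hi, chrom_length - 1L)
  pos <- lo:hi
  v <- numeric(length(pos))
  tv <- track[[chrom]]
  if (!is.null(tv) && length(tv)) {
    inside <- pos < length(tv)
    v[inside] <- tv[pos[inside] + 1L]
  }
  as.integer(mean(v) > threshold)
}

#' Primary-TF (ERalpha) overlap bit
#'
#' @param peak Single-row peak data frame.
#' @param er_peaks Peak data frame of primary-TF peaks (may be empty).
#' @return `1L` iff `peak` shares at least one base pair with any primary-TF
#'   peak, else `0L`.
#' @export
er_overlap_bit <- function(peak, er_peaks) {
  if (is.null(er_peaks) || nrow(er_peaks) == 0L) return(0L)
  same <- er_peaks[er_peaks$chrom == peak$chrom, , drop = FALSE]
  as.integer(any(peak$start < same$end & same$start < peak$end))
}

#' Map a peak to its nearest-TSS gene
#'
#' Returns the same-chromosome gene whose TSS is nearest to the peak summit
#' (`distance = |tss - summit|`). Distance ties are broken by the smaller
#' TSS, then lexicographically by `gene_id`. Returns `NA` when the
#' chromosome carries no gene or the nearest TSS is farther than
#' `max_distance`.
#'
#' @param peak Single-row peak data frame.
#' @param genes Gene table from [read_genes()].
#' @param max_distance Cap in bp (default `Inf`, i.e. nearest TSS wins
#'   regardless of distance; set to e.g. `50000` to require the TSS within
#'   50 kb).
#' @return A `gene_id` string or `NA_character_`.
#' @export
map_peak_to_gene <- function(peak, genes, max_distance = Inf) {
  g <- genes[genes$chrom == peak$chrom, , drop = FALSE]
  if (nrow(g) == 0L) return(NA_character_)
  d <- abs(g$tss - peak$summit)
  best <- which(d == min(d))
  if (length(best) > 1L) {
    best <- best[order(g$tss[best], g$gene_id[best])][1L]
  }
  if (d[best] > max_distance) return(NA_character_)
  g$gene_id[best]
}

#' Sensitive-gene bit
#'
#' @inheritParams map_peak_to_gene
#' @return `1L` iff the peak maps to a gene (see [map_peak_to_gene()]) and
#'   that gene is co-regulator-sensitive, else `0L`.
#' @export
sensitive_gene_bit <- function(peak, genes, max_distance = Inf) {
  gid <- map_peak_to_gene(peak, genes, max_distance)
  if (is.na(gid)) return(0L)
  as.integer(isTRUE(genes$sensitive[match(gid, genes$gene_id)]))
}

#' Build the 67-column binary feature matrix for a set of peaks
#'
#' Encodes each peak as the fixed-layout feature vector: 64 trigram-presence
#' bits from the `+/- seq_flank` window around the summit, the
#' nucleosome-occupancy bit, the primary-TF overlap bit, and the
#' sensitive-gene bit. Row order follows the input peaks; row names are the
#' peak ids.
#'
#' @param peaks Peak `data.frame`, or a `"candidate_pool"` (its `$peaks` is
#'   used).
#' @param genome Named character vector from [read_fasta()].
#' @param track Occupancy track from [read_occupancy()] (or `NULL` for
#'   all-zero occupancy).
#' @param er_peaks Primary-TF peak `data.frame` (or `NULL`).
#' @param genes Gene table from [read_genes()] (or `NULL`).
#' @param config A [feature_config()].
#' @return Integer matrix (`n x 67`) with values in `{0, 1}`, column names
#'   `tri_AAA ... tri_TTT, occ, er_overlap, sensitive_gene`.
#' @export
build_feature_matrix <- function(peaks, genome, track = NULL,
                                 er_peaks = NULL, genes = NULL,
                                 config = feature_config()) {
  if (inherits(peaks, "candidate_pool")) peaks <- peaks$peaks
  validate_peaks(peaks)
  lens <- genome_lengths(genome)
  n <- nrow(peaks)
  m <- matrix(0L, nrow = n, ncol = 67L,
              dimnames = list(peaks$id,
                              c(paste0("tri_", trigram_names()),
                                "occ", "er_overlap", "sensitive_gene")))
  for (i in seq_len(n)) {
    p <- peaks[i, , drop = FALSE]
    if (!p$chrom %in% names(genome)) {
      stop(sprintf("peak '%s': chromosome %s absent from genome",
                   p$id, p$chrom), call. = FALSE)
    }
    win <- extract_window(genome, p$chrom, p$summit, config$seq_flank)
    m[i, 1:64] <- trigram_presence(win, config$both_strands)
    m[i, "occ"] <- if (is.null(track)) 0L else {
      occupancy_bit(track, p$chrom, p$summit, config$occ_flank,
                    config$occ_threshold, chrom_length = lens[[p$chrom]])
    }
    m[i, "er_overlap"] <- if (is.null(er_peaks)) 0L else er_overlap_bit(p, er_peaks)
    m[i, "sensitive_gene"] <- if (is.null(genes)) 0L else {
      sensitive_gene_bit(p, genes, config$gene_max_distance)
    }
  }
  m
}
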