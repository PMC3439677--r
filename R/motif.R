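# motif_eval: PWM scanning for ERE containment and per-set containment
# ratios.
#
# Per-peak containment replaces a set-level over-representation test: a
# peak "contains" the motif when the best log2-odds hit in the +/- 300 bp
# summit window, over both strands, reaches a fixed fraction (default 0.8)
# of the matrix's maximum achievable score.

#' Build a position weight matrix from base counts
#'
#' Frequencies use a pseudocount: `f[i, b] = (counts[i, b] + pc) /
#' (rowsum_i + 4 pc)`; scores are `log2(f[i, b] / background[b])`.
#'
#' @param counts `width x 4` non-negative matrix (columns A, C, G, T). Rows
#'   of all zeros are allowed (uniform after the pseudocount; they score 0
#'   against a uniform background and act as free positions).
#' @param pseudocount Added to every cell (default 0.5).
#' @param background Background base probabilities (default uniform).
#' @param score_threshold_frac Fraction of the maximum achievable score a
#'   hit must reach to count as containment (default 0.8).
#' @param name Optional motif name.
#' @return Object of class `"pwm"`: list with `width`, `freq`, `log_odds`
#'   (`width x 4`), `max_score`, `consensus`, `score_threshold_frac`,
#'   `name`.
#' @examples
#' pwm_from_counts(matrix(c(10, 0, 0, 0), 1, 4,
#'                        dimnames = list(NULL, c("A", "C", "G", "T"))),
#'                 pseudocount = 0.5)$log_odds  # log2(3.5) for A
#' @export
pwm_from_counts <- function(counts, pseudocount = 0.5,
                            background = rep(0.25, 4),
                            score_threshold_frac = 0.8, name = NULL) {
  counts <- as.matrix(counts)
  if (ncol(counts) != 4L) stop("counts must have 4 columns (A,C,G,T)",
                               call. = FALSE)
  if (any(counts < 0)) stop("negative counts", call. = FALSE)
  if (nrow(counts) < 4L) stop("motif width must be >= 4", call. = FALSE)
  if (all(counts == 0)) stop("count matrix is entirely zero", call. = FALSE)
  stopifnot(length(background) == 4L, all(background > 0),
            abs(sum(background) - 1) < 1e-9,
            score_threshold_frac > 0, score_threshold_frac <= 1)
  w <- nrow(counts)
  freq <- (counts + pseudocount) / (rowSums(counts) + 4 * pseudocount)
  lo <- log2(sweep(freq, 2L, background, "/"))
  colnames(freq) <- colnames(lo) <- c("A", "C", "G", "T")
  cons <- apply(lo, 1L, function(r) {
    if (max(r) - min(r) < 1e-12) "n" else c("A", "C", "G", "T")[which.max(r)]
  })
  structure(list(width = w, freq = freq, log_odds = lo,
                 max_score = sum(apply(lo, 1L, max)),
                 consensus = paste(cons, collapse = ""),
                 score_threshold_frac = score_threshold_frac,
                 name = name %||% "pwm"),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("PWM '%s': width %d, consensus %s, max score %.3f, threshold %.0f%% of max\n",
              x$name, x$width, x$consensus, x$max_score,
              100 * x$score_threshold_frac))
  invisible(x)
}

#' Read a JASPAR-style plain-text PFM
#'
#' Accepts the common JASPAR layouts: a `>` header line followed by four
#' rows, either `A [ 1 2 3 ]`-style or bare whitespace-separated counts in
#' A, C, G, T order.
#'
#' @param path Path to the PFM file.
#' @inheritParams pwm_from_counts
#' @return A `"pwm"` object.
#' @export
read_jaspar_pfm <- function(path, pseudocount = 0.5,
                            background = rep(0.25, 4),
                            score_threshold_frac = 0.8) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  name <- "pwm"
  if (startsWith(lines[1L], ">")) {
    name <- sub("^>\\s*", "", lines[1L])
    lines <- lines[-1L]
  }
  if (length(lines) < 4L) stop("PFM needs 4 base rows: ", path, call. = FALSE)
  rows <- lapply(lines[1:4], function(ln) {
    ln <- gsub("^[ACGTacgt]\\s*", "", trimws(ln))
    ln <- gsub("[][]", " ", ln)
    as.numeric(strsplit(trimws(ln), "\\s+")[[1L]])
  })
  if (length(unique(vapply(rows, length, 0L))) != 1L) {
    stop("ragged PFM rows: ", path, call. = FALSE)
  }
  counts <- t(do.call(rbind, rows))
  colnames(counts) <- c("A", "C", "G", "T")
  pwm_from_counts(counts, pseudocount, background, score_threshold_frac,
                  name = name)
}

#' The packaged ERE position weight matrix
#'
#' A synthetic matrix built from the palindromic estrogen-response-element
#' consensus `GGTCAnnnTGACC`: each consensus base has count 10, other bases
#' 0, and the three free center positions are all-zero rows (uniform after
#' the pseudocount). Shipped as a JASPAR-format text fixture
#' (`extdata/ere_consensus_synthetic.pfm`); any JASPAR matrix can be
#' substituted via [read_jaspar_pfm()].
#'
#' @inheritParams pwm_from_counts
#' @return A `"pwm"` object of width 13.
#' @export
ere_pwm <- function(score_threshold_frac = 0.8) {
  path <- system.file("extdata", "ere_consensus_synthetic.pfm",
                      package = "coregpeaks", mustWork = TRUE)
  read_jaspar_pfm(path, score_threshold_frac = score_threshold_frac)
}

#' Best PWM hit in a sequence
#'
#' Scores every offset on the forward strand and on the reverse complement;
#' any window containing `N` scores `-Inf`. Ties are resolved to the
#' leftmost position (in forward-strand coordinates), forward strand first.
#'
#' @param seq DNA string over `{A,C,G,T,N}`.
#' @param pwm A `"pwm"` object.
#' @return List with `score` (best log2-odds score; `-Inf` when no window
#'   is scorable or the sequence is shorter than the motif), `start`
#'   (0-based offset of the best window on the forward strand, `NA` if
#'   none) and `strand` (`"+"`, `"-"`, or `NA`).
#' @export
scan_pwm <- function(seq, pwm) {
  stopifnot(inherits(pwm, "pwm"))
  w <- pwm$width
  L <- nchar(seq)
  if (L < w) return(list(score = -Inf, start = NA_integer_,
                         strand = NA_character_))
  score_strand <- function(s) {
    code <- dna_codes(s)
    noff <- L - w + 1L
    idx <- outer(seq_len(noff) - 1L, seq_len(w), "+")  # 1-based codes index
    m <- matrix(code[idx], nrow = noff)
    lin <- (m - 1L) * w + matrix(rep(seq_len(w), each = noff), nrow = noff)
    v <- matrix(pwm$log_odds[lin], nrow = noff)
    sc <- rowSums(v)
    sc[is.na(sc)] <- -Inf
    sc
  }
  fwd <- score_strand(seq)
  rev <- score_strand(revcomp_chr(seq))
  bf <- max(fwd); br <- max(rev)
  if (bf == -Inf && br == -Inf) {
    return(list(score = -Inf, start = NA_integer_, strand = NA_character_))
  }
  fpos <- which.max(fwd) - 1L                      # leftmost forward max
  rpos <- L - w - (max(which(rev == br)) - 1L)     # leftmost (fwd coords) reverse max
  if (bf > br || (bf == br && fpos <= rpos)) {
    list(score = bf, start = fpos, strand = "+")
  } else {
    list(score = br, start = rpos, strand = "-")
  }
}

#' Does a peak contain the motif near its summit?
#'
#' @param peak Single-row peak data frame.
#' @param genome Named character vector from [read_fasta()].
#' @param pwm A `"pwm"` object.
#' @param flank Half-width of the summit window scanned (default 300 bp).
#' @return `TRUE` iff the best hit in the window reaches
#'   `score_threshold_frac * max_score`.
#' @export
contains_motif <- function(peak, genome, pwm, flank = 300L) {
  win <- extract_window(genome, peak$chrom, peak$summit, flank)
  hit <- scan_pwm(win, pwm)
  hit$score >= pwm$score_threshold_frac * pwm$max_score
}

#' ERE-containment ratio of a peak set
#'
#' The per-set evaluation statistic: the fraction of peaks whose +/- 300 bp
#' summit window contains a motif hit. Kept at full precision; round only
#' at the presentation layer (see [containment_ratio()]).
#'
#' @param peaks Peak `data.frame` (may be empty).
#' @param genome Named character vector from [read_fasta()].
#' @param pwm A `"pwm"` object (default [ere_pwm()]).
#' @param flank Summit window half-width (default 300 bp).
#' @return List with `n_total`, `n_with_motif`, `ratio` (`NaN` when the set
#'   is empty) and `has_motif` (the per-peak logical vector, named by id).
#' @export
ere_ratio <- function(peaks, genome, pwm = ere_pwm(), flank = 300L) {
  validate_peaks(peaks)
  n <- nrow(peaks)
  if (n == 0L) {
    return(list(n_total = 0L, n_with_motif = 0L, ratio = NaN,
                has_motif = stats::setNames(logical(0), character(0))))
  }
  has <- vapply(seq_len(n), function(i) {
    contains_motif(peaks[i, , drop = FALSE], genome, pwm, flank)
  }, NA)
  names(has) <- peaks$id
  list(n_total = n, n_with_motif = sum(has), ratio = sum(has) / n,
       has_motif = has)
}

#' Containment ratio from printed counts
#'
#' The report-layer arithmetic used for containment tables: the
#' full-precision ratio `n_with_motif / n_total` and its 2-decimal rendering
#' (the precision used in published summaries).
#'
#' @param n_with_motif,n_total Non-negative counts.
#' @return List with `ratio` (full precision, `NaN` if `n_total` is 0) and
#'   `ratio_2dp`.
#' @export
containment_ratio <- function(n_with_motif, n_total) {
  r <- if (n_total > 0) n_with_motif / n_total else NaN
  list(ratio = r, ratio_2dp = round2(r))
}
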