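# io_formats: on-disk formats with strict coordinate conventions.
#
# BED-family files are already 0-based half-open, so coordinates are taken
# verbatim. Summits are converted to ABSOLUTE 0-based positions on ingest,
# whatever the dialect encodes.

#' Read a peak-call file
#'
#' Parses the output of an upstream peak caller into the canonical peak
#' data frame. Two dialects are supported:
#'
#' * `"bed6_summit"`: BED6 (`chrom start end name score strand`) plus an
#'   optional 7th column holding the *absolute* 0-based summit position.
#'   Without a 7th column (or with `-1`) the summit defaults to the interval
#'   midpoint `floor((start + end) / 2)`.
#' * `"narrowPeak"`: ENCODE narrowPeak; column 10 is the summit offset
#'   relative to `start` and is converted to an absolute position (`-1`
#'   means no summit, again the midpoint). The peak score is taken from
#'   column 8 (-log10 p).
#'
#' @param path Path to the peak file (TSV/whitespace separated, `#` comments
#'   ignored).
#' @param source_label Label recorded in the `source` column (typically the
#'   caller name).
#' @param dialect `"bed6_summit"` or `"narrowPeak"`.
#' @return A peak `data.frame` (see [new_peaks()]).
#' @seealso [union_peaks()] for pooling several callers' files.
#' @export
read_peaks <- function(path, source_label = "caller",
                       dialect = c("bed6_summit", "narrowPeak")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  keep <- which(nzchar(trimws(lines)) & !startsWith(trimws(lines), "#"))
  need <- if (dialect == "narrowPeak") 10L else 6L
  out <- vector("list", length(keep))
  for (k in seq_along(keep)) {
    ln <- keep[k]
    f <- strsplit(trimws(lines[ln]), "[ \t]+")[[1L]]
    if (length(f) < need) {
      stop(sprintf("%s line %d: expected >= %d columns for dialect '%s', got %d",
                   path, ln, need, dialect, length(f)), call. = FALSE)
    }
    start <- suppressWarnings(as.integer(f[2L]))
    end <- suppressWarnings(as.integer(f[3L]))
    if (is.na(start) || is.na(end)) {
      stop(sprintf("%s line %d: non-numeric coordinates", path, ln),
           call. = FALSE)
    }
    if (start < 0L || start >= end) {
      stop(sprintf("%s line %d: invalid interval %d-%d (need 0 <= start < end)",
                   path, ln, start, end), call. = FALSE)
    }
    if (dialect == "narrowPeak") {
      score <- suppressWarnings(as.numeric(f[8L]))
      off <- suppressWarnings(as.integer(f[10L]))
      summit <- if (is.na(off) || off < 0L) (start + end) %/% 2L else start + off
    } else {
      score <- suppressWarnings(as.numeric(f[5L]))
      summit <- if (length(f) >= 7L) suppressWarnings(as.integer(f[7L])) else NA_integer_
      if (is.na(summit) || summit < 0L) summit <- (start + end) %/% 2L
    }
    if (is.na(score)) score <- 0
    if (summit < start || summit >= end) {
      stop(sprintf("%s line %d: summit %d outside [%d, %d)",
                   path, ln, summit, start, end), call. = FALSE)
    }
    out[[k]] <- list(chrom = f[1L], start = start, end = end,
                     summit = summit, score = score, name = f[4L])
  }
  if (!length(out)) {
    return(new_peaks(character(), integer(), integer(), source = source_label))
  }
  new_peaks(
    chrom = vapply(out, `[[`, "", "chrom"),
    start = vapply(out, `[[`, 0L, "start"),
    end = vapply(out, `[[`, 0L, "end"),
    summit = vapply(out, `[[`, 0L, "summit"),
    score = vapply(out, `[[`, 0, "score"),
    id = make.unique(vapply(out, `[[`, "", "name"), sep = "_"),
    source = source_label
  )
}

#' Read a genome FASTA
#'
#' Loads a FASTA file into a named character vector of upper-case
#' chromosome sequences over `{A,C,G,T,N}`; any other IUPAC letter is
#' mapped to `N`.
#'
#' @param path Path to an (uncompressed or gzipped) FASTA file.
#' @return Named character vector, one element per chromosome.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) == 0L) stop("empty FASTA: ", path, call. = FALSE)
  nm <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(nm)) {
    stop("duplicate chromosome name in FASTA: ", nm[duplicated(nm)][1L],
         call. = FALSE)
  }
  seqs <- toupper(as.character(ss))
  seqs <- gsub("[^ACGTN]", "N", seqs)
  names(seqs) <- nm
  seqs
}

#' Chromosome lengths of a genome
#'
#' @param genome Named character vector as returned by [read_fasta()].
#' @return Named integer vector of sequence lengths (bp).
#' @export
genome_lengths <- function(genome) {
  stats::setNames(nchar(genome), names(genome))
}

#' Read a nucleosome-occupancy bedGraph
#'
#' Expands a bedGraph of per-base nucleosome-occupancy probabilities into
#' dense per-chromosome numeric vectors. Positions not covered by any
#' interval default to 0 (no occupancy evidence).
#'
#' @param path Path to a bedGraph file (`chrom start end value`, 0-based
#'   half-open). Intervals must not overlap and values must lie in `[0, 1]`.
#' @param seqlengths Optional named integer vector of chromosome lengths;
#'   when given, each dense vector has exactly that length.
#' @return Named list of numeric vectors in `[0, 1]` (class
#'   `"occupancy_track"`).
#' @export
read_occupancy <- function(path, seqlengths = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  info <- file.info(path)
  tab <- if (info$size == 0) {
    data.frame(chrom = character(), start = integer(), end = integer(),
               value = numeric())
  } else {
    utils::read.table(path, header = FALSE, sep = "", comment.char = "#",
                      col.names = c("chrom", "start", "end", "value"),
                      colClasses = c("character", "integer", "integer",
                                     "numeric"))
  }
  if (nrow(tab) && (any(tab$value < 0) || any(tab$value > 1))) {
    bad <- which(tab$value < 0 | tab$value > 1)[1L]
    stop(sprintf("occupancy value %g outside [0, 1] (row %d)",
                 tab$value[bad], bad), call. = FALSE)
  }
  if (nrow(tab) && any(tab$start < 0 | tab$start >= tab$end)) {
    stop("invalid bedGraph interval (need 0 <= start < end)", call. = FALSE)
  }
  track <- list()
  chroms <- unique(c(tab$chrom, names(seqlengths)))
  for (ch in chroms) {
    sub <- tab[tab$chrom == ch, , drop = FALSE]
    len <- if (!is.null(seqlengths) && ch %in% names(seqlengths)) {
      as.integer(seqlengths[[ch]])
    } else if (nrow(sub)) max(sub$end) else 0L
    v <- numeric(len)
    if (nrow(sub)) {
      sub <- sub[order(sub$start), , drop = FALSE]
      if (nrow(sub) > 1L && any(sub$start[-1L] < sub$end[-nrow(sub)])) {
        stop("overlapping bedGraph intervals on ", ch, call. = FALSE)
      }
      if (any(sub$end > len)) {
        stop("bedGraph interval beyond chromosome end on ", ch, call. = FALSE)
      }
      for (i in seq_len(nrow(sub))) {
        v[(sub$start[i] + 1L):sub$end[i]] <- sub$value[i]
      }
    }
    track[[ch]] <- v
  }
  structure(track, class = "occupancy_track")
}

#' Write classified peaks to TSV
#'
#' One row per peak: `id, chrom, start, end, summit, label, posterior`,
#' with a header. Round-trips through [read_classified_peaks()] without
#' loss of label or posterior.
#'
#' @param peaks Peak `data.frame`.
#' @param labels Character vector in `{"positive", "negative"}`, one per peak.
#' @param posteriors Numeric vector in `[0, 1]`, one per peak.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_classified_peaks <- function(peaks, labels, posteriors, path) {
  validate_peaks(peaks)
  if (length(labels) != nrow(peaks) || length(posteriors) != nrow(peaks)) {
    stop(sprintf("length mismatch: %d peaks, %d labels, %d posteriors",
                 nrow(peaks), length(labels), length(posteriors)),
         call. = FALSE)
  }
  if (length(labels) && !all(labels %in% c("positive", "negative"))) {
    stop("labels must be 'positive' or 'negative'", call. = FALSE)
  }
  df <- data.frame(
    id = peaks$id, chrom = peaks$chrom, start = peaks$start, end = peaks$end,
    summit = peaks$summit, label = as.character(labels),
    posterior = as.numeric(posteriors), stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read classified peaks from TSV
#'
#' @param path A file written by [write_classified_peaks()].
#' @return A `data.frame` with columns `id, chrom, start, end, summit,
#'   label, posterior`.
#' @export
read_classified_peaks <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    colClasses = c("character", "character", "integer",
                                   "integer", "integer", "character",
                                   "numeric"))
}

#' Write a 67-column feature matrix to TSV
#'
#' Columns are named `tri_AAA ... tri_TTT, occ, er_overlap, sensitive_gene`
#' preceded by the peak `id`; see [build_feature_matrix()] for the layout.
#'
#' @param x Binary feature matrix with row names (peak ids).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(x, path) {
  stopifnot(is.matrix(x), !is.null(rownames(x)))
  df <- data.frame(id = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a feature matrix written by [write_feature_matrix()]
#'
#' @param path Input TSV path.
#' @return Integer matrix with peak ids as row names.
#' @export
read_feature_matrix <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          colClasses = "character")
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df$id
  m
}

#' Read a gene annotation table
#'
#' @param path TSV with header and columns `gene_id, chrom, tss, strand`
#'   (TSS is 0-based bp).
#' @param sensitive_ids Optional character vector (or path to a one-id-per-
#'   line file) naming the co-regulator-sensitive genes.
#' @return `data.frame` with columns `gene_id, chrom, tss, strand,
#'   sensitive`.
#' @export
read_genes <- function(path, sensitive_ids = NULL) {
  g <- utils::read.table(path, header = TRUE, sep = "\t",
                         colClasses = c("character", "character", "integer",
                                        "character"))
  if (any(g$tss < 0L)) stop("negative TSS in gene table", call. = FALSE)
  if (is.character(sensitive_ids) && length(sensitive_ids) == 1L &&
      file.exists(sensitive_ids)) {
    sensitive_ids <- readLines(sensitive_ids)
    sensitive_ids <- sensitive_ids[nzchar(sensitive_ids)]
  }
  g$sensitive <- g$gene_id %in% (sensitive_ids %||% character())
  g
}
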