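# Fixture builders and independent brute-force oracles used across tests.

rand_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

toy_genome <- function(...) {
  seqs <- c(...)
  stopifnot(!is.null(names(seqs)))
  seqs
}

rand_peaks <- function(n, chroms = c("chr1", "chr2"), max_pos = 1000L,
                       max_width = 120L, source = "fuzz") {
  start <- sample.int(max_pos, n, replace = TRUE) - 1L
  width <- sample.int(max_width, n, replace = TRUE)
  summit <- start + vapply(width, function(w) sample.int(w, 1L) - 1L, 0L)
  new_peaks(chrom = sample(chroms, n, replace = TRUE),
            start = start, end = start + width, summit = summit,
            score = round(stats::runif(n, 0, 100), 3),
            id = sprintf("%s_%03d", source, seq_len(n)), source = source)
}

# --- union_peaks oracle: O(n^2) pairwise-overlap connected components ----
oracle_components <- function(all_peaks) {
  n <- nrow(all_peaks)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j &&
        all_peaks$chrom[i] == all_peaks$chrom[j] &&
        all_peaks$start[i] < all_peaks$end[j] &&
        all_peaks$start[j] < all_peaks$end[i]) {
      parent[find(i)] <- find(j)
    }
  }
  roots <- vapply(seq_len(n), find, 0L)
  split(seq_len(n), roots)
}

# partition of original peak keys implied by a candidate pool
pool_partition <- function(pool) {
  unname(lapply(pool$provenance, function(p) {
    sort(paste(p$source, p$id, sep = "/"))
  }))
}

# --- trigram oracle: sliding-window substring set ------------------------
oracle_trigrams <- function(seq) {
  out <- stats::setNames(integer(64), paste0("tri_", trigram_names()))
  L <- nchar(seq)
  if (L >= 3) {
    words <- substring(seq, 1:(L - 2), 3:L)
    words <- words[!grepl("N", words, fixed = TRUE)]
    out[paste0("tri_", unique(words))] <- 1L
  }
  out
}

# --- NB posterior oracle: direct product form (no logs) ------------------
oracle_nb_posterior <- function(model, x) {
  lik <- function(cl) {
    th <- model$theta[cl, ]
    model$prior[[cl]] * prod(th^x * (1 - th)^(1 - x))
  }
  lik("positive") / (lik("positive") + lik("negative"))
}

# --- PWM oracle: enumerate all windows on both strands -------------------
oracle_scan <- function(seq, pwm) {
  w <- pwm$width
  L <- nchar(seq)
  if (L < w) return(list(score = -Inf, start = NA_integer_,
                         strand = NA_character_))
  win_score <- function(s) {
    b <- strsplit(s, "")[[1L]]
    if (any(!b %in% c("A", "C", "G", "T"))) return(-Inf)
    sum(vapply(seq_len(w), function(i) pwm$log_odds[i, b[i]], 0))
  }
  best <- list(score = -Inf, start = NA_integer_, strand = NA_character_)
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else revcomp_string(seq)
    for (o in 0:(L - w)) {
      sc <- win_score(substr(s, o + 1, o + w))
      fstart <- if (strand == "+") o else L - w - o
      better <- sc > best$score ||
        (sc == best$score && !is.na(best$start) &&
           (fstart < best$start ||
              (fstart == best$start && strand == "+" && best$strand == "-")))
      if (is.infinite(sc) && sc < 0) better <- FALSE
      if (better) best <- list(score = sc, start = fstart, strand = strand)
    }
  }
  best
}

revcomp_string <- function(seq) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", seq), "")[[1L]]),
        collapse = "")
}

# --- k-means oracle: exhaustive best 2-partition (n <= 12) ---------------
oracle_best_partition_inertia <- function(x) {
  n <- nrow(x)
  stopifnot(n <= 12)
  best <- Inf
  for (mask in 1:(2^(n - 1) - 1)) {  # row 1 fixed in cluster A
    a <- c(TRUE, as.logical(bitwAnd(bitwShiftR(mask, 0:(n - 2)), 1L)))
    inertia <- 0
    for (grp in list(which(a), which(!a))) {
      cen <- apply(x[grp, , drop = FALSE], 2, stats::median)
      inertia <- inertia + sum(abs(sweep(x[grp, , drop = FALSE], 2, cen)))
    }
    best <- min(best, inertia)
  }
  best
}

# random binary feature matrix with ids
rand_features <- function(n, p = 8L, prefix = "x") {
  m <- matrix(rbinom(n * p, 1L, 0.5), nrow = n)
  rownames(m) <- sprintf("%s_%03d", prefix, seq_len(n))
  m
}

# small synthetic bundle shared by the slower tests (cached per session)
small_synth <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      dir <- file.path(tempdir(), "coregpeaks_small_synth")
      cfg <- synth_config(seed = 7L, chrom_length = 2e5, n_true_sites = 30L,
                          n_decoy_sites = 60L, n_labeled_pos = 10L,
                          n_negative_pool = 120L, n_background_genes = 60L)
      cache <<- generate_synthetic(cfg, dir)
    }
    cache
  }
})
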