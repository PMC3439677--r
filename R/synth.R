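# synthetic_data: a fully self-contained toy dataset with the statistical
# structure the classifier assumes.
#
# True sites carry the planted ERE consensus, elevated nucleosome
# occupancy, frequent primary-TF (ERalpha) overlap and frequent proximity
# to a sensitive gene; decoy sites carry all four signals at background
# rates. Three pseudo-callers re-report the sites with independent misses
# and jittered summits, so the candidate pool and every downstream stage
# can be exercised without any external data.

#' Configuration of the synthetic dataset generator
#'
#' Defaults define the study conditions used throughout the test-suite and
#' acceptance runs.
#'
#' @param seed Integer seed; the whole bundle is reproducible bit-exactly
#'   from it.
#' @param n_chroms Number of chromosomes (default 2).
#' @param chrom_length Length of each chromosome in bp (default 1,000,000 —
#'   large enough to hold the default 600 sites at the 2 kb minimum
#'   spacing).
#' @param n_true_sites,n_decoy_sites Numbers of functional / decoy sites
#'   (defaults 200 / 400).
#' @param p_plant_motif_true,p_plant_motif_decoy Probability the ERE
#'   consensus is planted at the site summit (defaults 0.9 / 0.1).
#' @param p_er_overlap_true,p_er_overlap_decoy Probability an ERalpha peak
#'   overlaps the site (defaults 0.8 / 0.1).
#' @param occ_mean_true,occ_mean_decoy Nucleosome-occupancy level written
#'   over the site (defaults 0.85 / 0.5); each site's constant level gets
#'   uniform noise of +/- 0.05.
#' @param p_sensitive_gene_true,p_sensitive_gene_decoy Probability the
#'   site's nearest gene is co-regulator-sensitive (defaults 0.6 / 0.05).
#' @param caller_fnr Per-pseudo-caller miss rate (default 0.2).
#' @param summit_jitter_sd Gaussian sd (bp) of per-caller summit jitter,
#'   truncated to stay inside the peak (default 20).
#' @param n_labeled_pos Number of validated positive training sites
#'   (default 18).
#' @param n_negative_pool Size of the control (IgG stand-in) negative pool
#'   (default 500).
#' @param n_background_genes Non-sensitive genes placed uniformly across
#'   the genome, emulating a genome-wide annotation (default 300).
#' @param peak_halfwidth Half-width (bp) of each site's reported peak
#'   interval (default 100).
#' @param min_site_spacing Minimum distance between site summits (default
#'   2000 bp, so pooled peaks never merge across sites).
#' @return A list of class `"synth_config"`.
#' @export
synth_config <- function(seed = 1L, n_chroms = 2L, chrom_length = 1e6,
                         n_true_sites = 200L, n_decoy_sites = 400L,
                         p_plant_motif_true = 0.9, p_plant_motif_decoy = 0.1,
                         p_er_overlap_true = 0.8, p_er_overlap_decoy = 0.1,
                         occ_mean_true = 0.85, occ_mean_decoy = 0.5,
                         p_sensitive_gene_true = 0.6,
                         p_sensitive_gene_decoy = 0.05,
                         caller_fnr = 0.2, summit_jitter_sd = 20,
                         n_labeled_pos = 18L, n_negative_pool = 500L,
                         n_background_genes = 300L, peak_halfwidth = 100L,
                         min_site_spacing = 2000L) {
  cfg <- list(seed = as.integer(seed), n_chroms = as.integer(n_chroms),
              chrom_length = as.integer(chrom_length),
              n_true_sites = as.integer(n_true_sites),
              n_decoy_sites = as.integer(n_decoy_sites),
              p_plant_motif_true = p_plant_motif_true,
              p_plant_motif_decoy = p_plant_motif_decoy,
              p_er_overlap_true = p_er_overlap_true,
              p_er_overlap_decoy = p_er_overlap_decoy,
              occ_mean_true = occ_mean_true, occ_mean_decoy = occ_mean_decoy,
              p_sensitive_gene_true = p_sensitive_gene_true,
              p_sensitive_gene_decoy = p_sensitive_gene_decoy,
              caller_fnr = caller_fnr, summit_jitter_sd = summit_jitter_sd,
              n_labeled_pos = as.integer(n_labeled_pos),
              n_negative_pool = as.integer(n_negative_pool),
              n_background_genes = as.integer(n_background_genes),
              peak_halfwidth = as.integer(peak_halfwidth),
              min_site_spacing = as.integer(min_site_spacing))
  probs <- cfg[grep("^p_|caller_fnr|occ_mean", names(cfg))]
  stopifnot(all(unlist(probs) >= 0), all(unlist(probs) <= 1))
  if (cfg$n_labeled_pos > cfg$n_true_sites) {
    stop("n_labeled_pos cannot exceed n_true_sites", call. = FALSE)
  }
  structure(cfg, class = "synth_config")
}

# Positions >= gap apart within [margin, L - margin], uniform given spacing.
place_spaced <- function(k, L, gap, margin) {
  slack <- L - 2L * margin - (k - 1L) * gap
  if (k > 0L && slack < k) {
    stop(sprintf("genome too short: cannot place %d sites %d bp apart on %d bp",
                 k, gap, L), call. = FALSE)
  }
  if (k == 0L) return(integer(0))
  sort(sample.int(slack, k)) + (seq_len(k) - 1L) * gap + margin
}

#' Generate the synthetic dataset bundle
#'
#' Writes a genome FASTA, a ground-truth site table, three pseudo-caller
#' peak files, an ERalpha peak file, a nucleosome-occupancy bedGraph, a
#' gene table with sensitive-gene list, a labeled positive peak file and a
#' control negative-pool peak file — everything the pipeline ingests —
#' reproducibly from `config$seed`.
#'
#' @param config A [synth_config()].
#' @param outdir Output directory (created if needed).
#' @return Invisibly, a list with `paths` (named file paths), `truth` (the
#'   site table: `site_id, chrom, start, end, summit, is_true,
#'   motif_planted, er_overlap, occ_value, gene_id, gene_sensitive`),
#'   `config`, and `feature_gaps` (empirical true-minus-decoy probability
#'   gaps of the occupancy, ERalpha-overlap and sensitive-gene signals,
#'   checked at generation time).
#' @export
generate_synthetic <- function(config = synth_config(), outdir) {
  stopifnot(inherits(config, "synth_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  cfg <- config
  chroms <- paste0("chr", seq_len(cfg$n_chroms))
  motif <- "GGTCANNNTGACC"  # free positions drawn at random when planted
  mw <- nchar(motif)

  with_seed(cfg$seed, {
    # --- genome ---------------------------------------------------------
    genome <- vapply(chroms, function(ch) {
      paste(sample(c("A", "C", "G", "T"), cfg$chrom_length, replace = TRUE),
            collapse = "")
    }, "")

    # --- sites ----------------------------------------------------------
    n_sites <- cfg$n_true_sites + cfg$n_decoy_sites
    per_chrom <- diff(round(seq(0, n_sites, length.out = cfg$n_chroms + 1L)))
    # keep sites clear of the edges: sequence window (300), occupancy
    # window (200) and the +/- 1 kb gene TSS offset must stay on-chromosome
    margin <- cfg$peak_halfwidth + 1000L
    summit <- integer(0); site_chrom <- character(0)
    for (i in seq_along(chroms)) {
      s <- place_spaced(per_chrom[i], cfg$chrom_length,
                        cfg$min_site_spacing, margin)
      summit <- c(summit, s)
      site_chrom <- c(site_chrom, rep(chroms[i], per_chrom[i]))
    }
    is_true <- rep(FALSE, n_sites)
    is_true[sample.int(n_sites, cfg$n_true_sites)] <- TRUE
    truth <- data.frame(
      site_id = sprintf("site_%04d", seq_len(n_sites)),
      chrom = site_chrom,
      start = summit - cfg$peak_halfwidth,
      end = summit + cfg$peak_halfwidth,
      summit = summit,
      is_true = is_true,
      stringsAsFactors = FALSE
    )

    # --- planted motifs -------------------------------------------------
    p_plant <- ifelse(is_true, cfg$p_plant_motif_true, cfg$p_plant_motif_decoy)
    truth$motif_planted <- stats::runif(n_sites) < p_plant
    half <- mw %/% 2L
    for (i in which(truth$motif_planted)) {
      inst <- strsplit(motif, "")[[1L]]
      inst[inst == "N"] <- sample(c("A", "C", "G", "T"), sum(inst == "N"),
                                  replace = TRUE)
      at <- truth$summit[i] - half  # 0-based start of the 13-mer
      substr(genome[[truth$chrom[i]]], at + 1L, at + mw) <-
        paste(inst, collapse = "")
    }

    # --- pseudo-caller peak files ---------------------------------------
    callers <- c("callerA", "callerB", "callerC")
    caller_peaks <- list()
    for (cal in callers) {
      keep <- stats::runif(n_sites) >= cfg$caller_fnr
      jit <- round(stats::rnorm(n_sites, 0, cfg$summit_jitter_sd))
      jit <- pmax(pmin(jit, cfg$peak_halfwidth - 1L), -cfg$peak_halfwidth)
      sc <- round(stats::runif(n_sites, 1, 100), 2)
      caller_peaks[[cal]] <- new_peaks(
        chrom = truth$chrom[keep], start = truth$start[keep],
        end = truth$end[keep], summit = (truth$summit + jit)[keep],
        score = sc[keep], id = paste0(cal, "_", truth$site_id[keep]),
        source = cal
      )
    }

    # --- primary-TF (ERalpha) peaks -------------------------------------
    p_er <- ifelse(is_true, cfg$p_er_overlap_true, cfg$p_er_overlap_decoy)
    truth$er_overlap <- stats::runif(n_sites) < p_er
    er_idx <- which(truth$er_overlap)
    shift <- sample(-50:50, length(er_idx), replace = TRUE)
    er_peaks <- new_peaks(
      chrom = truth$chrom[er_idx],
      start = truth$summit[er_idx] - 150L + shift,
      end = truth$summit[er_idx] + 150L + shift,
      summit = truth$summit[er_idx] + shift,
      score = round(stats::runif(length(er_idx), 1, 100), 2),
      id = paste0("er_", truth$site_id[er_idx]), source = "er"
    )

    # --- occupancy track ------------------------------------------------
    # constant level over summit +/- 200 bp so the +/- 50 bp window of a
    # jittered summit stays inside the elevated region
    occ_level <- ifelse(is_true, cfg$occ_mean_true, cfg$occ_mean_decoy) +
      stats::runif(n_sites, -0.05, 0.05)
    truth$occ_value <- pmin(pmax(occ_level, 0), 1)
    occ <- data.frame(chrom = truth$chrom,
                      start = truth$summit - 200L,
                      end = truth$summit + 201L,
                      value = round(truth$occ_value, 6))
    occ <- occ[order(occ$chrom, occ$start), ]

    # --- genes ----------------------------------------------------------
    gene_off <- sample(c(-(1000:1), 1:1000), n_sites, replace = TRUE)
    p_sens <- ifelse(is_true, cfg$p_sensitive_gene_true,
                     cfg$p_sensitive_gene_decoy)
    truth$gene_id <- sprintf("gene_%04d", seq_len(n_sites))
    truth$gene_sensitive <- stats::runif(n_sites) < p_sens
    bg_chrom <- sample(chroms, cfg$n_background_genes, replace = TRUE)
    bg_tss <- vapply(bg_chrom, function(ch) {
      sample.int(cfg$chrom_length, 1L) - 1L
    }, 0L)
    genes <- data.frame(
      gene_id = c(truth$gene_id,
                  sprintf("bg_gene_%04d", seq_len(cfg$n_background_genes))),
      chrom = c(truth$chrom, bg_chrom),
      tss = c(truth$summit + gene_off, bg_tss),
      strand = sample(c("+", "-"), n_sites + cfg$n_background_genes,
                      replace = TRUE),
      stringsAsFactors = FALSE
    )
    sensitive_ids <- truth$gene_id[truth$gene_sensitive]

    # --- labeled training data ------------------------------------------
    pos_idx <- sample(which(is_true), cfg$n_labeled_pos)
    labeled_pos <- new_peaks(
      chrom = truth$chrom[pos_idx], start = truth$start[pos_idx],
      end = truth$end[pos_idx], summit = truth$summit[pos_idx],
      score = rep(1, length(pos_idx)),
      id = paste0("pos_", truth$site_id[pos_idx]), source = "validated"
    )
    # control negatives: intervals >= min spacing away from every site
    neg_summit <- integer(0); neg_chrom <- character(0)
    tries <- 0L
    while (length(neg_summit) < cfg$n_negative_pool) {
      tries <- tries + 1L
      if (tries > 50L * cfg$n_negative_pool) {
        stop("could not place the negative pool away from sites",
             call. = FALSE)
      }
      ch <- sample(chroms, 1L)
      s <- sample.int(cfg$chrom_length - 2L * margin, 1L) + margin
      near <- truth$summit[truth$chrom == ch]
      if (all(abs(near - s) >= cfg$min_site_spacing)) {
        neg_summit <- c(neg_summit, s); neg_chrom <- c(neg_chrom, ch)
      }
    }
    negatives <- new_peaks(
      chrom = neg_chrom, start = neg_summit - cfg$peak_halfwidth,
      end = neg_summit + cfg$peak_halfwidth, summit = neg_summit,
      score = rep(1, cfg$n_negative_pool),
      id = sprintf("igg_%04d", seq_len(cfg$n_negative_pool)), source = "igg"
    )

    # --- write bundle ---------------------------------------------------
    paths <- list(
      genome = file.path(outdir, "genome.fa"),
      truth = file.path(outdir, "truth.tsv"),
      occupancy = file.path(outdir, "occupancy.bedGraph"),
      er_peaks = file.path(outdir, "er_peaks.bed"),
      genes = file.path(outdir, "genes.tsv"),
      sensitive_genes = file.path(outdir, "sensitive_genes.txt"),
      labeled_pos = file.path(outdir, "labeled_positives.bed"),
      negative_pool = file.path(outdir, "negative_pool.bed")
    )
    for (cal in callers) {
      paths[[cal]] <- file.path(outdir, paste0(cal, "_peaks.bed"))
    }
    write_fasta_chr(genome, paths$genome)
    utils::write.table(truth, paths$truth, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(occ, paths$occupancy, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    write_bed6_summit(er_peaks, paths$er_peaks)
    utils::write.table(genes, paths$genes, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    writeLines(sensitive_ids, paths$sensitive_genes)
    write_bed6_summit(labeled_pos, paths$labeled_pos)
    write_bed6_summit(negatives, paths$negative_pool)
    for (cal in callers) write_bed6_summit(caller_peaks[[cal]], paths[[cal]])

    gaps <- c(
      occ = mean(truth$occ_value[is_true] > 0.75) -
        mean(truth$occ_value[!is_true] > 0.75),
      er_overlap = mean(truth$er_overlap[is_true]) -
        mean(truth$er_overlap[!is_true]),
      sensitive_gene = mean(truth$gene_sensitive[is_true]) -
        mean(truth$gene_sensitive[!is_true])
    )
    invisible(list(paths = paths, truth = truth, config = cfg,
                   feature_gaps = gaps))
  })
}

# Minimal deterministic FASTA writer (60-column wrap).
write_fasta_chr <- function(genome, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(genome)) {
    writeLines(paste0(">", nm), con)
    s <- genome[[nm]]
    starts <- seq(1L, nchar(s), by = 60L)
    writeLines(substring(s, starts, pmin(starts + 59L, nchar(s))), con)
  }
  invisible(path)
}

#' Write peaks in the bed6+summit dialect
#'
#' BED6 plus a 7th column holding the absolute 0-based summit, the dialect
#' [read_peaks()] ingests.
#'
#' @param peaks Peak `data.frame`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed6_summit <- function(peaks, path) {
  validate_peaks(peaks)
  df <- data.frame(peaks$chrom, peaks$start, peaks$end, peaks$id,
                   peaks$score, ".", peaks$summit)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Confusion-matrix metrics against generative truth
#'
#' Compares predicted labels for sites against the generator's true/decoy
#' flags (distinct from cross-validation metrics, which only ever see the
#' labeled subset).
#'
#' @param pred `data.frame` with columns `id` (site ids, a subset of
#'   `truth$site_id`) and `label` (`"positive"`/`"negative"`).
#' @param truth Truth table from [generate_synthetic()].
#' @return List with `precision` (`NaN` when nothing is called positive),
#'   `recall`, `accuracy` and the 2 x 2 `confusion` matrix.
#' @export
ground_truth_metrics <- function(pred, truth) {
  stopifnot(is.data.frame(pred), all(c("id", "label") %in% names(pred)))
  unknown <- setdiff(pred$id, truth$site_id)
  if (length(unknown)) {
    stop("unknown site id(s): ", paste(utils::head(unknown, 3), collapse = ", "),
         call. = FALSE)
  }
  actual <- truth$is_true[match(pred$id, truth$site_id)]
  called <- pred$label == "positive"
  tp <- sum(called & actual); fp <- sum(called & !actual)
  fn <- sum(!called & actual); tn <- sum(!called & !actual)
  list(precision = if (tp + fp > 0) tp / (tp + fp) else NaN,
       recall = if (tp + fn > 0) tp / (tp + fn) else NaN,
       accuracy = (tp + tn) / nrow(pred),
       confusion = matrix(c(tp, fn, fp, tn), 2L, 2L,
                          dimnames = list(predicted = c("positive", "negative"),
                                          truth = c("true", "decoy"))))
}
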