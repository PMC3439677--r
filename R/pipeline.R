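# cli_pipeline: end-to-end orchestration.
#
# pool -> featurize -> train / self-train / cluster -> predict ->
# motif-eval -> report. Ratios are stored at full precision and rendered at
# 2 decimals only in the human-readable reports.

#' Pipeline run configuration
#'
#' @param peak_files Named character vector of caller peak files (names =
#'   caller labels).
#' @param dialects Dialect per peak file (recycled; see [read_peaks()]).
#' @param genome_file Genome FASTA.
#' @param occupancy_file Nucleosome-occupancy bedGraph (or `NULL`).
#' @param er_peaks_file Primary-TF peak file (or `NULL`).
#' @param genes_file Gene table TSV (or `NULL`).
#' @param sensitive_genes_file One sensitive gene id per line (or `NULL`).
#' @param labeled_pos_file Validated positive peaks (bed6+summit).
#' @param negative_pool_file Control negative peaks (bed6+summit).
#' @param truth_file Optional generator truth table; when present the
#'   report adds generative-truth metrics.
#' @param features A [feature_config()].
#' @param threshold NB posterior threshold (default 0.8).
#' @param ratio Negatives per positive in training (default 2, the 1:2
#'   design).
#' @param selftrain_m,selftrain_max_iter Self-training promotions per
#'   iteration and iteration cap (defaults 5 / 75); set `selftrain_m = 0`
#'   to skip self-training.
#' @param kmeans_restarts Random restarts of the k-means baseline
#'   (default 20).
#' @param cv_folds Cross-validation folds (default 9).
#' @param seed Master seed; stage seeds are derived from it.
#' @param pwm The evaluation motif, a `"pwm"` (default [ere_pwm()]).
#' @return A list of class `"run_config"`.
#' @export
run_config <- function(peak_files, genome_file, labeled_pos_file,
                       negative_pool_file, dialects = "bed6_summit",
                       occupancy_file = NULL, er_peaks_file = NULL,
                       genes_file = NULL, sensitive_genes_file = NULL,
                       truth_file = NULL, features = feature_config(),
                       threshold = 0.8, ratio = 2L, selftrain_m = 5L,
                       selftrain_max_iter = 75L, kmeans_restarts = 20L,
                       cv_folds = 9L, seed = 1L, pwm = NULL) {
  stopifnot(length(peak_files) >= 1L, !is.null(names(peak_files)))
  structure(list(peak_files = peak_files,
                 dialects = rep_len(dialects, length(peak_files)),
                 genome_file = genome_file, occupancy_file = occupancy_file,
                 er_peaks_file = er_peaks_file, genes_file = genes_file,
                 sensitive_genes_file = sensitive_genes_file,
                 labeled_pos_file = labeled_pos_file,
                 negative_pool_file = negative_pool_file,
                 truth_file = truth_file, feature_config = features,
                 threshold = threshold, ratio = as.integer(ratio),
                 selftrain_m = as.integer(selftrain_m),
                 selftrain_max_iter = as.integer(selftrain_max_iter),
                 kmeans_restarts = as.integer(kmeans_restarts),
                 cv_folds = as.integer(cv_folds), seed = as.integer(seed),
                 pwm = pwm),
            class = "run_config")
}

#' Configuration pointing at a [generate_synthetic()] bundle
#'
#' @param paths The `paths` element returned by [generate_synthetic()].
#' @param ... Passed on to [run_config()].
#' @return A `"run_config"`.
#' @export
run_config_from_synth <- function(paths, ...) {
  run_config(
    peak_files = c(callerA = paths$callerA, callerB = paths$callerB,
                   callerC = paths$callerC),
    genome_file = paths$genome, occupancy_file = paths$occupancy,
    er_peaks_file = paths$er_peaks, genes_file = paths$genes,
    sensitive_genes_file = paths$sensitive_genes,
    labeled_pos_file = paths$labeled_pos,
    negative_pool_file = paths$negative_pool,
    truth_file = paths$truth, ...
  )
}

derive_seed <- function(seed, k) (as.integer(seed) * 131L + k) %% 2147483647L

#' Run the full classification pipeline
#'
#' Reads all inputs, pools the caller peak sets into merged candidates,
#' builds the 67-column feature matrix, trains the supervised NB classifier
#' at the configured positive:negative ratio, classifies every candidate,
#' runs the k-means baseline and (optionally) self-training, evaluates each
#' predicted peak set by ERE-motif containment, and writes the report
#' bundle.
#'
#' @param config A [run_config()].
#' @param outdir Output directory for the report bundle.
#' @return Invisibly, a list with elements `pool`, `features`, `model`,
#'   `labels` (per-candidate calls + posteriors), `kmeans`, `selftrain`,
#'   `containment` (Table-2-style: per method/peak-set `n_peaks`,
#'   `n_with_motif`, `ratio`), `gene_mapping` (Table-3-style: `n_peaks`,
#'   `n_genes_mapped`, `n_sensitive_intersect`), `cv` (cross-validation
#'   metrics), `selftrain_series` (per-iteration evaluation), and
#'   `truth_metrics` (when a truth table was supplied). Written files:
#'   `classified_peaks.tsv`, `feature_matrix.tsv`, `nb_model.json`,
#'   `containment_report.tsv`, `gene_mapping_report.tsv`, `cv_report.tsv`,
#'   `selftrain_series.tsv`, `manifest.json`.
#' @export
run_pipeline <- function(config, outdir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  # ---- load inputs -----------------------------------------------------
  inputs <- stage("load", {
    genome <- read_fasta(config$genome_file)
    list(
      genome = genome,
      track = if (!is.null(config$occupancy_file)) {
        read_occupancy(config$occupancy_file, genome_lengths(genome))
      },
      er_peaks = if (!is.null(config$er_peaks_file)) {
        read_peaks(config$er_peaks_file, "er", "bed6_summit")
      },
      genes = if (!is.null(config$genes_file)) {
        read_genes(config$genes_file, config$sensitive_genes_file)
      },
      caller_peaks = lapply(seq_along(config$peak_files), function(i) {
        read_peaks(config$peak_files[[i]], names(config$peak_files)[i],
                   config$dialects[i])
      }),
      labeled_pos = read_peaks(config$labeled_pos_file, "validated",
                               "bed6_summit"),
      negatives = read_peaks(config$negative_pool_file, "igg", "bed6_summit"),
      pwm = config$pwm %||% ere_pwm()
    )
  })

  # ---- pool + features -------------------------------------------------
  pool <- stage("pool", union_peaks(inputs$caller_peaks))
  featurize <- function(p) {
    build_feature_matrix(p, inputs$genome, inputs$track, inputs$er_peaks,
                         inputs$genes, config$feature_config)
  }
  feats <- stage("featurize", featurize(pool$peaks))
  pos_x <- stage("featurize", featurize(inputs$labeled_pos))
  neg_x <- stage("featurize", featurize(inputs$negatives))
  write_feature_matrix(feats, file.path(outdir, "feature_matrix.tsv"))

  # ---- supervised NB ---------------------------------------------------
  train <- stage("train", sample_training(pos_x, neg_x, config$ratio,
                                          seed = derive_seed(config$seed, 1L)))
  model <- stage("train", nb_fit(train$x, train$y,
                                 threshold = config$threshold))
  write_nb_model(model, file.path(outdir, "nb_model.json"))
  post <- predict(model, feats, type = "posterior")
  label <- ifelse(post >= config$threshold, "positive", "negative")
  write_classified_peaks(pool$peaks, label, post,
                         file.path(outdir, "classified_peaks.tsv"))

  # ---- k-means baseline ------------------------------------------------
  km <- stage("cluster", kmeans_l1(feats, seed = derive_seed(config$seed, 2L),
                                   restarts = config$kmeans_restarts))

  # ---- self-training ---------------------------------------------------
  st <- NULL
  if (config$selftrain_m > 0L) {
    evaluator <- function(ids) {
      sub <- pool$peaks[pool$peaks$id %in% ids, , drop = FALSE]
      ere_ratio(sub, inputs$genome, inputs$pwm)$ratio
    }
    st <- stage("selftrain", self_train(
      pos_x, neg_x, feats, m = config$selftrain_m,
      max_iter = config$selftrain_max_iter, threshold = config$threshold,
      seed = derive_seed(config$seed, 3L), evaluator = evaluator
    ))
  }

  # ---- motif evaluation (Table-2-style) --------------------------------
  containment <- stage("motif-eval", {
    sets <- list(
      "NB positive" = pool$peaks[label == "positive", , drop = FALSE],
      "NB negative" = pool$peaks[label == "negative", , drop = FALSE],
      "k-means cluster 1" = pool$peaks[km$cluster == 1L, , drop = FALSE],
      "k-means cluster 2" = pool$peaks[km$cluster == 2L, , drop = FALSE]
    )
    if (!is.null(st)) {
      stpos <- st$labels$id[st$labels$label == "positive"]
      sets[["self-train positive"]] <-
        pool$peaks[pool$peaks$id %in% stpos, , drop = FALSE]
      sets[["self-train negative"]] <-
        pool$peaks[!pool$peaks$id %in% stpos, , drop = FALSE]
    }
    rows <- lapply(names(sets), function(nm) {
      er <- ere_ratio(sets[[nm]], inputs$genome, inputs$pwm)
      data.frame(peak_set = nm, n_peaks = er$n_total,
                 n_with_motif = er$n_with_motif, ratio = er$ratio,
                 ratio_2dp = round2(er$ratio), stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })

  # ---- gene mapping (Table-3-style) ------------------------------------
  gene_mapping <- stage("report", {
    if (is.null(inputs$genes)) NULL else {
      map_set <- function(p) {
        gids <- vapply(seq_len(nrow(p)), function(i) {
          map_peak_to_gene(p[i, , drop = FALSE], inputs$genes,
                           config$feature_config$gene_max_distance)
        }, "")
        gids <- gids[!is.na(gids)]
        sens <- inputs$genes$gene_id[inputs$genes$sensitive]
        c(n_genes = length(unique(gids)),
          n_sensitive = length(intersect(unique(gids), sens)))
      }
      sets <- list("all candidates" = pool$peaks,
                   "NB positive" = pool$peaks[label == "positive", ,
                                              drop = FALSE])
      rows <- lapply(names(sets), function(nm) {
        mm <- map_set(sets[[nm]])
        data.frame(peak_set = nm, n_peaks = nrow(sets[[nm]]),
                   n_genes_mapped = unname(mm["n_genes"]),
                   n_sensitive_intersect = unname(mm["n_sensitive"]),
                   stringsAsFactors = FALSE)
      })
      do.call(rbind, rows)
    }
  })

  # ---- cross-validation (Table-4-style) --------------------------------
  cv <- stage("cv", cross_validate(train$x, train$y, folds = config$cv_folds,
                                   threshold = config$threshold,
                                   seed = derive_seed(config$seed, 4L)))

  # ---- generative-truth metrics (synthetic runs) -----------------------
  truth_metrics <- NULL
  if (!is.null(config$truth_file)) {
    truth_metrics <- stage("truth", {
      truth <- utils::read.table(config$truth_file, header = TRUE, sep = "\t",
                                 stringsAsFactors = FALSE)
      pred <- candidates_to_sites(pool$peaks, label, truth)
      ground_truth_metrics(pred, truth)
    })
  }

  # ---- write reports ---------------------------------------------------
  series <- if (!is.null(st)) evaluate_history(st) else NULL
  rep2 <- containment
  rep2$ratio <- sprintf("%.2f", rep2$ratio)  # presentation copy only
  utils::write.table(rep2, file.path(outdir, "containment_report.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(gene_mapping)) {
    utils::write.table(gene_mapping,
                       file.path(outdir, "gene_mapping_report.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  utils::write.table(
    data.frame(precision = cv$precision, recall = cv$recall,
               accuracy = cv$accuracy),
    file.path(outdir, "cv_report.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE
  )
  if (!is.null(series)) {
    utils::write.table(series, file.path(outdir, "selftrain_series.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  manifest <- list(
    package = "coregpeaks",
    version = as.character(utils::packageVersion("coregpeaks")),
    seed = config$seed, threshold = config$threshold, ratio = config$ratio,
    selftrain_m = config$selftrain_m,
    selftrain_max_iter = config$selftrain_max_iter,
    inputs = lapply(Filter(Negate(is.null), list(
      genome = config$genome_file, occupancy = config$occupancy_file,
      er_peaks = config$er_peaks_file, genes = config$genes_file,
      labeled_pos = config$labeled_pos_file,
      negative_pool = config$negative_pool_file
    )), function(p) list(path = p, md5 = unname(tools::md5sum(p))))
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(pool = pool, features = feats, model = model,
                 labels = data.frame(id = pool$peaks$id, label = label,
                                     posterior = unname(post),
                                     stringsAsFactors = FALSE),
                 kmeans = km, selftrain = st, containment = containment,
                 gene_mapping = gene_mapping, cv = cv,
                 selftrain_series = series, truth_metrics = truth_metrics))
}

#' Map merged candidates back to generator sites
#'
#' Assigns each truth site the label of the candidate overlapping it (sites
#' dropped by every pseudo-caller have no candidate and are omitted).
#'
#' @param candidates Candidate peak `data.frame`.
#' @param labels Character labels parallel to `candidates`.
#' @param truth Truth table from [generate_synthetic()].
#' @return `data.frame` with columns `id` (site id) and `label`, suitable
#'   for [ground_truth_metrics()].
#' @export
candidates_to_sites <- function(candidates, labels, truth) {
  stopifnot(nrow(candidates) == length(labels))
  cand_gr <- peaks_to_granges(candidates)
  site_gr <- GenomicRanges::GRanges(
    seqnames = truth$chrom,
    ranges = IRanges::IRanges(truth$start + 1L, truth$end)
  )
  hit <- GenomicRanges::findOverlaps(site_gr, cand_gr)
  data.frame(id = truth$site_id[S4Vectors::queryHits(hit)],
             label = labels[S4Vectors::subjectHits(hit)],
             stringsAsFactors = FALSE)
}
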