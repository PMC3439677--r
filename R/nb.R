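# classify: Bernoulli naive Bayes with posterior thresholding.
#
# The model treats each of the 67 binary features as an independent
# Bernoulli variable per class. Parameters are estimated with Laplace
# add-one smoothing,
#     theta[c, j] = (n_{c,j} + 1) / (n_c + 2),
# which keeps every theta strictly inside (0, 1); with only 18 labeled
# positives, unsmoothed maximum likelihood would put exact zeros into the
# product form. Posteriors are evaluated in log space.

normalize_labels <- function(y) {
  if (is.logical(y)) y <- ifelse(y, "positive", "negative")
  y <- as.character(y)
  bad <- setdiff(unique(y), c("positive", "negative"))
  if (length(bad)) {
    stop("labels must be 'positive'/'negative' (or logical); got: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  y
}

as_binary_matrix <- function(x) {
  if (is.vector(x) && is.numeric(x)) x <- matrix(x, nrow = 1L)
  if (is.data.frame(x)) x <- as.matrix(x)
  storage.mode(x) <- "integer"
  if (length(x) && !all(x %in% c(0L, 1L))) {
    stop("feature values must be binary (0/1)", call. = FALSE)
  }
  x
}

#' Fit a Bernoulli naive Bayes classifier
#'
#' Class priors are the empirical class fractions; per-feature Bernoulli
#' parameters use Laplace add-one smoothing:
#' `theta[c, j] = (count of x_j = 1 in class c + 1) / (n_c + 2)`.
#'
#' @param x Binary feature matrix (rows = examples). A numeric vector is
#'   treated as a single-feature column per example only when `y` has the
#'   same length.
#' @param y Labels: `"positive"`/`"negative"` (or logical, `TRUE` =
#'   positive). Both classes must be present.
#' @param threshold Posterior threshold for calling a peak positive
#'   (inclusive; default 0.8).
#' @return An object of class `"bernoulli_nb"`: list with `prior` (named
#'   numeric, sums to 1), `theta` (2 x p matrix, rows `positive`/
#'   `negative`), `counts` (per-class training sizes), `threshold` and
#'   `feature_names`.
#' @examples
#' x <- matrix(c(1, 1, 0, 0), ncol = 1)
#' fit <- nb_fit(x, c("positive", "positive", "negative", "negative"))
#' fit$theta  # 3/4 and 1/4
#' @export
nb_fit <- function(x, y, threshold = 0.8) {
  if (is.vector(x) && is.numeric(x) && !is.matrix(x) &&
      length(x) == length(y)) {
    x <- matrix(x, ncol = 1L)
  }
  x <- as_binary_matrix(x)
  y <- normalize_labels(y)
  if (nrow(x) != length(y)) stop("nrow(x) != length(y)", call. = FALSE)
  if (length(unique(y)) < 2L) {
    stop("training data must contain both classes", call. = FALSE)
  }
  stopifnot(threshold > 0, threshold < 1)
  classes <- c("positive", "negative")
  n_c <- vapply(classes, function(cl) sum(y == cl), 0L)
  theta <- matrix(0, 2L, ncol(x), dimnames = list(classes, colnames(x)))
  for (cl in classes) {
    theta[cl, ] <- (colSums(x[y == cl, , drop = FALSE]) + 1) / (n_c[[cl]] + 2)
  }
  structure(list(
    prior = n_c / sum(n_c),
    theta = theta,
    counts = n_c,
    threshold = threshold,
    feature_names = colnames(x)
  ), class = "bernoulli_nb")
}

#' Posterior probabilities and class calls from a fitted NB model
#'
#' @param object A `"bernoulli_nb"` fit.
#' @param newdata Binary matrix (or single vector) of feature rows matching
#'   the model's feature count.
#' @param type `"class"` (default) for `"positive"`/`"negative"` calls at
#'   the model's threshold (posterior >= threshold is positive), or
#'   `"posterior"` for `P(positive | x)`.
#' @param threshold Optional override of the stored threshold.
#' @param ... Unused.
#' @return Character vector of calls, or numeric vector of posteriors in
#'   `[0, 1]` (named by row names when present).
#' @export
predict.bernoulli_nb <- function(object, newdata, type = c("class", "posterior"),
                                 threshold = NULL, ...) {
  type <- match.arg(type)
  if (is.vector(newdata) && !is.matrix(newdata)) {
    newdata <- matrix(newdata, nrow = 1L)
  }
  x <- as_binary_matrix(newdata)
  p <- ncol(object$theta)
  if (ncol(x) != p) {
    stop(sprintf("feature length mismatch: model has %d, data has %d",
                 p, ncol(x)), call. = FALSE)
  }
  loglik <- function(cl) {
    th <- object$theta[cl, ]
    drop(x %*% log(th) + (1 - x) %*% log(1 - th)) + log(object$prior[[cl]])
  }
  lp <- loglik("positive"); ln <- loglik("negative")
  mx <- pmax(lp, ln)
  post <- exp(lp - mx) / (exp(lp - mx) + exp(ln - mx))
  names(post) <- rownames(x)
  if (type == "posterior") return(post)
  thr <- threshold %||% object$threshold
  stats::setNames(ifelse(post >= thr, "positive", "negative"), rownames(x))
}

#' @export
print.bernoulli_nb <- function(x, ...) {
  cat("Bernoulli naive Bayes classifier\n")
  cat(sprintf("  features: %d   threshold: %g\n", ncol(x$theta), x$threshold))
  cat(sprintf("  training: %d positive, %d negative (prior %.3f / %.3f)\n",
              x$counts[["positive"]], x$counts[["negative"]],
              x$prior[["positive"]], x$prior[["negative"]]))
  invisible(x)
}

#' @method summary bernoulli_nb
#' @export
summary.bernoulli_nb <- function(object, n_top = 10L, ...) {
  lo <- log2(object$theta["positive", ] / object$theta["negative", ])
  ord <- order(abs(lo), decreasing = TRUE)
  cat("Bernoulli naive Bayes classifier\n")
  print(object)
  k <- min(n_top, length(lo))
  cat(sprintf("  top %d features by |log2 theta ratio|:\n", k))
  df <- data.frame(feature = (object$feature_names %||%
                                as.character(seq_along(lo)))[ord[1:k]],
                   theta_pos = object$theta["positive", ord[1:k]],
                   theta_neg = object$theta["negative", ord[1:k]],
                   log2_ratio = lo[ord[1:k]], row.names = NULL)
  print(df, digits = 3)
  invisible(df)
}

#' @method coef bernoulli_nb
#' @export
coef.bernoulli_nb <- function(object, ...) object$theta

#' Serialize / restore an NB model as JSON
#'
#' @param model A `"bernoulli_nb"` fit.
#' @param path Output (input) path.
#' @return `path` invisibly (`write_nb_model`); the restored model
#'   (`read_nb_model`).
#' @export
write_nb_model <- function(model, path) {
  stopifnot(inherits(model, "bernoulli_nb"))
  obj <- list(
    format = "coregpeaks-nb-model", version = 1L,
    prior = as.list(model$prior),
    theta_positive = unname(model$theta["positive", ]),
    theta_negative = unname(model$theta["negative", ]),
    counts = as.list(model$counts),
    threshold = model$threshold,
    feature_names = model$feature_names
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_nb_model
#' @export
read_nb_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "coregpeaks-nb-model")) {
    stop("not a coregpeaks NB model file: ", path, call. = FALSE)
  }
  theta <- rbind(positive = obj$theta_positive, negative = obj$theta_negative)
  colnames(theta) <- obj$feature_names
  structure(list(
    prior = unlist(obj$prior),
    theta = theta,
    counts = unlist(obj$counts),
    threshold = obj$threshold,
    feature_names = obj$feature_names
  ), class = "bernoulli_nb")
}

#' Assemble a labeled training set at a positive:negative ratio
#'
#' Keeps all positives and draws `ratio * n_positive` negatives uniformly
#' without replacement from the negative pool; deterministic for a fixed
#' seed.
#'
#' @param positives Binary feature matrix of validated positive peaks (row
#'   names = ids).
#' @param negative_pool Binary feature matrix of control (IgG-derived)
#'   negative peaks.
#' @param ratio Negatives per positive: 1, 2 or 3 (the 1:1, 1:2, 1:3
#'   designs).
#' @param seed Integer seed for the negative draw.
#' @return List with `x` (row-bound matrix), `y` (labels) and `ids`.
#' @export
sample_training <- function(positives, negative_pool, ratio = 2L, seed = 1L) {
  ratio <- as.integer(ratio)
  stopifnot(ratio %in% 1:3)
  npos <- nrow(positives)
  need <- ratio * npos
  if (nrow(negative_pool) < need) {
    stop(sprintf("negative pool too small: need %d, have %d",
                 need, nrow(negative_pool)), call. = FALSE)
  }
  pick <- with_seed(seed, sample.int(nrow(negative_pool), need))
  x <- rbind(positives, negative_pool[pick, , drop = FALSE])
  list(x = x,
       y = rep(c("positive", "negative"), c(npos, need)),
       ids = rownames(x))
}

#' Rank features by ROC class-separability
#'
#' For each feature taken alone as a score for the positive class, computes
#' the empirical ROC AUC with midrank tie handling (equivalently the
#' Mann-Whitney U statistic divided by `n_pos * n_neg`) and ranks features
#' by the separability criterion `|AUC - 0.5|`, descending; criterion ties
#' are broken by ascending feature index.
#'
#' @param x Feature matrix (binary or numeric scores).
#' @param y Labels (`"positive"`/`"negative"` or logical).
#' @return `data.frame` sorted by rank with columns `feature` (column
#'   index), `name`, `auc`, `criterion`.
#' @export
rank_features_roc <- function(x, y) {
  if (is.data.frame(x)) x <- as.matrix(x)
  y <- normalize_labels(y)
  if (length(unique(y)) < 2L) {
    stop("both classes required to rank features", call. = FALSE)
  }
  pos <- y == "positive"
  n1 <- sum(pos); n0 <- sum(!pos)
  auc <- apply(x, 2L, function(v) {
    r <- rank(v)  # midranks
    (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  })
  crit <- abs(auc - 0.5)
  ord <- order(-crit, seq_along(crit))
  data.frame(feature = ord,
             name = (colnames(x) %||% as.character(seq_len(ncol(x))))[ord],
             auc = unname(auc[ord]), criterion = unname(crit[ord]),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Stratified k-fold cross-validation of the NB classifier
#'
#' Folds are assigned per class (stratified) under the seed; metrics are
#' computed from the confusion matrix pooled over all held-out folds
#' (with only a couple of positives per fold, per-fold averages would be
#' unstable):
#' precision `TP/(TP+FP)`, recall `TP/(TP+FN)`, accuracy `(TP+TN)/n`.
#'
#' @param x Binary feature matrix.
#' @param y Labels.
#' @param folds Number of folds (default 9).
#' @param threshold NB posterior threshold (default 0.8).
#' @param seed Seed for fold assignment.
#' @return List with `precision`, `recall`, `accuracy`, `confusion`
#'   (2 x 2 table) and `fold` (the per-example fold assignment).
#' @export
cross_validate <- function(x, y, folds = 9L, threshold = 0.8, seed = 1L) {
  x <- as_binary_matrix(x)
  y <- normalize_labels(y)
  folds <- as.integer(folds)
  n_c <- table(y)
  if (folds < 2L || any(n_c < folds)) {
    # stratification requires >= 1 example of each class per fold
    stop(sprintf("cannot stratify %d/%d examples into %d folds",
                 n_c[["positive"]], n_c[["negative"]], folds), call. = FALSE)
  }
  fold <- integer(length(y))
  with_seed(seed, {
    for (cl in unique(y)) {
      idx <- which(y == cl)
      fold[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    }
  })
  pred <- character(length(y))
  for (f in seq_len(folds)) {
    hold <- fold == f
    fit <- nb_fit(x[!hold, , drop = FALSE], y[!hold], threshold = threshold)
    pred[hold] <- predict(fit, x[hold, , drop = FALSE], type = "class")
  }
  tp <- sum(pred == "positive" & y == "positive")
  fp <- sum(pred == "positive" & y == "negative")
  fn <- sum(pred == "negative" & y == "positive")
  tn <- sum(pred == "negative" & y == "negative")
  list(precision = if (tp + fp > 0) tp / (tp + fp) else NaN,
       recall = tp / (tp + fn),
       accuracy = (tp + tn) / length(y),
       confusion = matrix(c(tp, fn, fp, tn), 2L, 2L,
                          dimnames = list(predicted = c("positive", "negative"),
                                          truth = c("positive", "negative"))),
       fold = fold)
}
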