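# selftrain: self-training semi-supervised wrapper around the NB classifier.
#
# Starting from L0 = (all labeled positives P) + (an equal number of
# negatives drawn from the control pool N), each iteration fits an NB
# classifier on the current labeled set L_t, scores the unlabeled pool U_t,
# promotes the m unlabeled instances with the highest positive posterior as
# pseudo-positives, draws m fresh negatives from the reservoir N_t, removes
# both from their pools and appends them to L_{t+1}. The loop stops when U
# is empty, the negative reservoir cannot supply a matching draw, or the
# iteration cap is reached; the final classifier is then applied to the
# remaining unlabeled instances.

#' Self-training semi-supervised Bernoulli NB
#'
#' @param positives Binary feature matrix of labeled positive peaks (row
#'   names = ids).
#' @param negative_pool Binary feature matrix of control negatives; `l_p`
#'   rows are drawn (seeded) for the initial labeled set, the rest form the
#'   reservoir for per-iteration draws.
#' @param unlabeled Binary feature matrix of unlabeled candidate peaks (row
#'   names = ids; required, used for deterministic tie-breaking).
#' @param m Instances promoted per iteration (default 5). `m = 0` performs
#'   no self-training and reduces exactly to supervised NB on the initial
#'   labeled set.
#' @param max_iter Iteration cap (default 75).
#' @param threshold NB posterior threshold (default 0.8).
#' @param seed Integer seed (initial negative draw + per-iteration draws).
#' @param evaluator Optional function taking the character vector of ids
#'   currently called positive in the unlabeled pool and returning a
#'   numeric ratio (e.g. ERE containment); evaluated every iteration into
#'   the history.
#' @return Object of class `"self_train"`: list with
#'   \describe{
#'     \item{model}{final `"bernoulli_nb"` classifier}
#'     \item{labels}{`data.frame` over the original unlabeled pool: `id`,
#'       `label`, `posterior` (under the final model), `promoted_iter`
#'       (`NA` for never-promoted instances)}
#'     \item{history}{per-iteration `data.frame`: `iter`, `n_labeled`
#'       (|L_t| when C_t was fitted), `n_promoted`, `promoted_ids`
#'       (comma-joined), `n_positive_calls`, `eval_ratio`,
#'       `eval_empty` flag}
#'     \item{initial}{the initial labeled set (`x`, `y`, `ids`)}
#'     \item{state}{final pool sizes (`n_labeled`, `n_unlabeled`,
#'       `n_reservoir`) and `iterations` completed}
#'   }
#' @export
self_train <- function(positives, negative_pool, unlabeled, m = 5L,
                       max_iter = 75L, threshold = 0.8, seed = 1L,
                       evaluator = NULL) {
  m <- as.integer(m); max_iter <- as.integer(max_iter)
  stopifnot(m >= 0L, max_iter >= 0L)
  if (is.null(rownames(unlabeled)) || is.null(rownames(negative_pool)) ||
      is.null(rownames(positives))) {
    stop("positives, negative_pool and unlabeled need row names (ids)",
         call. = FALSE)
  }
  if (nrow(unlabeled) == 0L) stop("unlabeled pool is empty", call. = FALSE)
  l_p <- nrow(positives)
  if (nrow(negative_pool) < l_p) {
    stop("negative pool smaller than the positive set", call. = FALSE)
  }

  with_seed(seed, {
    init_neg <- sample.int(nrow(negative_pool), l_p)
    L_x <- rbind(positives, negative_pool[init_neg, , drop = FALSE])
    L_y <- rep(c("positive", "negative"), c(l_p, l_p))
    initial <- list(x = L_x, y = L_y, ids = rownames(L_x))
    reservoir <- negative_pool[-init_neg, , drop = FALSE]
    U <- unlabeled
    promoted_iter <- stats::setNames(rep(NA_integer_, nrow(unlabeled)),
                                     rownames(unlabeled))
    hist_rows <- list()
    t <- 0L
    repeat {
      model <- nb_fit(L_x, L_y, threshold = threshold)
      post <- if (nrow(U)) predict(model, U, type = "posterior") else numeric(0)
      pos_ids <- names(post)[post >= threshold]
      ev <- NA_real_; ev_empty <- NA
      if (!is.null(evaluator)) {
        ev_empty <- length(pos_ids) == 0L
        ev <- if (ev_empty) 0 else as.numeric(evaluator(pos_ids))
      }
      k <- min(m, nrow(U))
      can_promote <- k > 0L && nrow(reservoir) >= k && t < max_iter
      hist_rows[[length(hist_rows) + 1L]] <- data.frame(
        iter = t, n_labeled = nrow(L_x),
        n_promoted = if (can_promote) k else 0L,
        promoted_ids = "", n_positive_calls = length(pos_ids),
        eval_ratio = ev, eval_empty = ev_empty,
        stringsAsFactors = FALSE
      )
      if (!can_promote) break
      # m highest-posterior instances; ties by ascending id
      ord <- order(-post, names(post))
      take <- ord[seq_len(k)]
      take_ids <- rownames(U)[take]
      hist_rows[[length(hist_rows)]]$promoted_ids <-
        paste(take_ids, collapse = ",")
      neg_take <- sample.int(nrow(reservoir), k)
      L_x <- rbind(L_x, U[take, , drop = FALSE],
                   reservoir[neg_take, , drop = FALSE])
      L_y <- c(L_y, rep("positive", k), rep("negative", k))
      promoted_iter[take_ids] <- t
      U <- U[-take, , drop = FALSE]
      reservoir <- reservoir[-neg_take, , drop = FALSE]
      t <- t + 1L
    }
    final_post <- predict(model, unlabeled, type = "posterior")
    labels <- data.frame(
      id = rownames(unlabeled),
      label = ifelse(!is.na(promoted_iter), "positive",
                     ifelse(final_post >= threshold, "positive", "negative")),
      posterior = unname(final_post),
      promoted_iter = unname(promoted_iter),
      stringsAsFactors = FALSE
    )
    structure(list(
      model = model, labels = labels,
      history = do.call(rbind, hist_rows),
      initial = initial,
      state = list(n_labeled = nrow(L_x), n_unlabeled = nrow(U),
                   n_reservoir = nrow(reservoir), iterations = t)
    ), class = "self_train")
  })
}

#' @export
print.self_train <- function(x, ...) {
  cat("Self-training Bernoulli NB\n")
  cat(sprintf("  iterations: %d   labeled set: %d -> %d\n",
              x$state$iterations, nrow(x$initial$x), x$state$n_labeled))
  cat(sprintf("  positive calls in unlabeled pool: %d / %d\n",
              sum(x$labels$label == "positive"), nrow(x$labels)))
  invisible(x)
}

#' Per-iteration evaluation series from a self-training history
#'
#' Re-emits (or computes, when the run was made without an attached
#' evaluator) the per-iteration evaluation ratio — typically ERE-motif
#' containment of the current positive calls — as a plotting-ready table.
#'
#' @param history The `history` data frame of a [self_train()] run (or the
#'   `"self_train"` object itself).
#' @return `data.frame` with columns `iter`, `n_labeled`,
#'   `n_positive_calls`, `ratio`, `empty` (flag: no positive calls at that
#'   iteration; the ratio is then recorded as 0).
#' @export
evaluate_history <- function(history) {
  if (inherits(history, "self_train")) history <- history$history
  stopifnot(is.data.frame(history))
  data.frame(iter = history$iter, n_labeled = history$n_labeled,
             n_positive_calls = history$n_positive_calls,
             ratio = ifelse(is.na(history$eval_ratio), 0, history$eval_ratio),
             empty = ifelse(is.na(history$eval_empty),
                            history$n_positive_calls == 0L,
                            history$eval_empty))
}
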