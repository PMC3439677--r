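# classify: unsupervised k-means (k = 2) baseline with city-block distance.
#
# Lloyd-style iteration under the L1 metric: assignments minimize
# city-block distance (ties to the lower cluster index), centroids are
# component-wise medians (the L1 minimizer). The total L1 distance
# ("inertia") is non-increasing across iterations within a run; the best of
# several seeded random initializations is kept.

l1_dist_to <- function(x, centroid) {
  rowSums(abs(sweep(x, 2L, centroid)))
}

#' Two-cluster k-means with city-block distance
#'
#' @param x Numeric matrix (rows = peaks, columns = features); must contain
#'   at least two distinct rows.
#' @param seed Integer seed controlling the random initializations.
#' @param restarts Number of random initializations (two distinct random
#'   rows as initial centroids); the run with the lowest inertia wins.
#' @param max_iter Safety cap on Lloyd iterations per restart.
#' @return Object of class `"kmeans_l1"`: list with `cluster` (per-row index
#'   in `{1, 2}`; cluster 1 is the larger cluster), `centroids` (2 x p),
#'   `inertia` (total city-block distance), `sizes`, and `trace` (inertia
#'   after each iteration of the winning run).
#' @export
kmeans_l1 <- function(x, seed = 1L, restarts = 20L, max_iter = 100L) {
  if (is.data.frame(x)) x <- as.matrix(x)
  storage.mode(x) <- "double"
  n <- nrow(x)
  if (n < 2L || nrow(unique(x)) < 2L) {
    stop("k-means needs at least two distinct rows", call. = FALSE)
  }
  run_once <- function() {
    repeat {  # two distinct rows as initial centroids
      init <- sample.int(n, 2L)
      cen <- x[init, , drop = FALSE]
      if (any(cen[1L, ] != cen[2L, ])) break
    }
    assign_prev <- integer(n)
    trace <- numeric(0)
    for (it in seq_len(max_iter)) {
      d1 <- l1_dist_to(x, cen[1L, ]); d2 <- l1_dist_to(x, cen[2L, ])
      a <- ifelse(d1 <= d2, 1L, 2L)  # ties to the lower index
      if (!any(a == 1L) || !any(a == 2L)) {
        # a centroid lost all members; re-seed it at the farthest point
        far <- which.max(if (any(a == 1L)) d1 else d2)
        a[far] <- if (any(a == 1L)) 2L else 1L
      }
      for (k in 1:2) {
        cen[k, ] <- apply(x[a == k, , drop = FALSE], 2L, stats::median)
      }
      d1 <- l1_dist_to(x, cen[1L, ]); d2 <- l1_dist_to(x, cen[2L, ])
      trace <- c(trace, sum(pmin(d1, d2)))
      if (identical(a, assign_prev)) break
      assign_prev <- a
    }
    list(cluster = a, centroids = cen, inertia = trace[length(trace)],
         trace = trace)
  }
  best <- with_seed(seed, {
    b <- NULL
    for (r in seq_len(restarts)) {
      cand <- run_once()
      if (is.null(b) || cand$inertia < b$inertia) b <- cand
    }
    b
  })
  # relabel so cluster 1 is the larger one (ties: keep current labels)
  if (sum(best$cluster == 2L) > sum(best$cluster == 1L)) {
    best$cluster <- 3L - best$cluster
    best$centroids <- best$centroids[2:1, , drop = FALSE]
  }
  rownames(best$centroids) <- c("cluster1", "cluster2")
  names(best$cluster) <- rownames(x)
  structure(list(cluster = best$cluster, centroids = best$centroids,
                 inertia = best$inertia,
                 sizes = c(sum(best$cluster == 1L), sum(best$cluster == 2L)),
                 trace = best$trace),
            class = "kmeans_l1")
}

#' @export
print.kmeans_l1 <- function(x, ...) {
  cat("City-block k-means (k = 2)\n")
  cat(sprintf("  cluster sizes: %d / %d   inertia: %.3f\n",
              x$sizes[1L], x$sizes[2L], x$inertia))
  invisible(x)
}
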