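# Bernoulli naive Bayes: smoothing, posteriors, thresholding, training-set
# assembly, ROC feature ranking, cross-validation.

test_that("Laplace smoothing gives the hand-computed parameters", {
  x <- matrix(c(1, 1, 0, 0), ncol = 1)
  y <- c("positive", "positive", "negative", "negative")
  fit <- nb_fit(x, y)
  expect_equal(unname(fit$theta["positive", 1]), 3 / 4)  # (2+1)/(2+2)
  expect_equal(unname(fit$theta["negative", 1]), 1 / 4)
  expect_equal(unname(fit$prior), c(0.5, 0.5))
  fit2 <- nb_fit(matrix(0, 3, 1), c("positive", "negative", "negative"))
  expect_equal(unname(fit2$prior["positive"]), 1 / 3)
  expect_error(nb_fit(matrix(1, 3, 1), rep("positive", 3)), "both classes")
})

test_that("posterior matches the closed form and the product-form oracle", {
  x <- matrix(c(1, 1, 0, 0), ncol = 1)
  fit <- nb_fit(x, c("positive", "positive", "negative", "negative"))
  # (0.5 * 0.75) / (0.5 * 0.75 + 0.5 * 0.25)
  expect_equal(unname(predict(fit, matrix(1, 1, 1), type = "posterior")),
               0.75)
  set.seed(31)
  for (rep in 1:100) {
    p <- sample(3:20, 1)
    n <- sample(6:30, 1)
    xm <- matrix(rbinom(n * p, 1, runif(1, 0.2, 0.8)), n, p)
    ym <- c("positive", "negative",
            sample(c("positive", "negative"), n - 2, replace = TRUE))
    m <- nb_fit(xm, ym)
    q <- rbinom(p, 1, 0.5)
    expect_equal(unname(predict(m, q, type = "posterior")),
                 oracle_nb_posterior(m, q), tolerance = 1e-9)
  }
})

test_that("posteriors over both classes always normalize to 1", {
  set.seed(32)
  xm <- matrix(rbinom(200, 1, 0.5), 20, 10)
  ym <- rep(c("positive", "negative"), 10)
  m <- nb_fit(xm, ym)
  for (rep in 1:50) {
    q <- rbinom(10, 1, 0.5)
    ppos <- unname(predict(m, q, type = "posterior"))
    # P(neg | x) via the symmetric model with classes swapped
    swap <- m
    swap$theta <- m$theta[2:1, ]
    rownames(swap$theta) <- c("positive", "negative")
    swap$prior <- stats::setNames(m$prior[2:1], c("positive", "negative"))
    pneg <- unname(predict(swap, q, type = "posterior"))
    expect_equal(ppos + pneg, 1, tolerance = 1e-12)
  }
})

test_that("a symmetric model is indifferent: posterior 0.5 for any input", {
  xm <- rbind(diag(4), diag(4))
  ym <- rep(c("positive", "negative"), each = 4)
  m <- nb_fit(xm, ym)
  expect_true(all(abs(predict(m, diag(4), type = "posterior") - 0.5) < 1e-12))
})

test_that("fitting is invariant to training-example order", {
  set.seed(33)
  xm <- matrix(rbinom(120, 1, 0.4), 12, 10)
  ym <- rep(c("positive", "negative"), 6)
  perm <- sample(12)
  m1 <- nb_fit(xm, ym)
  m2 <- nb_fit(xm[perm, ], ym[perm])
  expect_equal(m1$theta, m2$theta)
  expect_equal(m1$prior, m2$prior)
})

test_that("smoothing bounds every theta inside [1/(n_c+2), (n_c+1)/(n_c+2)]", {
  set.seed(34)
  for (rep in 1:10) {
    n <- sample(4:20, 1)
    xm <- matrix(rbinom(n * 5, 1, runif(1)), n, 5)
    ym <- c("positive", "negative",
            sample(c("positive", "negative"), n - 2, replace = TRUE))
    m <- nb_fit(xm, ym)
    for (cl in c("positive", "negative")) {
      nc <- m$counts[[cl]]
      expect_true(all(m$theta[cl, ] >= 1 / (nc + 2)))
      expect_true(all(m$theta[cl, ] <= (nc + 1) / (nc + 2)))
    }
  }
})

test_that("classification threshold is inclusive and 0.5 equals argmax", {
  set.seed(35)
  xm <- matrix(rbinom(300, 1, 0.5), 30, 10)
  ym <- rep(c("positive", "negative"), 15)
  m <- nb_fit(xm, ym)
  q <- matrix(rbinom(200, 1, 0.5), 20, 10)
  post <- predict(m, q, type = "posterior")
  cls8 <- predict(m, q, type = "class", threshold = 0.8)
  expect_identical(unname(cls8),
                   ifelse(post >= 0.8, "positive", "negative"))
  cls5 <- predict(m, q, type = "class", threshold = 0.5)
  argmax <- ifelse(post >= 0.5, "positive", "negative")
  expect_identical(unname(cls5), argmax)
  expect_error(predict(m, rbinom(4, 1, 0.5)), "mismatch")
})

test_that("model JSON serialization round-trips", {
  set.seed(36)
  xm <- matrix(rbinom(120, 1, 0.5), 12, 10)
  colnames(xm) <- paste0("f", 1:10)
  m <- nb_fit(xm, rep(c("positive", "negative"), 6), threshold = 0.8)
  f <- withr::local_tempfile(fileext = ".json")
  write_nb_model(m, f)
  back <- read_nb_model(f)
  expect_equal(back$theta, m$theta, ignore_attr = FALSE)
  expect_equal(back$prior, m$prior)
  expect_equal(back$threshold, m$threshold)
  expect_equal(back$feature_names, m$feature_names)
})

test_that("training sets keep all positives and draw seeded negatives", {
  pos <- rand_features(18, prefix = "pos")
  neg <- rand_features(100, prefix = "neg")
  tr <- sample_training(pos, neg, ratio = 2, seed = 9)
  expect_equal(sum(tr$y == "positive"), 18L)
  expect_equal(sum(tr$y == "negative"), 36L)
  expect_equal(nrow(tr$x), 54L)
  tr2 <- sample_training(pos, neg, ratio = 2, seed = 9)
  expect_identical(tr$ids, tr2$ids)
  expect_error(sample_training(pos, rand_features(10), ratio = 2, seed = 1),
               "too small")
})

test_that("ROC ranking matches the Mann-Whitney U statistic with midranks", {
  x <- cbind(perfect = c(1, 1, 1, 0, 0, 0),
             constant = rep(1, 6),
             anti = c(0, 0, 0, 1, 1, 1))
  y <- rep(c("positive", "negative"), each = 3)
  r <- rank_features_roc(x, y)
  expect_equal(r$name[1], "perfect")
  expect_equal(r$criterion[1], 0.5)           # AUC = 1
  expect_equal(r$criterion[r$name == "constant"], 0)
  expect_equal(r$auc[r$name == "anti"], 0)
  expect_true(all(r$criterion >= 0 & r$criterion <= 0.5))
  # U-statistic oracle on fuzzed binary features
  set.seed(37)
  for (rep in 1:20) {
    n <- sample(8:24, 1)
    v <- rbinom(n, 1, 0.5)
    yy <- c("positive", "negative",
            sample(c("positive", "negative"), n - 2, replace = TRUE))
    pos <- v[yy == "positive"]; negv <- v[yy == "negative"]
    u <- sum(outer(pos, negv, function(a, b) (a > b) + 0.5 * (a == b)))
    auc_u <- u / (length(pos) * length(negv))
    r1 <- rank_features_roc(matrix(v, ncol = 1), yy)
    expect_equal(r1$auc, auc_u, tolerance = 1e-12)
  }
})

test_that("ROC ranking agrees with pROC on a labeled set", {
  skip_if_not_installed("pROC")
  set.seed(38)
  x <- matrix(rbinom(40 * 6, 1, 0.5), 40, 6)
  y <- sample(c("positive", "negative"), 40, replace = TRUE,
              prob = c(0.4, 0.6))
  r <- rank_features_roc(x, y)
  for (j in 1:6) {
    ref <- as.numeric(pROC::auc(pROC::roc(
      response = y, predictor = x[, j], levels = c("negative", "positive"),
      direction = "<", quiet = TRUE)))
    expect_equal(r$auc[r$feature == j], ref, tolerance = 1e-12)
  }
})

test_that("criterion ties are broken by ascending feature index", {
  x <- cbind(a = c(1, 1, 0, 0), b = c(1, 1, 0, 0))
  y <- c("positive", "positive", "negative", "negative")
  r <- rank_features_roc(x, y)
  expect_equal(r$feature, c(1L, 2L))
})

test_that("cross-validation pools fold confusion matrices", {
  # threshold ~0 predicts everything positive: recall 1, precision 1/3 on 1:2
  set.seed(39)
  x <- rand_features(54, p = 6)
  y <- rep(c("positive", "negative"), c(18, 36))
  cv <- cross_validate(x, y, folds = 9, threshold = 1e-12, seed = 5)
  expect_equal(cv$recall, 1)
  expect_equal(cv$precision, 1 / 3)
  expect_equal(cv$accuracy, 1 / 3)
  # a perfectly separable feature gives all-1 metrics
  xs <- cbind(rand_features(54, p = 3),
              sig = rep(c(1L, 0L), c(18, 36)))
  rownames(xs) <- sprintf("s%02d", 1:54)
  cvp <- cross_validate(xs, y, folds = 9, threshold = 0.5, seed = 5)
  expect_equal(cvp$precision, 1)
  expect_equal(cvp$recall, 1)
  expect_equal(cvp$accuracy, 1)
  expect_error(cross_validate(x[1:10, ], y[c(1:5, 19:23)], folds = 9),
               "stratify")
})
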