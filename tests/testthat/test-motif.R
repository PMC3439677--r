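# PWM construction, scanning, containment calls and set-level ratios.

test_that("PWM log-odds follow the pseudocount arithmetic", {
  counts <- matrix(0, 4, 4, dimnames = list(NULL, c("A", "C", "G", "T")))
  counts[1, "A"] <- 10
  counts[2, ] <- c(2.5, 2.5, 2.5, 2.5)
  pwm <- pwm_from_counts(counts, pseudocount = 0.5)
  expect_equal(unname(pwm$log_odds[1, "A"]), log2((10.5 / 12) / 0.25))  # log2(3.5)
  expect_equal(unname(pwm$log_odds[2, ]), rep(0, 4))   # uniform row
  expect_equal(unname(pwm$log_odds[3, ]), rep(0, 4))   # all-zero row
  expect_error(pwm_from_counts(matrix(-1, 4, 4)), "negative")
  expect_error(pwm_from_counts(matrix(1, 3, 4)), "width")
})

test_that("the packaged ERE matrix scores its consensus at the maximum", {
  pwm <- ere_pwm()
  expect_equal(pwm$width, 13L)
  expect_equal(pwm$consensus, "GGTCAnnnTGACC")
  expect_equal(pwm$max_score, 10 * log2(3.5), tolerance = 1e-12)
  hit <- scan_pwm("GGTCAAAATGACC", pwm)
  expect_equal(hit$score, pwm$max_score)
  expect_equal(hit$start, 0L)
  expect_equal(hit$strand, "+")
})

test_that("reverse-complement hits score identically on the minus strand", {
  # non-palindromic consensus ACGGTTAC so the two strands are distinguishable
  counts <- matrix(0, 8, 4, dimnames = list(NULL, c("A", "C", "G", "T")))
  cons <- c("A", "C", "G", "G", "T", "T", "A", "C")
  for (i in 1:8) counts[i, cons[i]] <- 10
  pwm <- pwm_from_counts(counts)
  h <- scan_pwm(paste(cons, collapse = ""), pwm)
  expect_equal(h$score, pwm$max_score)
  expect_equal(h$strand, "+")
  hr <- scan_pwm(revcomp_string(paste(cons, collapse = "")), pwm)
  expect_equal(hr$score, pwm$max_score)
  expect_equal(hr$strand, "-")
  expect_equal(hr$start, 0L)
})

test_that("scanning matches brute-force window enumeration on fuzzed 50-mers", {
  set.seed(61)
  counts <- matrix(stats::rpois(6 * 4, 3), 6, 4,
                   dimnames = list(NULL, c("A", "C", "G", "T")))
  counts[2, ] <- 0
  pwm <- pwm_from_counts(counts)
  for (rep in 1:50) {
    s <- rand_dna(50, alphabet = c("A", "C", "G", "T", "N"))
    got <- scan_pwm(s, pwm)
    want <- oracle_scan(s, pwm)
    expect_equal(got$score, want$score, tolerance = 1e-9, info = s)
    if (is.finite(want$score)) {
      expect_equal(got$start, want$start, info = s)
      expect_equal(got$strand, want$strand, info = s)
    }
  }
})

test_that("short or all-N sequences yield a no-hit result", {
  pwm <- ere_pwm()
  expect_equal(scan_pwm("ACGT", pwm)$score, -Inf)
  expect_equal(scan_pwm(paste(rep("N", 30), collapse = ""), pwm)$score, -Inf)
})

test_that("containment calls react to planted motifs and the threshold", {
  set.seed(62)
  pwm <- ere_pwm()
  bg <- rand_dna(2000)
  planted <- paste0(substr(bg, 1, 993), "GGTCAGCATGACC",
                    substr(bg, 1007, 2000))
  g <- toy_genome(good = planted,
                  polyA = paste(rep("A", 2000), collapse = ""))
  pk_good <- new_peaks("good", 900, 1100, summit = 1000)[1, ]
  pk_bad <- new_peaks("polyA", 900, 1100, summit = 1000)[1, ]
  expect_true(contains_motif(pk_good, g, pwm))
  expect_false(contains_motif(pk_bad, g, pwm))
  strict <- ere_pwm(score_threshold_frac = 1)
  expect_true(contains_motif(pk_good, g, strict))  # exact consensus planted
})

test_that("raising the score threshold never gains motif calls", {
  set.seed(63)
  g <- toy_genome(c1 = rand_dna(20000))
  st <- seq(1000L, 15000L, by = 1000L)
  peaks <- new_peaks("c1", st, st + 200L, summit = st + 100L)
  prev <- Inf
  for (frac in c(0.2, 0.5, 0.8, 1)) {
    n <- ere_ratio(peaks, g, ere_pwm(score_threshold_frac = frac))$n_with_motif
    expect_lte(n, prev)
    prev <- n
  }
})

test_that("containment ratio is strand-symmetric", {
  set.seed(64)
  bg <- rand_dna(3000)
  g <- toy_genome(c1 = paste0(substr(bg, 1, 1493), "GGTCAGCATGACC",
                              substr(bg, 1507, 3000)))
  L <- nchar(g[["c1"]])
  peaks <- new_peaks("c1", c(1400, 400), c(1600, 600),
                     summit = c(1500, 500), id = c("a", "b"))
  fwd <- ere_ratio(peaks, g)
  grc <- toy_genome(c1 = revcomp_string(g[["c1"]]))
  mirrored <- peaks
  mirrored$start <- L - peaks$end
  mirrored$end <- L - peaks$start
  mirrored$summit <- L - 1L - peaks$summit
  rev <- ere_ratio(mirrored, grc)
  expect_equal(fwd$ratio, rev$ratio)
  expect_equal(unname(fwd$has_motif), unname(rev$has_motif))
})

test_that("set-level ratios count containment and handle empty sets", {
  set.seed(65)
  g <- toy_genome(c1 = rand_dna(5000))
  empty <- new_peaks(character(), integer(), integer())
  e <- ere_ratio(empty, g)
  expect_equal(e$n_total, 0L)
  expect_true(is.nan(e$ratio))
  peaks <- rand_peaks(5, chroms = "c1", max_pos = 4000L)
  r <- ere_ratio(peaks, g)
  expect_equal(r$ratio, r$n_with_motif / r$n_total)
  expect_lte(r$n_with_motif, r$n_total)
})

test_that("report-layer ratio arithmetic renders at two decimals", {
  expect_equal(containment_ratio(941, 1286)$ratio_2dp, 0.73)
  expect_equal(containment_ratio(0, 5)$ratio, 0)
  expect_true(is.nan(containment_ratio(0, 0)$ratio))
})

test_that("JASPAR-style PFM files round-trip through the reader", {
  f <- withr::local_tempfile(fileext = ".pfm")
  writeLines(c(">toy",
               "A [ 4 0 0 1 ]",
               "C [ 0 4 0 1 ]",
               "G [ 0 0 4 1 ]",
               "T [ 0 0 0 1 ]"), f)
  pwm <- read_jaspar_pfm(f)
  expect_equal(pwm$width, 4L)
  expect_equal(pwm$name, "toy")
  expect_equal(unname(pwm$freq[1, "A"]), 4.5 / 6)
  bare <- withr::local_tempfile(fileext = ".pfm")
  writeLines(c("4 0 0 1", "0 4 0 1", "0 0 4 1", "0 0 0 1"), bare)
  expect_equal(read_jaspar_pfm(bare)$log_odds, pwm$log_odds)
})
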