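# Feature encoding: window extraction, trigram presence, occupancy,
# primary-TF overlap, gene mapping, and the assembled 67-column matrix.

test_that("sequence windows are clamped at chromosome edges, never padded", {
  g <- toy_genome(c1 = rand_dna(1000))
  expect_equal(nchar(extract_window(g, "c1", 500, 300)), 600L)
  expect_identical(extract_window(g, "c1", 500, 300),
                   substr(g[["c1"]], 201, 800))
  expect_equal(nchar(extract_window(g, "c1", 10, 300)), 310L)
  expect_identical(extract_window(g, "c1", 10, 300), substr(g[["c1"]], 1, 310))
  expect_error(extract_window(g, "c1", 1000, 300), "outside")
  expect_error(extract_window(g, "c9", 10, 300), "not in genome")
})

test_that("trigram presence matches the sliding-window oracle on fuzzed 600-mers", {
  set.seed(21)
  expect_equal(unname(trigram_presence("AAAA")),
               c(1L, rep(0L, 63)))            # presence, not count
  expect_equal(sum(trigram_presence("")), 0L)
  expect_equal(sum(trigram_presence("AC")), 0L)
  for (rep in 1:100) {
    s <- rand_dna(600, alphabet = c("A", "C", "G", "T", "N"))
    expect_identical(trigram_presence(s), oracle_trigrams(s))
  }
  # windows containing N never match
  expect_equal(sum(trigram_presence("ANANANAN")), 0L)
})

test_that("trigram block agrees with Biostrings trinucleotide counts", {
  skip_if_not_installed("Biostrings")
  set.seed(22)
  for (rep in 1:20) {
    s <- rand_dna(300)
    counts <- Biostrings::trinucleotideFrequency(Biostrings::DNAString(s))
    expect_identical(unname(trigram_presence(s)),
                     unname(as.integer(counts > 0)))
  }
})

test_that("trigram block ignores sequence outside the flank window", {
  set.seed(23)
  g1 <- toy_genome(c1 = rand_dna(800))
  g2 <- toy_genome(c1 = paste0(substr(g1[["c1"]], 1, 700), rand_dna(500)))
  w1 <- extract_window(g1, "c1", 400, 300)
  w2 <- extract_window(g2, "c1", 400, 300)
  expect_identical(trigram_presence(w1), trigram_presence(w2))
})

test_that("occupancy bit uses a strict threshold on the inclusive window mean", {
  tr <- structure(list(c1 = rep(0.8, 1000)), class = "occupancy_track")
  expect_equal(occupancy_bit(tr, "c1", 500, chrom_length = 1000L), 1L)
  tr75 <- structure(list(c1 = rep(0.75, 1000)), class = "occupancy_track")
  expect_equal(occupancy_bit(tr75, "c1", 500, chrom_length = 1000L), 0L)
  # half 1.0 / half 0.4 -> mean 0.7 -> 0 (101 positions: 51 high, 50 low)
  v <- c(rep(1, 501), rep(0.4, 499))
  trh <- structure(list(c1 = v), class = "occupancy_track")
  m <- mean(v[451:551])
  expect_lt(m, 0.75)
  expect_equal(occupancy_bit(trh, "c1", 500, chrom_length = 1000L), 0L)
  # missing chromosome defaults to zero occupancy
  expect_equal(occupancy_bit(tr, "c9", 500), 0L)
})

test_that("occupancy bit depends only on the window mean, not the layout", {
  set.seed(24)
  vals <- runif(101, 0.5, 1)
  mk <- function(v) structure(list(c1 = c(rep(0, 450), v, rep(0, 449))),
                              class = "occupancy_track")
  b1 <- occupancy_bit(mk(vals), "c1", 500, chrom_length = 1000L)
  b2 <- occupancy_bit(mk(sample(vals)), "c1", 500, chrom_length = 1000L)
  expect_equal(b1, b2)
})

test_that("primary-TF overlap bit needs >= 1 shared bp and is monotone", {
  p <- new_peaks("chr1", 100, 200)[1, ]
  er1 <- new_peaks("chr1", 150, 160, id = "e1", source = "er")
  expect_equal(er_overlap_bit(p, er1), 1L)
  expect_equal(er_overlap_bit(p, NULL), 0L)
  abut <- new_peaks("chr1", 200, 300, id = "e2", source = "er")
  expect_equal(er_overlap_bit(p, abut), 0L)
  # adding a peak can only flip 0 -> 1
  set.seed(25)
  for (rep in 1:20) {
    ers <- rand_peaks(sample(0:5, 1), source = "er")
    more <- rbind(ers, rand_peaks(1, source = "er2"))
    expect_gte(er_overlap_bit(p, more), er_overlap_bit(p, ers))
  }
})

test_that("gene mapping takes the nearest TSS with deterministic ties", {
  genes <- data.frame(gene_id = c("g1", "g2"), chrom = "chr1",
                      tss = c(480L, 900L), strand = "+",
                      sensitive = c(FALSE, TRUE))
  pk <- new_peaks("chr1", 400, 600, summit = 500)[1, ]
  expect_equal(map_peak_to_gene(pk, genes), "g1")
  tie <- data.frame(gene_id = c("gA", "gB"), chrom = "chr1",
                    tss = c(400L, 600L), strand = "+", sensitive = FALSE)
  expect_equal(map_peak_to_gene(pk, tie), "gA")   # smaller tss wins the tie
  expect_equal(map_peak_to_gene(pk, genes, max_distance = 10), NA_character_)
  far <- data.frame(gene_id = "g9", chrom = "chr1", tss = 60500L,
                    strand = "+", sensitive = TRUE)
  expect_equal(map_peak_to_gene(pk, far, max_distance = 50000), NA_character_)
  expect_equal(sensitive_gene_bit(pk, far, max_distance = 50000), 0L)
})

test_that("sensitive-gene bit only honours the mapped gene", {
  pk <- new_peaks("chr1", 400, 600, summit = 500)[1, ]
  genes <- data.frame(gene_id = c("near", "far"), chrom = "chr1",
                      tss = c(520L, 900L), strand = "+",
                      sensitive = c(FALSE, TRUE))
  expect_equal(sensitive_gene_bit(pk, genes), 0L)  # a farther sensitive gene does not count
  genes$sensitive <- c(TRUE, FALSE)
  expect_equal(sensitive_gene_bit(pk, genes), 1L)
  none <- data.frame(gene_id = "g", chrom = "chr2", tss = 1L, strand = "+",
                     sensitive = TRUE)
  expect_equal(sensitive_gene_bit(pk, none), 0L)
})

test_that("the assembled matrix is 67 columns matching per-feature oracles", {
  set.seed(26)
  g <- toy_genome(c1 = rand_dna(5000), c2 = rand_dna(5000))
  peaks <- rand_peaks(5, chroms = c("c1", "c2"), max_pos = 4000L)
  tr <- structure(list(c1 = runif(5000), c2 = runif(5000)),
                  class = "occupancy_track")
  ers <- rand_peaks(4, chroms = c("c1", "c2"), max_pos = 4000L, source = "er")
  genes <- data.frame(gene_id = sprintf("g%d", 1:6),
                      chrom = sample(c("c1", "c2"), 6, replace = TRUE),
                      tss = sample.int(5000, 6) - 1L, strand = "+",
                      sensitive = c(TRUE, FALSE, TRUE, FALSE, FALSE, TRUE))
  x <- build_feature_matrix(peaks, g, tr, ers, genes)
  expect_equal(dim(x), c(5L, 67L))
  expect_true(all(x %in% 0:1))
  expect_equal(colnames(x)[1:64], paste0("tri_", trigram_names()))
  expect_equal(colnames(x)[65:67], c("occ", "er_overlap", "sensitive_gene"))
  for (i in 1:5) {
    p <- peaks[i, , drop = FALSE]
    win <- extract_window(g, p$chrom, p$summit, 300)
    expect_identical(x[i, 1:64], oracle_trigrams(win))
    expect_equal(x[i, "occ"],
                 occupancy_bit(tr, p$chrom, p$summit, 50, 0.75,
                               chrom_length = 5000L),
                 ignore_attr = TRUE)
    expect_equal(x[i, "er_overlap"], er_overlap_bit(p, ers),
                 ignore_attr = TRUE)
    expect_equal(x[i, "sensitive_gene"], sensitive_gene_bit(p, genes),
                 ignore_attr = TRUE)
  }
  # all-N window zeroes the trigram block
  gN <- toy_genome(c1 = paste(rep("N", 2000), collapse = ""))
  pN <- new_peaks("c1", 900, 1100, summit = 1000)
  expect_equal(sum(build_feature_matrix(pN, gN)[, 1:64]), 0L)
  # unknown chromosome names the offending peak
  bad <- new_peaks("c9", 1, 10, id = "oops")
  expect_error(build_feature_matrix(bad, g), "oops")
})
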