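test_that("window counts bin fragment midpoints exclusively", {
  build <- genome_build(c(chr1 = 2000, chr2 = 1100))
  f1 <- fragment_set(interval_tbl("chr1", 700, 950), sample_id = "s1",
                     condition = "A")  # midpoint 825 -> window 4 (750-1000)
  wc <- window_counts(list(f1), build, w = 250)
  expect_equal(nrow(wc$windows), 8 + 5)
  expect_equal(unname(wc$counts[4, 1]), 1L)
  expect_equal(sum(wc$counts), 1L)
  # last window on chr2 is short
  last2 <- wc$windows[wc$windows$chrom == "chr2", ]
  expect_equal(max(last2$end), 1100)
  expect_equal(last2$end[5] - last2$start[5], 100)
  # conservation and oracle on random data
  set.seed(13)
  f <- random_intervals(400, list(chr1 = 2000, chr2 = 1100), 250)
  fs <- fragment_set(f, sample_id = "s", condition = "A")
  wc2 <- window_counts(list(fs, fs), build, w = 250)
  expect_equal(colSums(wc2$counts), c(s = 400L, s.1 = 400L))
  mid <- floor((f$start + f$end) / 2)
  key <- paste0(f$chrom, ":", floor(mid / 250))
  want <- as.integer(table(key)[paste0(wc2$windows$chrom, ":",
                                       floor(wc2$windows$start / 250))])
  want[is.na(want)] <- 0L
  expect_equal(wc2$counts[, 1], want, ignore_attr = TRUE)
})

test_that("exact test is symmetric, monotone, and binomial in the phi=0 limit", {
  # equal counts, equal libraries -> p = 1, logFC = 0
  r <- nb_exact_test(5, 5, 1e6, 1e6, phi = 0.1)
  expect_equal(r$p_value, 1)
  expect_equal(r$logfc, 0)
  # group swap: p invariant, logFC negated
  a <- matrix(c(3, 7), 1); b <- matrix(c(12, 15), 1)
  r1 <- nb_exact_test(a, b, c(1e6, 1e6), c(1e6, 1e6), 0.05)
  r2 <- nb_exact_test(b, a, c(1e6, 1e6), c(1e6, 1e6), 0.05)
  expect_equal(r1$p_value, r2$p_value)
  expect_equal(r1$logfc, -r2$logfc)
  # monotonicity in the split for fixed total
  tot <- 40
  ps <- vapply(0:20, function(k) {
    nb_exact_test(k, tot - k, 1e6, 1e6, 0.1)$p_value
  }, numeric(1))
  expect_true(all(diff(ps) >= -1e-12))
  # phi = 0 equals the two-sided binomial exact test on a grid
  for (ab in list(c(0, 7), c(3, 4), c(10, 30), c(25, 25), c(1, 49))) {
    got <- nb_exact_test(ab[1], ab[2], 1e6, 1e6, 0)$p_value
    want <- stats::binom.test(ab[1], sum(ab), 0.5)$p.value
    expect_equal(got, want, tolerance = 1e-9)
  }
  expect_error(nb_exact_test(1, 1, 1, 1, phi = -0.1), ">= 0")
})

test_that("exact test agrees with edgeR's exact NB test on pooled 1v1 data", {
  skip_if_not_installed("edgeR")
  set.seed(31)
  y <- matrix(rnbinom(400, mu = 25, size = 10), ncol = 2)
  lib <- c(1e6, 1e6)
  ours <- nb_exact_test(y[, 1, drop = FALSE], y[, 2, drop = FALSE],
                        lib[1], lib[2], phi = 0.1)
  p_edger <- edgeR::exactTest(
    edgeR::DGEList(counts = y, lib.size = lib, group = c(1, 2)),
    dispersion = 0.1, rejection.region = "smallp")$table$PValue
  expect_equal(ours$p_value, p_edger, tolerance = 1e-6)
})

test_that("common dispersion is recovered and degenerates to Poisson", {
  set.seed(17)
  n <- 6000
  counts <- cbind(matrix(rnbinom(2 * n, mu = 20, size = 10), ncol = 2),
                  matrix(rnbinom(2 * n, mu = 20, size = 10), ncol = 2))
  wc <- list(counts = counts, conditions = c("A", "A", "B", "B"),
             library_sizes = rep(1e6, 4))
  est <- estimate_common_dispersion(wc)
  expect_true(abs(est$phi - 0.1) < 0.03)
  # Poisson truth
  pois <- list(counts = matrix(rpois(4 * n, 20), ncol = 4),
               conditions = c("A", "A", "B", "B"),
               library_sizes = rep(1e6, 4))
  expect_true(estimate_common_dispersion(pois)$phi <= 0.02)
  # constant counts across replicates -> 0
  const <- list(counts = matrix(7L, 100, 4),
                conditions = c("A", "A", "B", "B"),
                library_sizes = rep(1e6, 4))
  expect_equal(estimate_common_dispersion(const)$phi, 0)
  # no replicate structure -> prior with warning
  single <- list(counts = matrix(rpois(200, 10), ncol = 2),
                 conditions = c("A", "B"), library_sizes = rep(1e6, 2))
  expect_warning(est1 <- estimate_common_dispersion(single), "replicate")
  expect_equal(est1$phi, 0.05)
})

test_that("DhMR calling merges adjacent same-direction windows across small gaps", {
  build <- genome_build(c(chr1 = 2500))
  wc <- window_counts(list(fragment_set(interval_tbl("chr1", 0, 10),
                                        condition = "A")), build, 250)
  stats <- tibble::tibble(
    p_value = c(0.01, 0.02, 0.01, 0.9, 0.03, 0.9, 0.9, 0.01, 0.01, 0.6),
    logfc = c(1, 1.5, 1, 0.1, 2, 0, 0, -1, -2, 0),
    total = c(10, 20, 10, 5, 8, 1, 1, 9, 12, 2))
  dh <- call_dhmrs(wc, stats, alpha = 0.05, max_gap_windows = 1)
  # windows 1-3 and 5 bridge the gap at 4; 8-9 form a loss region
  expect_equal(nrow(dh), 2)
  gain <- dh[dh$direction == "gain", ]
  expect_equal(gain$start, 0); expect_equal(gain$end, 1250)
  expect_equal(gain$n_windows, 4L)
  expect_equal(gain$p_value, 0.01)
  expect_equal(gain$logfc,
               sum(c(1, 1.5, 1, 2) * c(10, 20, 10, 8)) / sum(c(10, 20, 10, 8)))
  loss <- dh[dh$direction == "loss", ]
  expect_equal(c(loss$start, loss$end), c(1750, 2250))
  # no significant windows -> empty
  none <- call_dhmrs(wc, dplyr::mutate(stats, p_value = 0.5), alpha = 0.05)
  expect_equal(nrow(none), 0)
  # max_gap 0 splits at the gap
  dh0 <- call_dhmrs(wc, stats, alpha = 0.05, max_gap_windows = 0)
  expect_equal(sum(dh0$direction == "gain"), 2)
})

test_that("gene-level NB differential expression controls the null", {
  set.seed(23)
  n <- 400
  counts <- matrix(rnbinom(4 * n, mu = 50, size = 20), ncol = 4,
                   dimnames = list(paste0("g", 1:n), NULL))
  de <- differential_expression_nb(counts, c("A", "A", "B", "B"),
                                   lib_sizes = rep(2e4, 4))
  expect_true(mean(de$significant) <= 0.02)
  # identical count vectors -> q = 1 everywhere
  same <- cbind(counts[, 1:2], counts[, 1:2])
  de2 <- differential_expression_nb(same, c("A", "A", "B", "B"))
  expect_equal(de2$p, rep(1, n), tolerance = 1e-9)
  expect_equal(de2$q, rep(1, n), tolerance = 1e-9)
  # planted 4-fold genes are found
  counts2 <- counts
  counts2[1:40, 3:4] <- matrix(rnbinom(80, mu = 200, size = 20), ncol = 2)
  de3 <- differential_expression_nb(counts2, c("A", "A", "B", "B"),
                                    lib_sizes = rep(2e4, 4))
  expect_true(mean(de3$significant[1:40] & de3$direction[1:40] == "up") >= 0.9)
  expect_error(differential_expression_nb(counts[, 1:2], c("A", "B")),
               "2 replicates")
})

test_that("DhMR/expression integration respects the 'solely' rule", {
  g <- gene_tbl(c("g1", "g2", "g3"), "chr1",
                c(0, 20000, 40000), c(10000, 30000, 50000))
  dhmrs <- tibble::tibble(
    chrom = "chr1", start = c(1000, 21000, 22000, 41000),
    end = c(1500, 21500, 22500, 41500),
    direction = c("gain", "gain", "loss", "loss"),
    logfc = c(1, 1, -1, -1), p_value = 0.01, n_windows = 1L)
  de <- tibble::tibble(gene_id = c("g1", "g2", "g3"),
                       log2fc = c(2, 0.5, -2), p = c(0.001, 0.5, 0.001),
                       q = c(0.004, 0.6, 0.004),
                       direction = c("up", "up", "down"))
  ov <- dhmr_expression_overlap(dhmrs, g, de)
  expect_equal(ov$gain_only, "g1")     # g2 has gain AND loss -> excluded
  expect_equal(ov$loss_only, "g3")
  expect_equal(ov$gain_and_up, "g1")
  expect_equal(ov$loss_and_down, "g3")
  expect_error(dhmr_expression_overlap(dhmrs, g, de[1:2, ]), "lacks gene")
})
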