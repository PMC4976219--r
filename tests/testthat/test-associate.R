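test_that("Mann-Whitney matches exhaustive permutation for all small cases", {
  set.seed(51)
  for (rep in 1:30) {
    nx <- sample(2:8, 1); ny <- sample(2:8, 1)
    # mixture with ties to exercise mid-ranks
    x <- sample(c(rnorm(nx), sample(1:3, nx, TRUE)), nx)
    y <- sample(c(rnorm(ny), sample(1:3, ny, TRUE)), ny)
    got <- mann_whitney(x, y)$p_value
    expect_equal(got, exhaustive_mw_p(x, y), tolerance = 1e-12)
  }
})

test_that("fully separated small groups give the known enumeration p", {
  mw <- mann_whitney(1:5, 11:15)
  expect_equal(mw$p_value, 2 / 252)
  expect_equal(mw$u, 0)
  # identical equal samples: U = n^2/2, p = 1 by symmetry
  mw2 <- mann_whitney(c(1, 2, 3), c(1, 2, 3))
  expect_equal(mw2$u, 4.5)
  expect_equal(mw2$p_value, 1)
  expect_error(mann_whitney(numeric(0), 1:3), "non-empty")
})

test_that("large-sample path approximates the exact p and is rank-invariant", {
  set.seed(52)
  x <- rnorm(60); y <- rnorm(80, 0.7)
  p_norm <- mann_whitney(x, y)$p_value
  p_wilcox <- stats::wilcox.test(x, y, correct = TRUE)$p.value
  expect_equal(p_norm, p_wilcox, tolerance = 0.05)
  # invariance under strictly monotone transforms
  expect_equal(mann_whitney(exp(x), exp(y))$p_value, p_norm)
  expect_equal(mann_whitney(rank(c(x, y))[1:60],
                            rank(c(x, y))[61:140])$p_value, p_norm)
})

test_that("tidy/glance on Mann-Whitney results are tibbles", {
  mw <- mann_whitney(1:6, 4:9, labels = c("low", "high"))
  td <- tidy(mw)
  expect_equal(td$group, c("low", "high"))
  expect_equal(td$n, c(6L, 6L))
  gl <- glance(mw)
  expect_equal(gl$n_total, 12)
  expect_true(gl$p_value <= 1)
})

test_that("expression by position class reports each class against all genes", {
  set.seed(53)
  n <- 120
  expr <- tibble::tibble(gene_id = paste0("g", 1:n), rpkm = exp(rnorm(n)))
  cls <- tibble::tibble(
    gene_id = expr$gene_id,
    class = factor(rep(c("gb_only", "none", "none", "promoter_only"), n / 4),
                   levels = c("promoter_only", "gb_only", "promoter_and_gb",
                              "none")))
  out <- expression_by_position_class(expr, cls)
  expect_equal(out$class, c("promoter_only", "gb_only", "promoter_and_gb"))
  expect_equal(out$n[3], 0L)
  expect_true(is.na(out$p_value[3]))
  expect_false(anyNA(out$p_value[1:2]))
  # planted shift is detected
  expr2 <- expr
  expr2$rpkm[cls$class == "gb_only"] <- expr2$rpkm[cls$class == "gb_only"] * 6
  out2 <- expression_by_position_class(expr2, cls)
  expect_lt(out2$p_value[out2$class == "gb_only"], 0.01)
  expect_gt(out2$median[out2$class == "gb_only"], out2$median_all[1])
})

test_that("quartile assignment partitions expressed genes evenly", {
  set.seed(54)
  n <- 103
  expr <- tibble::tibble(gene_id = paste0("g", 1:n), rpkm = runif(n, 1, 50))
  cov <- tibble::tibble(gene_id = expr$gene_id, rpkm = runif(n))
  qt <- quartile_trend(expr, cov, n_perm = 200, seed = 4)
  expect_equal(sum(qt$quartiles$n), n)
  expect_true(max(qt$quartiles$n) - min(qt$quartiles$n) <= 1)
  # genes under the expression floor are excluded
  expr$rpkm[1:10] <- 0.2
  qt2 <- quartile_trend(expr, cov, n_perm = 200, seed = 4)
  expect_equal(qt2$n_genes, n - 10)
  expect_error(quartile_trend(expr[1:5, ], cov[1:5, ]), "fewer than 8")
})

test_that("quartile trend recovers planted coupling and stays flat when constant", {
  set.seed(55)
  n <- 200
  expr <- tibble::tibble(gene_id = paste0("g", 1:n), rpkm = exp(rnorm(n, 2)))
  cov <- tibble::tibble(gene_id = expr$gene_id,
                        rpkm = rank(expr$rpkm) / n + rnorm(n, 0, 0.05))
  qt <- quartile_trend(expr, cov, n_perm = 2000, seed = 9)
  med <- qt$quartiles$median_coverage
  expect_true(all(diff(med) > 0))
  expect_lt(qt$trend_p, 0.001)
  # constant coverage -> flat medians, p = 1
  cov0 <- tibble::tibble(gene_id = expr$gene_id, rpkm = 1)
  qt0 <- quartile_trend(expr, cov0, n_perm = 200, seed = 9)
  expect_equal(diff(qt0$quartiles$median_coverage), rep(0, 3))
  expect_equal(qt0$trend_p, 1)
})

test_that("histone co-marking compares the four joint groups with BH", {
  set.seed(56)
  n <- 160
  ids <- paste0("g", 1:n)
  hmc <- ids[1:80]
  mark <- ids[41:120]
  expr <- tibble::tibble(gene_id = ids, rpkm = exp(rnorm(n)))
  both <- intersect(hmc, mark)
  expr$rpkm[expr$gene_id %in% both] <- expr$rpkm[expr$gene_id %in% both] * 8
  out <- histone_comarking(expr, hmc, list(H3K79me2 = mark))
  g <- out$groups
  expect_equal(sum(g$n), n)
  expect_equal(g$median[g$group == "both"], max(g$median))
  cmp <- out$comparisons
  expect_equal(nrow(cmp), 6)
  both_vs <- cmp[cmp$group_a == "both" | cmp$group_b == "both", ]
  expect_true(all(both_vs$q_value <= 0.01))
  # mark set identical to 5-hmC set -> the "only" groups are empty, NA rows
  out2 <- histone_comarking(expr, hmc, list(m = hmc))
  expect_true(any(out2$groups$n == 0))
  expect_true(anyNA(out2$comparisons$p_value))
})

test_that("demethylation groups are nested by default, exclusive on request", {
  deltas <- tibble::tibble(gene_id = paste0("g", 1:5),
                           delta_mcg = c(-12, -0.5, -22, -16, -2))
  cov <- tibble::tibble(gene_id = deltas$gene_id, rpkm = c(5, 1, 9, 7, 2))
  out <- demethylation_grouping(deltas, cov)
  expect_equal(out$threshold, c(-1, -10, -15, -20))
  # gene with delta = -12 is in the -1 and -10 groups only
  expect_equal(out$n, c(4L, 3L, 2L, 1L))
  ex <- demethylation_grouping(deltas, cov, mode = "exclusive")
  expect_equal(ex$n, c(1L, 1L, 1L, 1L))
  # planted slope: deeper demethylation, higher coverage
  expect_true(all(diff(out$median_coverage) > 0))
  # all deltas zero -> all groups empty
  zero <- demethylation_grouping(
    tibble::tibble(gene_id = deltas$gene_id, delta_mcg = 0), cov)
  expect_true(all(zero$n == 0))
  expect_error(demethylation_grouping(
    tibble::tibble(gene_id = "g", delta_mcg = -120), cov), "-100")
})

test_that("repeat-class reads-in-peaks are library-normalized means", {
  repeats <- tibble::tibble(chrom = "chr1", start = c(0, 5000),
                            end = c(1000, 6000),
                            repeat_class = c("LINE", "SINE"))
  peaks <- interval_tbl("chr1", c(100, 5100), c(900, 5900))
  f1 <- fragment_set(interval_tbl("chr1", c(200, 300, 5200), c(450, 550, 5450)),
                     library_size = 1000)
  f2 <- fragment_set(interval_tbl("chr1", 250, 500), library_size = 500)
  out <- repeat_hmc_expression(list(f1, f2), peaks, repeats)
  expect_equal(out$value[out$repeat_class == "LINE"],
               mean(c(2 / 1000, 1 / 500)))
  expect_equal(out$value[out$repeat_class == "SINE"],
               mean(c(1 / 1000, 0)))
  # doubling fragments and library leaves values unchanged
  f1x <- fragment_set(dplyr::bind_rows(f1$fragments, f1$fragments),
                      library_size = 2000)
  out2 <- repeat_hmc_expression(list(f1x), peaks, repeats)
  expect_equal(out2$value[1], 2 / 1000)
  # no peaks over repeats -> zero
  out0 <- repeat_hmc_expression(list(f1), interval_tbl("chr1", 9000, 9500),
                                repeats)
  expect_true(all(out0$value == 0))
  # correlation with supplied repeat expression
  re <- tibble::tibble(repeat_class = c("LINE", "SINE"),
                       expression = c(10, 1))
  outc <- repeat_hmc_expression(list(f1, f2), peaks, repeats,
                                repeat_expression = re)
  expect_true("expression" %in% names(outc))
})

test_that("mark coverage over elements split by 5-hmC detects planted depletion", {
  set.seed(57)
  n_el <- 30
  elements <- tibble::tibble(chrom = "chr1",
                             start = seq(0, by = 2000, length.out = n_el),
                             end = seq(1000, by = 2000, length.out = n_el))
  hmc_peaks <- elements[1:15, ]
  mark_peaks <- elements  # every element is mark-enriched
  # plant depletion: few fragments on hmc+ elements, many on hmc-
  frag_rows <- lapply(seq_len(n_el), function(i) {
    k <- if (i <= 15) 2 else 20
    mids <- floor(runif(k, elements$start[i] + 100, elements$end[i] - 100))
    tibble::tibble(chrom = "chr1", start = mids - 50, end = mids + 50)
  })
  mf <- fragment_set(dplyr::bind_rows(frag_rows), library_size = 1e5)
  out <- mark_over_element_groups(mf, mark_peaks, elements, hmc_peaks)
  expect_equal(sum(out$elements$hmc_status == "hmc_pos"), 15)
  cmp <- out$comparison
  expect_lt(cmp$p_value, 0.01)
  expect_lt(cmp$groups$median[cmp$groups$group == "hmc_pos"],
            cmp$groups$median[cmp$groups$group == "hmc_neg"])
  # no hmc+ elements -> NA comparison
  out0 <- mark_over_element_groups(mf, mark_peaks, elements,
                                   interval_tbl("chr2", 0, 10))
  expect_null(out0$comparison)
})
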