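# small, fast configuration reused across generator tests
small_cfg <- function(seed = 1, ...) {
  synth_config(seed = seed, n_chroms = 2, chrom_length = 6e5, n_genes = 100,
               n_enhancers = 40, n_repeats = 40, n_planted_dhmrs = 10,
               n_background_conserved = 30, ...)
}

test_that("the same seed reproduces the bundle byte for byte", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  synth_generate(small_cfg(seed = 5), d1)
  synth_generate(small_cfg(seed = 5), d2)
  files <- list.files(d1, recursive = TRUE)
  expect_gt(length(files), 10)
  for (f in files) {
    expect_identical(readBin(file.path(d1, f), "raw", 5e6),
                     readBin(file.path(d2, f), "raw", 5e6), label = f)
  }
  # a different seed changes the data
  d3 <- withr::local_tempdir()
  synth_generate(small_cfg(seed = 6), d3)
  expect_false(identical(readBin(file.path(d1, "fragments/adult_rep1.bed"), "raw", 5e6),
                         readBin(file.path(d3, "fragments/adult_rep1.bed"), "raw", 5e6)))
})

test_that("every emitted file parses back and the manifest sizes are exact", {
  d <- withr::local_tempdir()
  ds <- synth_generate(small_cfg(seed = 2), d)
  man <- read_manifest(d)
  expect_equal(nrow(man), 4 * 2 + 4)  # 4 conditions x 2 IP reps + 4 inputs
  for (i in seq_len(nrow(man))) {
    frags <- read_bed(file.path(d, man$path[i]))
    expect_equal(nrow(frags), man$library_size[i])
  }
  genes <- read_bed12(file.path(d, "genes.bed12"))
  expect_equal(nrow(genes), 100)
  expect_equal(genes$gene_id, ds$genes$gene_id)
  build <- read_chrom_sizes(file.path(d, "chrom.sizes"))
  expect_equal(names(build), c("chr1", "chr2"))
  expr <- readr::read_tsv(file.path(d, "expression.tsv"),
                          show_col_types = FALSE)
  expect_equal(names(expr), c("gene_id", "E14.5", "neonatal", "adult", "TAC"))
  # truth round-trips through JSON
  tr <- read_truth(d)
  expect_equal(tr$conditions, c("E14.5", "neonatal", "adult", "TAC"))
  expect_equal(nrow(tr$dhmrs), 10)
  expect_equal(tr$genes$gene_id, genes$gene_id)
  # planted DhMRs lie within the genome
  expect_true(all(tr$dhmrs$end <= 6e5))
  # peak files are valid BED and fall inside the genome
  pk <- read_bed(file.path(d, "peaks", "TAC_rep1_hmc_peaks.bed"))
  expect_true(all(pk$end <= 6e5))
})

test_that("zero coupling leaves expression and gene-body rates unlinked", {
  d <- withr::local_tempdir()
  ds <- synth_generate(
    synth_config(seed = 3, n_chroms = 2, chrom_length = 2e6, n_genes = 500,
                 coupling_strength = 0, frac_stage_specific = 0,
                 enhancer_boost = 1, n_enhancers = 0, n_repeats = 0,
                 n_planted_dhmrs = 0, n_background_conserved = 0), d)
  # true per-gene GB rate is flat in expression when coupling is off; compare
  # realized fragment counts in gene bodies against expression rank
  genes <- ds$genes
  man <- ds$manifest
  frags <- read_bed(file.path(d, man$path[man$sample == "adult_rep1"]))
  counts <- count_overlaps(frags, genes)
  expr <- readr::read_tsv(file.path(d, "expression.tsv"),
                          show_col_types = FALSE)
  rho <- cor(expr$adult, counts / (genes$end - genes$start),
             method = "spearman")
  expect_lt(abs(rho), 0.1)
})

test_that("positive coupling produces monotone quartile rates by construction", {
  expr <- exp(rnorm(200, 2))
  rates <- plant_expression_coupling(expr, coupling_strength = 1)
  expect_true(all(diff(rates[order(expr)]) >= 0))
  # equal expression -> equal rates
  r2 <- plant_expression_coupling(c(4, 4, 9), 1)
  expect_equal(r2[1], r2[2])
  # quartile medians of true rates strictly increase
  q <- cut(rank(expr, ties.method = "first"), 4, labels = FALSE)
  med <- tapply(rates, q, median)
  expect_true(all(diff(med) > 0))
  expect_error(plant_expression_coupling(c(1, 0)), "strictly positive")
})

test_that("planted two-fold regions double the fragment rate at depth", {
  d <- withr::local_tempdir()
  cfg <- synth_config(seed = 9, n_chroms = 1, chrom_length = 8e5, n_genes = 30,
                      conditions = c("A", "B"), coupling_strength = 0,
                      frac_stage_specific = 0, n_enhancers = 0, n_repeats = 0,
                      n_background_conserved = 0, n_planted_dhmrs = 50,
                      dhmr_fold = 2, dhmr_width = 1000,
                      background_rate = 0.06, dhmr_base_rate = 0.06,
                      gb_base_rate = 0.02, peak_rate = 0.05)
  ds <- synth_generate(cfg, d)
  tr <- ds$truth$dhmrs
  man <- ds$manifest
  count_in <- function(sample, iv) {
    f <- read_bed(file.path(d, man$path[man$sample == sample]))
    mid <- floor((f$start + f$end) / 2)
    vapply(seq_len(nrow(iv)), function(i) {
      sum(f$chrom == iv$chrom[i] & mid >= iv$start[i] & mid < iv$end[i])
    }, numeric(1))
  }
  gains <- tr[tr$direction == "gain", ]
  low <- count_in("A_rep1", gains) + count_in("A_rep2", gains)
  high <- count_in("B_rep1", gains) + count_in("B_rep2", gains)
  expect_equal(mean(high) / mean(low), 2, tolerance = 0.1)
})

test_that("enhancer planting boosts the nearest gene and respects frac_hmc_pos", {
  d <- withr::local_tempdir()
  ds <- synth_generate(
    synth_config(seed = 4, n_chroms = 2, chrom_length = 6e5, n_genes = 100,
                 n_enhancers = 60, frac_hmc_pos = 0.3, n_repeats = 40,
                 n_planted_dhmrs = 10, n_background_conserved = 30), d)
  enh <- ds$truth$enhancers
  frac <- mean(enh$hmc_status == "positive")
  ci <- stats::qbinom(c(0.005, 0.995), 60, 0.3) / 60
  expect_gte(frac, ci[1]); expect_lte(frac, ci[2])
  # boost = 2: positive-adjacent genes about twice the negative group
  expr <- ds$truth$expression
  med_pos <- median(expr$adult[expr$gene_id %in%
                                 enh$nearest_gene_id[enh$hmc_status == "positive"]])
  med_neg <- median(expr$adult[expr$gene_id %in%
                                 setdiff(enh$nearest_gene_id[enh$hmc_status == "negative"],
                                         enh$nearest_gene_id[enh$hmc_status == "positive"])])
  expect_gt(med_pos / med_neg, 1.3)
  # frac_hmc_pos = 0 -> no positive enhancers anywhere
  d0 <- withr::local_tempdir()
  ds0 <- synth_generate(small_cfg(seed = 4, frac_hmc_pos = 0), d0)
  expect_true(all(ds0$truth$enhancers$hmc_status == "negative"))
  # boost = 1 leaves expression unmodified relative to boost applied
  expect_true(all(ds0$truth$expression[, -1] > 0))
})

test_that("degenerate configurations are rejected", {
  d <- withr::local_tempdir()
  expect_error(synth_generate(synth_config(n_genes = 0, coupling_strength = 1),
                              d), "zero genes")
  expect_error(synth_config(enhancer_boost = 0.5))
  expect_error(synth_config(frac_hmc_pos = 1.5))
  expect_error(
    synth_generate(synth_config(n_chroms = 1, chrom_length = 5e4,
                                n_genes = 40), withr::local_tempdir()),
    "too small")
})
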