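# one toy locus reused across the enhancer tests
enh_genes <- function() {
  gene_tbl(c("gA", "gB"), "chr1", c(20000, 60000), c(30000, 70000),
           strand = c("+", "-"),
           exons = list(tibble::tibble(start = c(20000, 25000),
                                       end = c(21000, 30000)),
                        tibble::tibble(start = 60000, end = 70000)))
}

test_that("putative enhancers exclude any peak touching exons or promoters", {
  g <- enh_genes()
  peaks <- tibble::tibble(
    chrom = "chr1",
    start = c(5000,   # clean intergenic -> kept
              18999,  # ends 1 bp inside gA's promoter window -> excluded
              24500,  # overlaps exon 2 of gA -> excluded
              21500,  # intron of gA, outside promoter -> kept
              40000), # intergenic -> kept
    end = c(5800, 19100, 25400, 22500, 40900))
  enh <- define_putative_enhancers(peaks, g)
  expect_equal(enh$start, c(5000, 21500, 40000))
  # boundary: a peak overlapping the promoter window by exactly 1 bp is out
  one_bp <- tibble::tibble(chrom = "chr1", start = 18000, end = 19001)
  expect_equal(nrow(define_putative_enhancers(one_bp, g)), 0)
  just_out <- tibble::tibble(chrom = "chr1", start = 18000, end = 19000)
  expect_equal(nrow(define_putative_enhancers(just_out, g)), 1)
})

test_that("enhancer exclusion matches a brute-force oracle on random peaks", {
  g <- enh_genes()
  set.seed(61)
  peaks <- random_intervals(200, list(chr1 = 100000), max_width = 1200)
  got <- define_putative_enhancers(peaks, g)
  excl <- dplyr::bind_rows(
    tibble::tibble(chrom = "chr1", start = c(20000, 25000, 60000),
                   end = c(21000, 30000, 70000)),           # exons
    tibble::tibble(chrom = "chr1", start = c(19000, 68999),
                   end = c(21000, 70999)))                  # promoters
  keep <- vapply(seq_len(nrow(peaks)), function(i) {
    !any(peaks$start[i] < excl$end & peaks$end[i] > excl$start)
  }, logical(1))
  expect_equal(got$start, peaks$start[keep])
  expect_equal(got$end, peaks$end[keep])
})

test_that("5-hmC status is a >=1 bp overlap partition", {
  enh <- tibble::tibble(chrom = "chr1", start = c(0, 5000, 10000),
                        end = c(1000, 6000, 11000))
  hmc <- interval_tbl("chr1", c(0, 5999), c(1000, 6001))
  out <- classify_by_hmc(enh, hmc)
  expect_equal(out$hmc_status, c("positive", "positive", "negative"))
  # no 5-hmC peaks at all -> all negative
  none <- classify_by_hmc(enh, interval_tbl("chr1", 1, 2)[0, ])
  expect_true(all(none$hmc_status == "negative"))
})

test_that("nearest-gene assignment matches the all-pairs oracle with stable ties", {
  set.seed(62)
  genes <- gene_tbl(paste0("g", sprintf("%02d", 1:12)), "chr1",
                    seq(10000, 230000, by = 20000),
                    seq(10000, 230000, by = 20000) + 5000,
                    strand = rep(c("+", "-"), 6))
  enh <- random_intervals(60, list(chr1 = 240000), max_width = 900)
  got <- assign_nearest_gene(enh, genes)
  tss <- tss_position(genes)
  for (i in seq_len(nrow(enh))) {
    mid <- floor((enh$start[i] + enh$end[i]) / 2)
    d <- abs(mid - tss)
    best <- sort(genes$gene_id[d == min(d)])[1]  # lexicographic tie-break
    expect_equal(got$nearest_gene_id[i], best)
    expect_equal(got$distance_bp[i], min(d))
  }
  # exact tie goes to the smaller gene id
  g2 <- gene_tbl(c("gB", "gA"), "chr1", c(0, 2000), c(1000, 3000))
  mid_tie <- tibble::tibble(chrom = "chr1", start = 995, end = 1005)
  expect_equal(assign_nearest_gene(mid_tie, g2)$nearest_gene_id, "gA")
  # chromosome without genes -> unassigned with warning
  lonely <- tibble::tibble(chrom = "chr9", start = 0, end = 100)
  expect_warning(out <- assign_nearest_gene(lonely, g2), "unassigned")
  expect_true(is.na(out$nearest_gene_id))
})

test_that("expression contrast separates boosted nearest genes", {
  set.seed(63)
  n <- 100
  genes <- gene_tbl(paste0("g", sprintf("%03d", 1:n)), "chr1",
                    seq(0, by = 10000, length.out = n),
                    seq(4000, by = 10000, length.out = n))
  enh <- tibble::tibble(chrom = "chr1",
                        start = seq(5000, by = 10000, length.out = n),
                        end = seq(5800, by = 10000, length.out = n),
                        hmc_status = rep(c("positive", "negative"), n / 2))
  enh <- assign_nearest_gene(enh, genes)
  expr <- tibble::tibble(gene_id = genes$gene_id, rpkm = exp(rnorm(n)))
  boosted <- enh$nearest_gene_id[enh$hmc_status == "positive"]
  expr$rpkm[expr$gene_id %in% boosted] <- expr$rpkm[expr$gene_id %in% boosted] * 4
  mw <- enhancer_expression_contrast(enh, expr)
  expect_lt(mw$p_value, 0.01)
  expect_gt(mw$groups$median[1], mw$groups$median[2])
  # a group missing -> NULL
  only_pos <- enh[enh$hmc_status == "positive", ]
  expect_null(enhancer_expression_contrast(only_pos, expr))
})

test_that("conservation overlap filters elements by score and splits by status", {
  enh <- tibble::tibble(chrom = "chr1", start = c(0, 5000, 10000, 15000),
                        end = c(1000, 6000, 11000, 16000),
                        hmc_status = c("positive", "positive", "negative",
                                       "negative"))
  cons <- tibble::tibble(chrom = "chr1",
                         start = c(100, 5100, 10100), end = c(300, 5300, 10300),
                         score = c(700, 500, 800))
  out <- conservation_overlap(enh, cons, min_score = 600)
  expect_equal(out$fraction[out$hmc_status == "positive"], 0.5)
  expect_equal(out$fraction[out$hmc_status == "negative"], 0.5)
  # no element above threshold -> 0
  out0 <- conservation_overlap(enh, cons, min_score = 1000)
  expect_true(all(out0$fraction == 0))
  # elements tiling the genome -> 1 for both statuses
  tiling <- tibble::tibble(chrom = "chr1", start = 0, end = 20000,
                           score = 900)
  out1 <- conservation_overlap(enh, tiling)
  expect_true(all(out1$fraction == 1))
})

test_that("knockdown loss analysis recovers deleted enhancers and repression", {
  set.seed(64)
  n <- 60
  genes <- gene_tbl(paste0("g", sprintf("%03d", 1:n)), "chr1",
                    seq(0, by = 10000, length.out = n),
                    seq(4000, by = 10000, length.out = n))
  enh <- tibble::tibble(chrom = "chr1",
                        start = seq(5000, by = 10000, length.out = n),
                        end = seq(5600, by = 10000, length.out = n),
                        hmc_status = "positive")
  enh <- assign_nearest_gene(enh, genes)
  lost_idx <- 1:20
  loss_dhmrs <- tibble::tibble(chrom = "chr1",
                               start = enh$start[lost_idx] + 100,
                               end = enh$start[lost_idx] + 300,
                               direction = "loss")
  expr <- tibble::tibble(gene_id = genes$gene_id,
                         control = exp(rnorm(n, 2)))
  expr$kd <- expr$control
  affected_truth <- enh$nearest_gene_id[lost_idx]
  expr$kd[expr$gene_id %in% affected_truth] <-
    expr$kd[expr$gene_id %in% affected_truth] * 0.25
  out <- kd_enhancer_loss(enh, loss_dhmrs, expr)
  expect_setequal(out$affected_genes, affected_truth)
  expect_lt(out$comparison$p_value, 0.01)
  expect_lt(out$comparison$groups$median[1], out$comparison$groups$median[2])
  # no loss DhMRs -> empty
  out0 <- kd_enhancer_loss(enh, loss_dhmrs[0, ], expr)
  expect_equal(nrow(out0$lost_enhancers), 0)
  expect_equal(length(out0$affected_genes), 0)
})

test_that("enhancer records never intersect exons or promoter windows", {
  g <- enh_genes()
  set.seed(65)
  peaks <- random_intervals(300, list(chr1 = 100000), max_width = 1500)
  enh <- define_putative_enhancers(peaks, g)
  excl <- dplyr::bind_rows(
    hmcscape:::exon_intervals(g)[, c("chrom", "start", "end")],
    gene_promoters(g)[, c("chrom", "start", "end")])
  expect_equal(nrow(bed_intersect(enh[, c("chrom", "start", "end")], excl)), 0)
})
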