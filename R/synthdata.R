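#' Configuration for the synthetic hydroxymethylome study
#'
#' Defines a complete toy study emulating the profiled design: four
#' conditions (embryonic E14.5, neonatal, adult, TAC hypertrophy) with two
#' IP replicates each plus per-condition input controls, gene models,
#' expression, planted gene-body-5-hmC/expression coupling, planted
#' differential regions, hydroxymethylated enhancers boosting their nearest
#' gene, repeat classes, conserved elements and per-gene CpG-methylation
#' deltas. Fragments are fixed-length (250 bp, the sonication-size mode);
#' counts are Poisson per region with per-replicate lognormal rate jitter,
#' so replicate counts are over-dispersed (NB-like) while the generator
#' stays distinct from the inference model.
#'
#' @param seed master RNG seed.
#' @param n_chroms,chrom_length genome shape.
#' @param n_genes number of gene models.
#' @param conditions ordered condition labels.
#' @param replicates IP replicates per condition.
#' @param coupling_strength >= 0; strength of the monotone link between a
#'   gene's expression rank and its gene-body 5-hmC rate (0 = no link).
#' @param frac_gb_marked fraction of genes carrying peak-level gene-body
#'   5-hmC (sampled with expression-rank weighting when coupling > 0).
#' @param frac_promoter_only fraction of genes with promoter-only 5-hmC,
#'   drawn from the below-median expression stratum (mild repression).
#' @param frac_stage_specific fraction of genes whose expression and
#'   5-hmC both peak at one stage.
#' @param stage_boost multiplicative expression/5-hmC boost at the
#'   preferred stage.
#' @param n_planted_dhmrs,dhmr_fold,dhmr_width,dhmr_base_rate planted
#'   differential regions: count, fold change, width (bp) and baseline
#'   fragment rate (fragments/bp).
#' @param n_enhancers,frac_hmc_pos,enhancer_boost enhancer planting:
#'   count, fraction also 5-hmC marked, expression boost of the nearest
#'   gene of each 5-hmC+ enhancer.
#' @param n_repeats,tac_repeat_gain repeat annotation size and the 5-hmC
#'   gain over a subset of LINEs specific to the TAC condition.
#' @param background_rate,gb_base_rate,peak_rate,input_rate fragment rates
#'   per bp for genomic background, coupled gene-body coverage, peak-level
#'   enrichment and input libraries.
#' @param fragment_length fragment size (bp).
#' @param rep_sigma lognormal sigma of per-region, per-replicate rate
#'   jitter (drives replicate overdispersion).
#' @param peak_jitter max +/- jitter (bp) applied to peak-call edges per
#'   replicate.
#' @param methylation_slope percentage-point scale linking neonatal
#'   gene-body 5-hmC to adult-vs-neonatal CpG demethylation depth.
#' @param enhancer_conserved_prob probability a 5-hmC+ enhancer co-locates
#'   with a high-scoring conserved element.
#' @param n_background_conserved background conserved elements.
#' @param rna_phi,rna_depth NB dispersion and per-sample depth for the
#'   synthetic RNA count table.
#' @return List of class `synth_config`.
#' @export
synth_config <- function(seed = 1L,
                         n_chroms = 2L, chrom_length = 2e6,
                         n_genes = 300L,
                         conditions = c("E14.5", "neonatal", "adult", "TAC"),
                         replicates = 2L,
                         coupling_strength = 1,
                         frac_gb_marked = 0.35,
                         frac_promoter_only = 0.15,
                         frac_stage_specific = 0.2,
                         stage_boost = 4,
                         n_planted_dhmrs = 30L,
                         dhmr_fold = 2,
                         dhmr_width = 1000L,
                         dhmr_base_rate = 2e-3,
                         n_enhancers = 150L,
                         frac_hmc_pos = 0.3,
                         enhancer_boost = 2,
                         n_repeats = 150L,
                         tac_repeat_gain = 2,
                         background_rate = 2e-4,
                         gb_base_rate = 1e-3,
                         peak_rate = 4e-3,
                         input_rate = 5e-4,
                         fragment_length = 250L,
                         rep_sigma = 0.08,
                         peak_jitter = 50L,
                         methylation_slope = 25,
                         enhancer_conserved_prob = 0.6,
                         n_background_conserved = 100L,
                         rna_phi = 0.05, rna_depth = 2e5) {
  cfg <- as.list(environment())
  with(cfg, {
    stopifnot(n_chroms >= 1, chrom_length > 0, n_genes >= 0,
              length(conditions) >= 1, replicates >= 1,
              coupling_strength >= 0, n_planted_dhmrs >= 0,
              dhmr_fold >= 1, n_enhancers >= 0, enhancer_boost >= 1,
              stage_boost >= 1, tac_repeat_gain >= 1,
              frac_hmc_pos >= 0, frac_hmc_pos <= 1,
              frac_gb_marked >= 0, frac_gb_marked <= 1,
              frac_promoter_only >= 0, frac_promoter_only <= 1,
              frac_stage_specific >= 0, frac_stage_specific <= 1,
              enhancer_conserved_prob >= 0, enhancer_conserved_prob <= 1,
              background_rate >= 0, gb_base_rate >= 0, peak_rate >= 0,
              input_rate >= 0, fragment_length > 0, rep_sigma >= 0)
  })
  structure(cfg, class = "synth_config")
}

#' @export
print.synth_config <- function(x, ...) {
  cat(sprintf(
    "<synthetic study config> seed %s: %d x %s bp chromosomes, %d genes, %s x %d reps\n",
    format(x$seed), x$n_chroms, format(x$chrom_length, big.mark = ","),
    x$n_genes, paste(x$conditions, collapse = "/"), x$replicates))
  invisible(x)
}

# sample n non-overlapping intervals of the given widths from free space
sample_free_intervals <- function(free, n, widths, what = "intervals") {
  if (n == 0) return(empty_intervals())
  widths <- rep_len(widths, n)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    seg_len <- free$end - free$start
    ok_seg <- which(seg_len >= widths[i])
    if (length(ok_seg) == 0) {
      abort(sprintf("genome too small to place %d %s", n, what))
    }
    j <- ok_seg[sample.int(length(ok_seg), 1,
                           prob = seg_len[ok_seg] - widths[i] + 1)]
    s <- free$start[j] + floor(runif(1) * (seg_len[j] - widths[i] + 1))
    cand <- tibble(chrom = free$chrom[j], start = s, end = s + widths[i])
    out[[i]] <- cand
    free <- bed_subtract(free, cand)
  }
  arrange(bind_rows(out), .data$chrom, .data$start)
}

# Poisson fragments with midpoints uniform in each region; one row per region
sample_region_fragments <- function(regions, rates, frag_len, rep_sigma,
                                    build) {
  if (nrow(regions) == 0) return(empty_intervals())
  jitter <- if (rep_sigma > 0) {
    rlnorm(nrow(regions), meanlog = -rep_sigma^2 / 2, sdlog = rep_sigma)
  } else rep(1, nrow(regions))
  lens <- regions$end - regions$start
  counts <- rpois(nrow(regions), rates * lens * jitter)
  idx <- rep.int(seq_len(nrow(regions)), counts)
  if (length(idx) == 0) return(empty_intervals())
  mids <- floor(regions$start[idx] + runif(length(idx)) * lens[idx])
  half <- floor(frag_len / 2)
  f <- tibble(chrom = regions$chrom[idx], start = mids - half,
              end = mids - half + frag_len)
  f <- clip_intervals(f, build)
  f[order(f$chrom, f$start, f$end), , drop = FALSE]
}

jitter_peaks <- function(peaks, jitter, build) {
  if (nrow(peaks) == 0 || jitter == 0) return(bed_merge(peaks))
  p <- peaks
  p$start <- p$start + sample.int(2 * jitter + 1, nrow(p), replace = TRUE) - jitter - 1
  p$end <- p$end + sample.int(2 * jitter + 1, nrow(p), replace = TRUE) - jitter - 1
  p <- clip_intervals(p[p$end > p$start, , drop = FALSE], build)
  bed_merge(p)
}

#' Generate the complete synthetic study
#'
#' Writes the study bundle to `dir` (gene models as BED12, expression and
#' RNA-count TSVs, per-sample fragment BEDs with a manifest, per-replicate
#' 5-hmC and H3K27ac peak calls, input-control fragments, repeats,
#' conserved elements, methylation deltas, machine-readable ground truth
#' as JSON) and returns the ground truth invisibly attached to the file
#' index. The same seed reproduces the bundle byte for byte.
#'
#' @param config [synth_config()].
#' @param dir output directory (created if absent).
#' @return List of class `synth_dataset`: `dir`, `files` (named paths),
#'   `truth` (ground-truth list), `build`, `genes`.
#' @export
synth_generate <- function(config, dir) {
  cfg <- config
  if (!inherits(cfg, "synth_config")) abort("config must be a synth_config")
  if (cfg$n_genes == 0 && cfg$coupling_strength > 0) {
    abort("zero genes with nonzero coupling")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) abort(sprintf("cannot create directory %s", dir))
  dir.create(file.path(dir, "fragments"), showWarnings = FALSE)
  dir.create(file.path(dir, "peaks"), showWarnings = FALSE)

  with_seed_preserved(cfg$seed, function() synth_generate_impl(cfg, dir))
}

synth_generate_impl <- function(cfg, dir) {
  conds <- cfg$conditions
  n_cond <- length(conds)
  build <- genome_build(setNames(rep(cfg$chrom_length, cfg$n_chroms),
                                 paste0("chr", seq_len(cfg$n_chroms))))
  genome <- tibble(chrom = names(build), start = 0,
                   end = as.numeric(build))
  total_len <- sum(as.numeric(build))
  # background fragments are generated over 10-kb blocks so replicate-level
  # rate jitter is local, making the extra-Poisson variance homogeneous
  # across the genome (the common-dispersion model of the analysis)
  bg_blocks <- bind_rows(lapply(names(build), function(cc) {
    len <- as.numeric(build[[cc]])
    s <- (seq_len(ceiling(len / 1e4)) - 1) * 1e4
    tibble(chrom = cc, start = s, end = pmin(s + 1e4, len))
  }))

  ## ---- gene models ----------------------------------------------------
  n <- cfg$n_genes
  slot <- floor(total_len / max(n, 1))
  if (n > 0 && slot < 5000) abort("genome too small for the requested genes")
  per_chrom <- diff(round(seq(0, n, length.out = cfg$n_chroms + 1)))
  gene_rows <- vector("list", n)
  i <- 0L
  for (ci in seq_len(cfg$n_chroms)) {
    k <- per_chrom[ci]
    if (k == 0) next
    cslot <- floor(cfg$chrom_length / k)
    for (s_idx in seq_len(k)) {
      i <- i + 1L
      off <- (s_idx - 1) * cslot
      max_len <- max(2001, min(6000, cslot - 3000))
      len <- floor(runif(1, 2000, max_len))
      s <- off + 1500 + floor(runif(1) * max(1, cslot - len - 3000))
      gene_rows[[i]] <- tibble(gene_id = sprintf("gene%03d", i),
                               chrom = names(build)[ci],
                               start = s, end = s + len,
                               strand = sample(c("+", "-"), 1))
    }
  }
  gd <- bind_rows(gene_rows)
  exons <- map(seq_len(n), function(i) {
    len <- gd$end[i] - gd$start[i]
    k <- sample.int(3, 1)
    cuts <- sort(c(0, len, floor(runif(2 * k - 1) * len)))
    ex <- tibble(start = gd$start[i] + cuts[seq(1, 2 * k, by = 2)],
                 end = gd$start[i] + cuts[seq(2, 2 * k + 1, by = 2)])
    ex <- ex[ex$end > ex$start, , drop = FALSE]
    if (nrow(ex) == 0) ex <- tibble(start = gd$start[i], end = gd$end[i])
    ex
  })
  genes <- gene_tbl(gd$gene_id, gd$chrom, gd$start, gd$end, gd$strand, exons)

  ## ---- expression ------------------------------------------------------
  base_expr <- rlnorm(n, meanlog = 1.5, sdlog = 1)
  stage_of <- rep(NA_character_, n)
  if (cfg$frac_stage_specific > 0 && n > 0) {
    idx <- sample.int(n, round(cfg$frac_stage_specific * n))
    stage_of[idx] <- sample(conds, length(idx), replace = TRUE)
  }
  expr <- matrix(rep(base_expr, n_cond), ncol = n_cond,
                 dimnames = list(genes$gene_id, conds))
  expr <- expr * matrix(rlnorm(n * n_cond, -0.005, 0.1), ncol = n_cond)
  for (j in seq_len(n_cond)) {
    boost <- ifelse(!is.na(stage_of) & stage_of == conds[j], cfg$stage_boost, 1)
    expr[, j] <- expr[, j] * boost
  }

  ## ---- free intergenic space ------------------------------------------
  gene_excl <- tibble(chrom = genes$chrom, start = genes$start - 2000,
                      end = genes$end + 2000)
  free <- bed_subtract(genome, clip_intervals(gene_excl, build))
  free <- free[free$end - free$start >= 2000, , drop = FALSE]

  ## ---- enhancers -------------------------------------------------------
  enh <- sample_free_intervals(free, cfg$n_enhancers, 800, "enhancers")
  if (nrow(enh) > 0) {
    enh$hmc_status <- ifelse(runif(nrow(enh)) < cfg$frac_hmc_pos,
                             "positive", "negative")
    mid <- floor((enh$start + enh$end) / 2)
    tss <- tss_position(genes)
    enh$nearest_gene_id <- map_chr(seq_len(nrow(enh)), function(e) {
      gi <- which(genes$chrom == enh$chrom[e])
      if (length(gi) == 0) return(NA_character_)
      gi <- gi[order(genes$gene_id[gi])]
      genes$gene_id[gi][which.min(abs(mid[e] - tss[gi]))]
    })
    boosted <- unique(enh$nearest_gene_id[enh$hmc_status == "positive"])
    boosted <- boosted[!is.na(boosted)]
    expr[boosted, ] <- expr[boosted, , drop = FALSE] * cfg$enhancer_boost
  } else {
    enh$hmc_status <- character(0)
    enh$nearest_gene_id <- character(0)
  }
  occupied <- enh[, c("chrom", "start", "end")]
  free2 <- bed_subtract(free, occupied)

  ## ---- planted DhMRs ---------------------------------------------------
  dhmr <- sample_free_intervals(free2, cfg$n_planted_dhmrs, cfg$dhmr_width,
                                "planted DhMRs")
  if (nrow(dhmr) > 0) {
    n_tr <- max(n_cond - 1, 1)
    dhmr$transition <- sample.int(n_tr, nrow(dhmr), replace = TRUE)
    dhmr$direction <- sample(c("gain", "loss"), nrow(dhmr), replace = TRUE)
    dhmr$cond_a <- conds[dhmr$transition]
    dhmr$cond_b <- conds[pmin(dhmr$transition + 1, n_cond)]
  } else {
    dhmr$transition <- integer(0); dhmr$direction <- character(0)
    dhmr$cond_a <- character(0); dhmr$cond_b <- character(0)
  }
  free3 <- bed_subtract(free2, dhmr[, c("chrom", "start", "end")])

  ## ---- repeats ---------------------------------------------------------
  rep_w <- floor(runif(cfg$n_repeats, 300, 1500))
  repeats <- sample_free_intervals(free3, cfg$n_repeats, rep_w, "repeats")
  if (nrow(repeats) > 0) {
    repeats$repeat_class <- sample(c("LINE", "SINE", "LTR"), nrow(repeats),
                                   replace = TRUE, prob = c(0.4, 0.4, 0.2))
    is_line <- repeats$repeat_class == "LINE"
    repeats$tac_gain <- is_line & runif(nrow(repeats)) < 0.5
  } else {
    repeats$repeat_class <- character(0); repeats$tac_gain <- logical(0)
  }

  ## ---- conserved elements ---------------------------------------------
  cons_rows <- list()
  if (nrow(enh) > 0) {
    prob <- ifelse(enh$hmc_status == "positive",
                   cfg$enhancer_conserved_prob, 0.15)
    sel <- runif(nrow(enh)) < prob
    if (any(sel)) {
      mid <- floor((enh$start[sel] + enh$end[sel]) / 2)
      cons_rows$enh <- tibble(chrom = enh$chrom[sel], start = mid - 100,
                              end = mid + 100,
                              score = floor(601 + stats::rexp(sum(sel), 1 / 200)))
    }
  }
  if (cfg$n_background_conserved > 0) {
    bg <- sample_free_intervals(free3, cfg$n_background_conserved, 200,
                                "conserved elements")
    bg$score <- floor(stats::rgamma(nrow(bg), shape = 3, scale = 120))
    cons_rows$bg <- bg
  }
  conserved <- bind_rows(cons_rows)

  ## ---- per-condition 5-hmC enrichment truth ---------------------------
  rank_norm <- apply(expr, 2, function(v) (rank(v, ties.method = "average") - 1) /
                       max(n - 1, 1))
  # the marked set is constitutive, so its expression weighting uses the
  # gene's mean expression over conditions; the exponent is calibrated so a
  # planted coupling yields the strong class-vs-all separation the assay is
  # meant to recover (not a borderline one)
  rank_mean <- (rank(rowMeans(expr), ties.method = "average") - 1) /
    max(n - 1, 1)
  w_mark <- if (cfg$coupling_strength > 0) {
    exp(8 * cfg$coupling_strength * rank_mean)
  } else rep(1, n)
  gb_marked <- rep(FALSE, n)
  if (n > 0 && cfg$frac_gb_marked > 0) {
    gb_marked[sample.int(n, round(cfg$frac_gb_marked * n), prob = w_mark)] <- TRUE
  }
  # stage-specific genes are planted in both assays: their gene bodies carry
  # peak-level 5-hmC so the stage boost shows up in expression and coverage
  gb_marked[!is.na(stage_of)] <- TRUE
  # the promoter-only subset emulates mild repression (below-median
  # expression) only when an expression/5-hmC coupling is planted at all;
  # with coupling off the subset is drawn uniformly so nothing is planted
  prom_pool <- if (cfg$coupling_strength > 0) {
    which(rowMeans(expr) < median(rowMeans(expr)) & !gb_marked)
  } else {
    which(!gb_marked)
  }
  prom_only <- rep(FALSE, n)
  n_po <- min(length(prom_pool), round(cfg$frac_promoter_only * n))
  if (n_po > 0) prom_only[sample(prom_pool, n_po)] <- TRUE
  prom_also <- gb_marked & runif(n) < 0.5

  tssv <- tss_position(genes)
  enrich_truth <- setNames(vector("list", n_cond), conds)
  for (j in seq_len(n_cond)) {
    rows <- list()
    stage_mult <- ifelse(!is.na(stage_of) & stage_of == conds[j],
                         cfg$stage_boost, 1)
    if (any(gb_marked)) {
      # enrichment kept clear of the TSS +/- 1 kb promoter window (plus
      # peak-jitter margin) so gb-only genes stay promoter-free
      k <- which(gb_marked)
      margin <- 1000 + 2 * cfg$peak_jitter
      gb_s <- ifelse(genes$strand[k] == "+", tssv[k] + margin, genes$start[k])
      gb_e <- ifelse(genes$strand[k] == "+", genes$end[k], tssv[k] - margin)
      ok <- gb_e - gb_s >= 200
      k <- k[ok]
      rows$gb <- tibble(chrom = genes$chrom[k], start = gb_s[ok],
                        end = gb_e[ok],
                        rate = cfg$peak_rate *
                          (0.5 + cfg$coupling_strength * rank_norm[k, j]) *
                          stage_mult[k],
                        kind = "gene_body", id = genes$gene_id[k])
    }
    pk <- which(prom_only | prom_also)
    if (length(pk) > 0) {
      rows$prom <- tibble(chrom = genes$chrom[pk], start = tssv[pk] - 500,
                          end = tssv[pk] + 500, rate = cfg$peak_rate,
                          kind = "promoter", id = genes$gene_id[pk])
    }
    pos_enh <- enh[enh$hmc_status == "positive", , drop = FALSE]
    if (nrow(pos_enh) > 0) {
      mid <- floor((pos_enh$start + pos_enh$end) / 2)
      rows$enh <- tibble(chrom = pos_enh$chrom, start = mid - 200,
                         end = mid + 200, rate = cfg$peak_rate,
                         kind = "enhancer", id = NA_character_)
    }
    if (nrow(dhmr) > 0) {
      # region rates are planted as totals: the genome background underneath
      # is subtracted so the high:low ratio is exactly dhmr_fold
      active_high <- (dhmr$direction == "gain" & j > dhmr$transition) |
        (dhmr$direction == "loss" & j <= dhmr$transition)
      target <- cfg$dhmr_base_rate * ifelse(active_high, cfg$dhmr_fold, 1)
      rows$dhmr <- tibble(chrom = dhmr$chrom, start = dhmr$start,
                          end = dhmr$end,
                          rate = pmax(target - cfg$background_rate, 0),
                          kind = "dhmr", id = NA_character_)
    }
    if (conds[j] == "TAC" && any(repeats$tac_gain)) {
      rk <- which(repeats$tac_gain)
      rows$reps <- tibble(chrom = repeats$chrom[rk], start = repeats$start[rk],
                          end = repeats$end[rk],
                          rate = cfg$dhmr_base_rate * cfg$tac_repeat_gain,
                          kind = "repeat", id = NA_character_)
    }
    enrich_truth[[j]] <- bind_rows(rows)
  }

  ## ---- fragments + peak calls per sample ------------------------------
  manifest_rows <- list()
  files <- list()
  for (j in seq_len(n_cond)) {
    et <- enrich_truth[[j]]
    gb_bg <- tibble(chrom = genes$chrom, start = genes$start,
                    end = genes$end,
                    rate = cfg$gb_base_rate *
                      (1 + 3 * cfg$coupling_strength * rank_norm[, j]))
    for (r in seq_len(cfg$replicates)) {
      parts <- list(
        sample_region_fragments(bg_blocks, cfg$background_rate,
                                cfg$fragment_length, cfg$rep_sigma, build),
        sample_region_fragments(gb_bg[, c("chrom", "start", "end")],
                                gb_bg$rate, cfg$fragment_length,
                                cfg$rep_sigma, build))
      if (nrow(et) > 0) {
        parts <- c(parts, list(
          sample_region_fragments(et[, c("chrom", "start", "end")], et$rate,
                                  cfg$fragment_length, cfg$rep_sigma, build)))
      }
      f <- bind_rows(parts)
      f <- f[order(f$chrom, f$start, f$end), , drop = FALSE]
      sid <- sprintf("%s_rep%d", conds[j], r)
      path <- file.path("fragments", paste0(sid, ".bed"))
      write_bed(f, file.path(dir, path))
      manifest_rows[[sid]] <- tibble(sample = sid, condition = conds[j],
                                     replicate = r, role = "IP",
                                     library_size = nrow(f), path = path)
      # per-replicate peak calls: truth enrichment intervals, jittered
      pk <- if (nrow(et) > 0) {
        jitter_peaks(et[, c("chrom", "start", "end")], cfg$peak_jitter, build)
      } else empty_intervals()
      pk_path <- file.path("peaks", sprintf("%s_hmc_peaks.bed", sid))
      write_bed(pk, file.path(dir, pk_path))
      files[[sprintf("hmc_peaks_%s", sid)]] <- pk_path
      # H3K27ac calls: enhancers plus some active promoters
      k27_parts <- list(enh[, c("chrom", "start", "end")])
      top <- order(expr[, j], decreasing = TRUE)[seq_len(min(30, n))]
      if (length(top) > 0) {
        k27_parts$prom <- clip_intervals(
          tibble(chrom = genes$chrom[top], start = tssv[top] - 400,
                 end = tssv[top] + 400), build)
      }
      k27 <- jitter_peaks(bind_rows(k27_parts), cfg$peak_jitter, build)
      k27_path <- file.path("peaks", sprintf("%s_h3k27ac_peaks.bed", sid))
      write_bed(k27, file.path(dir, k27_path))
      files[[sprintf("h3k27ac_peaks_%s", sid)]] <- k27_path
    }
    # input control
    fin <- sample_region_fragments(bg_blocks, cfg$input_rate,
                                   cfg$fragment_length, cfg$rep_sigma, build)
    sid <- sprintf("%s_input", conds[j])
    path <- file.path("fragments", paste0(sid, ".bed"))
    write_bed(fin, file.path(dir, path))
    manifest_rows[[sid]] <- tibble(sample = sid, condition = conds[j],
                                   replicate = 1L, role = "input",
                                   library_size = nrow(fin), path = path)
  }
  manifest <- bind_rows(manifest_rows)

  ## ---- RNA counts ------------------------------------------------------
  rna_cols <- list()
  for (j in seq_len(n_cond)) {
    pr <- expr[, j] / sum(expr[, j])
    for (r in seq_len(cfg$replicates)) {
      mu <- pr * cfg$rna_depth
      rna_cols[[sprintf("%s_rep%d", conds[j], r)]] <-
        rnbinom(n, size = 1 / cfg$rna_phi, mu = mu)
    }
  }
  rna_counts <- as_tibble(c(list(gene_id = genes$gene_id), rna_cols))

  ## ---- methylation deltas ---------------------------------------------
  neo_rate <- cfg$gb_base_rate * (1 + 3 * cfg$coupling_strength *
                                    rank_norm[, min(2, n_cond)]) +
    ifelse(gb_marked, cfg$peak_rate, 0)
  neo_norm <- if (n > 0 && max(neo_rate) > 0) neo_rate / max(neo_rate) else neo_rate
  delta <- -cfg$methylation_slope * neo_norm + rnorm(n, 0, 3)
  delta <- pmin(pmax(delta, -100), 100)
  methylation <- tibble(gene_id = genes$gene_id,
                        delta_mcg = round(delta, 3))

  ## ---- write shared files ---------------------------------------------
  files$chrom_sizes <- "chrom.sizes"
  write_chrom_sizes(build, file.path(dir, files$chrom_sizes))
  files$genes <- "genes.bed12"
  write_bed12(genes, file.path(dir, files$genes))
  files$expression <- "expression.tsv"
  expr_tbl <- as_tibble(cbind(tibble(gene_id = genes$gene_id),
                              as_tibble(round(expr, 4))))
  readr::write_tsv(expr_tbl, file.path(dir, files$expression), progress = FALSE)
  files$rna_counts <- "rna_counts.tsv"
  readr::write_tsv(rna_counts, file.path(dir, files$rna_counts), progress = FALSE)
  files$methylation <- "methylation.tsv"
  readr::write_tsv(methylation, file.path(dir, files$methylation), progress = FALSE)
  files$manifest <- "manifest.tsv"
  readr::write_tsv(manifest, file.path(dir, files$manifest), progress = FALSE)
  files$repeats <- "repeats.bed"
  write_bed(rename(repeats, name = "repeat_class")[, c("chrom", "start", "end", "name")],
            file.path(dir, files$repeats))
  files$conserved <- "conserved.bed"
  if (nrow(conserved) > 0) {
    conserved$name <- "conserved"
    write_bed(conserved[, c("chrom", "start", "end", "name", "score")],
              file.path(dir, files$conserved))
  } else {
    file.create(file.path(dir, files$conserved))
  }

  truth <- list(
    conditions = conds,
    enrichment = map(enrich_truth, function(t) {
      as.data.frame(t[, c("chrom", "start", "end", "rate", "kind")])
    }),
    dhmrs = as.data.frame(dhmr),
    genes = data.frame(
      gene_id = genes$gene_id,
      gb_marked = gb_marked, promoter_only = prom_only,
      promoter_and_gb = prom_also, stage = ifelse(is.na(stage_of), "",
                                                  stage_of),
      max_expr_stage = conds[apply(expr, 1, which.max)],
      stringsAsFactors = FALSE),
    enhancers = as.data.frame(enh),
    repeats = as.data.frame(repeats),
    methylation = as.data.frame(methylation),
    expression = as.data.frame(expr_tbl)
  )
  files$truth <- "truth.json"
  jsonlite::write_json(truth, file.path(dir, files$truth), auto_unbox = TRUE,
                       digits = NA, pretty = FALSE)
  files$config <- "config.json"
  cfg_plain <- unclass(cfg)
  jsonlite::write_json(cfg_plain, file.path(dir, files$config),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  structure(list(dir = dir, files = files, truth = truth, build = build,
                 genes = genes, manifest = manifest),
            class = "synth_dataset")
}

#' @export
print.synth_dataset <- function(x, ...) {
  cat(sprintf("<synthetic dataset> %s: %d files, %d genes\n", x$dir,
              length(x$files), nrow(x$genes)))
  invisible(x)
}

#' Read study inputs back from a generated or user-supplied bundle
#'
#' @param dir bundle directory containing `manifest.tsv`.
#' @return Tibble manifest with absolute fragment paths.
#' @export
read_manifest <- function(dir) {
  path <- file.path(dir, "manifest.tsv")
  if (!file.exists(path)) abort(sprintf("no manifest.tsv under %s", dir))
  m <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                       comment = "#")
  need <- c("sample", "condition", "replicate", "role", "library_size", "path")
  miss <- setdiff(need, names(m))
  if (length(miss) > 0) {
    abort(paste0("manifest lacks column(s): ", paste(miss, collapse = ", ")))
  }
  m
}

#' @rdname read_manifest
#' @param manifest manifest tibble row subset to load.
#' @export
load_fragment_sets <- function(dir, manifest) {
  map(seq_len(nrow(manifest)), function(i) {
    fragment_set(read_bed(file.path(dir, manifest$path[i])),
                 sample_id = manifest$sample[i],
                 condition = manifest$condition[i],
                 replicate = manifest$replicate[i],
                 role = manifest$role[i],
                 library_size = manifest$library_size[i])
  })
}

#' @rdname read_manifest
#' @export
read_truth <- function(dir) {
  jsonlite::read_json(file.path(dir, "truth.json"), simplifyVector = TRUE)
}

#' Plant a monotone expression / gene-body 5-hmC coupling
#'
#' Returns per-gene gene-body fragment rates that increase monotonically
#' with expression rank, scaled by the coupling strength; genes of equal
#' expression receive equal rates. The promoter-only subset of the full
#' generator is drawn from the below-median expression stratum (see
#' [synth_generate()]); this helper exposes the rate rule itself.
#'
#' @param expression numeric vector of (strictly positive) expression.
#' @param coupling_strength >= 0.
#' @param base_rate baseline fragments/bp.
#' @return Numeric vector of rates, same order as `expression`.
#' @export
plant_expression_coupling <- function(expression, coupling_strength = 1,
                                      base_rate = 1e-3) {
  if (any(expression <= 0)) abort("expression must be strictly positive")
  rn <- (rank(expression, ties.method = "average") - 1) /
    max(length(expression) - 1, 1)
  base_rate * (1 + 3 * coupling_strength * rn)
}
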