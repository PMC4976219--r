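#' Pipeline run configuration
#'
#' Points at a study bundle (a directory with `manifest.tsv`, gene models,
#' peak calls, expression and annotation files, as produced by
#' [synth_generate()] or assembled by hand in the same layout) and collects
#' the tunable parameters of every stage. All randomness downstream flows
#' from `seed`, expanded deterministically per stage.
#'
#' @param dir bundle directory.
#' @param out_dir report output directory.
#' @param promoter_halfwidth promoter half-width (bp).
#' @param window window width for differential analysis (bp).
#' @param alpha DhMR window p-value threshold.
#' @param min_expr expressed-gene RPKM threshold.
#' @param n_perm permutations for the quartile trend test.
#' @param seed master seed.
#' @return List of class `hmc_run_config`.
#' @export
run_config <- function(dir, out_dir = file.path(dir, "report"),
                       promoter_halfwidth = 1000, window = 250,
                       alpha = 0.05, min_expr = 1, n_perm = 2000,
                       seed = 1L) {
  if (!dir.exists(dir)) abort(sprintf("bundle directory %s does not exist", dir))
  structure(list(dir = dir, out_dir = out_dir,
                 promoter_halfwidth = promoter_halfwidth, window = window,
                 alpha = alpha, min_expr = min_expr, n_perm = n_perm,
                 seed = seed), class = "hmc_run_config")
}

#' Validate a study bundle before running
#'
#' Schema and consistency checks: manifest columns and referenced files,
#' BED dialect sanity (non-negative starts, end > start), chromosome-name
#' consistency against `chrom.sizes`, and library sizes at least as large
#' as the fragment files' record counts. Findings are returned, not
#' raised.
#'
#' @param config [run_config()] or a bundle directory.
#' @return Tibble of findings: `file`, `line`, `reason`; zero rows when
#'   the bundle is clean.
#' @export
validate_inputs <- function(config) {
  dir <- if (inherits(config, "hmc_run_config")) config$dir else config
  findings <- list()
  note <- function(file, line, reason) {
    findings[[length(findings) + 1]] <<- tibble(file = file, line = line,
                                                reason = reason)
  }
  man_path <- file.path(dir, "manifest.tsv")
  if (!file.exists(man_path)) {
    note("manifest.tsv", NA_integer_, "missing manifest")
    return(bind_rows(findings))
  }
  man <- tryCatch(read_manifest(dir), error = function(e) {
    note("manifest.tsv", NA_integer_, conditionMessage(e)); NULL
  })
  sizes_path <- file.path(dir, "chrom.sizes")
  build <- NULL
  if (file.exists(sizes_path)) {
    build <- read_chrom_sizes(sizes_path)
  } else {
    note("chrom.sizes", NA_integer_, "missing chrom.sizes")
  }
  check_bed <- function(rel) {
    p <- file.path(dir, rel)
    if (!file.exists(p)) { note(rel, NA_integer_, "file missing"); return(NULL) }
    x <- tryCatch(read_bed(p), error = function(e) {
      note(rel, NA_integer_, conditionMessage(e)); NULL
    })
    if (is.null(x) || nrow(x) == 0) return(x)
    bad <- which(x$end <= x$start)
    if (length(bad) > 0) {
      note(rel, bad[1], "end <= start (1-based or malformed BED?)")
    }
    if (!is.null(build)) {
      unknown <- setdiff(unique(x$chrom), names(build))
      if (length(unknown) > 0) {
        note(rel, NA_integer_,
             sprintf("chromosome '%s' absent from chrom.sizes", unknown[1]))
      } else {
        over <- which(x$end > as.numeric(build)[x$chrom])
        if (length(over) > 0) {
          note(rel, over[1], "interval extends past chromosome end")
        }
      }
    }
    x
  }
  if (!is.null(man)) {
    for (i in seq_len(nrow(man))) {
      f <- check_bed(man$path[i])
      if (!is.null(f) && man$library_size[i] < nrow(f)) {
        note(man$path[i], NA_integer_,
             "library_size smaller than fragment record count")
      }
    }
    for (rel in list.files(file.path(dir, "peaks"), full.names = FALSE)) {
      check_bed(file.path("peaks", rel))
    }
  }
  for (rel in c("repeats.bed", "conserved.bed")) {
    if (file.exists(file.path(dir, rel))) check_bed(rel)
  }
  if (length(findings) == 0) {
    return(tibble(file = character(), line = integer(), reason = character()))
  }
  bind_rows(findings)
}

write_report_table <- function(x, path, hash) {
  readr::write_tsv(x, path, progress = FALSE)
  cat(sprintf("# config_hash: %s\n", hash), file = path, append = TRUE)
  invisible(path)
}

#' Run the full integrative analysis
#'
#' Sequences the whole study on a bundle: replicate-consensus peaks per
#' condition, gene-body RPKM per sample, genomic-element annotation of the
#' consensus peaks, position classes, peaks common to all conditions,
#' windowed differential analysis of every consecutive condition pair,
#' expression associations (position classes, expression quartiles),
#' enhancer definition / 5-hmC stratification / nearest genes / expression
#' contrast / conservation, and dual-evidence stage co-clustering. All
#' tables are written under `out_dir` with a provenance footer; a JSON
#' summary and a deterministic log complete the bundle. Re-running with
#' the same configuration reproduces the outputs byte for byte.
#'
#' @param config [run_config()].
#' @return List of class `hmc_report` with the main result objects and
#'   `out_dir`.
#' @export
run_pipeline <- function(config) {
  rc <- config
  if (!inherits(rc, "hmc_run_config")) abort("config must be a run_config")
  dir.create(rc$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character()
  say <- function(...) {
    log_lines <<- c(log_lines, sprintf(...))
  }
  # provenance hash covers the analysis parameters, not filesystem paths
  params <- unclass(rc)[setdiff(names(unclass(rc)), c("dir", "out_dir"))]
  cfg_json <- jsonlite::toJSON(params, auto_unbox = TRUE)
  hash <- config_hash(as.character(cfg_json))
  say("hmcscape pipeline run")
  say("package version: %s", as.character(utils::packageVersion("hmcscape")))
  say("config hash: %s", hash)
  say("seed: %s", format(rc$seed))
  say("parameters: promoter_halfwidth=%s window=%s alpha=%s min_expr=%s n_perm=%s",
      rc$promoter_halfwidth, rc$window, rc$alpha, rc$min_expr, rc$n_perm)

  problems <- validate_inputs(rc)
  if (nrow(problems) > 0) {
    abort(sprintf("input validation failed at stage 'validate': %s (%s)",
                  problems$reason[1], problems$file[1]))
  }
  build <- read_chrom_sizes(file.path(rc$dir, "chrom.sizes"))
  genes <- read_bed12(file.path(rc$dir, "genes.bed12"))
  man <- read_manifest(rc$dir)
  conds <- unique(man$condition[man$role == "IP"])
  for (cc in conds) {
    n_rep <- sum(man$condition == cc & man$role == "IP")
    if (n_rep < 2) {
      abort(sprintf("stage 'consensus': condition %s has %d IP replicate(s), need 2",
                    cc, n_rep))
    }
  }
  has_input <- any(man$role == "input")
  if (!has_input) say("no input controls in manifest: input-dependent steps skipped")
  expr_path <- file.path(rc$dir, "expression.tsv")
  if (!file.exists(expr_path)) abort("stage 'expression': expression.tsv missing")
  expr <- readr::read_tsv(expr_path, show_col_types = FALSE, progress = FALSE,
                          comment = "#")
  frag_sets <- load_fragment_sets(rc$dir, man[man$role == "IP", ])
  names(frag_sets) <- man$sample[man$role == "IP"]

  out <- list(out_dir = rc$out_dir)

  ## consensus peaks per condition
  consensus <- list()
  for (cc in conds) {
    reps <- man[man$condition == cc & man$role == "IP", ]
    pk <- map(reps$sample, function(s) {
      read_bed(file.path(rc$dir, "peaks", sprintf("%s_hmc_peaks.bed", s)))
    })
    cons <- consensus_peaks(pk[[1]], pk[[2]], reps$sample[1], reps$sample[2])
    consensus[[cc]] <- cons
    say("consensus %s: %d intervals, retained %.1f%% / %.1f%%", cc,
        nrow(cons), 100 * consensus_retained(cons)[1],
        100 * consensus_retained(cons)[2])
    write_report_table(cons, file.path(rc$out_dir,
                                       sprintf("consensus_peaks_%s.tsv", cc)),
                       hash)
  }
  out$consensus <- consensus

  ## common peaks across all conditions
  common <- common_peaks(consensus)
  say("common peaks across %d conditions: %d intervals", length(conds),
      nrow(common))
  write_report_table(common, file.path(rc$out_dir, "common_peaks.tsv"), hash)
  out$common <- common

  ## gene-body RPKM per IP sample + replicate correlations
  quant <- map(frag_sets, gene_body_rpkm, genes = genes)
  gq <- tibble(gene_id = genes$gene_id)
  for (s in names(quant)) gq[[s]] <- quant[[s]]$rpkm
  write_report_table(gq, file.path(rc$out_dir, "gene_rpkm.tsv"), hash)
  rep_cor <- bind_rows(map(conds, function(cc) {
    ss <- man$sample[man$condition == cc & man$role == "IP"]
    tibble(condition = cc,
           pearson = replicate_correlation(quant[[ss[1]]], quant[[ss[2]]]))
  }))
  write_report_table(rep_cor, file.path(rc$out_dir,
                                        "replicate_correlation.tsv"), hash)
  out$replicate_correlation <- rep_cor

  ## peak annotation distribution + position classes per condition
  classes <- list()
  ann <- list()
  for (cc in conds) {
    ann[[cc]] <- peak_annotation_distribution(consensus[[cc]], genes)
    ann[[cc]]$condition <- cc
    classes[[cc]] <- classify_genes_by_position(
      consensus[[cc]], genes, promoter_halfwidth = rc$promoter_halfwidth,
      build = build)
  }
  write_report_table(bind_rows(ann),
                     file.path(rc$out_dir, "peak_annotation.tsv"), hash)
  cls_tbl <- tibble(gene_id = genes$gene_id)
  for (cc in conds) cls_tbl[[cc]] <- as.character(classes[[cc]]$class)
  write_report_table(cls_tbl, file.path(rc$out_dir, "position_classes.tsv"),
                     hash)
  out$classes <- classes
  gb_all <- genes_gb_all_conditions(classes)
  say("genes gene-body-marked at all conditions: %d", length(gb_all))
  out$gb_all_conditions <- gb_all

  ## DhMRs per consecutive transition
  dhmr_tables <- list()
  for (t in seq_len(length(conds) - 1)) {
    ca <- conds[t]; cb <- conds[t + 1]
    fa <- frag_sets[man$sample[man$condition == ca & man$role == "IP"]]
    fb <- frag_sets[man$sample[man$condition == cb & man$role == "IP"]]
    run <- dhmr_analysis(fa, fb, build, w = rc$window, alpha = rc$alpha)
    say("DhMRs %s vs %s: %d regions (phi = %.4f)", ca, cb,
        nrow(run$dhmrs), run$phi)
    d <- run$dhmrs
    d$transition <- sprintf("%s_vs_%s", ca, cb)
    dhmr_tables[[t]] <- d
  }
  dhmrs <- bind_rows(dhmr_tables)
  write_report_table(dhmrs, file.path(rc$out_dir, "dhmrs.tsv"), hash)
  out$dhmrs <- dhmrs

  ## expression associations (first condition's classes as reference view)
  assoc <- list()
  for (cc in conds) {
    e <- tibble(gene_id = expr$gene_id, rpkm = expr[[cc]])
    a <- expression_by_position_class(e, classes[[cc]])
    a$condition <- cc
    assoc[[cc]] <- a
  }
  write_report_table(bind_rows(assoc),
                     file.path(rc$out_dir, "expression_by_class.tsv"), hash)
  out$expression_by_class <- bind_rows(assoc)

  qt_cond <- conds[min(3, length(conds))]
  e <- tibble(gene_id = expr$gene_id, rpkm = expr[[qt_cond]])
  cov <- gene_body_rpkm(frag_sets[[man$sample[man$condition == qt_cond &
                                                man$role == "IP"][1]]], genes)
  qt <- quartile_trend(e, cov, min_expr = rc$min_expr, n_perm = rc$n_perm,
                       seed = derive_seed(rc$seed, 11))
  say("quartile trend (%s): rho = %.3f, p = %.4g", qt_cond, qt$trend_rho,
      qt$trend_p)
  write_report_table(qt$quartiles,
                     file.path(rc$out_dir, "quartile_trend.tsv"), hash)
  out$quartile_trend <- qt

  ## enhancers (per condition consensus H3K27ac)
  enh_rows <- list()
  contrast_rows <- list()
  cons_rows <- list()
  for (cc in conds) {
    ss <- man$sample[man$condition == cc & man$role == "IP"]
    k27 <- map(ss, function(s) {
      read_bed(file.path(rc$dir, "peaks", sprintf("%s_h3k27ac_peaks.bed", s)))
    })
    k27_cons <- consensus_peaks(k27[[1]], k27[[2]], ss[1], ss[2])
    enh <- define_putative_enhancers(k27_cons, genes,
                                     promoter_halfwidth = rc$promoter_halfwidth,
                                     condition = cc)
    enh <- classify_by_hmc(enh, consensus[[cc]])
    enh <- suppressWarnings(assign_nearest_gene(enh, genes))
    enh_rows[[cc]] <- enh
    e <- tibble(gene_id = expr$gene_id, rpkm = expr[[cc]])
    mw <- enhancer_expression_contrast(enh, e)
    contrast_rows[[cc]] <- tibble(
      condition = cc,
      n_positive = sum(enh$hmc_status == "positive"),
      n_negative = sum(enh$hmc_status == "negative"),
      median_positive = if (is.null(mw)) NA_real_ else mw$groups$median[1],
      median_negative = if (is.null(mw)) NA_real_ else mw$groups$median[2],
      u = if (is.null(mw)) NA_real_ else mw$u,
      p_value = if (is.null(mw)) NA_real_ else mw$p_value)
    cons_path <- file.path(rc$dir, "conserved.bed")
    if (file.exists(cons_path) && file.size(cons_path) > 0) {
      cons_el <- read_bed(cons_path)
      co <- conservation_overlap(enh, cons_el)
      co$condition <- cc
      cons_rows[[cc]] <- co
    }
  }
  enh_all <- bind_rows(enh_rows)
  write_report_table(enh_all, file.path(rc$out_dir, "enhancers.tsv"), hash)
  write_report_table(bind_rows(contrast_rows),
                     file.path(rc$out_dir, "enhancer_contrast.tsv"), hash)
  if (length(cons_rows) > 0) {
    write_report_table(bind_rows(cons_rows),
                       file.path(rc$out_dir, "enhancer_conservation.tsv"),
                       hash)
  }
  out$enhancers <- enh_all
  out$enhancer_contrast <- bind_rows(contrast_rows)

  ## stage co-clustering on expression + genic 5-hmC reads-in-peaks
  hmc_mat <- matrix(0, nrow(genes), length(conds),
                    dimnames = list(genes$gene_id, conds))
  for (cc in conds) {
    ss <- man$sample[man$condition == cc & man$role == "IP"]
    vals <- map(ss, function(s) {
      gene_body_rpkm(frag_sets[[s]], genes, peaks = consensus[[cc]])$rpkm
    })
    hmc_mat[, cc] <- rowMeans(do.call(cbind, vals))
  }
  expr_mat <- as.matrix(expr[, conds])
  rownames(expr_mat) <- expr$gene_id
  expr_mat <- expr_mat[genes$gene_id, , drop = FALSE]
  coclust <- stage_cocluster(expr_mat, hmc_mat)
  say("stage co-clustering: %d of %d genes assigned",
      sum(!is.na(coclust$stage)), nrow(coclust))
  write_report_table(coclust, file.path(rc$out_dir, "stage_cocluster.tsv"),
                     hash)
  out$stage_cocluster <- coclust

  ## summary + log
  summary <- list(
    config_hash = hash,
    conditions = as.list(setNames(map_int(consensus, nrow), conds)),
    common_peaks = nrow(common),
    genes = nrow(genes),
    gb_marked_all_conditions = length(gb_all),
    dhmrs = nrow(dhmrs),
    quartile_trend_p = qt$trend_p,
    stage_assigned = sum(!is.na(coclust$stage)),
    enhancers = nrow(enh_all))
  jsonlite::write_json(summary, file.path(rc$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(log_lines, file.path(rc$out_dir, "run_log.txt"))
  out$summary <- summary
  structure(out, class = "hmc_report")
}

#' @export
print.hmc_report <- function(x, ...) {
  cat("<pipeline report>", x$out_dir, "\n")
  cat(sprintf("  %d DhMRs, %d enhancers, %d co-clustered genes\n",
              nrow(x$dhmrs), nrow(x$enhancers),
              sum(!is.na(x$stage_cocluster$stage))))
  invisible(x)
}
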