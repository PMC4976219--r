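#' Define putative enhancers from H3K27ac consensus peaks
#'
#' A consensus H3K27ac peak is a putative enhancer unless it overlaps any
#' exon or any promoter window (TSS +/- `promoter_halfwidth`) by at least
#' 1 bp. Intronic overlap does not exclude a peak.
#'
#' @param h3k27ac_peaks interval tibble of replicate-consensus H3K27ac
#'   peaks.
#' @param genes gene-model tibble.
#' @param promoter_halfwidth promoter half-width in bp.
#' @param condition optional condition label stored on the records.
#' @return Interval tibble of enhancer records (`chrom`, `start`, `end`,
#'   `condition`).
#' @export
define_putative_enhancers <- function(h3k27ac_peaks, genes,
                                      promoter_halfwidth = 1000,
                                      condition = NA_character_) {
  validate_intervals(h3k27ac_peaks, "peak table")
  excl <- bind_rows(
    exon_intervals(genes)[, c("chrom", "start", "end")],
    gene_promoters(genes, promoter_halfwidth)[, c("chrom", "start", "end")])
  keep <- !overlaps_any(h3k27ac_peaks, excl)
  out <- h3k27ac_peaks[keep, intersect(c("chrom", "start", "end"),
                                       names(h3k27ac_peaks)), drop = FALSE]
  out$condition <- condition
  as_tibble(out)
}

#' Stratify enhancers by 5-hmC status
#'
#' An enhancer is 5-hmC-positive iff it overlaps any 5-hmC consensus peak
#' by at least 1 bp.
#'
#' @param enhancers interval tibble of enhancer records.
#' @param hmc_peaks interval tibble of 5-hmC consensus peaks.
#' @return `enhancers` with an `hmc_status` column (`positive`/`negative`).
#' @export
classify_by_hmc <- function(enhancers, hmc_peaks) {
  enhancers$hmc_status <- ifelse(overlaps_any(enhancers, hmc_peaks),
                                 "positive", "negative")
  enhancers
}

#' Assign each enhancer its single nearest gene
#'
#' Distance is from the enhancer midpoint to the gene TSS; ties go to the
#' lexicographically smaller gene id (stable). Enhancers on chromosomes
#' without genes are left unassigned (`NA`) with a warning.
#'
#' @param enhancers interval tibble of enhancer records.
#' @param genes gene-model tibble.
#' @return `enhancers` with `nearest_gene_id` and `distance_bp` columns.
#' @export
assign_nearest_gene <- function(enhancers, genes) {
  mid <- floor((enhancers$start + enhancers$end) / 2)
  tss <- tss_position(genes)
  ng <- rep(NA_character_, nrow(enhancers))
  dist <- rep(NA_real_, nrow(enhancers))
  for (cc in unique(enhancers$chrom)) {
    gi <- which(genes$chrom == cc)
    ei <- which(enhancers$chrom == cc)
    if (length(gi) == 0) next
    ord <- gi[order(genes$gene_id[gi])]  # stable lexicographic tie-break
    for (e in ei) {
      d <- abs(mid[e] - tss[ord])
      k <- which.min(d)
      ng[e] <- genes$gene_id[ord[k]]
      dist[e] <- d[k]
    }
  }
  if (anyNA(ng)) {
    warn(sprintf("%d enhancer(s) on chromosomes without genes left unassigned",
                 sum(is.na(ng))))
  }
  enhancers$nearest_gene_id <- ng
  enhancers$distance_bp <- dist
  enhancers
}

#' Expression contrast of genes nearest 5-hmC+ vs 5-hmC- enhancers
#'
#' Mann-Whitney comparison of nearest-gene expression between the two
#' enhancer status groups. By default each enhancer contributes its
#' nearest gene's expression once per enhancer; `dedupe = TRUE` collapses
#' to unique genes per group first.
#'
#' @param enhancers enhancer tibble with `hmc_status` and
#'   `nearest_gene_id`.
#' @param expr tibble with `gene_id` and expression column `value`.
#' @param value expression column name.
#' @param dedupe count each gene once per status group.
#' @return `hmc_mw` comparison, or `NULL` when either group is empty.
#' @export
enhancer_expression_contrast <- function(enhancers, expr, value = "rpkm",
                                         dedupe = FALSE) {
  e <- enhancers[!is.na(enhancers$nearest_gene_id), , drop = FALSE]
  v <- setNames(expr[[value]], expr$gene_id)
  pick <- function(status) {
    g <- e$nearest_gene_id[e$hmc_status == status]
    if (dedupe) g <- unique(g)
    v[g[g %in% names(v)]]
  }
  pos <- pick("positive"); neg <- pick("negative")
  if (length(pos) == 0 || length(neg) == 0) return(NULL)
  mann_whitney(pos, neg, labels = c("hmc_positive", "hmc_negative"))
}

#' Conserved-element overlap fraction by enhancer status
#'
#' Conserved elements are filtered to `score > min_score` (phastCons
#' element scores; 600 marks high conservation); the fraction of enhancers
#' overlapping at least one retained element is reported per 5-hmC status.
#'
#' @param enhancers enhancer tibble with `hmc_status`.
#' @param conserved interval tibble with a `score` column.
#' @param min_score retain elements with score strictly above this.
#' @return Tibble: `hmc_status`, `n`, `n_overlapping`, `fraction`.
#' @export
conservation_overlap <- function(enhancers, conserved, min_score = 600) {
  keep <- conserved[conserved$score > min_score,
                    c("chrom", "start", "end"), drop = FALSE]
  hit <- overlaps_any(enhancers, keep)
  tibble(hmc_status = c("positive", "negative")) |>
    mutate(n = map_int(.data$hmc_status,
                       ~ sum(enhancers$hmc_status == .x)),
           n_overlapping = map_int(.data$hmc_status,
                                   ~ sum(hit[enhancers$hmc_status == .x])),
           fraction = ifelse(.data$n > 0, .data$n_overlapping / .data$n,
                             NA_real_))
}

#' Enhancers losing 5-hmC after knockdown and their gene consequences
#'
#' Intersects fetal 5-hmC+ enhancers with the loss-direction DhMRs of a
#' knockdown-vs-control contrast (>= 1 bp overlap), collects the nearest
#' genes of the lost enhancers, and contrasts their expression between
#' control and knockdown with a Mann-Whitney test.
#'
#' @param enhancers fetal 5-hmC+ enhancer tibble with `nearest_gene_id`.
#' @param loss_dhmrs DhMR tibble filtered or filterable to
#'   `direction == "loss"`.
#' @param expr_contrast tibble: `gene_id`, `control`, `kd` expression.
#' @return List of class `hmc_kd_loss`: `lost_enhancers`,
#'   `affected_genes`, `comparison` (`hmc_mw` or `NULL`).
#' @export
kd_enhancer_loss <- function(enhancers, loss_dhmrs, expr_contrast = NULL) {
  if ("direction" %in% names(loss_dhmrs)) {
    loss_dhmrs <- loss_dhmrs[loss_dhmrs$direction == "loss", , drop = FALSE]
  }
  lost <- enhancers[overlaps_any(enhancers,
                                 loss_dhmrs[, c("chrom", "start", "end")]),
                    , drop = FALSE]
  genes <- sort(unique(lost$nearest_gene_id[!is.na(lost$nearest_gene_id)]))
  cmp <- NULL
  if (!is.null(expr_contrast) && length(genes) > 1) {
    e <- expr_contrast[expr_contrast$gene_id %in% genes, , drop = FALSE]
    if (nrow(e) > 1) {
      cmp <- mann_whitney(e$kd, e$control, labels = c("kd", "control"))
    }
  }
  structure(list(lost_enhancers = as_tibble(lost), affected_genes = genes,
                 comparison = cmp), class = "hmc_kd_loss")
}

#' @export
print.hmc_kd_loss <- function(x, ...) {
  cat(sprintf("<KD enhancer loss> %d lost enhancers, %d affected genes\n",
              nrow(x$lost_enhancers), length(x$affected_genes)))
  if (!is.null(x$comparison)) print(x$comparison)
  invisible(x)
}
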