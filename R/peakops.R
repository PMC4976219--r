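#' Replicate-consensus peaks
#'
#' Base-level intersection of two replicate peak sets: only peak base pairs
#' present in both biological replicates are retained. Also reports, for
#' each replicate, the fraction of its peak bases that survive.
#'
#' @param rep_a,rep_b interval tibbles of called peaks for the two
#'   biological replicates.
#' @param label_a,label_b replicate labels (for the overlap report).
#' @return An interval tibble of consensus peaks with attributes
#'   `retained` (named fractions) accessible via [consensus_retained()].
#' @export
consensus_peaks <- function(rep_a, rep_b, label_a = "repA", label_b = "repB") {
  if (identical(label_a, label_b)) warn("replicate labels are identical")
  cons <- bed_intersect(rep_a, rep_b)
  kept <- bed_bases(cons)
  ba <- bed_bases(rep_a); bb <- bed_bases(rep_b)
  retained <- c(if (ba > 0) kept / ba else 0, if (bb > 0) kept / bb else 0)
  names(retained) <- c(label_a, label_b)
  attr(cons, "retained") <- retained
  cons
}

#' @rdname consensus_peaks
#' @param consensus result of `consensus_peaks()`.
#' @export
consensus_retained <- function(consensus) attr(consensus, "retained")

#' Peak bases common to every condition
#'
#' Multi-way base-level intersection of per-condition consensus peak sets
#' (the intervals shared by all studied stages).
#'
#' @param consensus_sets list of >= 2 consensus peak tibbles.
#' @return Merged interval tibble.
#' @export
common_peaks <- function(consensus_sets) bed_multi_intersect(consensus_sets)

#' Distribution of peaks over genomic elements
#'
#' Each peak is assigned a single category (promoter, TTS flank, exon,
#' intron, intergenic) from its midpoint base via [annotate_position()].
#'
#' @param peaks interval tibble.
#' @param genes gene-model tibble.
#' @param ... passed to [annotate_position()].
#' @return Tibble: `category`, `count`, `fraction` (fractions sum to 1).
#' @export
peak_annotation_distribution <- function(peaks, genes, ...) {
  validate_intervals(peaks, "peak table")
  lv <- c("promoter", "tts_flank", "exon", "intron", "intergenic")
  if (nrow(peaks) == 0) {
    return(tibble(category = factor(lv, levels = lv), count = 0L,
                  fraction = NA_real_))
  }
  mid <- floor((peaks$start + peaks$end) / 2)
  cats <- annotate_position(peaks$chrom, mid, genes, ...)
  tab <- table(cats)
  tibble(category = factor(lv, levels = lv),
         count = as.integer(tab[lv]),
         fraction = as.integer(tab[lv]) / nrow(peaks))
}

#' Classify genes by where their 5-hmC peaks fall
#'
#' Promoter = TSS +/- `promoter_halfwidth`; gene body = TSS->TTS minus the
#' promoter window, so promoter and body evidence are disjoint. A gene is
#' `promoter_only` if peak bases fall in its promoter but not its body,
#' `gb_only` for the converse, `promoter_and_gb` for both, `none` for
#' neither. Any >= 1 bp overlap counts.
#'
#' @param peaks interval tibble of (consensus) peaks.
#' @param genes gene-model tibble.
#' @param promoter_halfwidth promoter half-width in bp.
#' @param build optional genome build for window clipping.
#' @return Tibble: `gene_id`, `class` (factor with the four levels).
#' @export
classify_genes_by_position <- function(peaks, genes, promoter_halfwidth = 1000,
                                       build = NULL) {
  prom <- gene_promoters(genes, promoter_halfwidth, build)
  body <- gene_bodies(genes, exclude_promoter = TRUE,
                      promoter_halfwidth = promoter_halfwidth, build = build)
  pk <- if (nrow(peaks) > 0) bed_merge(peaks) else peaks
  in_prom <- prom$gene_id[overlaps_any(prom, pk)]
  in_body <- unique(body$gene_id[overlaps_any(body, pk)])
  p <- genes$gene_id %in% in_prom
  b <- genes$gene_id %in% in_body
  cls <- case_when(p & b ~ "promoter_and_gb", p ~ "promoter_only",
                   b ~ "gb_only", TRUE ~ "none")
  tibble(gene_id = genes$gene_id,
         class = factor(cls, levels = c("promoter_only", "gb_only",
                                        "promoter_and_gb", "none")))
}

#' Genes with gene-body 5-hmC at every condition
#'
#' Intersection across conditions of the genes whose class is `gb_only` or
#' `promoter_and_gb` (i.e. any gene-body hydroxymethylation).
#'
#' @param class_tables named list of per-condition outputs of
#'   [classify_genes_by_position()] over the same gene universe.
#' @return Character vector of gene ids.
#' @export
genes_gb_all_conditions <- function(class_tables) {
  if (length(class_tables) < 1) abort("need at least one class table")
  gb_sets <- map(class_tables, function(ct) {
    ct$gene_id[ct$class %in% c("gb_only", "promoter_and_gb")]
  })
  sort(Reduce(intersect, gb_sets))
}
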