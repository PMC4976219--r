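#' Gene models
#'
#' A gene-model table is a tibble with one row per transcript/gene:
#' `gene_id`, `chrom`, `start`, `end` (transcribed span, 0-based half-open),
#' `strand` (`+`/`-`) and `exons`, a list-column of tibbles with `start`,
#' `end` columns. The TSS is strand-aware: the leftmost transcribed base on
#' `+`, the rightmost (`end - 1`) on `-`; the TTS is the opposite end.
#'
#' @param gene_id,chrom,strand character vectors.
#' @param start,end numeric, transcribed span.
#' @param exons list of per-gene exon tibbles (`start`, `end`); defaults to
#'   one exon spanning the whole transcript.
#' @return Gene-model tibble.
#' @export
gene_tbl <- function(gene_id, chrom, start, end, strand = "+", exons = NULL) {
  n <- length(gene_id)
  strand <- rep_len(strand, n)
  if (!all(strand %in% c("+", "-"))) abort("strand must be '+' or '-'")
  if (anyDuplicated(gene_id)) abort("gene ids must be unique")
  x <- tibble(gene_id = as.character(gene_id), chrom = as.character(chrom),
              start = as.numeric(start), end = as.numeric(end),
              strand = strand)
  validate_intervals(x, "gene table")
  if (is.null(exons)) {
    exons <- map2(x$start, x$end, ~ tibble(start = .x, end = .y))
  }
  x$exons <- exons
  validate_genes(x)
  x
}

validate_genes <- function(g) {
  validate_intervals(g, "gene table")
  stopifnot(all(c("gene_id", "strand", "exons") %in% names(g)))
  for (i in seq_len(nrow(g))) {
    ex <- g$exons[[i]]
    if (nrow(ex) == 0) abort(sprintf("gene %s has no exons", g$gene_id[i]))
    ex <- ex[order(ex$start), ]
    if (any(ex$end <= ex$start)) {
      abort(sprintf("gene %s has an empty exon", g$gene_id[i]))
    }
    if (nrow(ex) > 1 && any(ex$start[-1] < ex$end[-nrow(ex)])) {
      abort(sprintf("gene %s has overlapping exons", g$gene_id[i]))
    }
    if (ex$start[1] < g$start[i] || ex$end[nrow(ex)] > g$end[i]) {
      abort(sprintf("gene %s has exons outside the transcript", g$gene_id[i]))
    }
  }
  invisible(g)
}

#' Strand-aware TSS and TTS positions
#'
#' @param genes gene-model tibble.
#' @return Numeric vector of base positions (0-based).
#' @export
tss_position <- function(genes) {
  ifelse(genes$strand == "+", genes$start, genes$end - 1)
}

#' @rdname tss_position
#' @export
tts_position <- function(genes) {
  ifelse(genes$strand == "+", genes$end - 1, genes$start)
}

#' Promoter, TTS-flank and gene-body windows
#'
#' Promoters are TSS +/- `halfwidth` (default 1 kb, i.e. -1 kb to +1 kb
#' relative to the TSS); TTS flanks likewise around the TTS. Windows are
#' clipped at chromosome ends when a build is supplied. `gene_bodies()`
#' returns the transcribed span TSS->TTS; with `exclude_promoter = TRUE` the
#' promoter window is removed so promoter and gene-body evidence are
#' disjoint.
#'
#' @param genes gene-model tibble.
#' @param halfwidth window half-width in bp.
#' @param build optional genome build for clipping.
#' @return Interval tibble with a `gene_id` column.
#' @export
gene_promoters <- function(genes, halfwidth = 1000, build = NULL) {
  tss <- tss_position(genes)
  clip_intervals(tibble(chrom = genes$chrom, start = tss - halfwidth,
                        end = tss + halfwidth, gene_id = genes$gene_id), build)
}

#' @rdname gene_promoters
#' @export
gene_tts_flanks <- function(genes, halfwidth = 1000, build = NULL) {
  tts <- tts_position(genes)
  clip_intervals(tibble(chrom = genes$chrom, start = tts - halfwidth,
                        end = tts + halfwidth, gene_id = genes$gene_id), build)
}

#' @rdname gene_promoters
#' @param exclude_promoter drop the promoter window from each body?
#' @param promoter_halfwidth promoter half-width used when excluding.
#' @export
gene_bodies <- function(genes, exclude_promoter = FALSE,
                        promoter_halfwidth = 1000, build = NULL) {
  b <- tibble(chrom = genes$chrom, start = genes$start, end = genes$end,
              gene_id = genes$gene_id)
  if (!exclude_promoter) return(clip_intervals(b, build))
  prom <- gene_promoters(genes, promoter_halfwidth, build)
  out <- map(seq_len(nrow(b)), function(i) {
    d <- bed_subtract(b[i, c("chrom", "start", "end")],
                      prom[i, c("chrom", "start", "end")])
    if (nrow(d) > 0) d$gene_id <- b$gene_id[i]
    d
  })
  clip_intervals(bind_rows(out), build)
}

exon_intervals <- function(genes) {
  if (nrow(genes) == 0) return(empty_intervals())
  bind_rows(map(seq_len(nrow(genes)), function(i) {
    ex <- genes$exons[[i]]
    tibble(chrom = genes$chrom[i], start = ex$start, end = ex$end,
           gene_id = genes$gene_id[i])
  }))
}

#' Annotate genomic positions by feature category
#'
#' Assigns each base position the single highest-precedence category among
#' `promoter > tts_flank > exon > intron > intergenic`. Promoter and TTS
#' windows are TSS/TTS +/- 1 kb by default; introns are gene-body bases that
#' are neither exonic nor inside a promoter/TTS window. UTRs are not
#' distinguished from other exonic sequence.
#'
#' @param chrom character vector of chromosome names.
#' @param pos numeric vector of 0-based base positions.
#' @param genes gene-model tibble.
#' @param promoter_halfwidth,tts_halfwidth window half-widths in bp.
#' @param unknown_chrom what to do for positions on chromosomes absent from
#'   `genes`: `"intergenic"` (with a warning) or `"error"`.
#' @return Factor with levels promoter, tts_flank, exon, intron, intergenic.
#' @export
annotate_position <- function(chrom, pos, genes, promoter_halfwidth = 1000,
                              tts_halfwidth = 1000,
                              unknown_chrom = c("intergenic", "error")) {
  unknown_chrom <- match.arg(unknown_chrom)
  stopifnot(length(chrom) == length(pos))
  lv <- c("promoter", "tts_flank", "exon", "intron", "intergenic")
  unk <- !(chrom %in% unique(genes$chrom))
  if (any(unk)) {
    msg <- sprintf("%d position(s) on chromosome(s) absent from the gene set (e.g. %s)",
                   sum(unk), chrom[which(unk)[1]])
    if (unknown_chrom == "error") abort(msg) else warn(msg)
  }
  pts <- tibble(chrom = chrom, start = pos, end = pos + 1)
  hit <- function(feat) {
    if (nrow(feat) == 0) rep(FALSE, nrow(pts)) else overlaps_any(pts, feat)
  }
  in_prom <- hit(gene_promoters(genes, promoter_halfwidth))
  in_tts <- hit(gene_tts_flanks(genes, tts_halfwidth))
  in_exon <- hit(exon_intervals(genes))
  in_body <- hit(gene_bodies(genes))
  out <- case_when(
    in_prom ~ "promoter",
    in_tts ~ "tts_flank",
    in_exon ~ "exon",
    in_body ~ "intron",
    TRUE ~ "intergenic"
  )
  factor(out, levels = lv)
}

#' Read gene models from BED12
#'
#' Columns 1-12; blocks become exons. Coordinates are BED-native 0-based
#' half-open.
#'
#' @param path BED12 file.
#' @return Gene-model tibble.
#' @export
read_bed12 <- function(path) {
  x <- readr::read_tsv(path, col_names = FALSE, comment = "#",
                       col_types = readr::cols(.default = "c"),
                       progress = FALSE)
  if (ncol(x) < 12) abort(sprintf("%s: BED12 requires 12 columns", path))
  chrom <- as.character(x[[1]]); start <- as.numeric(x[[2]])
  end <- as.numeric(x[[3]]); gene_id <- as.character(x[[4]])
  strand <- as.character(x[[6]])
  n_blocks <- as.integer(x[[10]])
  sizes <- strsplit(gsub(",$", "", as.character(x[[11]])), ",")
  offsets <- strsplit(gsub(",$", "", as.character(x[[12]])), ",")
  exons <- map(seq_along(chrom), function(i) {
    sz <- as.numeric(sizes[[i]]); of <- as.numeric(offsets[[i]])
    if (length(sz) != n_blocks[i] || length(of) != n_blocks[i]) {
      abort(sprintf("%s: block fields disagree with blockCount at line %d", path, i))
    }
    ex_start <- start[i] + of
    tibble(start = ex_start, end = ex_start + sz)
  })
  gene_tbl(gene_id, chrom, start, end, strand, exons)
}

write_bed12 <- function(genes, path) {
  rows <- map_chr(seq_len(nrow(genes)), function(i) {
    ex <- genes$exons[[i]]
    ex <- ex[order(ex$start), ]
    paste(genes$chrom[i], format_coord(genes$start[i]), format_coord(genes$end[i]),
          genes$gene_id[i], 0, genes$strand[i],
          format_coord(genes$start[i]), format_coord(genes$end[i]), "0",
          nrow(ex),
          paste0(paste(format_coord(ex$end - ex$start), collapse = ","), ","),
          paste0(paste(format_coord(ex$start - genes$start[i]), collapse = ","), ","),
          sep = "\t")
  })
  writeLines(rows, path)
  invisible(path)
}

#' Read gene models from a GTF file
#'
#' Uses rtracklayer to parse the GTF (1-based closed coordinates, converted
#' to 0-based half-open on read) and assembles one model per `gene_id` from
#' its exon records.
#'
#' @param path GTF file.
#' @return Gene-model tibble.
#' @export
read_gtf_genes <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    abort("read_gtf_genes() requires the rtracklayer package")
  }
  gr <- rtracklayer::import(path, format = "gtf")
  ex <- as.data.frame(gr[gr$type == "exon"])
  if (nrow(ex) == 0) abort(sprintf("%s: no exon records", path))
  d <- tibble(gene_id = as.character(ex$gene_id),
              chrom = as.character(ex$seqnames),
              start = as.numeric(ex$start) - 1,
              end = as.numeric(ex$end),
              strand = as.character(ex$strand))
  per <- d |> group_by(.data$gene_id) |>
    summarise(chrom = first(.data$chrom), strand = first(.data$strand),
              exons = list(bed_merge(tibble(chrom = "x", start = .data$start,
                                            end = .data$end))[, c("start", "end")]),
              start = min(.data$start), end = max(.data$end),
              .groups = "drop")
  gene_tbl(per$gene_id, per$chrom, per$start, per$end, per$strand, per$exons)
}
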