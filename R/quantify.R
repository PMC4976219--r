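#' Fragment sets
#'
#' A fragment set holds one sample's read/fragment placements (an interval
#' tibble) together with its library size and sample metadata. The library
#' size is the total number of mapped fragments and may exceed the number of
#' fragments loaded (subsampled fixtures stay correctly normalized).
#'
#' @param fragments interval tibble of fragment placements.
#' @param sample_id,condition,replicate,role sample metadata; `role` is
#'   `"IP"` or `"input"`.
#' @param library_size total mapped fragments (defaults to `nrow(fragments)`).
#' @return Object of class `hmc_frags`.
#' @export
fragment_set <- function(fragments, sample_id = "sample", condition = NA_character_,
                         replicate = NA_integer_, role = "IP",
                         library_size = NULL) {
  validate_intervals(fragments, "fragment table")
  library_size <- library_size %||% nrow(fragments)
  if (library_size < nrow(fragments)) {
    abort("library_size smaller than the number of fragments loaded")
  }
  if (!role %in% c("IP", "input")) abort("role must be 'IP' or 'input'")
  structure(list(fragments = as_tibble(fragments), sample_id = sample_id,
                 condition = condition, replicate = replicate, role = role,
                 library_size = as.numeric(library_size)),
            class = "hmc_frags")
}

#' @export
print.hmc_frags <- function(x, ...) {
  cat(sprintf("<fragment set %s> %s/%s role=%s  %d fragments, library %s\n",
              x$sample_id, x$condition, x$replicate, x$role,
              nrow(x$fragments), format(x$library_size, big.mark = ",")))
  invisible(x)
}

frags_of <- function(x) {
  if (inherits(x, "hmc_frags")) x$fragments else {
    validate_intervals(x, "fragment table"); as_tibble(x)
  }
}

libsize_of <- function(x, library_size = NULL) {
  if (!is.null(library_size)) return(as.numeric(library_size))
  if (inherits(x, "hmc_frags")) return(x$library_size)
  nrow(frags_of(x))
}

#' Count fragments overlapping each feature
#'
#' A fragment is counted for every feature it overlaps by at least 1 bp, so
#' a fragment spanning two features contributes to both.
#'
#' @param frags fragment set or interval tibble.
#' @param features interval tibble; one count per row, order preserved.
#' @return Integer vector of per-feature counts.
#' @export
count_overlaps <- function(frags, features) {
  f <- frags_of(frags)
  validate_intervals(features, "feature table")
  out <- integer(nrow(features))
  if (nrow(f) == 0 || nrow(features) == 0) return(out)
  for (cc in intersect(unique(features$chrom), unique(f$chrom))) {
    idx <- which(features$chrom == cc)
    ir_feat <- ir_of(features$start[idx], features$end[idx])
    ir_frag <- ir_of(f$start[f$chrom == cc], f$end[f$chrom == cc])
    out[idx] <- IRanges::countOverlaps(ir_feat, ir_frag)
  }
  out
}

#' Gene-body counts and RPKM
#'
#' Counts fragments falling on each gene from TSS to TTS and normalizes to
#' library size and gene length:
#' `rpkm = count / (gene_length_kb * library_size_millions)`.
#' With `peaks` supplied, only fragments overlapping the peak set are
#' counted (enrichment-level quantification restricted to enriched
#' regions); without it all fragments count (raw coverage).
#'
#' @param frags fragment set (or interval tibble plus `library_size`).
#' @param genes gene-model tibble.
#' @param peaks optional interval tibble restricting counted fragments.
#' @param library_size override for plain tibble input.
#' @return Tibble: `gene_id`, `count`, `rpkm`.
#' @export
gene_body_rpkm <- function(frags, genes, peaks = NULL, library_size = NULL) {
  lib <- libsize_of(frags, library_size)
  if (lib <= 0) abort("library_size must be > 0")
  f <- frags_of(frags)
  if (!is.null(peaks) && nrow(f) > 0) {
    f <- f[overlaps_any(f, peaks), , drop = FALSE]
  }
  body <- tibble(chrom = genes$chrom, start = genes$start, end = genes$end)
  counts <- count_overlaps(f, body)
  len_kb <- (genes$end - genes$start) / 1000
  tibble(gene_id = genes$gene_id, count = counts,
         rpkm = counts / (len_kb * lib / 1e6))
}

#' Library-normalized fragment counts in fixed-width chromosome bins
#'
#' Each fragment is assigned to the bin containing its midpoint (exclusive
#' assignment, so fragments are counted once); bin values are
#' `count / library_size`. The final bin on each chromosome may be short.
#'
#' @param frags fragment set or interval tibble.
#' @param build genome build (named lengths).
#' @param binsize bin width in bp (default 100 kb).
#' @param library_size override for plain tibble input.
#' @return Tibble: `chrom`, `start`, `end`, `count`, `value`.
#' @export
chromosome_bins <- function(frags, build, binsize = 100000,
                            library_size = NULL) {
  if (binsize <= 0) abort("binsize must be > 0")
  lib <- libsize_of(frags, library_size)
  f <- frags_of(frags)
  bins <- bind_rows(lapply(names(build), function(cc) {
    len <- as.numeric(build[[cc]])
    s <- (seq_len(ceiling(len / binsize)) - 1) * binsize
    tibble(chrom = cc, start = s, end = pmin(s + binsize, len))
  }))
  counts <- integer(nrow(bins))
  if (nrow(f) > 0) {
    mid <- floor((f$start + f$end) / 2)
    key_bin <- paste0(bins$chrom, ":", floor(bins$start / binsize))
    key_frag <- paste0(f$chrom, ":", floor(mid / binsize))
    tab <- table(key_frag)
    counts <- as.integer(tab[key_bin])
    counts[is.na(counts)] <- 0L
  }
  bins$count <- counts
  bins$value <- counts / lib
  bins
}

new_profile <- function(bin_center, value, n_anchors, units = "RPM",
                        kind = "anchor") {
  structure(tibble(bin_center = bin_center, value = value),
            n_anchors = n_anchors, units = units, kind = kind,
            class = c("hmc_profile", "tbl_df", "tbl", "data.frame"))
}

# count fragments overlapping each of a stack of per-anchor bins and average
profile_from_bins <- function(f, bins_tbl, n_bins, n_anchors, lib, flip) {
  val <- numeric(n_bins)
  if (nrow(f) > 0 && nrow(bins_tbl) > 0) {
    counts <- count_overlaps(f, bins_tbl)
    idx <- ifelse(flip, n_bins + 1 - bins_tbl$bin, bins_tbl$bin)
    val <- as.numeric(rowsum(counts, idx, reorder = TRUE))
    got <- sort(unique(idx))
    full <- numeric(n_bins); full[got] <- val; val <- full
  }
  val / n_anchors / lib * 1e6
}

#' Metagene coverage profile across scaled gene bodies
#'
#' Average fragment coverage across all gene bodies scaled to a common
#' number of bins, with fixed-width flanking bins on both sides. Minus-strand
#' genes are orientation-flipped before averaging so the left edge is always
#' the TSS. Values are reads per million mapped fragments (RPM), averaged
#' over genes. Genes shorter than `n_body_bins` bp are skipped with a
#' warning. With `peaks` supplied only fragments inside the peak set are
#' profiled (coverage of enriched regions only).
#'
#' @param frags fragment set or interval tibble.
#' @param genes gene-model tibble.
#' @param flank_bp flank width in bp on each side.
#' @param n_body_bins,n_flank_bins bin counts for body and each flank.
#' @param peaks optional interval tibble restricting fragments.
#' @param library_size override for plain tibble input.
#' @return An `hmc_profile` tibble: `bin_center` (relative coordinate;
#'   body bins on a 0-100 percent scale mapped into the flank coordinate),
#'   `value` (RPM).
#' @export
metagene_profile <- function(frags, genes, flank_bp = 2000, n_body_bins = 40,
                             n_flank_bins = 20, peaks = NULL,
                             library_size = NULL) {
  if (nrow(genes) == 0) abort("need at least one gene")
  lib <- libsize_of(frags, library_size)
  f <- frags_of(frags)
  if (!is.null(peaks) && nrow(f) > 0) f <- f[overlaps_any(f, peaks), , drop = FALSE]
  len <- genes$end - genes$start
  short <- len < n_body_bins
  if (any(short)) {
    warn(sprintf("%d gene(s) shorter than n_body_bins bp skipped", sum(short)))
    genes <- genes[!short, , drop = FALSE]
    len <- len[!short]
  }
  if (nrow(genes) == 0) abort("all genes shorter than n_body_bins")
  n_bins <- n_body_bins + 2 * n_flank_bins
  flank_w <- flank_bp / n_flank_bins
  bins <- bind_rows(map(seq_len(nrow(genes)), function(i) {
    up <- tibble(start = genes$start[i] - flank_bp + (seq_len(n_flank_bins) - 1) * flank_w,
                 end = genes$start[i] - flank_bp + seq_len(n_flank_bins) * flank_w)
    bw <- len[i] / n_body_bins
    body <- tibble(start = genes$start[i] + (seq_len(n_body_bins) - 1) * bw,
                   end = genes$start[i] + seq_len(n_body_bins) * bw)
    dn <- tibble(start = genes$end[i] + (seq_len(n_flank_bins) - 1) * flank_w,
                 end = genes$end[i] + seq_len(n_flank_bins) * flank_w)
    out <- bind_rows(up, body, dn)
    out$chrom <- genes$chrom[i]
    out$bin <- seq_len(n_bins)
    out$flip <- genes$strand[i] == "-"
    out
  }))
  bins$start <- floor(bins$start); bins$end <- ceiling(bins$end)
  bins$start <- pmax(bins$start, 0)
  bins <- bins[bins$end > bins$start, , drop = FALSE]
  val <- profile_from_bins(f, bins, n_bins, nrow(genes), lib, bins$flip)
  segment <- rep(c("upstream", "body", "downstream"),
                 c(n_flank_bins, n_body_bins, n_flank_bins))
  out <- new_profile(seq_len(n_bins), val, nrow(genes), kind = "metagene")
  out$segment <- segment
  out
}

#' Coverage profile centred on anchor midpoints
#'
#' Bins of width `binwidth` spanning `+/- halfwidth` around each anchor's
#' midpoint, averaged over anchors, in RPM. Anchors near chromosome edges
#' keep their out-of-range bins, which contribute zero coverage while still
#' entering the anchor average (the effective n at the edges is reduced).
#'
#' @param frags fragment set or interval tibble.
#' @param anchors interval tibble; the anchor point is the midpoint.
#' @param halfwidth,binwidth profile extent and bin width in bp.
#' @param library_size override for plain tibble input.
#' @return An `hmc_profile` tibble: `bin_center` (bp from anchor), `value`.
#' @export
anchor_profile <- function(frags, anchors, halfwidth = 5000, binwidth = 200,
                           library_size = NULL) {
  validate_intervals(anchors, "anchor table")
  if (nrow(anchors) == 0) abort("anchors must be non-empty")
  lib <- libsize_of(frags, library_size)
  f <- frags_of(frags)
  n_bins <- as.integer(2 * halfwidth / binwidth)
  mid <- floor((anchors$start + anchors$end) / 2)
  offs <- -halfwidth + (seq_len(n_bins) - 1) * binwidth
  bins <- tibble(
    chrom = rep(anchors$chrom, each = n_bins),
    start = rep(mid, each = n_bins) + rep(offs, nrow(anchors)),
    end = rep(mid, each = n_bins) + rep(offs + binwidth, nrow(anchors)),
    bin = rep(seq_len(n_bins), nrow(anchors)),
    flip = FALSE
  )
  bins <- bins[bins$end > 0, , drop = FALSE]
  bins$start <- pmax(bins$start, 0)
  bins <- bins[bins$end > bins$start, , drop = FALSE]
  val <- profile_from_bins(f, bins, n_bins, nrow(anchors), lib, bins$flip)
  new_profile(offs + binwidth / 2, val, nrow(anchors), kind = "anchor")
}

#' Pearson correlation between replicate quantifications
#'
#' @param quant_a,quant_b gene quantification tibbles sharing a gene
#'   universe (`gene_id`, `rpkm`).
#' @param log2 correlate `log2(rpkm + pseudo)` rather than raw RPKM.
#' @param pseudo pseudo-count for the log transform.
#' @return Pearson correlation; `NA` when either vector has zero variance.
#' @export
replicate_correlation <- function(quant_a, quant_b, log2 = TRUE, pseudo = 0.5) {
  m <- inner_join(quant_a[, c("gene_id", "rpkm")],
                  quant_b[, c("gene_id", "rpkm")],
                  by = "gene_id", suffix = c("_a", "_b"))
  if (nrow(m) != nrow(quant_a) || nrow(m) != nrow(quant_b)) {
    abort("quantifications do not share the same gene universe")
  }
  a <- m$rpkm_a; b <- m$rpkm_b
  if (log2) { a <- base::log2(a + pseudo); b <- base::log2(b + pseudo) }
  if (sd(a) == 0 || sd(b) == 0) return(NA_real_)
  cor(a, b)
}
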