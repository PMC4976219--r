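#' Genome-wide windowed fragment counts
#'
#' Tiles every chromosome of the build with fixed-width windows (the last
#' window per chromosome may be short) and counts, for each sample, the
#' fragments whose midpoint falls in the window. Midpoint assignment is
#' exclusive, so per-sample column sums equal the number of fragments.
#'
#' @param frag_sets list of fragment sets (see [fragment_set()]).
#' @param build genome build.
#' @param w window width in bp.
#' @return Object of class `hmc_windows`: list with `windows` (interval
#'   tibble), `counts` (windows x samples integer matrix), `library_sizes`,
#'   `conditions`, `samples`.
#' @export
window_counts <- function(frag_sets, build, w = 250) {
  if (w <= 0) abort("window width must be > 0")
  windows <- bind_rows(lapply(names(build), function(cc) {
    len <- as.numeric(build[[cc]])
    s <- (seq_len(ceiling(len / w)) - 1) * w
    tibble(chrom = cc, start = s, end = pmin(s + w, len))
  }))
  key <- paste0(windows$chrom, ":", floor(windows$start / w))
  counts <- matrix(0L, nrow = nrow(windows), ncol = length(frag_sets))
  for (j in seq_along(frag_sets)) {
    f <- frags_of(frag_sets[[j]])
    if (nrow(f) == 0) next
    mid <- floor((f$start + f$end) / 2)
    tab <- table(paste0(f$chrom, ":", floor(mid / w)))
    v <- as.integer(tab[key]); v[is.na(v)] <- 0L
    counts[, j] <- v
  }
  samples <- map_chr(frag_sets, function(fs) {
    if (inherits(fs, "hmc_frags")) fs$sample_id else "sample"
  })
  colnames(counts) <- make.unique(samples)
  structure(list(
    windows = windows, counts = counts,
    library_sizes = map_dbl(frag_sets, libsize_of),
    conditions = map_chr(frag_sets, function(fs) {
      if (inherits(fs, "hmc_frags")) as.character(fs$condition) else NA_character_
    }),
    samples = colnames(counts), width = w
  ), class = "hmc_windows")
}

#' @export
print.hmc_windows <- function(x, ...) {
  cat(sprintf("<windowed counts> %d windows x %d samples (w = %s bp)\n",
              nrow(x$counts), ncol(x$counts), format(x$width)))
  invisible(x)
}

#' Common negative-binomial dispersion from replicate variability
#'
#' Pooled method-of-moments estimate of the common NB dispersion phi
#' (variance = mu + phi mu^2) from library-size-adjusted window counts.
#' Counts are scaled to the geometric-mean library; within each condition
#' with >= 2 replicates the per-window sample mean and variance contribute
#' `sum(s2 - xbar) / sum(xbar^2 - xbar/n)`, a ratio whose expectation is
#' `phi / (1 + phi/n)`; the small-sample correction inverts that. Windows
#' in the upper/lower 5% of mean count can be trimmed to guard against
#' outlier regions. Under-dispersed data give phi = 0 (Poisson).
#'
#' @param wc `hmc_windows` object (or a bare counts matrix plus
#'   `conditions`/`library_sizes`).
#' @param trim trim fraction applied to each tail of the window-mean
#'   distribution (default 0.05, the central 90%).
#' @param prior_phi returned (with a warning) when no condition has
#'   replicate structure.
#' @return List of class `hmc_dispersion`: `phi`, `n_windows_used`.
#' @export
estimate_common_dispersion <- function(wc, trim = 0.05, prior_phi = 0.05) {
  counts <- wc$counts; conds <- wc$conditions; libs <- wc$library_sizes
  lstar <- exp(mean(log(libs)))
  adj <- sweep(counts, 2, lstar / libs, `*`)
  num <- 0; den <- 0; used <- 0L
  for (cc in unique(conds)) {
    j <- which(conds == cc)
    n <- length(j)
    if (n < 2) next
    y <- adj[, j, drop = FALSE]
    xbar <- rowMeans(y)
    s2 <- apply(y, 1, var)
    keep <- xbar > 0
    if (trim > 0 && sum(keep) > 20) {
      qs <- quantile(xbar[keep], c(trim, 1 - trim))
      keep <- keep & xbar >= qs[1] & xbar <= qs[2]
    }
    num <- num + sum(s2[keep] - xbar[keep])
    den <- den + sum(xbar[keep]^2 - xbar[keep] / n)
    used <- used + sum(keep)
    n_for_corr <- n
  }
  if (used == 0L) {
    warn("no condition has >= 2 replicates; returning prior dispersion")
    return(structure(list(phi = prior_phi, n_windows_used = 0L),
                     class = "hmc_dispersion"))
  }
  r <- num / den
  phi <- if (r <= 0) 0 else r / max(1 - r / n_for_corr, 1e-8)
  structure(list(phi = max(0, phi), n_windows_used = used),
            class = "hmc_dispersion")
}

#' @export
print.hmc_dispersion <- function(x, ...) {
  cat(sprintf("<common dispersion> phi = %.4f (%d windows)\n",
              x$phi, x$n_windows_used))
  invisible(x)
}

# conditional two-sided exact p for one window.
# Pooled counts ya, yb; na, nb replicates; phi common per-sample dispersion;
# pr_a = expected share of the total falling in condition A under the null.
exact_p_one <- function(ya, yb, na, nb, phi, pr_a) {
  t <- ya + yb
  if (t == 0) return(1)
  k <- 0:t
  if (phi <= 0) {
    logp <- dbinom(k, t, pr_a, log = TRUE)
  } else {
    mu_a <- t * pr_a; mu_b <- t * (1 - pr_a)
    logp <- dnbinom(k, size = na / phi, mu = mu_a, log = TRUE) +
      dnbinom(t - k, size = nb / phi, mu = mu_b, log = TRUE)
    logp <- logp - matrixStats_logsumexp(logp)
  }
  obs <- logp[ya + 1]
  # binom.test convention: sum outcomes no more probable than the observed
  sum(exp(logp[logp <= obs + log(1 + 1e-7)]))
}

matrixStats_logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

#' Negative-binomial exact test on windowed counts
#'
#' Two-condition exact test in the spirit of the small-sample NB exact test
#' used by edgeR: counts are scaled to the geometric-mean library, pooled
#' within condition, and the split of each window's pooled total between
#' conditions is compared with its conditional null distribution under a
#' common dispersion `phi` (`phi = 0` degenerates to the two-sided binomial
#' exact test). The two-sided p-value sums all outcomes no more probable
#' than the one observed. `logFC` is
#' `log2((yB + 0.5)/libB_eff) - log2((yA + 0.5)/libA_eff)` on the pooled
#' scaled counts, so positive values are gains in condition B.
#'
#' @param counts_a,counts_b matrices (windows x replicates) or vectors of
#'   per-window counts for the two conditions.
#' @param lib_a,lib_b per-replicate library sizes.
#' @param phi common NB dispersion (>= 0).
#' @return Tibble: `p_value`, `logfc`, `total` (pooled scaled total).
#' @export
nb_exact_test <- function(counts_a, counts_b, lib_a, lib_b, phi = 0) {
  if (phi < 0) abort("phi must be >= 0")
  ma <- as.matrix(counts_a); mb <- as.matrix(counts_b)
  if (nrow(ma) != nrow(mb)) abort("count inputs differ in window number")
  na <- ncol(ma); nb <- ncol(mb)
  if (length(lib_a) != na || length(lib_b) != nb) {
    abort("library sizes do not match replicate counts")
  }
  lstar <- exp(mean(log(c(lib_a, lib_b))))
  ya <- round(as.numeric(ma %*% (lstar / lib_a)))
  yb <- round(as.numeric(mb %*% (lstar / lib_b)))
  lib_a_eff <- na * lstar; lib_b_eff <- nb * lstar
  pr_a <- lib_a_eff / (lib_a_eff + lib_b_eff)
  p <- map_dbl(seq_along(ya), function(i) {
    exact_p_one(ya[i], yb[i], na, nb, phi, pr_a)
  })
  logfc <- log2((yb + 0.5) / lib_b_eff) - log2((ya + 0.5) / lib_a_eff)
  tibble(p_value = pmin(p, 1), logfc = logfc, total = ya + yb)
}

#' Call differentially hydroxymethylated regions
#'
#' Windows with `p <= alpha` (the raw-p rule; no multiplicity correction by
#' default, BH optional) and a common direction are merged into DhMRs when
#' separated by at most `max_gap_windows` non-significant windows. Each
#' record keeps the minimum constituent p-value and the count-weighted mean
#' log2 fold change.
#'
#' @param wc `hmc_windows` object supplying window coordinates.
#' @param stats per-window tibble from [nb_exact_test()] (rows aligned with
#'   `wc$windows`).
#' @param alpha significance threshold on the window p-value.
#' @param max_gap_windows maximum number of intervening windows to bridge.
#' @param adjust apply Benjamini-Hochberg correction before thresholding.
#' @return Tibble of DhMRs: `chrom`, `start`, `end`, `direction`
#'   (gain/loss, gain meaning higher in condition B), `logfc`, `p_value`,
#'   `n_windows`.
#' @export
call_dhmrs <- function(wc, stats, alpha = 0.05, max_gap_windows = 1,
                       adjust = FALSE) {
  if (alpha <= 0 || alpha >= 1) abort("alpha must be in (0,1)")
  win <- wc$windows
  if (nrow(win) != nrow(stats)) abort("stats rows do not match windows")
  p <- if (adjust) p.adjust(stats$p_value, "BH") else stats$p_value
  sig <- which(p <= alpha & stats$logfc != 0)
  if (length(sig) == 0) {
    return(tibble(chrom = character(), start = numeric(), end = numeric(),
                  direction = character(), logfc = numeric(),
                  p_value = numeric(), n_windows = integer()))
  }
  d <- tibble(idx = sig, chrom = win$chrom[sig], start = win$start[sig],
              end = win$end[sig],
              direction = ifelse(stats$logfc[sig] > 0, "gain", "loss"),
              logfc = stats$logfc[sig], p_value = p[sig],
              weight = pmax(stats$total[sig], 1))
  d <- d[order(d$chrom, d$start), ]
  new_grp <- c(TRUE, d$chrom[-1] != d$chrom[-nrow(d)] |
                 d$direction[-1] != d$direction[-nrow(d)] |
                 (d$idx[-1] - d$idx[-nrow(d)]) > (max_gap_windows + 1))
  d$grp <- cumsum(new_grp)
  d |> group_by(.data$grp) |>
    summarise(chrom = first(.data$chrom), start = min(.data$start),
              end = max(.data$end), direction = first(.data$direction),
              logfc = sum(.data$logfc * .data$weight) / sum(.data$weight),
              p_value = min(.data$p_value), n_windows = n(),
              .groups = "drop") |>
    select(-"grp")
}

#' Two-condition windowed differential analysis
#'
#' Convenience wrapper: builds window counts for the two conditions,
#' estimates the common dispersion from replicate variability, runs the
#' exact test and calls DhMRs.
#'
#' @param frag_sets_a,frag_sets_b lists of fragment sets (replicates of
#'   conditions A and B).
#' @param build genome build.
#' @param w window width (bp).
#' @param alpha DhMR p-value threshold.
#' @param max_gap_windows gap bridging for region merging.
#' @param phi fixed dispersion; `NULL` (default) estimates it.
#' @return List of class `hmc_dhmr_run`: `dhmrs`, `stats`, `windows`
#'   (`hmc_windows`), `phi`.
#' @export
dhmr_analysis <- function(frag_sets_a, frag_sets_b, build, w = 250,
                          alpha = 0.05, max_gap_windows = 1, phi = NULL) {
  wc <- window_counts(c(frag_sets_a, frag_sets_b), build, w)
  ja <- seq_along(frag_sets_a)
  jb <- length(frag_sets_a) + seq_along(frag_sets_b)
  if (is.null(phi)) phi <- estimate_common_dispersion(wc)$phi
  st <- nb_exact_test(wc$counts[, ja, drop = FALSE],
                      wc$counts[, jb, drop = FALSE],
                      wc$library_sizes[ja], wc$library_sizes[jb], phi)
  dh <- call_dhmrs(wc, st, alpha = alpha, max_gap_windows = max_gap_windows)
  structure(list(dhmrs = dh, stats = st, windows = wc, phi = phi),
            class = "hmc_dhmr_run")
}

#' @export
print.hmc_dhmr_run <- function(x, ...) {
  cat(sprintf("<DhMR analysis> %d regions (%d gain, %d loss), phi = %.4f\n",
              nrow(x$dhmrs), sum(x$dhmrs$direction == "gain"),
              sum(x$dhmrs$direction == "loss"), x$phi))
  invisible(x)
}

#' Per-gene NB differential expression on synthetic counts
#'
#' Applies the windowed exact test machinery to gene-level counts and
#' Benjamini-Hochberg-adjusts the p-values; genes are significant at
#' `q <= 0.05`. A stand-in for an external differential-expression table
#' when only synthetic counts exist.
#'
#' @param counts genes x samples matrix of counts (rownames = gene ids).
#' @param conditions length-ncol character vector with exactly two levels.
#' @param lib_sizes per-sample library sizes (defaults to column sums).
#' @param phi common dispersion; `NULL` estimates it from the counts.
#' @param alpha q-value threshold for the `significant` flag.
#' @return Tibble: `gene_id`, `log2fc`, `p`, `q`, `direction`,
#'   `significant`.
#' @export
differential_expression_nb <- function(counts, conditions, lib_sizes = NULL,
                                       phi = NULL, alpha = 0.05) {
  counts <- as.matrix(counts)
  lv <- unique(conditions)
  if (length(lv) != 2) abort("conditions must have exactly two levels")
  ja <- which(conditions == lv[1]); jb <- which(conditions == lv[2])
  if (length(ja) < 2 || length(jb) < 2) {
    abort("need >= 2 replicates per condition")
  }
  lib_sizes <- lib_sizes %||% colSums(counts)
  if (is.null(phi)) {
    wc <- list(counts = counts, conditions = conditions,
               library_sizes = lib_sizes)
    phi <- estimate_common_dispersion(wc)$phi
  }
  st <- nb_exact_test(counts[, ja, drop = FALSE], counts[, jb, drop = FALSE],
                      lib_sizes[ja], lib_sizes[jb], phi)
  q <- p.adjust(st$p_value, "BH")
  tibble(gene_id = rownames(counts) %||% as.character(seq_len(nrow(counts))),
         log2fc = st$logfc, p = st$p_value, q = q,
         direction = ifelse(st$logfc > 0, "up",
                            ifelse(st$logfc < 0, "down", "none")),
         significant = q <= alpha & st$logfc != 0)
}

#' Integrate DhMRs with differential expression on gene bodies
#'
#' Genes are partitioned into those undergoing solely 5-hmC gain on the
#' gene body and those undergoing solely loss (a gene carrying both gain
#' and loss DhMRs is excluded from either "solely" set), then intersected
#' with the up- and downregulated gene sets (`q <= 0.05`). Also reports the
#' Mann-Whitney comparison of expression change (log2 fold change) between
#' the gain and loss gene sets.
#'
#' @param dhmrs DhMR tibble (from [call_dhmrs()]).
#' @param genes gene-model tibble (gene body = TSS->TTS span).
#' @param de_table differential-expression tibble with `gene_id`, `log2fc`,
#'   `q`, `direction` columns (contract of
#'   [differential_expression_nb()]).
#' @param alpha q-value threshold for calling a gene up/down.
#' @return List of class `hmc_dhmr_expr`: gene-id vectors `gain_only`,
#'   `loss_only`, `up`, `down`, `gain_and_up`, `loss_and_down`, and
#'   `expression_shift` (an `hmc_mw` comparison, or `NULL` when a side is
#'   empty).
#' @export
dhmr_expression_overlap <- function(dhmrs, genes, de_table, alpha = 0.05) {
  missing_ids <- setdiff(genes$gene_id, de_table$gene_id)
  if (length(missing_ids) > 0) {
    abort(paste0("de_table lacks gene(s): ",
                 paste(head(missing_ids, 5), collapse = ", "),
                 if (length(missing_ids) > 5) ", ..." else ""))
  }
  body <- gene_bodies(genes)
  hit_genes <- function(set) {
    if (nrow(set) == 0) return(character())
    unique(body$gene_id[overlaps_any(body, set)])
  }
  gain_genes <- hit_genes(dhmrs[dhmrs$direction == "gain", , drop = FALSE])
  loss_genes <- hit_genes(dhmrs[dhmrs$direction == "loss", , drop = FALSE])
  both <- intersect(gain_genes, loss_genes)
  gain_only <- setdiff(gain_genes, both)
  loss_only <- setdiff(loss_genes, both)
  de <- de_table[de_table$gene_id %in% genes$gene_id, , drop = FALSE]
  up <- de$gene_id[de$q <= alpha & de$direction == "up"]
  down <- de$gene_id[de$q <= alpha & de$direction == "down"]
  shift <- NULL
  lfc <- setNames(de$log2fc, de$gene_id)
  if (length(gain_only) > 0 && length(loss_only) > 0) {
    shift <- mann_whitney(lfc[gain_only], lfc[loss_only],
                          labels = c("gain", "loss"))
  }
  structure(list(gain_only = sort(gain_only), loss_only = sort(loss_only),
                 up = sort(up), down = sort(down),
                 gain_and_up = sort(intersect(gain_only, up)),
                 loss_and_down = sort(intersect(loss_only, down)),
                 expression_shift = shift),
            class = "hmc_dhmr_expr")
}

#' @export
print.hmc_dhmr_expr <- function(x, ...) {
  cat(sprintf(
    "<DhMR x expression> gain-only %d, loss-only %d, up %d, down %d; gain&up %d, loss&down %d\n",
    length(x$gain_only), length(x$loss_only), length(x$up), length(x$down),
    length(x$gain_and_up), length(x$loss_and_down)))
  invisible(x)
}
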