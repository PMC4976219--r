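#' Two-sided Mann-Whitney U test
#'
#' Rank-sum comparison of two groups. For small problems (number of
#' distinct group-A/group-B arrangements up to `exact_max_comb`) the exact
#' permutation distribution of U is enumerated, which handles ties exactly;
#' larger problems use the normal approximation with the tie-corrected
#' variance and a 0.5 continuity correction. The two-sided p-value is the
#' probability of a U at least as far from its null mean as the observed
#' one.
#'
#' @param x,y numeric vectors for the two groups.
#' @param labels length-2 character vector of group labels.
#' @param exact_max_comb enumerate exactly when `choose(n, n_x)` is at most
#'   this (default covers all n_x, n_y <= 8).
#' @return Object of class `hmc_mw` with `u`, `p_value`, `method` and
#'   per-group summaries; see [tidy()] and [glance()].
#' @export
mann_whitney <- function(x, y, labels = c("A", "B"), exact_max_comb = 20000) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) == 0 || length(y) == 0) abort("both groups must be non-empty")
  nx <- length(x); ny <- length(y); n <- nx + ny
  pooled <- c(x, y)
  r <- rank(pooled)
  u <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  mu <- nx * ny / 2
  if (choose(n, nx) <= exact_max_comb) {
    combs <- utils::combn(n, nx)
    us <- colSums(matrix(r[combs], nrow = nx)) - nx * (nx + 1) / 2
    p <- mean(abs(us - mu) >= abs(u - mu) - 1e-9)
    method <- "exact enumeration"
  } else {
    ties <- table(r)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- nx * ny / 12 * (n + 1 - tie_term)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (abs(u - mu) - 0.5) / sqrt(sigma2)
      p <- min(1, 2 * pnorm(z, lower.tail = FALSE))
    }
    method <- "normal approximation (tie-corrected)"
  }
  qs <- function(v) stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
  structure(list(
    groups = tibble(group = labels, n = c(nx, ny),
                    q1 = c(qs(x)[1], qs(y)[1]),
                    median = c(qs(x)[2], qs(y)[2]),
                    q3 = c(qs(x)[3], qs(y)[3])),
    u = u, p_value = p, method = method), class = "hmc_mw")
}

#' @export
print.hmc_mw <- function(x, ...) {
  cat(sprintf("<Mann-Whitney> U = %.1f, p = %.4g (%s)\n", x$u, x$p_value,
              x$method))
  print(x$groups)
  invisible(x)
}

#' @export
tidy.hmc_mw <- function(x, ...) x$groups

#' @export
glance.hmc_mw <- function(x, ...) {
  tibble(u = x$u, p_value = x$p_value, method = x$method,
         n_total = sum(x$groups$n))
}

#' Expression contrast by 5-hmC position class
#'
#' For each class (`promoter_only`, `gb_only`, `promoter_and_gb`) compares
#' the expression of the class genes against all genes with a two-sided
#' Mann-Whitney test. Classes with no genes yield `NA` rows.
#'
#' @param expr tibble with `gene_id` and an expression column.
#' @param classes output of [classify_genes_by_position()].
#' @param value name of the expression column in `expr`.
#' @return Tibble: `class`, `n`, `median`, `median_all`, `u`, `p_value`.
#' @export
expression_by_position_class <- function(expr, classes, value = "rpkm") {
  e <- inner_join(expr, classes, by = "gene_id")
  v <- e[[value]]
  if (is.null(v)) abort(sprintf("no column '%s' in expr", value))
  lv <- c("promoter_only", "gb_only", "promoter_and_gb")
  bind_rows(map(lv, function(cl) {
    g <- v[e$class == cl]
    if (length(g) == 0) {
      return(tibble(class = cl, n = 0L, median = NA_real_,
                    median_all = median(v), u = NA_real_, p_value = NA_real_))
    }
    mw <- mann_whitney(g, v, labels = c(cl, "all"))
    tibble(class = cl, n = length(g), median = median(g),
           median_all = median(v), u = mw$u, p_value = mw$p_value)
  }))
}

#' Gene-body 5-hmC across expression quartiles
#'
#' Restricts to expressed genes (RPKM >= `min_expr`), splits them into
#' expression quartiles (ties broken by stable input order), reports the
#' median gene-body 5-hmC coverage per quartile and a seeded permutation
#' p-value for a monotone increasing trend (statistic: Spearman correlation
#' between expression rank and coverage; one-sided, larger means
#' increasing).
#'
#' @param expr tibble with `gene_id` and expression column `value`.
#' @param gb_coverage tibble with `gene_id` and coverage column
#'   `coverage_value`.
#' @param value,coverage_value column names.
#' @param min_expr expressed-gene threshold (default RPKM >= 1).
#' @param n_perm permutations for the trend test.
#' @param seed RNG seed for the permutation test.
#' @return Object of class `hmc_quartiles`: `quartiles` tibble (`quartile`,
#'   `n`, `median_coverage`), `trend_rho`, `trend_p`, `n_genes`.
#' @export
quartile_trend <- function(expr, gb_coverage, value = "rpkm",
                           coverage_value = "rpkm", min_expr = 1,
                           n_perm = 10000, seed = 1) {
  m <- inner_join(
    tibble(gene_id = expr$gene_id, expr = expr[[value]]),
    tibble(gene_id = gb_coverage$gene_id, cov = gb_coverage[[coverage_value]]),
    by = "gene_id")
  m <- m[m$expr >= min_expr, , drop = FALSE]
  if (nrow(m) < 8) abort("fewer than 8 expressed genes")
  r <- rank(m$expr, ties.method = "first")
  m$quartile <- ceiling(4 * r / nrow(m))
  qt <- m |> group_by(.data$quartile) |>
    summarise(n = n(), median_coverage = median(.data$cov), .groups = "drop")
  if (sd(m$cov) == 0) {
    rho <- 0; p <- 1
  } else {
    cr <- rank(m$cov)
    rho <- cor(r, cr)
    obs <- sum(r * cr)
    perms <- with_seed_preserved(seed, function() {
      vapply(seq_len(n_perm), function(i) sum(r * sample(cr)), numeric(1))
    })
    p <- (1 + sum(perms >= obs)) / (1 + n_perm)
  }
  structure(list(quartiles = qt, trend_rho = rho, trend_p = p,
                 n_genes = nrow(m)), class = "hmc_quartiles")
}

#' @export
print.hmc_quartiles <- function(x, ...) {
  cat(sprintf("<expression-quartile trend> %d genes, rho = %.3f, p = %.4g\n",
              x$n_genes, x$trend_rho, x$trend_p))
  print(x$quartiles)
  invisible(x)
}

#' @export
tidy.hmc_quartiles <- function(x, ...) x$quartiles

#' @export
glance.hmc_quartiles <- function(x, ...) {
  tibble(n_genes = x$n_genes, trend_rho = x$trend_rho, trend_p = x$trend_p)
}

#' Expression by joint 5-hmC / histone-mark gene-body status
#'
#' For each histone mark, genes are split into four groups (neither, 5-hmC
#' only, mark only, both on the gene body) and all pairwise Mann-Whitney
#' comparisons of expression are reported with BH correction across the
#' pairs of each mark. Empty groups yield `NA` comparisons.
#'
#' @param expr tibble with `gene_id` and expression column `value`.
#' @param gb_hmc_genes character vector: genes with gene-body 5-hmC.
#' @param mark_gene_sets named list of character vectors: genes with the
#'   mark's peaks on the gene body.
#' @param value expression column name.
#' @return List with `groups` (per mark/group n and median) and
#'   `comparisons` (mark, group_a, group_b, u, p_value, q_value).
#' @export
histone_comarking <- function(expr, gb_hmc_genes, mark_gene_sets,
                              value = "rpkm") {
  v <- setNames(expr[[value]], expr$gene_id)
  out_groups <- list(); out_cmp <- list()
  for (mark in names(mark_gene_sets)) {
    mk <- mark_gene_sets[[mark]]
    grp <- list(
      neither = setdiff(names(v), union(gb_hmc_genes, mk)),
      hmc_only = setdiff(intersect(names(v), gb_hmc_genes), mk),
      mark_only = setdiff(intersect(names(v), mk), gb_hmc_genes),
      both = intersect(intersect(names(v), gb_hmc_genes), mk))
    out_groups[[mark]] <- tibble(
      mark = mark, group = names(grp),
      n = unname(map_int(grp, length)),
      median = unname(map_dbl(grp, function(g) {
        if (length(g) == 0) NA_real_ else median(v[g])
      })))
    pairs <- utils::combn(names(grp), 2)
    cmp <- map(seq_len(ncol(pairs)), function(j) {
      ga <- grp[[pairs[1, j]]]; gb <- grp[[pairs[2, j]]]
      if (length(ga) == 0 || length(gb) == 0) {
        return(tibble(mark = mark, group_a = pairs[1, j],
                      group_b = pairs[2, j], u = NA_real_,
                      p_value = NA_real_))
      }
      mw <- mann_whitney(v[ga], v[gb])
      tibble(mark = mark, group_a = pairs[1, j], group_b = pairs[2, j],
             u = mw$u, p_value = mw$p_value)
    })
    cmp <- bind_rows(cmp)
    cmp$q_value <- p.adjust(cmp$p_value, "BH")
    out_cmp[[mark]] <- cmp
  }
  list(groups = bind_rows(out_groups), comparisons = bind_rows(out_cmp))
}

#' Neonatal gene-body 5-hmC by CpG-demethylation depth
#'
#' Genes are grouped by the change in CpG methylation percentage between
#' adult and neonatal cells at the thresholds Delta <= -1, -10, -15, -20.
#' Groups are cumulative/nested by default (a gene with Delta = -12 belongs
#' to the -1 and -10 groups); `mode = "exclusive"` bins genes between
#' consecutive thresholds instead. Reports each group's median neonatal
#' gene-body 5-hmC and the Spearman correlation between demethylation depth
#' and coverage.
#'
#' @param deltas tibble: `gene_id`, `delta_mcg` (percentage points, adult
#'   minus neonatal).
#' @param coverage tibble: `gene_id` and coverage column `value`.
#' @param thresholds descending Delta thresholds.
#' @param mode `"cumulative"` (nested groups) or `"exclusive"`.
#' @param value coverage column name.
#' @return Tibble: `threshold`, `n`, `median_coverage`, with attribute
#'   `trend_rho` (Spearman of -delta vs coverage over grouped genes).
#' @export
demethylation_grouping <- function(deltas, coverage,
                                   thresholds = c(-1, -10, -15, -20),
                                   mode = c("cumulative", "exclusive"),
                                   value = "rpkm") {
  mode <- match.arg(mode)
  if (any(deltas$delta_mcg < -100 | deltas$delta_mcg > 100)) {
    abort("delta_mcg must lie in [-100, 100]")
  }
  m <- inner_join(deltas, tibble(gene_id = coverage$gene_id,
                                 cov = coverage[[value]]), by = "gene_id")
  thresholds <- sort(thresholds, decreasing = TRUE)
  rows <- map(seq_along(thresholds), function(i) {
    t_hi <- thresholds[i]
    keep <- m$delta_mcg <= t_hi
    if (mode == "exclusive" && i < length(thresholds)) {
      keep <- keep & m$delta_mcg > thresholds[i + 1]
    }
    tibble(threshold = t_hi, n = sum(keep),
           median_coverage = if (any(keep)) median(m$cov[keep]) else NA_real_)
  })
  out <- bind_rows(rows)
  grouped <- m[m$delta_mcg <= max(thresholds), , drop = FALSE]
  attr(out, "trend_rho") <- if (nrow(grouped) > 2 && sd(grouped$cov) > 0 &&
                                sd(grouped$delta_mcg) > 0) {
    cor(-grouped$delta_mcg, grouped$cov, method = "spearman")
  } else NA_real_
  out
}

#' Library-normalized 5-hmC reads in peaks over repeat classes
#'
#' For each repeat class, the mean over replicates of the number of
#' fragments falling inside peak bases overlapping that class's repeats,
#' divided by the library size. Optionally correlates the per-class values
#' with a supplied repeat-class expression table.
#'
#' @param frag_sets list of replicate fragment sets.
#' @param peaks interval tibble (consensus 5-hmC peaks).
#' @param repeats interval tibble with a `repeat_class` (or `name`) column.
#' @param repeat_expression optional tibble: `repeat_class`, `expression`.
#' @return Tibble: `repeat_class`, `value` (mean normalized reads-in-peaks),
#'   plus `expression` and attributes `pearson`, `spearman` when expression
#'   is supplied.
#' @export
repeat_hmc_expression <- function(frag_sets, peaks, repeats,
                                  repeat_expression = NULL) {
  cls_col <- if ("repeat_class" %in% names(repeats)) "repeat_class" else "name"
  if (!cls_col %in% names(repeats)) abort("repeats need a repeat_class column")
  classes <- sort(unique(as.character(repeats[[cls_col]])))
  if (length(classes) == 0 || any(!nzchar(classes))) {
    abort("repeat classes must be non-empty labels")
  }
  vals <- map(classes, function(cl) {
    reg <- bed_intersect(peaks, repeats[repeats[[cls_col]] == cl,
                                        c("chrom", "start", "end")])
    per_rep <- map_dbl(frag_sets, function(fs) {
      f <- frags_of(fs)
      if (nrow(reg) == 0 || nrow(f) == 0) return(0)
      sum(overlaps_any(f, reg)) / libsize_of(fs)
    })
    mean(per_rep)
  })
  out <- tibble(repeat_class = classes, value = unlist(vals))
  if (!is.null(repeat_expression)) {
    out <- left_join(out, repeat_expression, by = "repeat_class")
    ok <- complete.cases(out[, c("value", "expression")])
    attr(out, "pearson") <- if (sum(ok) > 2) cor(out$value[ok], out$expression[ok]) else NA_real_
    attr(out, "spearman") <- if (sum(ok) > 2) cor(out$value[ok], out$expression[ok], method = "spearman") else NA_real_
  }
  out
}

#' Histone-mark coverage over elements split by 5-hmC status
#'
#' Elements (e.g. LINE repeats) are split by whether they overlap the 5-hmC
#' peak set; per element the mark coverage is the library-normalized count
#' of mark fragments falling inside the element's bases that lie within
#' mark-enriched regions (only enriched regions are considered). The two
#' groups are compared with a Mann-Whitney test.
#'
#' @param mark_frags fragment set of the histone mark.
#' @param mark_peaks interval tibble of the mark's enriched regions.
#' @param elements interval tibble of elements to split.
#' @param hmc_peaks interval tibble of 5-hmC peaks defining the split.
#' @return List: `elements` (per-element tibble with `hmc_status`,
#'   `coverage`), `comparison` (`hmc_mw` or `NULL` when a group is empty).
#' @export
mark_over_element_groups <- function(mark_frags, mark_peaks, elements,
                                     hmc_peaks) {
  validate_intervals(elements, "element table")
  status <- ifelse(overlaps_any(elements, hmc_peaks), "hmc_pos", "hmc_neg")
  f <- frags_of(mark_frags)
  lib <- libsize_of(mark_frags)
  cov <- map_dbl(seq_len(nrow(elements)), function(i) {
    reg <- bed_intersect(elements[i, c("chrom", "start", "end")], mark_peaks)
    if (nrow(reg) == 0) return(0)
    sum(overlaps_any(f, reg)) / lib * 1e6
  })
  el <- elements
  el$hmc_status <- status
  el$coverage <- cov
  cmp <- NULL
  if (all(c("hmc_pos", "hmc_neg") %in% status)) {
    cmp <- mann_whitney(cov[status == "hmc_pos"], cov[status == "hmc_neg"],
                        labels = c("hmc_pos", "hmc_neg"))
  }
  list(elements = as_tibble(el), comparison = cmp)
}
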