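# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's interval machinery: everything is per-base boolean
# vectors or quadratic loops on tiny instances.

# random interval set on a toy genome (list of per-chrom lengths)
random_intervals <- function(n, chrom_lengths, max_width = 500) {
  chroms <- names(chrom_lengths)
  cc <- sample(chroms, n, replace = TRUE)
  len <- unname(unlist(chrom_lengths))[match(cc, chroms)]
  start <- floor(runif(n) * (len - 1))
  width <- 1 + floor(runif(n) * pmin(max_width, len - start - 1e-9))
  tibble::tibble(chrom = cc, start = start, end = pmin(start + width, len))
}

# per-base boolean cover of an interval set
base_mask <- function(x, chrom_lengths) {
  lapply(names(chrom_lengths), function(cc) {
    v <- logical(chrom_lengths[[cc]])
    rows <- which(x$chrom == cc)
    for (i in rows) v[(x$start[i] + 1):x$end[i]] <- TRUE
    v
  }) |> stats::setNames(names(chrom_lengths))
}

# boolean mask -> merged interval tibble
mask_to_intervals <- function(masks) {
  out <- list()
  for (cc in names(masks)) {
    v <- masks[[cc]]
    d <- diff(c(FALSE, v, FALSE))
    starts <- which(d == 1) - 1
    ends <- which(d == -1) - 1
    if (length(starts) > 0) {
      out[[cc]] <- tibble::tibble(chrom = cc, start = starts, end = ends)
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(chrom = character(), start = numeric(),
                          end = numeric()))
  }
  dplyr::bind_rows(out)
}

expect_same_intervals <- function(got, want) {
  got <- dplyr::arrange(got[, c("chrom", "start", "end")], chrom, start)
  want <- dplyr::arrange(want[, c("chrom", "start", "end")], chrom, start)
  expect_equal(as.data.frame(got), as.data.frame(want),
               ignore_attr = TRUE)
}

# quadratic >=1 bp overlap counter
naive_count_overlaps <- function(frags, features) {
  vapply(seq_len(nrow(features)), function(i) {
    sum(frags$chrom == features$chrom[i] &
          frags$start < features$end[i] &
          frags$end > features$start[i])
  }, numeric(1))
}

# exhaustive two-sided Mann-Whitney permutation p
exhaustive_mw_p <- function(x, y) {
  nx <- length(x); n <- nx + length(y)
  r <- rank(c(x, y))
  mu <- nx * length(y) / 2
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  combs <- utils::combn(n, nx)
  us <- apply(combs, 2, function(idx) sum(r[idx]) - nx * (nx + 1) / 2)
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# O(n^3) complete-linkage agglomeration returning the merge-height sequence
naive_complete_linkage <- function(m, metric = "euclidean") {
  d <- if (metric == "pearson") as.matrix(1 - cor(t(m))) else
    as.matrix(dist(m))
  n <- nrow(m)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(Inf, NA, NA)
    for (i in seq_along(clusters)) {
      for (j in seq_len(i - 1)) {
        h <- max(d[clusters[[i]], clusters[[j]]])
        if (h < best[1]) best <- c(h, j, i)
      }
    }
    heights <- c(heights, best[1])
    clusters[[best[2]]] <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters[[best[3]]] <- NULL
  }
  heights
}

# tiny deterministic gene set for annotation tests
toy_genes <- function() {
  gene_tbl(
    gene_id = c("gA", "gB"),
    chrom = c("chr1", "chr1"),
    start = c(10000, 40000),
    end = c(18000, 46000),
    strand = c("+", "-"),
    exons = list(
      tibble::tibble(start = c(10000, 14000), end = c(11000, 18000)),
      tibble::tibble(start = c(40000, 44500), end = c(42000, 46000))))
}
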