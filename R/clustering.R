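#' Profile matrices
#'
#' Clustering functions accept either a numeric matrix (rownames = gene
#' ids) or a tibble whose first column is `gene_id` and remaining columns
#' are per-condition values.
#'
#' @param x tibble or matrix.
#' @return Numeric matrix with rownames.
#' @export
as_profile_matrix <- function(x) {
  if (is.matrix(x)) {
    m <- x
  } else {
    stopifnot(is.data.frame(x), names(x)[1] == "gene_id")
    m <- as.matrix(x[, -1, drop = FALSE])
    rownames(m) <- x$gene_id
  }
  if (!is.numeric(m)) abort("profile values must be numeric")
  if (anyNA(m)) abort("profile matrix contains missing values")
  if (ncol(m) < 2) abort("profile matrix needs >= 2 columns")
  m
}

#' Row normalization for heat-map display
#'
#' `"median"` divides each row by its median (median-normalized values, the
#' display scale of the stage co-clustering heat maps; rows with median 0
#' fall back to the row mean, or are left as-is when that is also 0);
#' `"zscore"` centres and scales each row.
#'
#' @param x profile matrix or tibble.
#' @param method `"median"` or `"zscore"`.
#' @return Normalized numeric matrix.
#' @export
normalize_profiles <- function(x, method = c("median", "zscore")) {
  method <- match.arg(method)
  m <- as_profile_matrix(x)
  if (method == "median") {
    d <- apply(m, 1, median)
    d[d == 0] <- rowMeans(m)[d == 0]
    d[d == 0] <- 1
    m / d
  } else {
    s <- apply(m, 1, sd)
    s[s == 0] <- 1
    (m - rowMeans(m)) / s
  }
}

row_distance <- function(m, metric) {
  if (metric == "pearson") {
    stats::as.dist(1 - cor(t(m)))
  } else {
    dist(m)
  }
}

#' Complete-linkage hierarchical clustering of profiles
#'
#' Agglomerative clustering with complete linkage on `1 - Pearson`
#' correlation distance (default) or Euclidean distance, returning the
#' dendrogram, the row order and the reordered matrix for heat-map display,
#' plus a Newick rendering of the tree.
#'
#' @param x profile matrix or tibble (see [as_profile_matrix()]).
#' @param metric `"pearson"` or `"euclidean"`.
#' @return List of class `hmc_hclust`: `hclust`, `order` (row ids),
#'   `matrix` (reordered), `newick`.
#' @export
hclust_profiles <- function(x, metric = c("pearson", "euclidean")) {
  metric <- match.arg(metric)
  m <- as_profile_matrix(x)
  if (nrow(m) < 2) abort("need >= 2 rows to cluster")
  d <- row_distance(m, metric)
  if (anyNA(d)) abort("distance matrix contains NaN (constant rows under correlation metric?)")
  hc <- hclust(d, method = "complete")
  phy <- ape::as.phylo(hc)
  structure(list(hclust = hc, order = rownames(m)[hc$order],
                 matrix = m[hc$order, , drop = FALSE],
                 newick = ape::write.tree(phy)),
            class = "hmc_hclust")
}

#' @export
print.hmc_hclust <- function(x, ...) {
  cat(sprintf("<complete-linkage clustering> %d rows\n", nrow(x$matrix)))
  invisible(x)
}

#' SOTA parameters
#'
#' Learning rates for the winning cell, its mother node and its sister
#' cell (`0 < sister <= mother <= winner < 1`), the variability threshold
#' that stops cell splitting, the maximum number of adaptation cycles and
#' the distance metric.
#'
#' @param winner,mother,sister learning rates.
#' @param threshold variability threshold (same units as the metric).
#' @param max_cycles adaptation-cycle budget.
#' @param metric `"pearson"` (1 - correlation) or `"euclidean"`.
#' @param tol relative-error convergence tolerance within a tree size.
#' @return List of class `sota_params`.
#' @export
sota_params <- function(winner = 0.01, mother = 0.005, sister = 0.001,
                        threshold = 0.02, max_cycles = 1000,
                        metric = c("pearson", "euclidean"), tol = 1e-6) {
  metric <- match.arg(metric)
  if (!(sister <= mother && mother <= winner && winner < 1 && sister > 0)) {
    abort("need 0 < sister <= mother <= winner < 1")
  }
  if (threshold < 0) abort("threshold must be >= 0")
  structure(list(winner = winner, mother = mother, sister = sister,
                 threshold = threshold, max_cycles = max_cycles,
                 metric = metric, tol = tol), class = "sota_params")
}

sota_dist <- function(a, b, metric) {
  if (metric == "pearson") {
    if (sd(a) == 0 || sd(b) == 0) {
      # degenerate flat profile: fall back to scaled euclidean
      sqrt(sum((a - b)^2)) / length(a)
    } else {
      1 - cor(a, b)
    }
  } else {
    sqrt(sum((a - b)^2))
  }
}

#' Self-Organizing Tree Algorithm clustering
#'
#' Divisive neural-tree clustering: the tree starts as one root with two
#' terminal cells and grows by splitting the most variable cell until every
#' terminal cell's variability (mean distance of its members to the cell
#' centroid) is at or below the threshold, or the cycle budget is spent.
#' Within each tree size, rows are presented in order; the winning terminal
#' cell moves towards the row by the `winner` rate and, when its sister is
#' also terminal, the mother and sister move by their rates. The procedure
#' is deterministic given the row order and parameters.
#'
#' @param x profile matrix or tibble.
#' @param params [sota_params()].
#' @return List of class `hmc_sota`: `assignments` tibble (`gene_id`,
#'   `cluster`), `centroids` matrix, `variability` per cluster,
#'   `converged`, `n_cycles`.
#' @export
sota_cluster <- function(x, params = sota_params()) {
  m <- as_profile_matrix(x)
  p <- params
  n <- nrow(m)
  centroid0 <- colMeans(m)
  # growth only happens while variability exceeds the threshold; when the
  # whole data set already satisfies it, the tree never leaves the root
  root_var <- mean(vapply(seq_len(n),
                          function(i) sota_dist(m[i, ], centroid0, p$metric),
                          numeric(1)))
  if (root_var <= p$threshold) {
    cent <- matrix(centroid0, 1, dimnames = list("cluster_1", colnames(m)))
    return(structure(list(
      assignments = tibble(gene_id = rownames(m), cluster = rep(1L, n)),
      centroids = cent, variability = root_var, converged = TRUE,
      n_cycles = 0L, params = p), class = "hmc_sota"))
  }
  # flat representation: centroids of terminal cells + tree bookkeeping
  cent <- rbind(centroid0, centroid0)
  sister <- c(2L, 1L)
  mother <- list(centroid0, centroid0)  # shared mother centroid per pair
  pair_id <- c(1L, 1L)                  # cells sharing a mother
  mothers <- list(`1` = centroid0)
  cycles <- 0L
  assign_rows <- function() {
    apply(m, 1, function(row) {
      which.min(vapply(seq_len(nrow(cent)),
                       function(k) sota_dist(row, cent[k, ], p$metric),
                       numeric(1)))
    })
  }
  cell_variability <- function(asg) {
    vapply(seq_len(nrow(cent)), function(k) {
      rows <- which(asg == k)
      if (length(rows) == 0) return(0)
      mean(vapply(rows, function(i) sota_dist(m[i, ], cent[k, ], p$metric),
                  numeric(1)))
    }, numeric(1))
  }
  converged <- FALSE
  repeat {
    # adapt current tree until the error stabilizes
    prev_err <- Inf
    while (cycles < p$max_cycles) {
      cycles <- cycles + 1L
      err <- 0
      for (i in seq_len(n)) {
        dists <- vapply(seq_len(nrow(cent)),
                        function(k) sota_dist(m[i, ], cent[k, ], p$metric),
                        numeric(1))
        w <- which.min(dists)
        err <- err + dists[w]
        cent[w, ] <- cent[w, ] + p$winner * (m[i, ] - cent[w, ])
        s <- sister[w]
        if (!is.na(s) && s <= nrow(cent)) {
          key <- as.character(pair_id[w])
          mothers[[key]] <- mothers[[key]] + p$mother * (m[i, ] - mothers[[key]])
          cent[s, ] <- cent[s, ] + p$sister * (m[i, ] - cent[s, ])
        }
      }
      err <- err / n
      if (is.finite(prev_err) &&
          abs(prev_err - err) <= p$tol * max(prev_err, 1e-12)) break
      prev_err <- err
    }
    asg <- assign_rows()
    vari <- cell_variability(asg)
    if (max(vari) <= p$threshold) { converged <- TRUE; break }
    if (cycles >= p$max_cycles) break
    # split the most variable cell into two daughters seeded at its centroid
    w <- which.max(vari)
    new_pair <- max(pair_id) + 1L
    k1 <- nrow(cent) + 1L; k2 <- nrow(cent) + 2L
    cent <- rbind(cent, cent[w, ], cent[w, ])
    mothers[[as.character(new_pair)]] <- cent[w, ]
    # the split cell becomes internal: remove it from the terminal set by
    # replacing it with its daughters; reindex
    keep <- setdiff(seq_len(nrow(cent)), w)
    remap <- setNames(seq_along(keep), keep)
    cent <- cent[keep, , drop = FALSE]
    old_sister <- sister
    sister <- rep(NA_integer_, nrow(cent))
    pair_id2 <- rep(NA_integer_, nrow(cent))
    for (k in seq_along(keep)) {
      ko <- keep[k]
      os <- old_sister[ko]
      sister[k] <- if (!is.na(os) && os != w && as.character(os) %in% names(remap)) {
        remap[[as.character(os)]]
      } else NA_integer_
      pair_id2[k] <- pair_id[ko]
    }
    # daughters are the last two cells
    n_now <- nrow(cent)
    sister[n_now - 1] <- n_now; sister[n_now] <- n_now - 1L
    pair_id2[n_now - 1] <- new_pair; pair_id2[n_now] <- new_pair
    pair_id <- pair_id2
    # orphaned cells (their sister was split) keep NA sisters
  }
  asg <- assign_rows()
  vari <- cell_variability(asg)
  rownames(cent) <- paste0("cluster_", seq_len(nrow(cent)))
  structure(list(
    assignments = tibble(gene_id = rownames(m),
                         cluster = as.integer(asg)),
    centroids = cent, variability = vari, converged = converged,
    n_cycles = cycles, params = p), class = "hmc_sota")
}

#' @export
print.hmc_sota <- function(x, ...) {
  cat(sprintf("<SOTA> %d terminal cells, %d cycles, converged: %s\n",
              nrow(x$centroids), x$n_cycles, x$converged))
  invisible(x)
}

#' @export
tidy.hmc_sota <- function(x, ...) x$assignments

#' @export
glance.hmc_sota <- function(x, ...) {
  tibble(n_clusters = length(unique(x$assignments$cluster)),
         n_cells = nrow(x$centroids), n_cycles = x$n_cycles,
         converged = x$converged,
         max_variability = max(x$variability))
}

#' Dual-evidence stage co-clustering
#'
#' A gene is assigned to a stage only when the stage of its maximal
#' expression and the stage of its maximal genic 5-hmC coverage coincide
#' and both maxima are unique; otherwise it is unassigned (`NA`). The rule
#' depends only on per-row argmaxes, so it is invariant under any per-row
#' strictly increasing transform of either matrix.
#'
#' @param expr,hmc profile matrices or tibbles with identical row ids and
#'   identical column (stage) order.
#' @return Tibble: `gene_id`, `stage` (`NA` when unassigned).
#' @export
stage_cocluster <- function(expr, hmc) {
  me <- as_profile_matrix(expr)
  mh <- as_profile_matrix(hmc)
  if (!identical(rownames(me), rownames(mh))) {
    abort("expression and 5-hmC matrices must share row ids in order")
  }
  if (!identical(colnames(me), colnames(mh))) {
    abort("expression and 5-hmC matrices must share column (stage) order")
  }
  unique_argmax <- function(v) {
    k <- which(v == max(v))
    if (length(k) == 1) k else NA_integer_
  }
  ae <- unname(apply(me, 1, unique_argmax))
  ah <- unname(apply(mh, 1, unique_argmax))
  stage <- ifelse(!is.na(ae) & !is.na(ah) & ae == ah,
                  colnames(me)[ifelse(is.na(ae), 1L, ae)], NA_character_)
  tibble(gene_id = rownames(me), stage = stage)
}
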