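#' Interval tables
#'
#' Genomic intervals are plain tibbles with columns `chrom`, `start`, `end`
#' using 0-based half-open coordinates (BED convention): `start` is the first
#' base of the interval, `end` is one past the last. Zero-length intervals are
#' invalid. Extra columns (`name`, `score`, `strand`, ...) are carried by I/O
#' but dropped by the base-level set algebra, which always returns merged
#' (disjoint, non-adjacent) intervals sorted by chromosome and start.
#'
#' @param chrom character vector of chromosome names.
#' @param start,end numeric vectors, 0-based half-open.
#' @param ... further columns passed to [tibble::tibble()].
#' @return A tibble with at least `chrom`, `start`, `end`.
#' @export
#' @examples
#' interval_tbl("chr1", c(0, 100), c(50, 200))
interval_tbl <- function(chrom, start, end, ...) {
  x <- tibble(chrom = as.character(chrom), start = as.numeric(start),
              end = as.numeric(end), ...)
  validate_intervals(x)
  x
}

validate_intervals <- function(x, what = "interval table") {
  if (!is.data.frame(x)) abort(paste0(what, " must be a data frame"))
  miss <- setdiff(c("chrom", "start", "end"), names(x))
  if (length(miss) > 0) {
    abort(paste0(what, " lacks column(s): ", paste(miss, collapse = ", ")))
  }
  if (nrow(x) == 0) return(invisible(x))
  if (!is.numeric(x$start) || !is.numeric(x$end)) {
    abort(paste0(what, ": start/end must be numeric"))
  }
  if (anyNA(x$start) || anyNA(x$end)) abort(paste0(what, ": NA coordinates"))
  if (any(x$start < 0)) abort(paste0(what, ": negative start"))
  bad <- which(x$end <= x$start)
  if (length(bad) > 0) {
    abort(sprintf("%s: empty or inverted interval at row %d (%s:%s-%s)",
                  what, bad[1], x$chrom[bad[1]], x$start[bad[1]], x$end[bad[1]]))
  }
  invisible(x)
}

# Error when the two sets plainly use different chromosome naming schemes:
# no shared name, but names that agree once the "chr" prefix is stripped
# ("chr1" vs "1"). Genuinely disjoint chromosome sets are allowed (their
# intersection is simply empty).
check_chrom_namespace <- function(a, b) {
  if (nrow(a) == 0 || nrow(b) == 0) return(invisible(NULL))
  ca <- unique(a$chrom); cb <- unique(b$chrom)
  if (length(intersect(ca, cb)) > 0) return(invisible(NULL))
  norm <- function(x) sub("^chr", "", x)
  clash <- intersect(norm(ca), norm(cb))
  if (length(clash) > 0) {
    abort(sprintf(
      "mismatched chromosome namespaces: '%s' in one set vs '%s' in the other",
      ca[match(clash[1], norm(ca))], cb[match(clash[1], norm(cb))]))
  }
  invisible(NULL)
}

empty_intervals <- function() {
  tibble(chrom = character(), start = numeric(), end = numeric())
}

# tibble rows for one chromosome -> IRanges (1-based closed)
ir_of <- function(start, end) IRanges::IRanges(start = start + 1, end = end)

ir_to_tbl <- function(chrom, ir) {
  if (length(ir) == 0) return(empty_intervals())
  tibble(chrom = chrom, start = as.numeric(IRanges::start(ir)) - 1,
         end = as.numeric(IRanges::end(ir)))
}

# apply an IRanges set operation per chromosome
per_chrom_setop <- function(a, b, fun, chroms = NULL) {
  validate_intervals(a, "first interval set")
  validate_intervals(b, "second interval set")
  if (is.null(chroms)) chroms <- union(unique(a$chrom), unique(b$chrom))
  chroms <- sort(chroms)
  out <- bind_rows(lapply(chroms, function(cc) {
    ia <- ir_of(a$start[a$chrom == cc], a$end[a$chrom == cc])
    ib <- ir_of(b$start[b$chrom == cc], b$end[b$chrom == cc])
    ir_to_tbl(cc, fun(IRanges::reduce(ia), IRanges::reduce(ib)))
  }))
  if (nrow(out) == 0) empty_intervals() else out
}

#' Merge overlapping or adjacent intervals
#'
#' Collapses an interval set to its maximal disjoint form. Adjacent intervals
#' (`[0,10)`, `[10,20)`) are merged, matching per-base set semantics.
#'
#' @param x interval tibble.
#' @return Merged interval tibble sorted by `chrom`, `start`.
#' @export
bed_merge <- function(x) {
  validate_intervals(x)
  if (nrow(x) == 0) return(empty_intervals())
  chroms <- sort(unique(x$chrom))
  out <- bind_rows(lapply(chroms, function(cc) {
    ir <- ir_of(x$start[x$chrom == cc], x$end[x$chrom == cc])
    ir_to_tbl(cc, IRanges::reduce(ir))
  }))
  if (nrow(out) == 0) empty_intervals() else out
}

#' Base-level intersection of two interval sets
#'
#' Returns exactly the bases present in both inputs, merged into maximal
#' intervals. This is the replicate-consensus primitive: consensus peaks are
#' the peak base pairs shared by both biological replicates.
#'
#' @param a,b interval tibbles on the same chromosome namespace.
#' @return Merged interval tibble of the shared bases.
#' @export
#' @examples
#' bed_intersect(interval_tbl("chr1", 10, 50), interval_tbl("chr1", 30, 70))
bed_intersect <- function(a, b) {
  check_chrom_namespace(a, b)
  per_chrom_setop(a, b, IRanges::intersect,
                  chroms = intersect(unique(a$chrom), unique(b$chrom)))
}

#' Base-level subtraction of interval sets
#'
#' @param a,b interval tibbles; returns the bases of `a` not in `b`, merged.
#' @return Merged interval tibble.
#' @export
bed_subtract <- function(a, b) {
  validate_intervals(a, "first interval set")
  validate_intervals(b, "second interval set")
  if (nrow(a) == 0) return(empty_intervals())
  chroms <- sort(unique(a$chrom))
  out <- bind_rows(lapply(chroms, function(cc) {
    ia <- ir_of(a$start[a$chrom == cc], a$end[a$chrom == cc])
    ib <- ir_of(b$start[b$chrom == cc], b$end[b$chrom == cc])
    ir_to_tbl(cc, IRanges::setdiff(IRanges::reduce(ia), IRanges::reduce(ib)))
  }))
  if (nrow(out) == 0) empty_intervals() else out
}

#' Bases common to every set in a list
#'
#' Left fold of [bed_intersect()]; the multi-way analogue of `bedtools
#' multiinter` restricted to bases present in all inputs, used for the
#' peaks common to all developmental stages.
#'
#' @param sets list of at least two interval tibbles.
#' @return Merged interval tibble of bases present in every set.
#' @export
bed_multi_intersect <- function(sets) {
  if (!is.list(sets) || length(sets) < 2) {
    abort("bed_multi_intersect() needs a list of >= 2 interval sets")
  }
  Reduce(bed_intersect, sets)
}

#' Total number of bases covered by an interval set
#'
#' @param x interval tibble (merged internally first).
#' @return Numeric base count.
#' @export
bed_bases <- function(x) {
  m <- bed_merge(x)
  sum(m$end - m$start)
}

# which intervals of x overlap >=1 bp with the set y; returns logical by row of x
overlaps_any <- function(x, y) {
  validate_intervals(x); validate_intervals(y)
  out <- rep(FALSE, nrow(x))
  if (nrow(x) == 0 || nrow(y) == 0) return(out)
  for (cc in intersect(unique(x$chrom), unique(y$chrom))) {
    ix <- which(x$chrom == cc)
    ir_x <- ir_of(x$start[ix], x$end[ix])
    ir_y <- IRanges::reduce(ir_of(y$start[y$chrom == cc], y$end[y$chrom == cc]))
    out[ix] <- IRanges::overlapsAny(ir_x, ir_y)
  }
  out
}

#' Read / write BED files
#'
#' BED3/BED6 (tab-separated, no header, 0-based half-open). Lines starting
#' with `#` are skipped. Extra columns beyond the sixth are ignored.
#'
#' @param path file path.
#' @return `read_bed()`: tibble with `chrom`, `start`, `end` and, when
#'   present, `name`, `score`, `strand`.
#' @export
read_bed <- function(path) {
  x <- readr::read_tsv(path, col_names = FALSE, comment = "#",
                       show_col_types = FALSE, progress = FALSE)
  if (nrow(x) == 0) return(empty_intervals())
  cols <- c("chrom", "start", "end", "name", "score", "strand")
  names(x)[seq_len(min(ncol(x), 6))] <- cols[seq_len(min(ncol(x), 6))]
  x <- x[, intersect(cols, names(x))]
  x$chrom <- as.character(x$chrom)
  x$start <- as.numeric(x$start)
  x$end <- as.numeric(x$end)
  validate_intervals(x, paste0("BED file ", path))
  as_tibble(x)
}

#' @rdname read_bed
#' @param x interval tibble; `name`, `score`, `strand` written when present.
#' @export
write_bed <- function(x, path) {
  validate_intervals(x)
  cols <- intersect(c("chrom", "start", "end", "name", "score", "strand"),
                    names(x))
  # BED requires name/score before strand; fill gaps so columns stay positional
  y <- x
  if ("strand" %in% cols || "score" %in% cols) {
    if (!"name" %in% cols) y$name <- "."
    if (!"score" %in% cols) y$score <- 0
  }
  if ("strand" %in% cols && !"score" %in% cols) y$score <- 0
  cols <- intersect(c("chrom", "start", "end", "name", "score", "strand"),
                    names(y))
  y <- y[, cols]
  y$start <- format_coord(y$start)
  y$end <- format_coord(y$end)
  readr::write_tsv(y, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

format_coord <- function(v) format(v, scientific = FALSE, trim = TRUE)

#' Read a two-column chrom.sizes file
#'
#' @param path tab-separated file: chromosome name, length in bp.
#' @return A genome build: named numeric vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  x <- readr::read_tsv(path, col_names = c("chrom", "size"),
                       show_col_types = FALSE, progress = FALSE)
  genome_build(setNames(as.numeric(x$size), as.character(x$chrom)))
}

#' Construct a genome build
#'
#' @param chrom_sizes named numeric vector, chromosome name -> length (bp).
#' @return Validated named numeric vector of class `hmc_build`.
#' @export
genome_build <- function(chrom_sizes) {
  if (is.null(names(chrom_sizes)) || any(names(chrom_sizes) == "")) {
    abort("chrom_sizes must be a named vector")
  }
  if (anyDuplicated(names(chrom_sizes))) abort("duplicate chromosome names")
  if (any(chrom_sizes <= 0)) abort("chromosome lengths must be > 0")
  structure(chrom_sizes, class = c("hmc_build", "numeric"))
}

#' @export
print.hmc_build <- function(x, ...) {
  cat("<genome build>", length(x), "chromosome(s),",
      format(sum(x), big.mark = ","), "bp\n")
  invisible(x)
}

write_chrom_sizes <- function(build, path) {
  readr::write_tsv(tibble(chrom = names(build), size = format_coord(as.numeric(build))),
                   path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

clip_intervals <- function(x, build) {
  x$start <- pmax(x$start, 0)
  if (!is.null(build)) {
    lim <- setNames(as.numeric(build), names(build))
    x$end <- pmin(x$end, unname(lim[x$chrom]))
  }
  x[x$end > x$start, , drop = FALSE]
}
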