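#' Filter segments reported in regions of low site density
#'
#' Artifactual candidate segments arise in regions of sparse genotyping (e.g.
#' assembly gaps). The chromosome's cM range is tiled with consecutive windows
#' of `window_cM` centiMorgans and the site density (sites/cM) of each full
#' window is computed. In the default `"own"` mode a segment is dropped when
#' its own site density (`n_sites / genetic_length_cM`) falls below the
#' `percentile`-th percentile of the window densities; in `"window"` mode a
#' segment is dropped when it overlaps any window below that percentile.
#' Retained segments keep their input order.
#'
#' @param segments Segment table (see [ibd_segments()]).
#' @param map The [site_map()] of the chromosome.
#' @param window_cM Window width in cM (default 1).
#' @param percentile Percentile of window densities defining "low" (default
#'   10, i.e. the lowest 10%).
#' @param mode `"own"` (compare the segment's own density) or `"window"`.
#' @param inclusive Drop segments exactly at the percentile value as well
#'   (default FALSE, so a chromosome of uniform density filters nothing).
#' @return The retained rows of `segments`.
#' @export
site_density_filter <- function(segments, map, window_cM = 1, percentile = 10,
                                mode = c("own", "window"), inclusive = FALSE) {
  mode <- match.arg(mode)
  if (nrow(segments) == 0L) return(segments)
  validate_segments(segments, map)
  span <- map$cM[n_sites(map)] - map$cM[1L]
  if (span < window_cM) {
    warning("chromosome is shorter than one density window; no filtering applied")
    return(segments)
  }
  edges <- seq(map$cM[1L], map$cM[n_sites(map)], by = window_cM)
  n_win <- length(edges) - 1L  # full windows only
  if (n_win < 1L) {
    warning("chromosome is shorter than one density window; no filtering applied")
    return(segments)
  }
  counts <- tabulate(findInterval(map$cM, edges, rightmost.closed = FALSE,
                                  left.open = FALSE), nbins = n_win + 1L)[1:n_win]
  dens <- counts / window_cM
  thr <- stats::quantile(dens, percentile / 100, names = FALSE)

  if (mode == "own") {
    glen <- segments$genetic_length_cM
    sdens <- ifelse(glen > 0, segments$n_sites / glen, Inf)
    drop <- if (inclusive) sdens <= thr else sdens < thr
  } else {
    low <- if (inclusive) dens <= thr else dens < thr
    lo_cm <- edges[seq_len(n_win)][low]
    hi_cm <- edges[seq_len(n_win) + 1L][low]
    s_lo <- map$cM[segments$site_start]
    s_hi <- map$cM[segments$site_end]
    drop <- vapply(seq_len(nrow(segments)), function(k) {
      any(s_lo[k] < hi_cm & s_hi[k] > lo_cm)
    }, logical(1))
  }
  segments[!drop, , drop = FALSE]
}

#' Build a HaploScore threshold matrix from validated segments
#'
#' Bins validated segments (carrying a genetic length, a parent-overlap
#' fraction and a HaploScore) by genetic length in `length_step` cM increments
#' over `length_range`, and within each length bin by overlap into
#' `n_overlap_bins` equal bins. The threshold of each (length, overlap) cell
#' starts as the mean HaploScore of the cell's segments and is then replaced
#' by the maximum over all cells of equal or higher overlap in the same length
#' row, which enforces monotonicity: demanding a higher target overlap never
#' loosens the score threshold. Empty cells inherit the running maximum from
#' higher-overlap cells; cells above the highest populated overlap bin of a
#' row, and rows with no segments at all, remain `NA` (missing, never
#' invented).
#'
#' @param segments Data frame with columns `genetic_length_cM`, `overlap` and
#'   `haploscore`. Segments with lengths outside `length_range` are ignored
#'   when building (they are clamped to the nearest bin at filtering time, see
#'   [filter_segments()]).
#' @param length_range Genetic-length range binned (default `c(2, 10)` cM).
#' @param length_step Length bin width (default 0.1 cM).
#' @param n_overlap_bins Number of equal overlap bins over (0, 1] (default
#'   100); an overlap of exactly 0 falls in the lowest bin.
#' @return An object of class `score_threshold_matrix` with fields
#'   `length_edges`, `overlap_levels` (upper bin edges), `thresholds` (length
#'   bins x overlap bins) and `counts`.
#' @export
build_threshold_matrix <- function(segments, length_range = c(2, 10),
                                   length_step = 0.1, n_overlap_bins = 100L) {
  need <- c("genetic_length_cM", "overlap", "haploscore")
  miss <- setdiff(need, names(segments))
  if (length(miss)) stop("segments lack columns: ", paste(miss, collapse = ", "))
  if (nrow(segments) &&
      (any(segments$overlap < 0 | segments$overlap > 1, na.rm = TRUE) ||
       any(segments$haploscore < 0, na.rm = TRUE))) {
    stop("overlap must lie in [0, 1] and haploscore must be non-negative")
  }
  length_edges <- seq(length_range[1L], length_range[2L], by = length_step)
  n_len <- length(length_edges) - 1L
  overlap_levels <- seq_len(n_overlap_bins) / n_overlap_bins

  keep <- !is.na(segments$haploscore) &
    segments$genetic_length_cM >= length_range[1L] &
    segments$genetic_length_cM <= length_range[2L]
  seg <- segments[keep, , drop = FALSE]
  lbin <- pmin(findInterval(seg$genetic_length_cM, length_edges,
                            rightmost.closed = TRUE), n_len)
  obin <- pmin(pmax(ceiling(seg$overlap * n_overlap_bins), 1L), n_overlap_bins)

  sums <- matrix(0, n_len, n_overlap_bins)
  cnts <- matrix(0L, n_len, n_overlap_bins)
  for (k in seq_len(nrow(seg))) {
    sums[lbin[k], obin[k]] <- sums[lbin[k], obin[k]] + seg$haploscore[k]
    cnts[lbin[k], obin[k]] <- cnts[lbin[k], obin[k]] + 1L
  }
  means <- ifelse(cnts > 0L, sums / cnts, NA_real_)

  thresholds <- matrix(NA_real_, n_len, n_overlap_bins)
  for (l in seq_len(n_len)) {
    cur <- NA_real_
    for (o in rev(seq_len(n_overlap_bins))) {
      m <- means[l, o]
      if (!is.na(m)) cur <- if (is.na(cur)) m else max(cur, m)
      thresholds[l, o] <- cur
    }
  }
  structure(list(length_edges = length_edges, overlap_levels = overlap_levels,
                 thresholds = thresholds, counts = cnts),
            class = "score_threshold_matrix")
}

#' @export
print.score_threshold_matrix <- function(x, ...) {
  n_len <- length(x$length_edges) - 1L
  filled <- sum(rowSums(x$counts) > 0L)
  cat(sprintf("<score_threshold_matrix> %d length bins (%.1f-%.1f cM, %d populated) x %d overlap levels\n",
              n_len, x$length_edges[1L], x$length_edges[length(x$length_edges)],
              filled, length(x$overlap_levels)))
  invisible(x)
}

threshold_lookup <- function(matrix, lengths_cM, target_overlap) {
  if (target_overlap <= 0 || target_overlap > 1) {
    stop("target_overlap must lie in (0, 1]")
  }
  n_len <- length(matrix$length_edges) - 1L
  nob <- length(matrix$overlap_levels)
  obin <- min(max(ceiling(target_overlap * nob), 1L), nob)
  # segments outside the binned range use the nearest bin
  lbin <- pmin(pmax(findInterval(lengths_cM, matrix$length_edges,
                                 rightmost.closed = TRUE), 1L), n_len)
  matrix$thresholds[cbind(lbin, obin)]
}

#' Filter scored segments with a threshold matrix
#'
#' Retains a segment iff its HaploScore is at most the matrix threshold for
#' its genetic-length bin at the requested target mean-overlap level. Segments
#' shorter or longer than the binned length range use the nearest length bin.
#' Segments whose length row carries no threshold (missing data) are dropped
#' with a warning.
#'
#' @param segments Data frame with columns `genetic_length_cM` and
#'   `haploscore`.
#' @param matrix A [build_threshold_matrix()] result.
#' @param target_overlap Target mean segment overlap level in (0, 1]; higher
#'   targets filter more stringently (never retain a superset of a lower
#'   target).
#' @return The retained rows of `segments`.
#' @export
filter_segments <- function(segments, matrix, target_overlap) {
  if (!inherits(matrix, "score_threshold_matrix")) {
    stop("matrix must be a score_threshold_matrix")
  }
  if (nrow(segments) == 0L) return(segments)
  thr <- threshold_lookup(matrix, segments$genetic_length_cM, target_overlap)
  if (anyNA(thr)) {
    warning(sum(is.na(thr)), " segment(s) dropped: no threshold available for their length bin")
  }
  keep <- !is.na(thr) & segments$haploscore <= thr
  keep[is.na(keep)] <- FALSE
  segments[keep, , drop = FALSE]
}

#' Filter segments by minimum genetic length
#'
#' @param segments Segment table with a `genetic_length_cM` column.
#' @param min_cM Minimum genetic length retained (inclusive).
#' @return The retained rows.
#' @export
length_filter <- function(segments, min_cM) {
  segments[segments$genetic_length_cM >= min_cM, , drop = FALSE]
}
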