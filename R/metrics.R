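#' Mann-Whitney AUC for a score-based segment classifier
#'
#' Area under the ROC curve computed as the Mann-Whitney probability that a
#' randomly chosen positive (true) segment scores lower than a randomly chosen
#' negative one, with ties counting one half. Equals the trapezoidal area
#' under the full ROC sweep.
#'
#' @param labels Logical vector: TRUE for true-IBD segments.
#' @param scores Numeric scores (HaploScores).
#' @param lower_is_positive Orientation: TRUE (default) means lower scores
#'   indicate true IBD.
#' @return The AUC. Errors when only one class is present.
#' @export
auc_mann_whitney <- function(labels, scores, lower_is_positive = TRUE) {
  check_label_scores(labels, scores)
  if (!lower_is_positive) scores <- -scores
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L) {
    stop("AUC requires both a positive and a negative class")
  }
  r <- rank(scores)
  (sum(r[!labels]) - n_neg * (n_neg + 1) / 2) / (n_pos * n_neg)
}

check_label_scores <- function(labels, scores) {
  if (length(labels) != length(scores)) {
    stop("labels and scores must have equal length")
  }
  if (!is.logical(labels)) stop("labels must be logical")
  if (anyNA(labels) || anyNA(scores)) stop("labels and scores must not contain NA")
  invisible(TRUE)
}

#' ROC sweep over score thresholds
#'
#' Sweeps a score threshold over every distinct score value (classifying a
#' segment positive when its score is strictly below the threshold, the
#' orientation used when HaploScore thresholds are varied from 0 upwards) and
#' reports the true- and false-positive rate at each threshold, plus the
#' Mann-Whitney AUC.
#'
#' @inheritParams auc_mann_whitney
#' @return A list of class `roc_sweep`: `points` (data frame `threshold`,
#'   `tpr`, `fpr`) and `auc` (`NA` with a warning when only one class is
#'   present).
#' @export
roc_curve <- function(labels, scores, lower_is_positive = TRUE) {
  check_label_scores(labels, scores)
  s <- if (lower_is_positive) scores else -scores
  thr <- c(sort(unique(s)), Inf)
  pts <- vapply(thr, function(t) {
    pred <- s < t
    c(tpr = if (any(labels)) sum(pred & labels) / sum(labels) else NA_real_,
      fpr = if (any(!labels)) sum(pred & !labels) / sum(!labels) else NA_real_)
  }, numeric(2))
  auc <- if (any(labels) && any(!labels)) {
    auc_mann_whitney(labels, scores, lower_is_positive)
  } else {
    warning("only one class present; AUC undefined")
    NA_real_
  }
  structure(list(points = data.frame(threshold = thr,
                                     tpr = pts["tpr", ], fpr = pts["fpr", ]),
                 auc = auc),
            class = "roc_sweep")
}

#' @export
print.roc_sweep <- function(x, ...) {
  cat(sprintf("<roc_sweep> %d thresholds, AUC = %s\n",
              nrow(x$points),
              if (is.na(x$auc)) "NA" else sprintf("%.4f", x$auc)))
  invisible(x)
}

pr_points <- function(labels, scores, lower_is_positive = TRUE) {
  s <- if (lower_is_positive) scores else -scores
  thr <- sort(unique(s))
  n_pos <- sum(labels)
  out <- vapply(thr, function(t) {
    pred <- s <= t
    c(precision = sum(pred & labels) / sum(pred),
      recall = if (n_pos) sum(pred & labels) / n_pos else NA_real_)
  }, numeric(2))
  data.frame(threshold = thr, precision = out["precision", ],
             recall = out["recall", ])
}

#' Precision-recall curves, optionally per genetic-length bin
#'
#' Sweeps a score threshold (a segment is predicted true when its score is at
#' most the threshold) and reports precision and recall at each threshold.
#' When `lengths_cM` and `length_breaks` are given, a separate curve is
#' computed within each length bin, with recall measured against the true
#' segments of that bin; `pooled = TRUE` adds a single curve over all
#' segments for global comparisons of filtering strategies.
#'
#' @inheritParams auc_mann_whitney
#' @param lengths_cM Optional genetic lengths for binning.
#' @param length_breaks Bin edges over `lengths_cM`.
#' @param pooled Add a pooled curve labelled `"all"`.
#' @return A data frame with columns `bin`, `threshold`, `precision`,
#'   `recall`.
#' @export
precision_recall <- function(labels, scores, lengths_cM = NULL,
                             length_breaks = NULL, pooled = is.null(lengths_cM),
                             lower_is_positive = TRUE) {
  check_label_scores(labels, scores)
  out <- list()
  if (!is.null(lengths_cM)) {
    if (is.null(length_breaks)) stop("length_breaks required with lengths_cM")
    bin <- cut(lengths_cM, length_breaks, include.lowest = TRUE)
    for (b in levels(bin)) {
      k <- which(bin == b)
      if (!length(k)) next
      out[[b]] <- cbind(bin = b, pr_points(labels[k], scores[k],
                                           lower_is_positive))
    }
  }
  if (pooled) {
    out[["all"]] <- cbind(bin = "all", pr_points(labels, scores,
                                                 lower_is_positive))
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Mean overlap binned over two segment variables
#'
#' Bins records (e.g. child-other segments) over two variables, typically
#' genetic length against physical length or against HaploScore, and reports
#' the per-bin mean of the overlap fraction and the per-bin count. Empty bins
#' are `NA` in the mean matrix and 0 in the count matrix.
#'
#' @param records Data frame carrying the binning variables and an `overlap`
#'   column.
#' @param x,y Names of the two binning columns.
#' @param x_breaks,y_breaks Strictly increasing bin edges (length >= 2).
#' @return A list with matrices `mean_overlap` and `count` (x bins in rows),
#'   plus the break vectors.
#' @export
binned_mean_overlap <- function(records, x, y, x_breaks, y_breaks) {
  for (v in c(x, y, "overlap")) {
    if (!v %in% names(records)) stop("records lack column: ", v)
  }
  for (b in list(x_breaks, y_breaks)) {
    if (length(b) < 2L || any(diff(b) <= 0)) {
      stop("bin breaks must be strictly increasing with length >= 2")
    }
  }
  nx <- length(x_breaks) - 1L
  ny <- length(y_breaks) - 1L
  xb <- findInterval(records[[x]], x_breaks, rightmost.closed = TRUE)
  yb <- findInterval(records[[y]], y_breaks, rightmost.closed = TRUE)
  keep <- xb >= 1L & xb <= nx & yb >= 1L & yb <= ny & !is.na(records$overlap)
  sums <- matrix(0, nx, ny)
  cnts <- matrix(0L, nx, ny)
  for (k in which(keep)) {
    sums[xb[k], yb[k]] <- sums[xb[k], yb[k]] + records$overlap[k]
    cnts[xb[k], yb[k]] <- cnts[xb[k], yb[k]] + 1L
  }
  list(mean_overlap = ifelse(cnts > 0L, sums / cnts, NA_real_),
       count = cnts, x_breaks = x_breaks, y_breaks = y_breaks)
}

#' Robustness of HaploScore AUC to parameter and truth-definition variation
#'
#' Re-scores candidate segments over a grid of switch-error rates `sigma`
#' (with `epsilon` fixed) and, for each requested overlap threshold defining
#' true IBD, computes the AUC of the re-scored classifier at every grid
#' point. Because only the ratio `sigma/epsilon` affects segment rankings,
#' this probes the full sensitivity of the metric to mis-specified error
#' rates. Also reports, per overlap threshold, the maximal relative AUC drop
#' versus the best grid point.
#'
#' @param cohort A [phased_cohort()].
#' @param segments Segment table of candidates (see [ibd_segments()]).
#' @param overlap Numeric vector of truth-overlap fractions, one per segment.
#' @param epsilon Fixed genotyping error rate.
#' @param sigma_grid Switch-error rates to scan; default: 25 logarithmically
#'   spaced points from `epsilon/100` to `10 * epsilon`.
#' @param overlap_thresholds Overlap thresholds defining true IBD (default
#'   0.8).
#' @return A list with `grid` (data frame `sigma`, `overlap_threshold`,
#'   `auc`) and `max_rel_drop` (named vector per overlap threshold, as a
#'   fraction of the best AUC).
#' @export
robustness_grid <- function(cohort, segments, overlap, epsilon = 0.0075,
                            sigma_grid = NULL, overlap_thresholds = 0.8) {
  if (is.null(sigma_grid)) {
    sigma_grid <- 10^seq(log10(epsilon / 100), log10(10 * epsilon),
                         length.out = 25L)
  }
  if (length(sigma_grid) == 0L || length(overlap_thresholds) == 0L) {
    stop("sigma_grid and overlap_thresholds must be non-empty")
  }
  if (length(overlap) != nrow(segments)) {
    stop("overlap must have one value per segment")
  }
  grid <- expand.grid(sigma = sigma_grid,
                      overlap_threshold = overlap_thresholds,
                      KEEP.OUT.ATTRS = FALSE)
  grid$auc <- NA_real_
  for (s in sigma_grid) {
    sc <- haploscore_batch(cohort, segments,
                           error_rates(epsilon, s))$haploscore
    for (t in overlap_thresholds) {
      labels <- overlap >= t
      a <- if (any(labels) && any(!labels)) {
        auc_mann_whitney(labels, sc)
      } else NA_real_
      grid$auc[grid$sigma == s & grid$overlap_threshold == t] <- a
    }
  }
  drop <- vapply(overlap_thresholds, function(t) {
    a <- grid$auc[grid$overlap_threshold == t]
    if (all(is.na(a))) return(NA_real_)
    (max(a, na.rm = TRUE) - min(a, na.rm = TRUE)) / max(a, na.rm = TRUE)
  }, numeric(1))
  names(drop) <- format(overlap_thresholds)
  list(grid = grid, max_rel_drop = drop)
}
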