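#' Error-rate parameter pair for HaploScore
#'
#' The two per-site error probabilities that parameterise HaploScore: the
#' genotyping error rate `epsilon` and the haplotype switch error rate
#' `sigma`. Both must be strictly positive so that the penalty weights
#' `1/epsilon` and `1/sigma` are finite. Defaults are the rates estimated from
#' genotyping-array trio data (`epsilon` = 0.0075, `sigma` = 0.003); see
#' [switch_error_rate()] and [genotyping_error_rate()] for estimating them on
#' other cohorts.
#'
#' @param epsilon Per-site genotyping error probability, in (0, 1).
#' @param sigma Per-site switch error probability, in (0, 1).
#' @return An object of class `error_rates`.
#' @export
error_rates <- function(epsilon = 0.0075, sigma = 0.003) {
  epsilon <- as.numeric(epsilon)
  sigma <- as.numeric(sigma)
  if (length(epsilon) != 1L || length(sigma) != 1L ||
      !is.finite(epsilon) || !is.finite(sigma) ||
      epsilon <= 0 || epsilon >= 1 || sigma <= 0 || sigma >= 1) {
    stop("epsilon and sigma must be single finite values in (0, 1)")
  }
  structure(list(epsilon = epsilon, sigma = sigma), class = "error_rates")
}

#' @export
print.error_rates <- function(x, ...) {
  cat(sprintf("<error_rates> epsilon (genotyping) = %g, sigma (switch) = %g\n",
              x$epsilon, x$sigma))
  invisible(x)
}

as_error_rates <- function(rates) {
  if (inherits(rates, "error_rates")) return(rates)
  if (is.numeric(rates) && length(rates) == 2L) {
    return(error_rates(rates[[1L]], rates[[2L]]))
  }
  stop("rates must be an error_rates object or c(epsilon, sigma)")
}

segment_haps <- function(cohort, id_a, id_b, site_start, site_end) {
  ia <- id_index(cohort, id_a)
  ib <- id_index(cohort, id_b)
  if (site_start < 1L || site_end > n_sites(cohort$map) || site_start > site_end) {
    stop("invalid segment site interval")
  }
  s <- site_start:site_end
  list(a1 = cohort$hap1[s, ia], a2 = cohort$hap2[s, ia],
       b1 = cohort$hap1[s, ib], b2 = cohort$hap2[s, ib])
}

#' HaploScore of a candidate IBD segment
#'
#' Scores a candidate segment by the minimum-cost reconciliation of the two
#' individuals' diplotypes as a single-haplotype match:
#' \deqn{HaploScore = (n_g/\epsilon + n_s/\sigma) / |S|}
#' where `|S|` is the number of genotyped sites in the segment and `n_g`,
#' `n_s` are the numbers of genotyping and switch errors that jointly minimise
#' the score. The minimisation is a shortest path through a DAG with one level
#' per site and four nodes per level (the haplotype configurations): a node
#' costs 0 when the configured alleles agree (or either is missing) and
#' `1/epsilon` otherwise; an edge costs `1/sigma` per haplotype coordinate
#' that changes between consecutive configurations; source and sink edges are
#' free, so the initial configuration is unconstrained. The dynamic program
#' performs 16 predecessor comparisons per site, i.e. O(|S|) per segment.
#'
#' True IBD segments need few errors to reconcile and score low; segments
#' reported only because of permissive diplotype matching need many and score
#' high. Only the ratio `sigma/epsilon` affects the ranking of segments:
#' scaling both rates by `c` divides every score by `c`.
#'
#' @param cohort A [phased_cohort()].
#' @param segment One-row segment `data.frame` (see [ibd_segments()]), or a
#'   list with `id_a`, `id_b`, `site_start`, `site_end`.
#' @param rates An [error_rates()] object (default: shipped defaults).
#' @param keep_path If TRUE, also return the optimal per-site haplotype
#'   configuration path (integers 0-3 coding `2*i + j` for haplotype `i` of
#'   `id_a` against haplotype `j` of `id_b`).
#' @return A list of class `haploscore` with elements `haploscore`, `n_g`,
#'   `n_s`, `n_sites`, `comparisons` (DP comparison count) and optionally
#'   `path`.
#' @seealso [haploscore_batch()] for many segments, [haploscore_bruteforce()]
#'   for the exhaustive oracle.
#' @export
haploscore <- function(cohort, segment, rates = error_rates(),
                       keep_path = FALSE) {
  rates <- as_error_rates(rates)
  h <- segment_haps(cohort, segment$id_a[1L], segment$id_b[1L],
                    segment$site_start[1L], segment$site_end[1L])
  out <- .haploscore_dp(h$a1, h$a2, h$b1, h$b2,
                        rates$epsilon, rates$sigma,
                        max_score = Inf, keep_path = keep_path)
  structure(out, class = "haploscore")
}

#' @export
print.haploscore <- function(x, ...) {
  cat(sprintf("<haploscore> %.4f  (n_g = %d, n_s = %d, |S| = %d)\n",
              x$haploscore, x$n_g, x$n_s, x$n_sites))
  invisible(x)
}

#' Brute-force HaploScore oracle
#'
#' Exhaustively enumerates all `4^|S|` haplotype-configuration sequences of a
#' segment and returns the minimum-cost reconciliation. Bit-identical cost
#' structure and tie-breaking to [haploscore()], but computed by a completely
#' independent code path; intended for verifying the dynamic program on short
#' segments.
#'
#' @inheritParams haploscore
#' @param max_sites Refuse segments longer than this (enumeration is
#'   exponential).
#' @return A list of class `haploscore`.
#' @export
haploscore_bruteforce <- function(cohort, segment, rates = error_rates(),
                                  max_sites = 10L) {
  rates <- as_error_rates(rates)
  h <- segment_haps(cohort, segment$id_a[1L], segment$id_b[1L],
                    segment$site_start[1L], segment$site_end[1L])
  out <- .haploscore_bruteforce(h$a1, h$a2, h$b1, h$b2,
                                rates$epsilon, rates$sigma,
                                max_sites = as.integer(max_sites))
  structure(out, class = "haploscore")
}

#' HaploScore for a table of segments
#'
#' Scores every segment of a segment table against a cohort. When `max_score`
#' is given, the computation of a segment is abandoned as soon as its score is
#' provably above `max_score` (the running level cost of the dynamic program
#' is a lower bound on the final cost); such segments get `haploscore = NA`
#' and `above_threshold = TRUE`, and are never misclassified relative to
#' `max_score`.
#'
#' @inheritParams haploscore
#' @param segments Segment `data.frame` (see [ibd_segments()]).
#' @param max_score Optional early-termination threshold.
#' @return The input table with columns `haploscore`, `n_g`, `n_s` and
#'   `above_threshold` appended.
#' @export
haploscore_batch <- function(cohort, segments, rates = error_rates(),
                             max_score = NULL) {
  rates <- as_error_rates(rates)
  validate_segments(segments, cohort$map)
  # re-scoring replaces any existing score columns
  segments <- segments[, setdiff(names(segments),
                                 c("haploscore", "n_g", "n_s",
                                   "above_threshold")), drop = FALSE]
  if (nrow(segments) == 0L) {
    return(cbind(segments,
                 data.frame(haploscore = numeric(0), n_g = integer(0),
                            n_s = integer(0), above_threshold = logical(0))))
  }
  res <- .haploscore_batch(cohort$hap1, cohort$hap2,
                           id_index(cohort, segments$id_a),
                           id_index(cohort, segments$id_b),
                           as.integer(segments$site_start),
                           as.integer(segments$site_end),
                           rates$epsilon, rates$sigma,
                           if (is.null(max_score)) Inf else as.numeric(max_score))
  cbind(segments, res)
}
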