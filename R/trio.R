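#' Trio phasing by Mendelian inheritance
#'
#' Resolves the parental origin of a trio child's alleles at every site where
#' the laws of Mendelian inheritance determine it, i.e. wherever at least one
#' trio member is homozygous (given Mendelian consistency). Sites where all
#' three members are heterozygous are underdetermined and flagged
#' `"ambiguous"`; Mendelian-inconsistent sites are flagged `"inconsistent"`.
#' At flagged sites the child's input haplotypes are passed through unchanged.
#' Missing genotypes in a parent make that parent uninformative; a missing
#' child genotype makes the site ambiguous.
#'
#' @param cohort A [phased_cohort()].
#' @param trio A list or one-row data frame with `father`, `mother`, `child`.
#' @return A list with integer vectors `paternal` and `maternal` (the child's
#'   phased haplotypes) and a character vector `status` with values
#'   `"resolved"`, `"ambiguous"` or `"inconsistent"`, one per site.
#' @export
trio_phase <- function(cohort, trio) {
  dF <- genotype_dosage_of(cohort, trio$father[1L])
  dM <- genotype_dosage_of(cohort, trio$mother[1L])
  ic <- id_index(cohort, trio$child[1L])
  c1 <- cohort$hap1[, ic]
  c2 <- cohort$hap2[, ic]
  dC <- c1 + c2

  # which alleles each parent can transmit; missing parents are uninformative
  f0 <- is.na(dF) | dF <= 1L; f1 <- is.na(dF) | dF >= 1L
  m0 <- is.na(dM) | dM <= 1L; m1 <- is.na(dM) | dM >= 1L

  pat <- c1
  mat <- c2
  status <- rep("resolved", length(dC))

  hom0 <- !is.na(dC) & dC == 0L
  hom2 <- !is.na(dC) & dC == 2L
  het <- !is.na(dC) & dC == 1L

  # homozygous child: phase is trivial, but parents must be able to transmit
  pat[hom0] <- 0L; mat[hom0] <- 0L
  pat[hom2] <- 1L; mat[hom2] <- 1L
  status[(hom0 & !(f0 & m0)) | (hom2 & !(f1 & m1))] <- "inconsistent"

  # heterozygous child: valid decompositions (paternal, maternal)
  v01 <- het & f0 & m1   # paternal 0, maternal 1
  v10 <- het & f1 & m0   # paternal 1, maternal 0
  res01 <- v01 & !v10
  res10 <- v10 & !v01
  pat[res01] <- 0L; mat[res01] <- 1L
  pat[res10] <- 1L; mat[res10] <- 0L
  amb <- (het & v01 & v10) | is.na(dC)
  status[amb] <- "ambiguous"
  status[het & !v01 & !v10] <- "inconsistent"

  keep <- status != "resolved"
  pat[keep] <- c1[keep]
  mat[keep] <- c2[keep]
  list(paternal = pat, maternal = mat, status = status)
}

genotype_dosage_of <- function(cohort, id) {
  i <- id_index(cohort, id)
  cohort$hap1[, i] + cohort$hap2[, i]
}

#' Count opposite-homozygote sites in a segment interval
#'
#' @param cohort A [phased_cohort()].
#' @param id_a,id_b Individual identifiers.
#' @param site_start,site_end Closed 1-based site interval.
#' @return Integer count of sites in the interval where the two individuals
#'   are opposite homozygotes.
#' @export
count_opposite_homozygotes <- function(cohort, id_a, id_b, site_start, site_end) {
  sum(is_opposite_homozygote(cohort, id_a, id_b, site_start:site_end))
}

#' Probability that a segment without parent support is a false negative
#'
#' A child-other segment with no corresponding parent-other segment contains
#' some number `n` of parent-other opposite-homozygote sites. For the region
#' to nevertheless be IBD between parent and other (a false-negative
#' parent-other segment), every one of those `n` opposite-homozygote calls
#' must be a genotyping error, which happens with probability
#' `(1 - accuracy)^n` under a per-site call accuracy `accuracy`.
#'
#' @param n_opposite_hom Non-negative integer count(s).
#' @param site_accuracy Per-site accuracy of opposite-homozygote calls,
#'   in (0, 1); default 0.95.
#' @return Numeric probability vector.
#' @export
false_negative_probability <- function(n_opposite_hom, site_accuracy = 0.95) {
  if (any(n_opposite_hom < 0)) stop("n_opposite_hom must be non-negative")
  if (site_accuracy <= 0 || site_accuracy >= 1) {
    stop("site_accuracy must lie in (0, 1)")
  }
  (1 - site_accuracy)^n_opposite_hom
}

#' Overlap of a child-other segment with parent-other segments
#'
#' Computes, separately for each parent, the fraction of the child-other
#' segment's sites covered by the union of that parent's segments with the
#' same other individual, and keeps the larger fraction and the identity of
#' that parent (the most favourable parent, mirroring the choice of the
#' smaller opposite-homozygote count across parents). Truncation flags are set
#' when the best parent's coverage is partial and stops strictly inside the
#' child segment.
#'
#' @param child_segment One-row segment table; one id must be `child_id`.
#' @param child_id,father_id,mother_id Trio identifiers.
#' @param parent_segments Segment table of parent-other segments; every row
#'   must pair one of the two parents with the child segment's other
#'   individual.
#' @param cohort Optional [phased_cohort()]; when supplied,
#'   `n_opposite_hom` is the minimum over the two parents of the
#'   opposite-homozygote count against the other individual inside the child
#'   segment interval (else `NA`).
#' @return One-row `data.frame`: `overlap`, `best_parent` ("father",
#'   "mother" or "none"), `trunc_left`, `trunc_right`, `n_opposite_hom`.
#' @export
segment_overlap <- function(child_segment, child_id, father_id, mother_id,
                            parent_segments, cohort = NULL) {
  ids <- c(child_segment$id_a[1L], child_segment$id_b[1L])
  if (!child_id %in% ids) stop("child segment does not involve child_id")
  other <- setdiff(ids, child_id)[1L]
  s0 <- child_segment$site_start[1L]
  s1 <- child_segment$site_end[1L]

  if (nrow(parent_segments)) {
    pids <- ifelse(parent_segments$id_a == other,
                   parent_segments$id_b, parent_segments$id_a)
    others <- ifelse(parent_segments$id_a == other,
                     parent_segments$id_a, parent_segments$id_b)
    if (any(others != other) || !all(pids %in% c(father_id, mother_id))) {
      stop("parent_segments must pair a parent of the trio with the child segment's other individual")
    }
  } else {
    pids <- character(0)
  }

  cover <- function(parent) {
    rows <- which(pids == parent)
    covered_sites(s0, s1, parent_segments$site_start[rows],
                  parent_segments$site_end[rows])
  }
  n <- s1 - s0 + 1L
  ov <- c(father = cover(father_id) / n, mother = cover(mother_id) / n)
  best <- if (max(ov) == 0) "none" else names(ov)[which.max(ov)]
  overlap <- max(ov)

  trunc_left <- trunc_right <- FALSE
  if (overlap > 0 && overlap < 1) {
    bp_id <- if (best == "father") father_id else mother_id
    rows <- which(pids == bp_id)
    cs <- pmax(parent_segments$site_start[rows], s0)
    ce <- pmin(parent_segments$site_end[rows], s1)
    ok <- cs <= ce
    trunc_left <- !any(ok & cs == s0)
    trunc_right <- !any(ok & ce == s1)
  }

  n_oh <- NA_integer_
  if (!is.null(cohort)) {
    n_oh <- min(count_opposite_homozygotes(cohort, father_id, other, s0, s1),
                count_opposite_homozygotes(cohort, mother_id, other, s0, s1))
  }
  data.frame(overlap = overlap, best_parent = best,
             trunc_left = trunc_left, trunc_right = trunc_right,
             n_opposite_hom = n_oh, stringsAsFactors = FALSE)
}

#' Overlap records for all child-other segments of a trio cohort
#'
#' Vectorised wrapper around [segment_overlap()]: for every child-other
#' segment, finds the trio of the child and the parent-other segments sharing
#' the same other individual, and appends the overlap record columns.
#'
#' @param cohort A [phased_cohort()], or NULL to skip opposite-homozygote
#'   counts.
#' @param trios A [trio_set()].
#' @param child_segments Segment table where one id of each row is a trio
#'   child.
#' @param parent_segments Segment table of candidate segments involving trio
#'   parents.
#' @return `child_segments` with columns `child`, `other`, `overlap`,
#'   `best_parent`, `trunc_left`, `trunc_right`, `n_opposite_hom` appended.
#' @export
overlap_records <- function(cohort, trios, child_segments, parent_segments) {
  if (nrow(child_segments) == 0L) {
    return(cbind(child_segments,
                 data.frame(child = character(0), other = character(0),
                            overlap = numeric(0), best_parent = character(0),
                            trunc_left = logical(0), trunc_right = logical(0),
                            n_opposite_hom = integer(0))))
  }
  is_child_a <- child_segments$id_a %in% trios$child
  child <- ifelse(is_child_a, child_segments$id_a, child_segments$id_b)
  other <- ifelse(is_child_a, child_segments$id_b, child_segments$id_a)
  if (!all(child %in% trios$child)) {
    stop("every child segment must involve a trio child")
  }
  ti <- match(child, trios$child)
  pkey <- pair_key(parent_segments$id_a, parent_segments$id_b)

  recs <- vector("list", nrow(child_segments))
  for (k in seq_len(nrow(child_segments))) {
    fa <- trios$father[ti[k]]
    mo <- trios$mother[ti[k]]
    rows <- parent_segments[pkey %in% pair_key(c(fa, mo), c(other[k], other[k])), ,
                            drop = FALSE]
    recs[[k]] <- segment_overlap(child_segments[k, , drop = FALSE], child[k],
                                 fa, mo, rows, cohort)
  }
  cbind(child_segments,
        data.frame(child = child, other = other, stringsAsFactors = FALSE),
        do.call(rbind, recs))
}

#' Classify a candidate segment as true IBD by parent overlap
#'
#' A child-other segment is classified true IBD when at least `threshold` of
#' its sites are covered by a corresponding parent-other segment (default 80%;
#' the boundary is inclusive). Precise IBD endpoints are hard to determine
#' from genotype data, which is why full containment is not required.
#'
#' @param overlap Numeric overlap fraction(s) in \[0, 1\], or a record table
#'   from [overlap_records()] (its `overlap` column is used).
#' @param threshold Classification threshold in (0, 1].
#' @return Logical vector.
#' @export
classify_true_ibd <- function(overlap, threshold = 0.8) {
  if (is.data.frame(overlap)) overlap <- overlap$overlap
  if (threshold <= 0 || threshold > 1) stop("threshold must lie in (0, 1]")
  if (any(overlap < 0 | overlap > 1, na.rm = TRUE)) {
    stop("overlap fractions must lie in [0, 1]")
  }
  overlap >= threshold
}

#' Diplotype and haplotype match criteria for a fixed-size window
#'
#' Mirrors the two matching criteria of seed-and-extend IBD detection on one
#' window of sites: the diplotype criterion holds when the window contains at
#' most `max_hom_err` opposite-homozygote sites (the `-err_hom` allowance);
#' the haplotype criterion holds when some pair of haplotypes, one from each
#' individual, is identical across the window at all sites where both alleles
#' are called.
#'
#' @inheritParams count_opposite_homozygotes
#' @param site_start First site of the window.
#' @param window_sites Window size in sites (default 100); the window
#'   `[site_start, site_start + window_sites - 1]` must fit inside the map.
#' @param max_hom_err Opposite-homozygote allowance for the diplotype
#'   criterion (default 2).
#' @return A list with logical elements `diplotype_match` and
#'   `haplotype_match`.
#' @export
window_match_classify <- function(cohort, id_a, id_b, site_start,
                                  window_sites = 100L, max_hom_err = 2L) {
  s1 <- site_start + window_sites - 1L
  if (site_start < 1L || s1 > n_sites(cohort$map)) {
    stop("window does not fit inside the site map")
  }
  sites <- site_start:s1
  diplo <- sum(is_opposite_homozygote(cohort, id_a, id_b, sites)) <= max_hom_err
  ia <- id_index(cohort, id_a)
  ib <- id_index(cohort, id_b)
  ha <- list(cohort$hap1[sites, ia], cohort$hap2[sites, ia])
  hb <- list(cohort$hap1[sites, ib], cohort$hap2[sites, ib])
  haplo <- FALSE
  for (p in 1:2) {
    for (q in 1:2) {
      if (all(ha[[p]] == hb[[q]], na.rm = TRUE)) haplo <- TRUE
    }
  }
  list(diplotype_match = diplo, haplotype_match = haplo)
}

window_class <- function(d, h) {
  if (d && h) "both" else if (h) "haplo" else if (d) "diplo" else "none"
}

#' Window match contingency tables for child-other segments
#'
#' Partitions every full window of every child-other segment by whether it is
#' contained in a corresponding parent-other segment, classifies the window
#' jointly in the child (child vs. other) and in the most favourable parent
#' (parent vs. other; favourability order both > haplo > diplo > none), and
#' tabulates the counts. Windows are consecutive non-overlapping blocks
#' anchored at each segment's start; trailing partial windows are skipped.
#'
#' @inheritParams overlap_records
#' @param window_sites,max_hom_err See [window_match_classify()].
#' @return A list with two 4x4 contingency tables (`contained`,
#'   `not_contained`), rows = parent class, columns = child class, both over
#'   none/diplo/haplo/both.
#' @export
tabulate_window_matches <- function(cohort, trios, child_segments,
                                    parent_segments, window_sites = 100L,
                                    max_hom_err = 2L) {
  lv <- c("none", "diplo", "haplo", "both")
  empty <- matrix(0L, 4L, 4L, dimnames = list(parent = lv, child = lv))
  out <- list(contained = empty, not_contained = empty)
  if (nrow(child_segments) == 0L) return(out)

  is_child_a <- child_segments$id_a %in% trios$child
  child <- ifelse(is_child_a, child_segments$id_a, child_segments$id_b)
  other <- ifelse(is_child_a, child_segments$id_b, child_segments$id_a)
  ti <- match(child, trios$child)
  if (anyNA(ti)) stop("every child segment must involve a trio child")
  pkey <- pair_key(parent_segments$id_a, parent_segments$id_b)
  rank <- stats::setNames(seq_along(lv), lv)

  for (k in seq_len(nrow(child_segments))) {
    fa <- trios$father[ti[k]]
    mo <- trios$mother[ti[k]]
    prows <- parent_segments[pkey %in% pair_key(c(fa, mo), rep(other[k], 2L)), ,
                             drop = FALSE]
    starts <- seq.int(child_segments$site_start[k],
                      by = window_sites,
                      length.out = (child_segments$site_end[k] -
                                    child_segments$site_start[k] + 1L) %/%
                                   window_sites)
    for (ws in starts) {
      we <- ws + window_sites - 1L
      contained <- any(prows$site_start <= ws & prows$site_end >= we)
      cc <- window_match_classify(cohort, child[k], other[k], ws,
                                  window_sites, max_hom_err)
      cls_child <- window_class(cc$diplotype_match, cc$haplotype_match)
      cls_par <- "none"
      for (p in c(fa, mo)) {
        pc <- window_match_classify(cohort, p, other[k], ws,
                                    window_sites, max_hom_err)
        cls <- window_class(pc$diplotype_match, pc$haplotype_match)
        if (rank[cls] > rank[cls_par]) cls_par <- cls
      }
      slot <- if (contained) "contained" else "not_contained"
      out[[slot]][cls_par, cls_child] <- out[[slot]][cls_par, cls_child] + 1L
    }
  }
  out
}

#' Classify a pairwise relationship from genome-wide IBD sharing
#'
#' Applies the IBD-sharing rules used to identify trios: a parent-child pair
#' shares at least 85% of the genetic length of the genome on at least one
#' haplotype (IBD1) and at most 10% on both haplotypes (IBD2); a pair is
#' "unrelated" enough to serve as the two parents of a trio when it shares at
#' most 20% on at least one haplotype.
#'
#' @param ibd1_fraction,ibd2_fraction Fractions of genome genetic length
#'   shared on >= 1 haplotype and on both haplotypes, in \[0, 1\].
#' @return Character vector: `"parent_child"`, `"unrelated_pairable"` or
#'   `"other"`.
#' @export
classify_relationship <- function(ibd1_fraction, ibd2_fraction) {
  if (any(ibd1_fraction < 0 | ibd1_fraction > 1) ||
      any(ibd2_fraction < 0 | ibd2_fraction > 1)) {
    stop("IBD fractions must lie in [0, 1]")
  }
  out <- rep("other", length(ibd1_fraction))
  out[ibd1_fraction <= 0.20] <- "unrelated_pairable"
  out[ibd1_fraction >= 0.85 & ibd2_fraction <= 0.10] <- "parent_child"
  out
}
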