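#' Estimate the per-site switch error rate against truth haplotypes
#'
#' Compares statistically phased haplotypes with truth haplotypes (typically
#' trio-phased, assumed to carry the true phase) and counts switch errors:
#' positions where the alignment of the statistical haplotypes to the truth
#' haplotypes flips between consecutive phase-informative sites. A site is
#' phase-informative for an individual when it is heterozygous with the same
#' genotype in both cohorts, not missing, and not excluded. Homozygous sites
#' carry no phase information and are skipped when counting, but the reported
#' rate is normalised by all sites of the map:
#' `rate = total switches / (n individuals x n sites)`. Two consecutive
#' switches flipping a single site back and forth count as two switches.
#'
#' @param statistical A [phased_cohort()] of statistically phased haplotypes.
#' @param truth A [phased_cohort()] over the same sites carrying the true
#'   phase.
#' @param individuals Ids to compare (default: all ids of `statistical`);
#'   every id must be present in both cohorts.
#' @param exclude Optional exclusion of unreliable sites (e.g. ambiguous or
#'   Mendelian-inconsistent trio-phase sites): a logical vector over sites
#'   applied to every individual, or a named list of such vectors keyed by
#'   individual id.
#' @return A list with `rate`, `n_switches`, `n_individuals`, `n_sites` and a
#'   `per_individual` data frame of switch and informative-site counts.
#' @export
switch_error_rate <- function(statistical, truth, individuals = NULL,
                              exclude = NULL) {
  if (n_sites(statistical$map) != n_sites(truth$map)) {
    stop("cohorts must share the same site map")
  }
  if (is.null(individuals)) individuals <- statistical$ids
  is_ <- id_index(statistical, individuals)
  it <- id_index(truth, individuals)

  n_ind <- length(individuals)
  n_map <- n_sites(statistical$map)
  switches <- integer(n_ind)
  informative <- integer(n_ind)

  for (k in seq_len(n_ind)) {
    s1 <- statistical$hap1[, is_[k]]; s2 <- statistical$hap2[, is_[k]]
    t1 <- truth$hap1[, it[k]]; t2 <- truth$hap2[, it[k]]
    excl <- exclusion_vector(exclude, individuals[k], n_map)
    het <- !is.na(s1) & !is.na(s2) & !is.na(t1) & !is.na(t2) &
      s1 + s2 == 1L & t1 + t2 == 1L & !excl
    ori <- as.integer(s1[het] != t1[het])
    informative[k] <- length(ori)
    switches[k] <- if (length(ori) > 1L) sum(diff(ori) != 0L) else 0L
  }
  list(rate = sum(switches) / (n_ind * n_map),
       n_switches = sum(switches),
       n_individuals = n_ind,
       n_sites = n_map,
       per_individual = data.frame(id = individuals, n_switches = switches,
                                   n_informative = informative,
                                   stringsAsFactors = FALSE))
}

exclusion_vector <- function(exclude, id, n) {
  if (is.null(exclude)) return(rep(FALSE, n))
  v <- if (is.list(exclude)) exclude[[id]] else exclude
  if (is.null(v)) return(rep(FALSE, n))
  if (length(v) != n) stop("exclusion vector length must equal the site count")
  as.logical(v)
}

#' Per-site switch error rate from aggregate counts
#'
#' The rate arithmetic used when only totals are at hand: total switch errors
#' divided by (number of individuals x number of sites).
#'
#' @param n_switches Total switch errors counted.
#' @param n_individuals Number of individuals compared.
#' @param n_sites Number of genotyped sites per individual.
#' @return The per-site switch error rate.
#' @examples
#' switch_rate_from_counts(3629, 52, 23142)  # ~0.003
#' @export
switch_rate_from_counts <- function(n_switches, n_individuals, n_sites) {
  if (n_individuals <= 0 || n_sites <= 0) {
    stop("n_individuals and n_sites must be positive")
  }
  n_switches / (n_individuals * n_sites)
}

#' Estimate the per-allele genotyping error rate from replicate calls
#'
#' Repeat genotyping of the same samples gives paired genotype call vectors;
#' the per-allele genotyping error rate is estimated as the fraction of
#' discordant non-missing call pairs, halved (a single-allele error changes
#' the genotype, and each genotype carries two alleles). With no replicate
#' data, returns the shipped default of 0.0075.
#'
#' @param calls_a,calls_b Paired genotype dosage vectors (0/1/2, `NA`
#'   missing) from replicate genotyping of the same samples, or NULL.
#' @return Per-allele genotyping error rate.
#' @export
genotyping_error_rate <- function(calls_a = NULL, calls_b = NULL) {
  if (is.null(calls_a) && is.null(calls_b)) return(0.0075)
  if (length(calls_a) != length(calls_b)) {
    stop("replicate call vectors must have equal length")
  }
  ok <- !is.na(calls_a) & !is.na(calls_b)
  if (!any(ok)) stop("no comparable non-missing call pairs")
  sum(calls_a[ok] != calls_b[ok]) / (2 * sum(ok))
}
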