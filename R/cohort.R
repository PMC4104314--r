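#' Phased cohort: per-individual haplotype pairs over a site map
#'
#' Container for the phased diplotypes of a cohort: for every individual, two
#' haplotype allele vectors (coded 0/1, `NA` = missing) over one [site_map()].
#' An individual's genotype at a site is the unordered pair of its two
#' haplotype alleles; a site is treated as missing when either allele is
#' missing. Optional per-site genotype confidence scores in \[0, 1\] may be
#' attached (e.g. Illumina GenCall scores).
#'
#' @param ids Character vector of individual identifiers (unique).
#' @param hap1,hap2 Integer matrices, sites x individuals, alleles 0/1/`NA`.
#' @param map A [site_map()] with as many sites as the matrices have rows.
#' @param confidence Optional numeric matrix (sites x individuals) in \[0, 1\].
#' @return An object of class `phased_cohort`.
#' @export
phased_cohort <- function(ids, hap1, hap2, map, confidence = NULL) {
  ids <- as.character(ids)
  hap1 <- as.matrix(hap1); storage.mode(hap1) <- "integer"
  hap2 <- as.matrix(hap2); storage.mode(hap2) <- "integer"
  if (anyDuplicated(ids)) stop("individual ids must be unique")
  if (!inherits(map, "site_map")) stop("map must be a site_map")
  if (nrow(hap1) != n_sites(map) || nrow(hap2) != n_sites(map)) {
    stop("haplotype matrices must have one row per site of the map")
  }
  if (ncol(hap1) != length(ids) || ncol(hap2) != length(ids)) {
    stop("haplotype matrices must have one column per individual")
  }
  ok <- function(h) all(h %in% c(0L, 1L) | is.na(h))
  if (!ok(hap1) || !ok(hap2)) stop("alleles must be coded 0/1 or NA (missing)")
  if (!is.null(confidence)) {
    confidence <- as.matrix(confidence)
    if (!all(dim(confidence) == dim(hap1))) {
      stop("confidence matrix must match haplotype matrix dimensions")
    }
    if (any(confidence < 0 | confidence > 1, na.rm = TRUE)) {
      stop("confidence scores must lie in [0, 1]")
    }
  }
  colnames(hap1) <- ids
  colnames(hap2) <- ids
  structure(list(ids = ids, hap1 = hap1, hap2 = hap2, map = map,
                 confidence = confidence),
            class = "phased_cohort")
}

#' @export
print.phased_cohort <- function(x, ...) {
  cat(sprintf("<phased_cohort> %d individuals x %d sites (chrom %s)%s\n",
              length(x$ids), n_sites(x$map), x$map$chrom,
              if (is.null(x$confidence)) "" else ", with confidence scores"))
  invisible(x)
}

id_index <- function(cohort, id) {
  i <- match(id, cohort$ids)
  if (anyNA(i)) stop("unknown individual id(s): ", paste(id[is.na(i)], collapse = ", "))
  i
}

#' Genotype class of an individual at sites
#'
#' Derives the genotype class from the unordered allele pair: `hom_ref` (0/0),
#' `het` (0/1), `hom_alt` (1/1), or `missing` when either allele is missing.
#'
#' @param cohort A [phased_cohort()].
#' @param id Individual identifier.
#' @param sites Integer vector of site indices (default: all sites).
#' @return Character vector of genotype classes.
#' @export
genotype_class <- function(cohort, id, sites = NULL) {
  i <- id_index(cohort, id)
  if (is.null(sites)) sites <- seq_len(n_sites(cohort$map))
  if (any(sites < 1L | sites > n_sites(cohort$map))) stop("site index out of range")
  a <- cohort$hap1[sites, i]
  b <- cohort$hap2[sites, i]
  d <- a + b
  out <- c("hom_ref", "het", "hom_alt")[d + 1L]
  out[is.na(d)] <- "missing"
  out
}

#' Are two individuals opposite homozygotes at sites?
#'
#' TRUE at a site iff one individual is homozygous reference and the other
#' homozygous alternate. Heterozygous or missing genotypes never create
#' opposite homozygotes. Opposite homozygosity is incompatible with IBD at the
#' site absent genotyping error, which is why segment truncation points are
#' informative about false-positive IBD.
#'
#' @inheritParams genotype_class
#' @param id_a,id_b The two individual identifiers.
#' @return Logical vector over `sites`.
#' @export
is_opposite_homozygote <- function(cohort, id_a, id_b, sites = NULL) {
  ia <- id_index(cohort, id_a)
  ib <- id_index(cohort, id_b)
  if (is.null(sites)) sites <- seq_len(n_sites(cohort$map))
  if (any(sites < 1L | sites > n_sites(cohort$map))) stop("site index out of range")
  da <- cohort$hap1[sites, ia] + cohort$hap2[sites, ia]
  db <- cohort$hap1[sites, ib] + cohort$hap2[sites, ib]
  out <- (da == 0L & db == 2L) | (da == 2L & db == 0L)
  out[is.na(out)] <- FALSE
  out
}

#' Genotype dosage matrix of a cohort
#'
#' @param cohort A [phased_cohort()].
#' @return Integer matrix (sites x individuals) of alternate-allele dosages
#'   0/1/2, `NA` where either allele is missing.
#' @export
genotype_dosage <- function(cohort) {
  d <- cohort$hap1 + cohort$hap2
  colnames(d) <- cohort$ids
  d
}

#' Trio set: father-mother-child triples over a cohort
#'
#' @param father,mother,child Character vectors of equal length.
#' @param cohort Optional [phased_cohort()]; when given, all ids are checked
#'   for membership.
#' @return A `data.frame` of class `trio_set` with columns `father`, `mother`,
#'   `child`.
#' @export
trio_set <- function(father, mother, child, cohort = NULL) {
  father <- as.character(father); mother <- as.character(mother)
  child <- as.character(child)
  if (length(father) != length(mother) || length(father) != length(child)) {
    stop("father, mother and child must have equal lengths")
  }
  if (any(father == child) || any(mother == child)) {
    stop("no individual can be its own parent")
  }
  if (!is.null(cohort)) {
    id_index(cohort, unique(c(father, mother, child)))
  }
  structure(data.frame(father = father, mother = mother, child = child,
                       stringsAsFactors = FALSE),
            class = c("trio_set", "data.frame"))
}
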