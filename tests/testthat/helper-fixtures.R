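# Shared fixture builders: everything is generated in code.

# Evenly spaced site map: n sites, `spacing_cM` apart, 3 kb apart physically.
tiny_map <- function(n, spacing_cM = 0.01, chrom = "t1") {
  site_map(chrom, seq_len(n) * 3000, seq_len(n) * spacing_cM)
}

# Cohort from explicit haplotype vectors: haps is a named list, each element
# list(h1, h2).
tiny_cohort <- function(haps, map = tiny_map(length(haps[[1]][[1]]))) {
  n <- n_sites_of(map)
  h1 <- matrix(unlist(lapply(haps, function(x) as.integer(x[[1]]))), n)
  h2 <- matrix(unlist(lapply(haps, function(x) as.integer(x[[2]]))), n)
  phased_cohort(names(haps), h1, h2, map)
}

n_sites_of <- function(map) length(map$bp)

# Random two-individual cohort with optional missingness.
random_pair_cohort <- function(L, miss = 0.1, map = tiny_map(L)) {
  draw <- function() sample(c(0L, 1L, NA_integer_), L, replace = TRUE,
                            prob = c((1 - miss) / 2, (1 - miss) / 2, miss))
  tiny_cohort(list(a = list(draw(), draw()), b = list(draw(), draw())), map)
}

whole_segment <- function(cohort) {
  ibd_segments("a", "b", 1L, n_sites_of(cohort$map), cohort$map)
}

# Small simulation config used by unit tests (fast: ~8k sites, 5 trios).
small_sim_config <- function(seed, ...) {
  sim_config(seed = seed, n_sites = 8000L, chrom_bp = 24e6, chrom_cM = 24,
             n_trios = 5L, n_others = 30L, n_true = 30L, n_lures = 30L,
             length_range_cM = c(2, 5), ...)
}
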