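#' Configuration for the synthetic trio-cohort simulator
#'
#' Bundles the parameters of [simulate_truth()]. The defaults describe a
#' desk-scale genotyping-array-like chromosome: 20,000 common biallelic sites
#' over 60 cM / 60 Mb at a uniform recombination rate, 200 individuals (20
#' father-mother-child trios plus 140 unrelated individuals), error rates at
#' the shipped HaploScore defaults, and planted ground truth of two kinds:
#'
#' * **true IBD segments** — a contiguous haplotype stretch copied between two
#'   individuals (at most one trio parent per pair, so Mendelian transmission
#'   bookkeeping stays exact);
#' * **diplotype lures** — intervals made free of opposite homozygotes between
#'   a donor and a receiver, with the receiver's phase left uninformative
#'   except inside one or more short genuinely shared haplotype blocks. These
#'   are the synthetic counterpart of the long diplotype-compatible,
#'   haplotype-incompatible stretches that linkage disequilibrium produces in
#'   real data, and they are what permissive diplotype extension wrongly
#'   reports as IBD.
#'
#' @param seed Integer RNG seed (mandatory: cohorts must be reproducible).
#' @param n_sites Number of biallelic sites.
#' @param chrom Chromosome label.
#' @param chrom_bp,chrom_cM Physical and genetic chromosome length.
#' @param maf_range Founder allele frequencies are drawn uniformly from this
#'   range (chip-like common variants).
#' @param n_trios,n_others Number of trios and of additional unrelated
#'   individuals.
#' @param n_true,n_lures Number of planted true IBD segments and diplotype
#'   lures.
#' @param length_range_cM Genetic-length law (uniform) for planted intervals.
#' @param sigma,epsilon Per-site switch and genotyping error probabilities
#'   used by [degrade()].
#' @param recomb_scale Multiplier on the Poisson crossover rate (0 forces
#'   zero crossovers, children then inherit verbatim parental haplotypes).
#' @param lure_block_sites Length (sites) of each genuinely shared haplotype
#'   block inside a lure; one block per ~2 cM of lure length seeds detection,
#'   mimicking the short chance haplotype matches that seed false segments.
#'   The default (250 sites at the default marker density) always spans at
#'   least one full seed window while leaving the bulk of the lure haplotype-
#'   uninformative.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed,
                       n_sites = 20000L,
                       chrom = "sim1",
                       chrom_bp = 60e6,
                       chrom_cM = 60,
                       maf_range = c(0.05, 0.5),
                       n_trios = 20L,
                       n_others = 140L,
                       n_true = 150L,
                       n_lures = 150L,
                       length_range_cM = c(2, 8),
                       sigma = 0.003,
                       epsilon = 0.0075,
                       recomb_scale = 1,
                       lure_block_sites = 250L) {
  if (missing(seed) || is.null(seed)) stop("a seed is mandatory")
  stopifnot(n_sites >= 2L, chrom_cM > 0, chrom_bp > n_sites,
            sigma >= 0, sigma < 1, epsilon >= 0, epsilon < 1,
            length_range_cM[1L] > 0, length_range_cM[2L] <= chrom_cM,
            recomb_scale >= 0, n_trios >= 0L, n_others >= 0L)
  structure(list(seed = as.integer(seed), n_sites = as.integer(n_sites),
                 chrom = chrom, chrom_bp = chrom_bp, chrom_cM = chrom_cM,
                 maf_range = maf_range, n_trios = as.integer(n_trios),
                 n_others = as.integer(n_others), n_true = as.integer(n_true),
                 n_lures = as.integer(n_lures),
                 length_range_cM = length_range_cM, sigma = sigma,
                 epsilon = epsilon, recomb_scale = recomb_scale,
                 lure_block_sites = as.integer(lure_block_sites)),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("<sim_config> seed %d: %d sites / %.0f cM, %d trios + %d others, %d true + %d lure plants, sigma=%g eps=%g\n",
              x$seed, x$n_sites, x$chrom_cM, x$n_trios, x$n_others,
              x$n_true, x$n_lures, x$sigma, x$epsilon))
  invisible(x)
}

# interval registry: avoids planting overlapping structure on one individual
new_registry <- function() new.env(parent = emptyenv())

registry_free <- function(reg, ids, s, e, margin = 200L) {
  for (id in ids) {
    iv <- reg[[id]]
    if (!is.null(iv) && any(iv[, 1L] <= e + margin & iv[, 2L] >= s - margin)) {
      return(FALSE)
    }
  }
  TRUE
}

registry_add <- function(reg, ids, s, e) {
  for (id in ids) reg[[id]] <- rbind(reg[[id]], c(s, e))
}

draw_interval <- function(map, length_range_cM, reg, ids, max_try = 50L) {
  cM <- map$cM
  for (k in seq_len(max_try)) {
    len <- stats::runif(1L, length_range_cM[1L], length_range_cM[2L])
    start <- stats::runif(1L, cM[1L], cM[length(cM)] - len)
    s <- findInterval(start, cM) + 1L           # first site with cM >= start
    e <- findInterval(start + len, cM)          # last site with cM <= start+len
    if (s >= e || e - s + 1L < 4L) next
    if (registry_free(reg, ids, s, e)) return(c(s, e))
  }
  NULL
}

#' Simulate a trio cohort with planted ground truth
#'
#' Generates founder haplotypes site-independently from the allele-frequency
#' law, plants true IBD segments and diplotype lures (see [sim_config()]),
#' then creates each trio child by Mendelian transmission of one recombinant
#' haplotype per parent, with crossovers placed as a Poisson process on the cM
#' axis. Every planted true segment whose carrier parent transmits (part of)
#' the carrying haplotype yields recorded child-other truth segments, so all
#' downstream truth labelling is exact.
#'
#' @param config A [sim_config()].
#' @return A list with elements `cohort` (true haplotypes, a
#'   [phased_cohort()]), `trios` (a [trio_set()]), `truth` (segment table of
#'   planted plus transmitted true IBD, with a `type` column), `lures`
#'   (segment table of planted diplotype lures), `origins` (per-child parental
#'   haplotype origin vectors) and `config`.
#' @export
simulate_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (diff(config$length_range_cM) >= 0 &&
      config$length_range_cM[2L] > config$chrom_cM) {
    stop("planted segments cannot be longer than the chromosome")
  }
  set.seed(config$seed)
  n <- config$n_sites

  bp <- sort(sample.int(config$chrom_bp - 1L, n))
  map <- site_map(config$chrom, bp, bp / config$chrom_bp * config$chrom_cM)
  freq <- stats::runif(n, config$maf_range[1L], config$maf_range[2L])

  fmt <- function(prefix, k) sprintf("%s%03d", prefix, seq_len(k))
  fathers <- fmt("fa", config$n_trios)
  mothers <- fmt("mo", config$n_trios)
  others <- fmt("ot", config$n_others)
  children <- fmt("ch", config$n_trios)
  founders <- c(fathers, mothers, others)
  ids <- c(founders, children)
  n_founders <- length(founders)

  hap1 <- matrix(stats::rbinom(n * n_founders, 1L, freq), n, n_founders)
  hap2 <- matrix(stats::rbinom(n * n_founders, 1L, freq), n, n_founders)
  colnames(hap1) <- founders
  colnames(hap2) <- founders

  reg <- new_registry()
  get_hap <- function(id, h) if (h == 1L) hap1[, id] else hap2[, id]

  # ---- plant true IBD between founder pairs (at most one trio parent) ----
  truth <- list()
  parents <- c(fathers, mothers)
  for (k in seq_len(config$n_true)) {
    a <- sample(founders, 1L)
    b <- sample(setdiff(others, a), 1L)
    iv <- draw_interval(map, config$length_range_cM, reg, c(a, b))
    if (is.null(iv)) next
    ha <- sample(1:2, 1L)
    hb <- sample(1:2, 1L)
    src <- get_hap(a, ha)[iv[1L]:iv[2L]]
    if (hb == 1L) hap1[iv[1L]:iv[2L], b] <- src else hap2[iv[1L]:iv[2L], b] <- src
    registry_add(reg, c(a, b), iv[1L], iv[2L])
    truth[[length(truth) + 1L]] <-
      data.frame(id_a = a, id_b = b, site_start = iv[1L], site_end = iv[2L],
                 hap_a = ha, hap_b = hb, type = "planted",
                 stringsAsFactors = FALSE)
  }
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(id_a = character(0), id_b = character(0),
               site_start = integer(0), site_end = integer(0),
               hap_a = integer(0), hap_b = integer(0), type = character(0))

  # ---- children: Mendelian transmission with Poisson crossovers ----
  gamete_origin <- function() {
    k <- stats::rpois(1L, config$chrom_cM / 100 * config$recomb_scale)
    xo <- sort(stats::runif(k, map$cM[1L], map$cM[n]))
    start <- sample(1:2, 1L)
    ((start - 1L + findInterval(map$cM, xo)) %% 2L) + 1L
  }
  ch1 <- matrix(NA_integer_, n, config$n_trios)
  ch2 <- matrix(NA_integer_, n, config$n_trios)
  origins <- vector("list", config$n_trios)
  names(origins) <- children
  for (t in seq_len(config$n_trios)) {
    po <- gamete_origin()
    mo <- gamete_origin()
    ch1[, t] <- ifelse(po == 1L, hap1[, fathers[t]], hap2[, fathers[t]])
    ch2[, t] <- ifelse(mo == 1L, hap1[, mothers[t]], hap2[, mothers[t]])
    origins[[t]] <- list(paternal = po, maternal = mo)
  }
  hap1 <- cbind(hap1, ch1)
  hap2 <- cbind(hap2, ch2)
  colnames(hap1) <- ids
  colnames(hap2) <- ids

  # ---- transmitted copies of planted segments become child-other truth ----
  transmitted <- list()
  if (nrow(truth) && config$n_trios > 0L) {
    for (k in seq_len(nrow(truth))) {
      for (side in c("a", "b")) {
        p <- truth[[paste0("id_", side)]][k]
        t <- match(p, fathers)
        role <- "paternal"
        if (is.na(t)) { t <- match(p, mothers); role <- "maternal" }
        if (is.na(t)) next
        partner <- if (side == "a") truth$id_b[k] else truth$id_a[k]
        h <- truth[[paste0("hap_", side)]][k]
        s <- truth$site_start[k]; e <- truth$site_end[k]
        ori <- origins[[t]][[role]][s:e]
        r <- rle(ori == h)
        ends <- cumsum(r$lengths)
        starts <- ends - r$lengths + 1L
        for (j in which(r$values & r$lengths >= 4L)) {
          transmitted[[length(transmitted) + 1L]] <-
            data.frame(id_a = children[t], id_b = partner,
                       site_start = s + starts[j] - 1L,
                       site_end = s + ends[j] - 1L,
                       hap_a = if (role == "paternal") 1L else 2L, hap_b = NA_integer_,
                       type = "transmitted", stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(transmitted)) truth <- rbind(truth, do.call(rbind, transmitted))

  # ---- diplotype lures: opposite-homozygote-free, phase-uninformative ----
  lures <- list()
  for (k in seq_len(config$n_lures)) {
    r_id <- sample(others, 1L)
    d_id <- sample(setdiff(ids, r_id), 1L)
    iv <- draw_interval(map, config$length_range_cM, reg, c(r_id, d_id))
    if (is.null(iv)) next
    s <- iv[1L]; e <- iv[2L]
    h <- sample(1:2, 1L)
    donor <- if (h == 1L) hap1[s:e, d_id] else hap2[s:e, d_id]
    len_cM <- map$cM[e] - map$cM[s]
    n_blocks <- max(1L, floor(len_cM / 2))

    # one shared block per ~2 cM, placed inside equal chunks of the interval
    n_iv <- e - s + 1L
    chunk <- n_iv %/% n_blocks
    for (b in seq_len(n_blocks)) {
      bl <- min(config$lure_block_sites, chunk)
      off <- if (chunk > bl) sample.int(chunk - bl, 1L) else 1L
      b0 <- s + (b - 1L) * chunk + off - 1L
      b1 <- b0 + bl - 1L
      rh <- sample(1:2, 1L)
      if (rh == 1L) hap1[b0:b1, r_id] <- donor[(b0:b1) - s + 1L]
      else hap2[b0:b1, r_id] <- donor[(b0:b1) - s + 1L]
    }

    # buffer: remove opposite homozygosity against the donor's genotype
    dd <- hap1[s:e, d_id] + hap2[s:e, d_id]
    rd <- hap1[s:e, r_id] + hap2[s:e, r_id]
    opp <- which((dd == 0L & rd == 2L) | (dd == 2L & rd == 0L))
    if (length(opp)) {
      pick <- sample(1:2, length(opp), replace = TRUE)
      for (j in seq_along(opp)) {
        w <- s + opp[j] - 1L
        val <- hap1[w, d_id]  # donor is homozygous here
        if (pick[j] == 1L) hap1[w, r_id] <- val else hap2[w, r_id] <- val
      }
    }
    registry_add(reg, c(r_id, d_id), s, e)
    lures[[length(lures) + 1L]] <-
      data.frame(id_a = d_id, id_b = r_id, site_start = s, site_end = e,
                 stringsAsFactors = FALSE)
  }
  lures <- if (length(lures)) do.call(rbind, lures) else
    data.frame(id_a = character(0), id_b = character(0),
               site_start = integer(0), site_end = integer(0))

  cohort <- phased_cohort(ids, hap1, hap2, map)
  truth_seg <- cbind(refresh_segments(truth, map),
                     truth[, c("hap_a", "hap_b", "type"), drop = FALSE])
  lure_seg <- refresh_segments(lures, map)
  list(cohort = cohort,
       trios = trio_set(fathers, mothers, children, cohort),
       truth = truth_seg, lures = lure_seg,
       origins = origins, config = config)
}

#' Inject switch and genotyping errors into a cohort
#'
#' Emulates the two observation error processes of array-genotyped,
#' statistically phased data: independently per individual and site, with
#' probability `epsilon` one uniformly chosen allele is flipped (a genotyping
#' error), and with probability `sigma` the two haplotypes are swapped from
#' that site onward (a switch error). Genotype errors are applied before
#' switches (chip first, phasing after). Every injected event is logged.
#'
#' @param cohort A [phased_cohort()] of true haplotypes.
#' @param sigma,epsilon Per-site error probabilities.
#' @param seed Optional seed; `NULL` continues the current RNG stream.
#' @return A list with `cohort` (degraded copy), `switch_log` (data frame
#'   `id`, `site`) and `genotype_log` (data frame `id`, `site`, `hap`).
#' @export
degrade <- function(cohort, sigma = 0.003, epsilon = 0.0075, seed = NULL) {
  stopifnot(sigma >= 0, sigma < 1, epsilon >= 0, epsilon < 1)
  if (!is.null(seed)) set.seed(seed)
  n <- n_sites(cohort$map)
  h1 <- cohort$hap1
  h2 <- cohort$hap2
  sw_log <- list()
  ge_log <- list()
  for (k in seq_along(cohort$ids)) {
    if (epsilon > 0) {
      err <- which(stats::runif(n) < epsilon)
      if (length(err)) {
        hp <- sample(1:2, length(err), replace = TRUE)
        i1 <- err[hp == 1L]; i2 <- err[hp == 2L]
        h1[i1, k] <- 1L - h1[i1, k]
        h2[i2, k] <- 1L - h2[i2, k]
        ge_log[[length(ge_log) + 1L]] <-
          data.frame(id = cohort$ids[k], site = err, hap = hp,
                     stringsAsFactors = FALSE)
      }
    }
    if (sigma > 0) {
      sw <- which(stats::runif(n) < sigma)
      if (length(sw)) {
        swap <- (cumsum(tabulate(sw, nbins = n)) %% 2L) == 1L
        tmp <- h1[swap, k]
        h1[swap, k] <- h2[swap, k]
        h2[swap, k] <- tmp
        sw_log[[length(sw_log) + 1L]] <-
          data.frame(id = cohort$ids[k], site = sw, stringsAsFactors = FALSE)
      }
    }
  }
  bindlog <- function(x, cols) {
    if (length(x)) do.call(rbind, x) else
      stats::setNames(as.data.frame(replicate(length(cols),
                                              integer(0), simplify = FALSE)), cols)
  }
  list(cohort = phased_cohort(cohort$ids, h1, h2, cohort$map,
                              cohort$confidence),
       switch_log = bindlog(sw_log, c("id", "site")),
       genotype_log = bindlog(ge_log, c("id", "site", "hap")))
}

#' Detect candidate IBD segments by permissive diplotype matching
#'
#' A deliberately permissive seed-and-extend matcher in the GERMLINE mould:
#' exact haplotype-pair matches over consecutive `window_sites`-site windows
#' seed candidate matches, which are extended site-by-site in both directions
#' through any site that is not an opposite homozygote, with a total allowance
#' of `max_hom_err` opposite homozygotes per match; overlapping matches are
#' merged and candidates shorter than `min_cM` are discarded. Because the
#' extension consults only the diplotypes, the output contains both
#' haplotype-consistent (true-like) and diplotype-only (false-like)
#' candidates.
#'
#' @param cohort A [phased_cohort()] (typically the degraded, observed one).
#' @param pairs Two-column matrix or data frame of individual id pairs to
#'   scan; default all unordered pairs of the cohort.
#' @param window_sites Seed window size in sites (default 100).
#' @param max_hom_err Total opposite-homozygote allowance per match (default
#'   2).
#' @param min_cM Minimum reported genetic length (default 2).
#' @return A segment table (see [ibd_segments()]).
#' @export
detect_candidates <- function(cohort, pairs = NULL, window_sites = 100L,
                              max_hom_err = 2L, min_cM = 2) {
  if (is.null(pairs)) {
    pairs <- t(utils::combn(cohort$ids, 2L))
  }
  pairs <- as.matrix(pairs)
  if (nrow(pairs) == 0L) return(empty_segments())
  ia <- id_index(cohort, pairs[, 1L])
  ib <- id_index(cohort, pairs[, 2L])
  hits <- .detect_candidates(cohort$hap1, cohort$hap2, ia, ib,
                             as.integer(window_sites), as.integer(max_hom_err))
  if (nrow(hits) == 0L) return(empty_segments())
  seg <- ibd_segments(pairs[hits$pair, 1L], pairs[hits$pair, 2L],
                      hits$site_start, hits$site_end, cohort$map)
  length_filter(seg, min_cM)
}

#' Label candidate segments against planted truth
#'
#' For every candidate, computes the fraction of its sites covered by the
#' union of planted/transmitted truth segments of the same (unordered)
#' individual pair, and classifies it true IBD when that fraction reaches
#' `threshold`.
#'
#' @param candidates Candidate segment table.
#' @param truth Truth segment table (e.g. `simulate_truth()$truth`).
#' @param threshold Overlap threshold for the true label (default 0.8).
#' @return `candidates` with `overlap` and `is_true` columns appended.
#' @export
label_candidates <- function(candidates, truth, threshold = 0.8) {
  if (nrow(candidates) == 0L) {
    return(cbind(candidates, data.frame(overlap = numeric(0),
                                        is_true = logical(0))))
  }
  ck <- pair_key(candidates$id_a, candidates$id_b)
  tk <- pair_key(truth$id_a, truth$id_b)
  overlap <- vapply(seq_len(nrow(candidates)), function(k) {
    rows <- which(tk == ck[k])
    covered_sites(candidates$site_start[k], candidates$site_end[k],
                  truth$site_start[rows], truth$site_end[rows]) /
      candidates$n_sites[k]
  }, numeric(1))
  cbind(candidates, data.frame(overlap = overlap,
                               is_true = classify_true_ibd(overlap, threshold)))
}

#' All scanning pairs of a trio cohort
#'
#' All unordered individual pairs except the within-trio parent-child pairs:
#' a parent and its child genuinely share a full haplotype, so candidate
#' segments are only meaningful between a child and individuals who are not
#' its parents (child-other) and between a parent and individuals who are not
#' its child (parent-other).
#'
#' @param cohort A [phased_cohort()].
#' @param trios A [trio_set()].
#' @return Two-column character matrix of id pairs.
#' @export
scan_pairs <- function(cohort, trios) {
  pairs <- t(utils::combn(cohort$ids, 2L))
  pk <- pair_key(pairs[, 1L], pairs[, 2L])
  drop <- pk %in% c(pair_key(trios$father, trios$child),
                    pair_key(trios$mother, trios$child))
  pairs[!drop, , drop = FALSE]
}

#' End-to-end synthetic IBD scoring experiment
#'
#' Runs the full pipeline on one synthetic cohort: simulate truth, degrade
#' with the configured error rates, detect candidates over all pairs except
#' within-trio parent-child pairs (see [scan_pairs()]), label them against the
#' planted truth, and score them with HaploScore at the configured rates.
#'
#' @param config A [sim_config()].
#' @param truth_threshold Overlap threshold defining true IBD (default 0.8).
#' @return A list with `sim` (the [simulate_truth()] result), `observed` (the
#'   degraded cohort), `candidates` (labelled, scored segment table) and
#'   `rates` (the [error_rates()] used for scoring).
#' @export
simulate_ibd_experiment <- function(config, truth_threshold = 0.8) {
  sim <- simulate_truth(config)
  deg <- degrade(sim$cohort, config$sigma, config$epsilon)
  cand <- detect_candidates(deg$cohort, pairs = scan_pairs(deg$cohort, sim$trios))
  cand <- label_candidates(cand, sim$truth, truth_threshold)
  rates <- error_rates(max(config$epsilon, 1e-6), max(config$sigma, 1e-6))
  cand <- haploscore_batch(deg$cohort, cand, rates)
  list(sim = sim, observed = deg$cohort, candidates = cand, rates = rates)
}

#' Replicated robustness study of HaploScore over the sigma grid
#'
#' Runs `n_replicates` independent synthetic experiments (seeds `seed`,
#' `seed + 1`, ...), restricts each to candidates longer than `min_cM`,
#' re-scores every candidate at each switch-error rate of a logarithmic grid
#' from `epsilon/100` to `10 * epsilon` (`epsilon` fixed), and computes the
#' AUC at each grid point over the pooled candidates. Pooling replicate
#' cohorts sharpens the Monte Carlo precision of the worst-case-drop
#' statistic, whose single-cohort value is a noisy maximum over the grid:
#' with only tens of false candidates per cohort the endpoint AUCs carry
#' sampling noise of about +/- 0.01, which inflates the observed maximum
#' drop.
#'
#' @param seed Base RNG seed; replicate r uses `seed + r - 1`.
#' @param n_replicates Number of independent cohorts (default 30).
#' @param min_cM Restrict to candidates longer than this (default 3, the
#'   length range where the score is a reliable classifier).
#' @param config_fn Function mapping a seed to a [sim_config()] (default:
#'   the shipped defaults).
#' @param n_sigma Number of grid points (default 25).
#' @return A list with `auc_primary` (AUC of the first replicate at the true
#'   rates), `sigma_grid`, `auc` (pooled AUC per grid point), `max_rel_drop`
#'   (fraction) and `n` (pooled candidate count).
#' @export
robustness_study <- function(seed, n_replicates = 30L, min_cM = 3,
                             config_fn = sim_config, n_sigma = 25L) {
  epsilon <- NULL
  sigma_grid <- NULL
  labs <- list()
  scores <- list()
  auc_primary <- NA_real_
  for (r in seq_len(n_replicates)) {
    ex <- simulate_ibd_experiment(config_fn(seed = seed + r - 1L))
    if (is.null(epsilon)) {
      epsilon <- ex$rates$epsilon
      sigma_grid <- 10^seq(log10(epsilon / 100), log10(10 * epsilon),
                           length.out = n_sigma)
    }
    cand <- ex$candidates[!is.na(ex$candidates$haploscore), ]
    sub <- cand[cand$genetic_length_cM > min_cM, ]
    if (r == 1L) auc_primary <- auc_mann_whitney(sub$is_true, sub$haploscore)
    labs[[r]] <- sub$is_true
    sc <- matrix(NA_real_, nrow(sub), length(sigma_grid))
    for (j in seq_along(sigma_grid)) {
      sc[, j] <- haploscore_batch(ex$observed, sub,
                                  error_rates(epsilon, sigma_grid[j]))$haploscore
    }
    scores[[r]] <- sc
  }
  labels <- unlist(labs)
  auc <- vapply(seq_along(sigma_grid), function(j)
    auc_mann_whitney(labels, unlist(lapply(scores, function(m) m[, j]))),
    numeric(1))
  list(auc_primary = auc_primary, sigma_grid = sigma_grid, auc = auc,
       max_rel_drop = (max(auc) - min(auc)) / max(auc), n = length(labels))
}
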