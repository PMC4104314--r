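test_that("simulation is bit-identical under a fixed seed", {
  cfg <- small_sim_config(seed = 77)
  s1 <- simulate_truth(cfg)
  s2 <- simulate_truth(cfg)
  expect_identical(s1$cohort$hap1, s2$cohort$hap1)
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$lures, s2$lures)
  expect_error(sim_config(), "seed is mandatory")
})

test_that("with zero crossovers children carry verbatim parental haplotypes", {
  cfg <- small_sim_config(seed = 31, recomb_scale = 0)
  sim <- simulate_truth(cfg)
  co <- sim$cohort
  for (t in 1:2) {
    trio <- sim$trios[t, ]
    pat <- co$hap1[, trio$child]
    expect_true(identical(pat, co$hap1[, trio$father]) ||
                  identical(pat, co$hap2[, trio$father]))
    mat <- co$hap2[, trio$child]
    expect_true(identical(mat, co$hap1[, trio$mother]) ||
                  identical(mat, co$hap2[, trio$mother]))
  }
})

test_that("planted segments score zero on the truth haplotypes", {
  sim <- simulate_truth(small_sim_config(seed = 5))
  planted <- sim$truth[sim$truth$type == "planted", ]
  sc <- haploscore_batch(sim$cohort, planted[1:10, ], error_rates())
  expect_true(all(sc$haploscore == 0))
  # transmitted child copies are exact too
  trans <- sim$truth[sim$truth$type == "transmitted", ]
  if (nrow(trans)) {
    sct <- haploscore_batch(sim$cohort, utils::head(trans, 5), error_rates())
    expect_true(all(sct$haploscore == 0))
  }
})

test_that("degrade with zero rates is the identity and logs are exact", {
  sim <- simulate_truth(small_sim_config(seed = 6))
  d0 <- degrade(sim$cohort, sigma = 0, epsilon = 0)
  expect_identical(d0$cohort$hap1, sim$cohort$hap1)
  expect_identical(d0$cohort$hap2, sim$cohort$hap2)
  expect_equal(nrow(d0$switch_log), 0L)

  d <- degrade(sim$cohort, sigma = 0.01, epsilon = 0, seed = 8)
  # replaying the logged switches reconstructs the degraded haplotypes
  id <- sim$cohort$ids[3]
  sw <- sort(d$switch_log$site[d$switch_log$id == id])
  n <- length(sim$cohort$map$bp)
  parity <- cumsum(tabulate(sw, nbins = n)) %% 2 == 1
  h1 <- ifelse(parity, sim$cohort$hap2[, id], sim$cohort$hap1[, id])
  expect_identical(as.integer(h1), d$cohort$hap1[, id])
})

test_that("a planted segment spanning injected switches needs only those switches", {
  sim <- simulate_truth(small_sim_config(seed = 9))
  d <- degrade(sim$cohort, sigma = 0.003, epsilon = 0, seed = 10)
  planted <- sim$truth[sim$truth$type == "planted", ]
  sc <- haploscore_batch(d$cohort, planted, error_rates())
  for (k in seq_len(nrow(planted))) {
    ids <- c(planted$id_a[k], planted$id_b[k])
    inside <- sum(d$switch_log$id %in% ids &
                    d$switch_log$site > planted$site_start[k] &
                    d$switch_log$site <= planted$site_end[k])
    # the injected switches always reconcile the segment, so the optimal
    # reconciliation can never need more switches or cost more than that
    expect_lte(sc$n_s[k], inside)
    expect_lte(sc$haploscore[k], inside / (0.003 * planted$n_sites[k]) + 1e-12)
  }
})

test_that("detection recovers a verbatim shared haplotype and splits on budget", {
  set.seed(23)
  L <- 3000
  map <- site_map("t", seq_len(L) * 3000, seq_len(L) * 0.003)  # 9 cM
  shared <- rbinom(L, 1, .5)
  mk <- function() rbinom(L, 1, .5)
  a1 <- mk(); a2 <- mk(); b1 <- mk(); b2 <- mk()
  a1[1001:3000] <- shared[1001:3000]   # ~6 cM shared stretch
  b2[1001:3000] <- shared[1001:3000]
  co <- tiny_cohort(list(a = list(a1, a2), b = list(b1, b2)), map)
  cand <- detect_candidates(co, min_cM = 2)
  expect_equal(nrow(cand), 1L)
  expect_lte(cand$site_start, 1001)
  expect_gte(cand$site_end, 3000)

  # an opposite homozygote inside the stretch with the budget exhausted
  # splits the match
  a1[2000] <- 0; a2[2000] <- 0; b1[2000] <- 1; b2[2000] <- 1
  co2 <- tiny_cohort(list(a = list(a1, a2), b = list(b1, b2)), map)
  cand2 <- detect_candidates(co2, max_hom_err = 0, min_cM = 1)
  expect_gte(nrow(cand2), 2L)
  expect_true(all(cand2$site_start != 2000 & cand2$site_end != 2000))
})

test_that("seed windows between unrelated individuals match a direct scan", {
  set.seed(24)
  L <- 200
  map <- tiny_map(L, spacing_cM = 0.001)
  a1 <- rbinom(L, 1, .5); a2 <- rbinom(L, 1, .5)
  b1 <- rbinom(L, 1, .5); b2 <- rbinom(L, 1, .5)
  co <- tiny_cohort(list(a = list(a1, a2), b = list(b1, b2)), map)
  cand <- detect_candidates(co, window_sites = 10L, max_hom_err = 0L,
                            min_cM = 0)
  # direct window scan for exact haplotype-pair matches
  seeds <- vapply(seq(1, L - 9, by = 10), function(s) {
    w <- s:(s + 9)
    any(all(a1[w] == b1[w]), all(a1[w] == b2[w]),
        all(a2[w] == b1[w]), all(a2[w] == b2[w]))
  }, logical(1))
  if (!any(seeds)) {
    expect_equal(nrow(cand), 0L)
  } else {
    # every seeded window is inside some candidate
    starts <- seq(1, L - 9, by = 10)[seeds]
    for (s in starts) {
      expect_true(any(cand$site_start <= s & cand$site_end >= s + 9))
    }
  }
})

test_that("default-config cohorts separate planted from lure candidates", {
  ex <- simulate_ibd_experiment(small_sim_config(seed = 40))
  cand <- ex$candidates
  expect_gt(sum(cand$is_true), 5)
  expect_gt(sum(!cand$is_true), 5)
  expect_lt(median(cand$haploscore[cand$is_true]),
            median(cand$haploscore[!cand$is_true]))
})

test_that("planted truth segments are recovered as true candidates", {
  ex <- simulate_ibd_experiment(small_sim_config(seed = 41))
  truth <- ex$sim$truth
  cand <- ex$candidates
  tk <- paste(pmin(truth$id_a, truth$id_b), pmax(truth$id_a, truth$id_b))
  ck <- paste(pmin(cand$id_a, cand$id_b), pmax(cand$id_a, cand$id_b))
  union_cover <- function(s0, s1, starts, ends) {
    if (!length(starts)) return(0)
    covered <- rep(FALSE, s1 - s0 + 1L)
    for (j in seq_along(starts)) {
      lo <- max(starts[j], s0); hi <- min(ends[j], s1)
      if (lo <= hi) covered[(lo - s0 + 1L):(hi - s0 + 1L)] <- TRUE
    }
    mean(covered)
  }
  big <- which(truth$genetic_length_cM >= 3)
  detected <- vapply(big, function(k) {
    rows <- which(ck == tk[k])
    any(cand$site_start[rows] <= truth$site_end[k] &
          cand$site_end[rows] >= truth$site_start[k])
  }, logical(1))
  # the permissive matcher finds most planted structure above 3 cM ...
  expect_gte(mean(detected), 0.7)
  # ... and candidates arising from planted truth are labelled true (only
  # segment-edge erosion is tolerated, never a false label)
  hit_rows <- unlist(lapply(big, function(k)
    which(ck == tk[k] & cand$site_start <= truth$site_end[k] &
            cand$site_end >= truth$site_start[k])))
  expect_gte(mean(cand$is_true[unique(hit_rows)]), 0.95)
  # most of each detected truth interval is covered by its true candidates
  coverage <- vapply(big[detected], function(k) {
    rows <- which(ck == tk[k] & cand$is_true)
    union_cover(truth$site_start[k], truth$site_end[k],
                cand$site_start[rows], cand$site_end[rows])
  }, numeric(1))
  expect_gte(mean(coverage), 0.8)
})
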