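rates_default <- error_rates()

test_that("a perfectly matching haplotype pair scores zero", {
  set.seed(1)
  L <- 10
  shared <- rbinom(L, 1, 0.5)
  co <- tiny_cohort(list(a = list(shared, rbinom(L, 1, 0.5)),
                         b = list(shared, rbinom(L, 1, 0.5))))
  hs <- haploscore(co, whole_segment(co), rates_default)
  expect_equal(hs$haploscore, 0)
  expect_equal(hs$n_g, 0L)
  expect_equal(hs$n_s, 0L)
})

test_that("a site mismatching in every configuration costs one genotyping error", {
  set.seed(2)
  L <- 10
  shared <- rbinom(L, 1, 0.5)
  a2 <- rbinom(L, 1, 0.5); b2 <- rbinom(L, 1, 0.5)
  a1 <- shared; b1 <- shared
  # site 5: a homozygous 0, b homozygous 1 -> all four configurations mismatch
  a1[5] <- 0; a2[5] <- 0; b1[5] <- 1; b2[5] <- 1
  # keep other configurations from accidentally matching everywhere
  co <- tiny_cohort(list(a = list(a1, a2), b = list(b1, b2)))
  hs <- haploscore(co, whole_segment(co), rates_default)
  expect_equal(hs$n_g, 1L)
  expect_equal(hs$n_s, 0L)
  expect_equal(hs$haploscore, 1 / (10 * 0.0075), tolerance = 1e-12)
  bf <- haploscore_bruteforce(co, whole_segment(co), rates_default)
  expect_equal(hs$haploscore, bf$haploscore)
})

test_that("a mid-segment haplotype switch costs one switch error", {
  L <- 10
  b1 <- c(1, 0, 1, 1, 0, 0, 1, 0, 1, 1)
  half <- 1:5
  a1 <- 1 - b1; a1[half] <- b1[half]          # matches b1 on first half
  a2 <- b1; a2[half] <- 1 - b1[half]          # matches b1 on second half
  b2 <- 1 - b1                                # matches nothing a1/a2 match
  co <- tiny_cohort(list(a = list(a1, a2), b = list(b1, b2)))
  hs <- haploscore(co, whole_segment(co), rates_default, keep_path = TRUE)
  expect_equal(hs$n_g, 0L)
  expect_equal(hs$n_s, 1L)
  expect_equal(hs$haploscore, 1 / (L * 0.003), tolerance = 1e-12)
  bf <- haploscore_bruteforce(co, whole_segment(co), rates_default)
  expect_equal(hs$haploscore, bf$haploscore)
  # path changes configuration exactly once
  expect_equal(sum(diff(hs$path) != 0), 1)
})

test_that("dynamic program equals exhaustive enumeration on random instances", {
  set.seed(33)
  for (k in 1:400) {
    L <- sample(1:8, 1)
    co <- random_pair_cohort(L, miss = 0.15)
    r <- error_rates(runif(1, 1e-3, 0.9), runif(1, 1e-3, 0.9))
    seg <- whole_segment(co)
    dp <- haploscore(co, seg, r)
    bf <- haploscore_bruteforce(co, seg, r)
    expect_identical(c(dp$n_g, dp$n_s), c(bf$n_g, bf$n_s))
    expect_equal(dp$haploscore, bf$haploscore, tolerance = 1e-12)
  }
})

test_that("score is symmetric in individuals and haplotype labels", {
  set.seed(4)
  for (k in 1:20) {
    co <- random_pair_cohort(30, miss = 0.1)
    seg <- whole_segment(co)
    hs_ab <- haploscore(co, seg, rates_default)$haploscore
    swapped <- ibd_segments("b", "a", 1, 30, co$map)
    expect_equal(haploscore(co, swapped, rates_default)$haploscore, hs_ab)
    # swapping one individual's haplotype labels over the whole segment is free
    co2 <- phased_cohort(co$ids,
                         cbind(a = co$hap2[, "a"], b = co$hap1[, "b"]),
                         cbind(a = co$hap1[, "a"], b = co$hap2[, "b"]),
                         co$map)
    expect_equal(haploscore(co2, seg, rates_default)$haploscore, hs_ab)
  }
})

test_that("scaling both rates by c divides scores by c and preserves ranking", {
  set.seed(5)
  cohorts <- replicate(15, random_pair_cohort(40), simplify = FALSE)
  base <- vapply(cohorts, function(co)
    haploscore(co, whole_segment(co), error_rates(0.0075, 0.003))$haploscore,
    numeric(1))
  for (c_ in c(0.1, 10)) {
    scaled <- vapply(cohorts, function(co)
      haploscore(co, whole_segment(co),
                 error_rates(0.0075 * c_, 0.003 * c_))$haploscore, numeric(1))
    expect_equal(scaled, base / c_, tolerance = 1e-12)
    expect_identical(order(scaled), order(base))
  }
})

test_that("flipping one allele of a perfect match never decreases the score", {
  set.seed(6)
  L <- 20
  shared <- rbinom(L, 1, 0.5)
  for (k in 1:20) {
    a2 <- rbinom(L, 1, 0.5); b2 <- rbinom(L, 1, 0.5)
    co <- tiny_cohort(list(a = list(shared, a2), b = list(shared, b2)))
    s0 <- haploscore(co, whole_segment(co), rates_default)$haploscore
    i <- sample(L, 1)
    a1_flip <- shared; a1_flip[i] <- 1 - a1_flip[i]
    co2 <- tiny_cohort(list(a = list(a1_flip, a2), b = list(shared, b2)))
    expect_gte(haploscore(co2, whole_segment(co2), rates_default)$haploscore, s0)
    expect_equal(s0, 0)
  }
})

test_that("cost ties are broken toward fewer switch errors", {
  # one isolated mismatch, reconcilable by one genotyping error or by a
  # switch-in/switch-out pair; with 1/eps == 2/sigma both cost the same
  b1 <- c(1, 0, 1, 0, 1)
  a1 <- b1; a1[3] <- 1 - b1[3]
  a2 <- 1 - a1; a2[3] <- b1[3]
  b2 <- 1 - b1
  co <- tiny_cohort(list(a = list(a1, a2), b = list(b1, b2)))
  r <- error_rates(epsilon = 0.1, sigma = 0.2)   # 1/eps = 10 = 2/sigma
  hs <- haploscore(co, whole_segment(co), r)
  bf <- haploscore_bruteforce(co, whole_segment(co), r)
  expect_equal(hs$n_s, 0L)
  expect_equal(hs$n_g, 1L)
  expect_identical(c(bf$n_g, bf$n_s), c(hs$n_g, hs$n_s))
})

test_that("missing alleles carry no node cost", {
  co <- tiny_cohort(list(a = list(rep(NA_integer_, 6), rep(NA_integer_, 6)),
                         b = list(rbinom(6, 1, .5), rbinom(6, 1, .5))))
  hs <- haploscore(co, whole_segment(co), rates_default)
  expect_equal(hs$haploscore, 0)
})

test_that("degenerate inputs are rejected", {
  co <- random_pair_cohort(5)
  seg <- whole_segment(co)
  expect_error(haploscore(co, seg, list(epsilon = 0, sigma = 0.1)),
               "error_rates|\\(0, 1\\)")
  bad <- seg; bad$site_end <- 0L
  expect_error(haploscore(co, bad, rates_default), "invalid segment")
  expect_error(haploscore_bruteforce(random_pair_cohort(12),
                                     whole_segment(random_pair_cohort(12))),
               "limited")
})

test_that("batch scoring matches single scoring and flags above-threshold", {
  set.seed(7)
  map <- tiny_map(60)
  co <- random_pair_cohort(60, miss = 0.05, map = map)
  segs <- ibd_segments(rep("a", 8), rep("b", 8),
                       seq(1, 36, by = 5), seq(20, 55, by = 5), map)
  out <- haploscore_batch(co, segs, rates_default)
  single <- vapply(seq_len(nrow(segs)), function(k)
    haploscore(co, segs[k, ], rates_default)$haploscore, numeric(1))
  expect_equal(out$haploscore, single)
  expect_false(any(out$above_threshold))

  # early termination never misclassifies relative to max_score
  thr <- stats::median(single)
  capped <- haploscore_batch(co, segs, rates_default, max_score = thr)
  expect_identical(capped$above_threshold, single > thr)
  expect_equal(capped$haploscore[!capped$above_threshold],
               single[single <= thr])
  expect_true(all(is.na(capped$haploscore[capped$above_threshold])))

  empty <- haploscore_batch(co, segs[0, ], rates_default)
  expect_equal(nrow(empty), 0L)
})

test_that("the DP performs exactly 16 predecessor comparisons per site level", {
  for (L in c(2, 5, 37)) {
    co <- random_pair_cohort(L)
    hs <- haploscore(co, whole_segment(co), rates_default)
    expect_equal(hs$comparisons, 16 * (L - 1))
  }
  # a single-site segment has no transition level
  co1 <- random_pair_cohort(1)
  expect_equal(haploscore(co1, whole_segment(co1), rates_default)$comparisons, 0)
})
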