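test_that("trio phasing resolves Mendelian-determined sites and flags the rest", {
  co <- tiny_cohort(list(
    f = list(c(0, 0, 0, 1, NA), c(0, 1, 0, 1, NA)),
    m = list(c(1, 0, 0, 0, 0), c(1, 1, 0, 1, 1)),
    c = list(c(0, 0, 1, 1, 0), c(1, 1, 0, 0, 1))))
  ph <- trio_phase(co, list(father = "f", mother = "m", child = "c"))
  # site 1: father hom0, mother hom1, child het -> paternal 0 / maternal 1
  expect_equal(ph$status[1], "resolved")
  expect_equal(ph$paternal[1], 0L)
  expect_equal(ph$maternal[1], 1L)
  # site 2: all three heterozygous -> ambiguous, haplotypes passed through
  expect_equal(ph$status[2], "ambiguous")
  expect_equal(ph$paternal[2], unname(co$hap1[2, "c"]))
  # site 3: father hom0, mother hom0, child het -> Mendelian inconsistency
  expect_equal(ph$status[3], "inconsistent")
  # site 4: child het, father hom1 -> paternal 1 / maternal 0
  expect_equal(ph$status[4], "resolved")
  expect_equal(ph$paternal[4], 1L)
  # site 5: missing father is uninformative; mother het, child het -> ambiguous
  expect_equal(ph$status[5], "ambiguous")
})

test_that("on error-free trios every site with a homozygous member resolves", {
  sim <- simulate_truth(small_sim_config(seed = 21))
  co <- sim$cohort
  for (t in 1:2) {
    trio <- sim$trios[t, ]
    ph <- trio_phase(co, trio)
    dF <- genotype_dosage(co)[, trio$father]
    dM <- genotype_dosage(co)[, trio$mother]
    dC <- genotype_dosage(co)[, trio$child]
    any_hom <- dF != 1L | dM != 1L | dC != 1L
    expect_true(all(ph$status[any_hom] == "resolved"))
    expect_true(all(ph$status[!any_hom] == "ambiguous"))
    # resolved paternal alleles are transmittable by the father
    het <- dC == 1L & any_hom
    expect_true(all(abs(2 * ph$paternal[het] - dF[het]) <= 1))
  }
})

test_that("opposite homozygote counts match a naive site loop", {
  set.seed(9)
  co <- random_pair_cohort(80, miss = 0.1)
  naive <- sum(vapply(10:60, function(s) {
    ga <- genotype_class(co, "a", s); gb <- genotype_class(co, "b", s)
    (ga == "hom_ref" && gb == "hom_alt") || (ga == "hom_alt" && gb == "hom_ref")
  }, logical(1)))
  expect_equal(count_opposite_homozygotes(co, "a", "b", 10, 60), naive)
  shared <- rbinom(5, 1, .5)
  co2 <- tiny_cohort(list(a = list(shared, shared), b = list(shared, shared)))
  expect_equal(count_opposite_homozygotes(co2, "a", "b", 1, 5), 0L)
})

test_that("false-negative probability follows (1 - accuracy)^n", {
  expect_equal(false_negative_probability(0), 1.0)
  expect_equal(false_negative_probability(1), 0.05)
  expect_equal(false_negative_probability(3), 1.25e-4)
  expect_equal(false_negative_probability(2, site_accuracy = 0.9), 0.01)
  expect_error(false_negative_probability(-1), "non-negative")
  expect_error(false_negative_probability(1, 1), "\\(0, 1\\)")
})

test_that("segment overlap takes the best parent and flags truncation", {
  map <- tiny_map(100)
  child_seg <- ibd_segments("ch", "ot", 1, 100, map)
  full <- ibd_segments("fa", "ot", 1, 100, map)
  r <- segment_overlap(child_seg, "ch", "fa", "mo", full)
  expect_equal(r$overlap, 1.0)
  expect_equal(r$best_parent, "father")
  expect_false(r$trunc_left || r$trunc_right)

  none <- full[0, ]
  r0 <- segment_overlap(child_seg, "ch", "fa", "mo", none)
  expect_equal(r0$overlap, 0.0)
  expect_equal(r0$best_parent, "none")

  part <- ibd_segments("mo", "ot", 1, 60, map)
  rp <- segment_overlap(child_seg, "ch", "fa", "mo", part)
  expect_equal(rp$overlap, 0.6)
  expect_equal(rp$best_parent, "mother")
  expect_false(rp$trunc_left)
  expect_true(rp$trunc_right)

  # adding parent segments never decreases overlap
  more <- rbind(part, ibd_segments("mo", "ot", 80, 100, map))
  expect_gte(segment_overlap(child_seg, "ch", "fa", "mo", more)$overlap,
             rp$overlap)

  wrong <- ibd_segments("fa", "xx", 1, 10, map)
  expect_error(segment_overlap(child_seg, "ch", "fa", "mo", wrong),
               "other individual")
})

test_that("true-IBD classification uses an inclusive 80% boundary", {
  expect_true(classify_true_ibd(0.85))
  expect_true(classify_true_ibd(0.8))
  expect_false(classify_true_ibd(0.79))
  expect_identical(classify_true_ibd(c(0.9, 0.1), threshold = 0.5),
                   c(TRUE, FALSE))
  expect_error(classify_true_ibd(0.5, threshold = 0), "\\(0, 1\\]")
  expect_error(classify_true_ibd(1.2), "\\[0, 1\\]")
})

test_that("window match criteria separate diplotype and haplotype matching", {
  set.seed(10)
  L <- 100
  shared <- rbinom(L, 1, .5)
  co <- tiny_cohort(list(a = list(shared, rbinom(L, 1, .5)),
                         b = list(shared, rbinom(L, 1, .5))),
                    map = tiny_map(L))
  m <- window_match_classify(co, "a", "b", 1)
  expect_true(m$diplotype_match)
  expect_true(m$haplotype_match)

  # 3 opposite-homozygote sites exceed the err_hom 2 allowance
  a1 <- shared; a2 <- shared; b1 <- shared; b2 <- shared
  a1[1:3] <- 0; a2[1:3] <- 0; b1[1:3] <- 1; b2[1:3] <- 1
  co2 <- tiny_cohort(list(a = list(a1, a2), b = list(b1, b2)),
                     map = tiny_map(L))
  m2 <- window_match_classify(co2, "a", "b", 1)
  expect_false(m2$diplotype_match)

  # diplotype-compatible window with a mid-window haplotype switch:
  # b carries the shared haplotype on hap1 first, hap2 after site 50
  b1 <- shared; b2 <- 1 - shared
  b1[51:100] <- 1 - shared[51:100]; b2[51:100] <- shared[51:100]
  co3 <- tiny_cohort(list(a = list(shared, 1 - shared), b = list(b1, b2)),
                     map = tiny_map(L))
  m3 <- window_match_classify(co3, "a", "b", 1)
  expect_true(m3$diplotype_match)   # genotypes identical, no opposite homs
  expect_false(m3$haplotype_match)

  expect_error(window_match_classify(co3, "a", "b", 50), "fit inside")
})

test_that("window tables conserve counts and fill the expected cells", {
  empty <- tabulate_window_matches(
    random_pair_cohort(100), trio_set("f", "m", "c"),
    empty_child <- ibd_segments("c", "o", 1, 100, tiny_map(100))[0, ],
    empty_child)
  expect_true(all(empty$contained == 0L) && all(empty$not_contained == 0L))

  # one perfect trio-shared segment: all windows contained, child and parent
  # both match on haplotype and diplotype
  L <- 300
  shared <- rbinom(L, 1, .5)
  co <- tiny_cohort(list(
    f = list(shared, rbinom(L, 1, .5)),
    m = list(rbinom(L, 1, .5), rbinom(L, 1, .5)),
    c = list(shared, rbinom(L, 1, .5)),
    o = list(shared, rbinom(L, 1, .5))), map = tiny_map(L))
  trios <- trio_set("f", "m", "c", co)
  child_seg <- ibd_segments("c", "o", 1, L, co$map)
  parent_seg <- ibd_segments("f", "o", 1, L, co$map)
  tabs <- tabulate_window_matches(co, trios, child_seg, parent_seg)
  expect_equal(sum(tabs$contained) + sum(tabs$not_contained), 3L)  # 3 windows
  expect_equal(tabs$contained["both", "both"], 3L)
})

test_that("relationship classification follows the IBD-sharing rules", {
  expect_equal(classify_relationship(0.99, 0.01), "parent_child")
  expect_equal(classify_relationship(0.05, 0.0), "unrelated_pairable")
  expect_equal(classify_relationship(0.5, 0.3), "other")
  expect_equal(classify_relationship(0.85, 0.10), "parent_child")  # boundaries
  expect_equal(classify_relationship(0.20, 0.0), "unrelated_pairable")
  expect_error(classify_relationship(1.5, 0), "\\[0, 1\\]")
})
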