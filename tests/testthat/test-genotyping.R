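test_that("band patterns map to the published genotypes", {
  hae <- fixture_assays()$rs713598
  call1 <- function(frags, uncut = TRUE) {
    call_snp_genotype(hae, observed_bands("s1", "HaeIII", frags,
                                          includes_uncut_lane = uncut))
  }
  expect_identical(call1(203)$genotype, "G/G")
  expect_identical(call1(c(47, 156))$genotype, "C/C")
  expect_identical(call1(c(203, 156, 47))$genotype, "C/G")
  expect_identical(call1(c(47, 156))$confidence, "exact")
  # within tolerance: tolerant confidence
  tol <- call1(c(205, 158, 49))
  expect_identical(tol$genotype, "C/G")
  expect_identical(tol$confidence, "tolerant")
  # outside tolerance: no-call
  expect_identical(call1(c(100))$confidence, "no-call")
  expect_identical(call1(c(100))$genotype, NA_character_)
  # enzyme mismatch is an error, not a silent no-call
  expect_error(
    call_snp_genotype(hae, observed_bands("s1", "RsaI", 203)),
    "digested with")
})

test_that("sub-floor fragments may go unobserved when an uncut lane disambiguates", {
  hae <- fixture_assays()$rs713598
  # with a 50 bp gel floor, the 47 bp fragment may escape detection (the
  # reference protocol eluted it separately rather than scoring it)
  dropped <- call_snp_genotype(hae, observed_bands("s1", "HaeIII", c(203, 156)),
                               detect_floor = 50L)
  expect_identical(dropped$genotype, "C/G")
  expect_identical(dropped$confidence, "tolerant")
  # cut homozygote missing the 47 bp band: {156}
  dropped <- call_snp_genotype(hae, observed_bands("s1", "HaeIII", 156),
                               detect_floor = 50L)
  expect_identical(dropped$genotype, "C/C")
  expect_identical(dropped$confidence, "tolerant")
  # without the uncut control lane the reduced pattern is not accepted
  no_lane <- call_snp_genotype(
    hae, observed_bands("s1", "HaeIII", c(203, 156),
                        includes_uncut_lane = FALSE), detect_floor = 50L)
  expect_identical(no_lane$confidence, "no-call")
  # at the default 40 bp floor, 47 bp is considered observable: no-call
  strict <- call_snp_genotype(hae, observed_bands("s1", "HaeIII", c(203, 156)))
  expect_identical(strict$confidence, "no-call")
})

test_that("diplotypes phase deterministically under the two-haplotype model", {
  expect_identical(call_diplotype("C/C", "C/C", "G/G")$haplotypes,
                   c("PAV", "PAV"))
  expect_identical(call_diplotype("G/G", "T/T", "A/A")$haplotypes,
                   c("AVI", "AVI"))
  trip <- call_diplotype("C/G", "C/T", "A/G")
  expect_identical(sort(trip$haplotypes), c("AVI", "PAV"))
  expect_true(trip$canonical)
  # single-het and double-het combinations consistent with {PAV, AVI}
  expect_true(call_diplotype("C/G", "C/T", "A/G")$canonical)
  # combination requiring a third haplotype: flagged, never coerced
  odd <- call_diplotype("C/C", "C/T", "G/G")
  expect_false(odd$canonical)
  expect_identical(odd$status, "non-canonical")
  expect_true("PAV" %in% odd$haplotypes)
  expect_true("PVV" %in% odd$haplotypes)   # C145 + T785 + G886
  # any no-call input -> undetermined
  nc <- structure(list(snp_id = "rs713598", genotype = NA_character_,
                       confidence = "no-call", candidates = character(0),
                       evidence = integer(0)), class = "genotype_call")
  expect_identical(call_diplotype(nc, "C/C", "G/G")$status, "undetermined")
})

test_that("taster classification and the CA6 annotation", {
  expect_identical(classify_taster("PAV/PAV")$taster_class, "super")
  expect_identical(classify_taster("AVI/AVI")$taster_class, "non-taster")
  med <- classify_taster("PAV/AVI", ca6_genotype = "AA")
  expect_identical(med$taster_class, "medium")  # base class never overridden
  expect_match(med$annotation, "super-compatible")
  expect_identical(classify_taster("PAV/AVI", "GG")$annotation, "")
  expect_identical(classify_taster("PAV/PAV", "AA")$annotation, "")
  expect_identical(classify_taster(call_diplotype("C/C", "C/T", "G/G"))$taster_class,
                   "undetermined")
  expect_error(classify_taster("PAV/AVI", "AT"), "must be")
})

test_that("allele frequencies count alleles, not subjects", {
  af <- allele_frequencies(c("C/C", "C/G"))
  expect_equal(af$frequencies[["C"]], 0.75)
  expect_equal(af$frequencies[["G"]], 0.25)
  expect_equal(sum(af$frequencies), 1)
  expect_equal(allele_frequencies(c("C/C", "C/C"))$frequencies[["C"]], 1)
  expect_error(allele_frequencies(character(0)), "no genotype")
  # permutation of subject order never changes cohort statistics
  g <- c("C/C", "C/G", "G/G", "C/G", "C/C")
  expect_identical(allele_frequencies(g)$frequencies,
                   allele_frequencies(rev(g))$frequencies)
})

test_that("simulated haplotype frequencies match the binomial oracle", {
  sim <- simulate_cohort(n = 10000, pav_freq = 0.5, seed = 7,
                         designs = fixture_assays())
  af <- allele_frequencies(sim$cohort, "rs713598")
  se <- sqrt(0.5 * 0.5 / (2 * 10000))
  expect_lt(abs(af$frequencies[["C"]] - 0.5), 3 * se)
})

test_that("fisher_exact_2x2 matches enumeration and stats::fisher.test", {
  expect_equal(fisher_exact_2x2(matrix(c(1, 1, 1, 1), 2)), 1.0)
  expect_equal(fisher_exact_2x2(matrix(c(5, 0, 0, 5), 2)), 2 / 252,
               tolerance = 1e-12)
  expect_equal(fisher_exact_2x2(matrix(c(0, 0, 0, 1), 2)), 1.0)
  expect_error(fisher_exact_2x2(matrix(c(-1, 1, 1, 1), 2)), "nonnegative")
  set.seed(3)
  for (i in 1:50) {
    tab <- matrix(sample(0:8, 4, replace = TRUE), 2)
    if (sum(tab) == 0) next
    p <- fisher_exact_2x2(tab)
    expect_equal(p, oracle_fisher_2x2(tab), tolerance = 1e-10)
    expect_equal(p, stats::fisher.test(tab)$p.value, tolerance = 1e-7)
  }
})

test_that("hwe_exact matches the enumeration oracle", {
  expect_equal(hwe_exact(c(1, 0, 0)), 1.0)
  expect_equal(hwe_exact(c(25, 50, 25)), oracle_hwe(25, 50, 25),
               tolerance = 1e-10)
  expect_lt(hwe_exact(c(50, 0, 50)), 1e-10)
  expect_error(hwe_exact(c(-1, 2, 3)), "nonnegative")
  set.seed(4)
  for (i in 1:50) {
    gc <- sample(0:12, 3, replace = TRUE)
    if (sum(gc) == 0) next
    expect_equal(hwe_exact(gc), oracle_hwe(gc[1], gc[2], gc[3]),
                 tolerance = 1e-10)
  }
})

test_that("call_cohort assembles per-sample calls with CA6 annotations", {
  assays <- fixture_assays()
  sim <- simulate_cohort(ratio = c(2, 2, 2), designs = assays, seed = 2,
                         ca6_model = c(super = 1, medium = 1,
                                       `non-taster` = 0))
  calls <- call_cohort(assays, sim$bands,
                       ca6 = sim$cohort[, c("sample_id", "ca6")])
  expect_identical(nrow(calls), 6L)
  expect_identical(calls$diplotype, sim$cohort$diplotype)
  expect_identical(calls$taster_class, sim$cohort$taster_class)
  med <- calls[calls$taster_class == "medium", ]
  expect_true(all(grepl("super-compatible", med$annotation)))
})
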