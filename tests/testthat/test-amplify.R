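catalog <- default_enzyme_catalog()

test_that("published primers bind the fixture template at the printed footprints", {
  tpl <- fixture_template()
  p <- tas2r38_primers()
  b <- find_primer_binding(tpl, p[["1Fmut"]], max_mismatches = 2)
  expect_length(b, 1L)
  expect_identical(b[[1L]]$span, c(98L, 144L))
  expect_identical(b[[1L]]$mismatches$template_pos, 143L)  # engineered G
  expect_true(b[[1L]]$three_prime_terminal_match)
  b <- find_primer_binding(tpl, p[["1R"]], max_mismatches = 0)
  expect_length(b, 1L)
  expect_identical(b[[1L]]$span[[2L]], 300L)
  expect_identical(nrow(b[[1L]]$mismatches), 0L)
  b <- find_primer_binding(tpl, p[["2Fmut"]], max_mismatches = 2)
  expect_identical(b[[1L]]$span, c(739L, 784L))
  expect_identical(b[[1L]]$mismatches$template_pos, c(781L, 783L))
  b <- find_primer_binding(tpl, p[["2Rmut"]], max_mismatches = 2)
  expect_identical(b[[1L]]$span, c(887L, 932L))
  expect_identical(b[[1L]]$mismatches$template_pos, 888L)
})

test_that("binding requires a matching 3'-terminal base", {
  set.seed(5)
  tpl <- random_dna(300)
  fwd_bases <- substr(tpl, 101, 120)
  # mutate the 3'-terminal base: never accepted, regardless of tolerance
  broken <- paste0(substr(fwd_bases, 1, 19),
                   setdiff(c("A", "C", "G", "T"),
                           substr(fwd_bases, 20, 20))[1])
  expect_length(
    find_primer_binding(tpl, primer(broken, "forward"), max_mismatches = 3),
    0L)
  expect_length(
    find_primer_binding(tpl, primer(fwd_bases, "forward"), max_mismatches = 0),
    1L)
  expect_error(find_primer_binding("ACGT", primer(strrep("T", 15), "forward")),
               "longer than template")
})

test_that("simulate_pcr reproduces the two published amplicons with their substitutions", {
  tpl <- fixture_template()
  p <- tas2r38_primers()
  amp1 <- simulate_pcr(tpl, p[["1Fmut"]], p[["1R"]], snps = tas2r38_snps())
  expect_identical(nchar(amp1$bases), 203L)
  expect_identical(amp1$template_span, c(98L, 300L))
  expect_identical(amp1$substitutions$amplicon_pos, 46L)
  expect_identical(amp1$substitutions$template_base, "A")
  expect_identical(amp1$substitutions$product_base, "G")
  expect_identical(amp1$snp_offsets, c(rs713598 = 48L))
  amp2 <- simulate_pcr(tpl, p[["2Fmut"]], p[["2Rmut"]], snps = tas2r38_snps())
  expect_identical(nchar(amp2$bases), 194L)
  expect_identical(amp2$template_span, c(739L, 932L))
  expect_identical(amp2$substitutions$amplicon_pos, c(43L, 45L, 150L))
  expect_identical(amp2$substitutions$product_base, c("A", "C", "A"))
  expect_identical(amp2$snp_offsets,
                   c(rs1726866 = 47L, rs10246939 = 148L))
})

test_that("simulate_pcr errors on divergent, absent or ambiguous products", {
  tpl <- fixture_template()
  p <- tas2r38_primers()
  # reverse primer upstream of forward: no convergent pair
  expect_error(simulate_pcr(tpl, p[["2Fmut"]], p[["1R"]]),
               "no amplification")
  set.seed(31)
  core <- random_dna(60)
  fwd <- substr(core, 1, 20)
  rev_site <- substr(core, 41, 60)
  rev_p <- primer(revcomp(rev_site), "reverse")
  tandem <- paste0(core, random_dna(30), core)  # two products
  expect_error(simulate_pcr(tandem, primer(fwd, "forward"), rev_p,
                            params = pcr_params(size_min = 20)),
               "ambiguous amplification")
})

test_that("amplicon equals template outside primer footprints", {
  set.seed(77)
  for (i in 1:10) {
    tpl <- random_dna(400)
    fstart <- sample(1:100, 1)
    rend <- sample(250:380, 1)
    fwd <- primer(substr(tpl, fstart, fstart + 21), "forward")
    rev <- primer(revcomp(substr(tpl, rend - 21, rend)), "reverse")
    amp <- tryCatch(simulate_pcr(tpl, fwd, rev), error = function(e) NULL)
    if (is.null(amp)) next  # accidental second binding site: skip draw
    expect_identical(amp$bases, substr(tpl, fstart, rend))
    expect_identical(nrow(amp$substitutions), 0L)
  }
})

test_that("amplicon_allele_variants places alleles at the derived offsets", {
  tpl <- fixture_template()
  p <- tas2r38_primers()
  snps <- tas2r38_snps()
  amp1 <- simulate_pcr(tpl, p[["1Fmut"]], p[["1R"]])
  v <- amplicon_allele_variants(amp1, snps$rs713598)
  expect_named(v, c("C", "G"))
  expect_identical(substr(v$C, 48, 48), "C")
  expect_identical(substr(v$G, 48, 48), "G")
  expect_identical(sum(strsplit(v$C, "")[[1]] != strsplit(v$G, "")[[1]]), 1L)
  amp2 <- simulate_pcr(tpl, p[["2Fmut"]], p[["2Rmut"]])
  v <- amplicon_allele_variants(amp2, snps$rs1726866)
  expect_identical(substr(v$C, 47, 47), "C")
  expect_identical(substr(v$T, 47, 47), "T")
  v <- amplicon_allele_variants(amp2, snps$rs10246939)
  expect_identical(substr(v$G, 148, 148), "G")
  expect_identical(substr(v$A, 148, 148), "A")
  # SNP under a primer footprint: genotype information would be erased
  under <- snp_spec("bad", 100L, c("A", "C"))
  expect_error(amplicon_allele_variants(amp1, under), "design violation")
  outside <- snp_spec("out", 500L, c("A", "C"))
  expect_error(amplicon_allele_variants(amp1, outside), "outside")
})
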