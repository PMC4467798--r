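catalog <- default_enzyme_catalog()
snps <- tas2r38_snps()

test_that("site placements over the three SNPs recover the published mutagenesis", {
  tpl <- fixture_template()
  pl <- enumerate_site_placements(tpl, snps$rs713598, catalog$HaeIII)
  hit <- Filter(function(p) identical(p$site_span, c(143L, 146L)), pl)
  expect_length(hit, 1L)
  hit <- hit[[1L]]
  expect_identical(hit$matching_allele, "C")
  expect_identical(hit$required_substitutions$template_pos, 143L)
  expect_identical(hit$required_substitutions$template_base, "A")
  expect_identical(hit$required_substitutions$new_base, "G")
  expect_identical(hit$side, "forward")

  pl <- enumerate_site_placements(tpl, snps$rs1726866, catalog$Eco47III)
  hit <- Filter(function(p) identical(p$site_span, c(781L, 786L)), pl)
  expect_length(hit, 1L)
  hit <- hit[[1L]]
  expect_identical(hit$matching_allele, "C")
  expect_identical(hit$required_substitutions$template_pos, c(781L, 783L))
  expect_identical(hit$required_substitutions$new_base, c("A", "C"))
  expect_identical(hit$side, "forward")

  pl <- enumerate_site_placements(tpl, snps$rs10246939, catalog$RsaI)
  hit <- Filter(function(p) identical(p$site_span, c(886L, 889L)), pl)
  expect_length(hit, 1L)
  hit <- hit[[1L]]
  expect_identical(hit$matching_allele, "G")
  expect_identical(hit$required_substitutions$template_pos, 888L)
  expect_identical(hit$required_substitutions$new_base, "A")
  expect_identical(hit$side, "reverse")
})

test_that("placement enumeration discards non-discriminating or split placements", {
  # site codes never distinguishing A from T at any slot -> empty
  none <- enumerate_site_placements(strrep("ACGT", 50),
                                    snp_spec("x", 100L, c("A", "T")),
                                    enzyme("GGCCx", "GGCC", 2))
  expect_length(none, 0L)
  # every kept placement has all substitutions on one side of the SNP
  set.seed(13)
  for (i in 1:10) {
    tpl <- random_dna(200)
    snp <- snp_spec("s", 100L, sample(c("A", "C", "G", "T"), 2))
    for (enz in catalog) {
      for (p in enumerate_site_placements(tpl, snp, enz)) {
        subs <- p$required_substitutions$template_pos
        expect_false(any(subs == snp$position))
        if (length(subs)) {
          expect_true(all(subs < snp$position) || all(subs > snp$position))
        }
      }
    }
  }
})

test_that("build_primers puts engineered bases at the published 3' offsets", {
  tpl <- fixture_template()
  cons <- tas2r38_constraints()
  pl <- Filter(function(p) identical(p$site_span, c(143L, 146L)),
               enumerate_site_placements(tpl, snps$rs713598, catalog$HaeIII))[[1L]]
  prm <- build_primers(tpl, pl, snps$rs713598, cons)
  expect_identical(prm$fwd$intended_span[[2L]], 144L)   # ends just before SNP
  n <- nchar(prm$fwd$bases)
  expect_identical(substr(prm$fwd$bases, n - 1, n - 1), "G")  # second-last
  expect_identical(substr(tpl, 143, 143), "A")

  pl <- Filter(function(p) identical(p$site_span, c(781L, 786L)),
               enumerate_site_placements(tpl, snps$rs1726866, catalog$Eco47III))[[1L]]
  prm <- build_primers(tpl, pl, snps$rs1726866, cons)
  n <- nchar(prm$fwd$bases)
  expect_identical(substr(prm$fwd$bases, n - 1, n - 1), "C")  # offset 2
  expect_identical(substr(prm$fwd$bases, n - 3, n - 3), "A")  # offset 4

  # a substitution that would sit on the 3'-terminal base is refused
  bad <- pl
  bad$required_substitutions <- data.frame(
    template_pos = snps$rs1726866$position - 1L,
    template_base = substr(tpl, 784, 784), new_base = "A")
  expect_error(build_primers(tpl, bad, snps$rs1726866, cons), "infeasible")
})

test_that("compute_tm: wallace rule and nearest-neighbor vs hand computation", {
  expect_identical(compute_tm("ACGT", "wallace"), 12)
  expect_identical(compute_tm("AAAA", "wallace"), 8)
  expect_error(compute_tm("ACGT", "bogus"))
  # hand NN summation for a fixed 20-mer (SantaLucia 1998 unified table)
  s <- "AGCTTGCATGCCTGCAGGTC"
  dh_tab <- c(AA = -7.9, AT = -7.2, TA = -7.2, CA = -8.5, GT = -8.4,
              CT = -7.8, GA = -8.2, CG = -10.6, GC = -9.8, GG = -8.0)
  ds_tab <- c(AA = -22.2, AT = -20.4, TA = -21.3, CA = -22.7, GT = -22.4,
              CT = -21.0, GA = -22.2, CG = -27.2, GC = -24.4, GG = -19.9)
  canon <- function(d) if (d %in% names(dh_tab)) d else oracle_revcomp(d)
  ch <- strsplit(s, "")[[1]]
  dh <- 0; ds <- 0
  for (i in 1:19) {
    d <- canon(paste0(ch[i], ch[i + 1]))
    dh <- dh + dh_tab[[d]]; ds <- ds + ds_tab[[d]]
  }
  for (b in ch[c(1, 20)]) {
    if (b %in% c("G", "C")) { dh <- dh + 0.1; ds <- ds - 2.8 }
    else { dh <- dh + 2.3; ds <- ds + 4.1 }
  }
  ds <- ds + 0.368 * 19 * log(0.05)
  want <- dh * 1000 / (ds + 1.987 * log(5e-7 / 4)) - 273.15
  expect_lt(abs(compute_tm(s) - want), 0.1)
})

test_that("validate_design passes the published designs and reports fragments", {
  assays <- fixture_assays()
  tpl <- fixture_template()
  cons <- tas2r38_constraints()
  for (a in assays) {
    val <- validate_design(tpl, a, cons)
    expect_true(val$pass, info = a$snp$id)
  }
  expect_identical(assays$rs713598$predicted_fragments[["C/C"]], c(47L, 156L))
  expect_identical(assays$rs10246939$predicted_fragments[["G/G"]], c(45L, 149L))
  expect_identical(assays$rs1726866$predicted_fragments[["C/C"]], c(45L, 149L))
})

test_that("a second native site inside the amplicon fails clause (a) with coordinates", {
  tpl <- fixture_template()
  # inject a native GGCC into the 203-bp amplicon interior (200..203)
  chars <- strsplit(tpl, "")[[1]]
  chars[200:203] <- c("G", "G", "C", "C")
  broken <- paste(chars, collapse = "")
  a <- fixture_assays()$rs713598
  val <- validate_design(broken, a, tas2r38_constraints())
  expect_false(val$pass)
  expect_false(val$clauses$a_cut_allele_single_site$pass)
  # both site coordinates listed: engineered at 46, native at 200-98+1 = 103
  expect_match(val$clauses$a_cut_allele_single_site$detail, "46")
  expect_match(val$clauses$a_cut_allele_single_site$detail, "103")
  expect_false(val$clauses$b_other_allele_no_site$pass)
})

test_that("design_assays is sound: predictions reproduce under simulation", {
  set.seed(23)
  cons <- tas2r38_constraints()
  checked <- 0L
  # random templates whose SNP neighbourhood is free of native catalog
  # sites (as in the reference gene, where no natural site distinguishes
  # the alleles); designs remain rare but occur
  clean_window <- function(n) {
    repeat {
      w <- random_dna(n)
      if (!any(vapply(default_enzyme_catalog(), function(e) {
        nrow(find_sites(w, e)) > 0L
      }, logical(1)))) return(w)
    }
  }
  for (i in 1:12) {
    tpl <- paste0(random_dna(220), clean_window(160), random_dna(220))
    alleles <- sample(c("A", "C", "G", "T"), 2)
    snp <- snp_spec(paste0("rnd", i), 300L, alleles)
    designs <- design_assays(tpl, snp, catalog, cons)
    for (d in designs) {
      amp <- simulate_pcr(tpl, d$fwd, d$rev,
                          pcr_params(max_mismatches =
                                       max(2L, d$n_engineered_mismatches)))
      v <- amplicon_allele_variants(amp, snp)
      hom <- lapply(v, function(s) digest_linear(s, d$enzyme)$fragments)
      for (al in names(hom)) {
        gt <- paste(sort(c(al, al)), collapse = "/")
        expect_identical(sort(d$predicted_fragments[[gt]]), sort(hom[[al]]))
      }
      # allele discrimination, re-checked by simulation
      expect_false(identical(sort(hom[[1L]]), sort(hom[[2L]])))
      # heterozygote is the exact union of the homozygotes
      het <- d$predicted_fragments[[paste(sort(alleles), collapse = "/")]]
      expect_identical(sort(het), sort(c(hom[[1L]], hom[[2L]])))
      checked <- checked + 1L
    }
  }
  expect_gt(checked, 0L)
})

test_that("tightening constraints never enlarges the design set", {
  tpl <- fixture_template()
  key <- function(d) paste(d$enzyme$name, d$placement$site_span[[1L]],
                           d$placement$side)
  for (snp in snps) {
    base <- design_assays(tpl, snp, catalog, tas2r38_constraints())
    tight_mm <- design_assays(tpl, snp, catalog,
                              tas2r38_constraints(max_engineered = 1L))
    tight_fr <- design_assays(tpl, snp, catalog,
                              tas2r38_constraints(min_fragment = 45L))
    expect_true(all(vapply(tight_mm, key, "") %in% vapply(base, key, "")))
    expect_true(all(vapply(tight_fr, key, "") %in% vapply(base, key, "")))
  }
})

test_that("design_assays validates its inputs and ranks deterministically", {
  tpl <- fixture_template()
  expect_error(design_assays(tpl, snps$rs713598, list()), "empty")
  d1 <- design_assays(tpl, snps$rs713598, catalog, tas2r38_constraints())
  d2 <- design_assays(tpl, snps$rs713598, catalog, tas2r38_constraints())
  expect_identical(vapply(d1, function(d) d$enzyme$name, ""),
                   vapply(d2, function(d) d$enzyme$name, ""))
  expect_identical(d1[[1L]]$enzyme$name, "HaeIII")
  expect_identical(d1[[1L]]$n_engineered_mismatches, 1L)
})
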