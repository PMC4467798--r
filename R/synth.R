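# Synthetic fixtures: a TAS2R38-like template reconstructed from the
# published primer footprints and SNP coordinates, and a cohort/band
# simulator. The true GenBank sequence (AY258597/AY258598) is NOT
# transcribed here: every quantity the reference assays predict (amplicon
# sizes 203/194 bp, fragments 47+156, 45+149, 149+45) depends only on the
# primer-pinned spans, the SNP alleles and the absence of stray sites, so
# a constraint-satisfying surrogate is generated instead. Users with the
# real sequence can substitute it anywhere a template is accepted.

TAS2R38_PRIMER_SEQS <- c(
  `1Fmut` = "ATGCCTTCGTTTTCTTGGTGAATTTTTGGGATGTAGTGAAGAGGCGG",
  `1R`    = "CATCCATAGCATGATGATGGCTTGGTA",
  `2Fmut` = "AAGTCTCTTGTCTCCTTTTTCTGCTTCTTTGTGATATCATCCAGCG",
  `2Rmut` = "ATGGTCATCACAGCTCTCCTCAACTTGGCATTGCCTGAGATCAGTA"
)

#' Reference mutagenic primers for the three TAS2R38 SNPs
#'
#' The two published primer pairs: 1Fmut/1R amplify 98..300 (203 bp,
#' covers rs713598); 2Fmut/2Rmut amplify 739..932 (194 bp, covers
#' rs1726866 and rs10246939). 1Fmut carries one engineered G (template A
#' at 143, offset 2 from its 3' end); 2Fmut carries two engineered bases
#' (A at 781 and C at 783, offsets 4 and 2); 2Rmut carries one engineered
#' base (product A at 888 where the template reads C, offset 2).
#'
#' @return named list of four `primer` objects.
#' @export
tas2r38_primers <- function() {
  list(
    `1Fmut` = primer(TAS2R38_PRIMER_SEQS[["1Fmut"]], "forward", "1Fmut",
                     intended_span = c(98L, 144L)),
    `1R`    = primer(TAS2R38_PRIMER_SEQS[["1R"]], "reverse", "1R",
                     intended_span = c(274L, 300L)),
    `2Fmut` = primer(TAS2R38_PRIMER_SEQS[["2Fmut"]], "forward", "2Fmut",
                     intended_span = c(739L, 784L)),
    `2Rmut` = primer(TAS2R38_PRIMER_SEQS[["2Rmut"]], "reverse", "2Rmut",
                     intended_span = c(887L, 932L))
  )
}

#' The three functional TAS2R38 SNPs
#'
#' rs713598 C/G at 145, rs1726866 C/T at 785, rs10246939 G/A at 886
#' (1-based gene coordinates). The first allele listed is the
#' taster-haplotype (PAV) allele, used as the reference allele of the
#' synthetic template.
#'
#' @return named list of three [snp_spec()]s.
#' @export
tas2r38_snps <- function() {
  list(
    rs713598  = snp_spec("rs713598", 145L, c("C", "G"), cut_allele = "C"),
    rs1726866 = snp_spec("rs1726866", 785L, c("C", "T"), cut_allele = "C"),
    rs10246939 = snp_spec("rs10246939", 886L, c("G", "A"), cut_allele = "G")
  )
}

# run code with a private, restorable RNG stream
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Build the synthetic TAS2R38-like reference template
#'
#' Assembles a template in which every published constraint holds:
#' primer footprints carry the genomic (un-engineered) counterparts of the
#' four printed primers — 98..144 is 1Fmut with position 143 reverted to
#' A; 274..300 is the reverse complement of 1R; 739..784 is 2Fmut with 781
#' and 783 reverted to T; 887..932 is the reverse complement of 2Rmut with
#' 888 reverted to C — the SNP positions carry the PAV (reference)
#' alleles, 146 = C and 786 = T complete the engineered sites, and filler
#' bases are rejection-sampled so that, inside either future amplicon and
#' under any allele state, no catalog enzyme finds a site other than the
#' three engineered ones. Motifs outside the amplicons are harmless and
#' allowed. Deterministic for a fixed seed.
#'
#' @param seed RNG seed (default 17).
#' @param length template length in bp (default 1000; must be >= 932).
#' @param catalog enzymes whose motifs are forbidden inside amplicons.
#' @param max_tries rejection-sampling attempts per amplicon interior.
#' @param extra_pins optional list of `list(span = c(start, end),
#'   seq = "...")` additional pinned spans; a pin that contradicts a
#'   built-in pinned base, or that forces a forbidden motif the filler
#'   cannot avoid, raises a generation error naming the clash.
#' @return the template sequence (character scalar).
#' @export
tas2r38_template <- function(seed = 17L, length = 1000L,
                             catalog = default_enzyme_catalog(),
                             max_tries = 200L, extra_pins = NULL) {
  if (length < 932L) stop("template length must be >= 932", call. = FALSE)
  primers <- tas2r38_primers()
  snps <- tas2r38_snps()
  chars <- rep(NA_character_, length)
  pin <- function(span, seq) {
    stopifnot(span[[2L]] - span[[1L]] + 1L == nchar(seq))
    chars[span[[1L]]:span[[2L]]] <<- seq_chars(seq)
  }
  revert <- function(seq, at, base) {
    s <- seq_chars(seq); s[at] <- base; paste(s, collapse = "")
  }
  pin(c(98L, 144L), revert(primers[["1Fmut"]]$bases, 46L, "A"))
  pin(c(274L, 300L), revcomp(primers[["1R"]]$bases))
  pin(c(739L, 784L), revert(revert(primers[["2Fmut"]]$bases, 43L, "T"),
                            45L, "T"))
  pin(c(887L, 932L), revert(revcomp(primers[["2Rmut"]]$bases), 2L, "C"))
  chars[145L] <- "C"; chars[146L] <- "C"
  chars[785L] <- "C"; chars[786L] <- "T"
  chars[886L] <- "G"
  for (pin_spec in extra_pins) {
    span <- as.integer(pin_spec$span)
    pseq <- dna(pin_spec$seq, what = "pinned span")
    if (span[[1L]] < 1L || span[[2L]] > length ||
        span[[2L]] - span[[1L]] + 1L != nchar(pseq)) {
      stop("pinned span ", span[[1L]], "..", span[[2L]],
           " inconsistent with its sequence", call. = FALSE)
    }
    idx <- span[[1L]]:span[[2L]]
    old <- chars[idx]
    new <- seq_chars(pseq)
    clash <- !is.na(old) & old != new
    if (any(clash)) {
      stop("pinned span ", span[[1L]], "..", span[[2L]],
           " clashes with built-in pinned base(s) at position(s) ",
           paste(idx[clash], collapse = ", "), call. = FALSE)
    }
    chars[idx] <- new
  }
  free1 <- which(is.na(chars[98:300])) + 97L    # amplicon-1 interior filler
  free2 <- which(is.na(chars[739:932])) + 738L  # amplicon-2 interior filler
  engineered <- list(
    data.frame(template_pos = 143L, template_base = "A", new_base = "G"),
    data.frame(template_pos = c(781L, 783L, 888L),
               template_base = c("T", "T", "C"),
               new_base = c("A", "C", "A"))
  )
  # allowed site starts (amplicon coordinates) per enzyme per amplicon
  allowed <- list(
    list(span = c(98L, 300L), snps = snps["rs713598"],
         sites = list(HaeIII = 46L)),
    list(span = c(739L, 932L), snps = snps[c("rs1726866", "rs10246939")],
         sites = list(Eco47III = 43L, RsaI = 148L))
  )
  amplicon_clean <- function(region) {
    span <- region$span
    eng <- engineered[[if (span[[1L]] == 98L) 1L else 2L]]
    allele_sets <- expand.grid(lapply(region$snps, function(s) s$alleles),
                               stringsAsFactors = FALSE)
    for (r in seq_len(nrow(allele_sets))) {
      amp <- chars[span[[1L]]:span[[2L]]]
      amp[eng$template_pos - span[[1L]] + 1L] <- eng$new_base
      for (k in seq_along(region$snps)) {
        amp[region$snps[[k]]$position - span[[1L]] + 1L] <-
          allele_sets[r, k]
      }
      ampseq <- paste(amp, collapse = "")
      for (enz_name in names(catalog)) {
        hits <- find_sites(ampseq, catalog[[enz_name]])
        ok_start <- region$sites[[enz_name]]
        extra <- if (is.null(ok_start)) hits$start
                 else setdiff(hits$start, ok_start)
        if (length(extra)) return(FALSE)
      }
    }
    TRUE
  }
  with_seed(seed, {
    for (i in c(1L, 2L)) {
      region <- allowed[[i]]
      free <- if (i == 1L) free1 else free2
      done <- FALSE
      for (try in seq_len(max_tries)) {
        chars[free] <- sample(c("A", "C", "G", "T"), length(free),
                              replace = TRUE)
        if (amplicon_clean(region)) { done <- TRUE; break }
      }
      if (!done) {
        # pinned spans themselves must be clashing
        stop("template generation failed for amplicon ",
             region$span[[1L]], "..", region$span[[2L]],
             ": pinned spans admit a forbidden recognition site that ",
             "filler resampling cannot remove", call. = FALSE)
      }
    }
    outside <- which(is.na(chars))
    chars[outside] <- sample(c("A", "C", "G", "T"), length(outside),
                             replace = TRUE)
  })
  paste(chars, collapse = "")
}

#' Reference assay designs on the synthetic template
#'
#' Convenience wrapper: builds `assay_design` objects for the three SNPs
#' directly from the published primers (not via the automatic designer),
#' validated by simulation on the given template.
#'
#' @param template template sequence (default [tas2r38_template()]).
#' @return named list of three `assay_design`s.
#' @export
tas2r38_reference_assays <- function(template = tas2r38_template()) {
  primers <- tas2r38_primers()
  snps <- tas2r38_snps()
  catalog <- default_enzyme_catalog()
  spec <- list(
    rs713598 = list(enzyme = catalog$HaeIII, fwd = primers[["1Fmut"]],
                    rev = primers[["1R"]], site_span = c(143L, 146L),
                    strand = "+", snp_slot = 3L, side = "forward",
                    subs = data.frame(template_pos = 143L,
                                      template_base = "A", new_base = "G")),
    rs1726866 = list(enzyme = catalog$Eco47III, fwd = primers[["2Fmut"]],
                     rev = primers[["2Rmut"]], site_span = c(781L, 786L),
                     strand = "+", snp_slot = 5L, side = "forward",
                     subs = data.frame(template_pos = c(781L, 783L),
                                       template_base = c("T", "T"),
                                       new_base = c("A", "C"))),
    rs10246939 = list(enzyme = catalog$RsaI, fwd = primers[["2Fmut"]],
                      rev = primers[["2Rmut"]], site_span = c(886L, 889L),
                      strand = "+", snp_slot = 1L, side = "reverse",
                      subs = data.frame(template_pos = 888L,
                                        template_base = "C", new_base = "A"))
  )
  cons <- tas2r38_constraints()
  out <- lapply(names(spec), function(id) {
    s <- spec[[id]]
    snp <- snps[[id]]
    pl <- structure(
      list(enzyme = s$enzyme, site_span = s$site_span, strand = s$strand,
           snp_slot = s$snp_slot, matching_allele = snp$cut_allele,
           required_substitutions = s$subs, side = s$side,
           cut_after_template = s$site_span[[1L]] + s$enzyme$cut_offset - 1L),
      class = "placement")
    dsg <- list(snp = snp, enzyme = s$enzyme, placement = pl,
                fwd = s$fwd, rev = s$rev)
    val <- validate_design(template, dsg, cons)
    if (!val$pass) {
      stop("reference assay for ", id, " failed validation on this template",
           call. = FALSE)
    }
    new_assay_design(
      snp, pl,
      list(fwd = s$fwd, rev = s$rev,
           tm_fwd = compute_tm(s$fwd), tm_rev = compute_tm(s$rev)),
      val)
  })
  names(out) <- names(spec)
  out
}

DIPLOTYPE_CLASSES <- c(`PAV/PAV` = "super", `PAV/AVI` = "medium",
                       `AVI/AVI` = "non-taster")

diplotype_genotypes <- function(diplotype) {
  haps <- strsplit(diplotype, "/", fixed = TRUE)[[1L]]
  hap_alleles <- list(
    PAV = c(rs713598 = "C", rs1726866 = "C", rs10246939 = "G"),
    AVI = c(rs713598 = "G", rs1726866 = "T", rs10246939 = "A")
  )
  vapply(names(HAPLOTYPE_CODE), function(l) {
    paste(sort(c(hap_alleles[[haps[[1L]]]][[l]],
                 hap_alleles[[haps[[2L]]]][[l]])), collapse = "/")
  }, character(1))
}

#' Simulate a genotyped cohort with band patterns
#'
#' Subjects receive PAV/AVI diplotypes either as deterministic class
#' counts (`ratio`, default 20:20:20 super:medium:non-taster, matching the
#' reference study's cohort structure) or by Hardy-Weinberg sampling from
#' a PAV haplotype frequency (`pav_freq`). Genotypes are rendered to band
#' patterns through the designs' digest predictions; optional noise is
#' additive integer jitter on band sizes (`noise_sd`, bp) plus Bernoulli
#' dropout of fragments below `floor` (`dropout` probability) — the
#' simplest model matching gel observables. An optional CA6 co-genotype is
#' drawn per taster class from A-allele frequencies.
#'
#' @param n number of subjects (required with `pav_freq`; with `ratio` it
#'   defaults to `sum(ratio)`).
#' @param ratio integer class counts c(super, medium, non) (exclusive with
#'   `pav_freq`).
#' @param pav_freq PAV haplotype frequency in `[0, 1]`.
#' @param designs list of three `assay_design`s (default: reference assays
#'   on the default synthetic template).
#' @param ca6_model optional named numeric: per-class CA6 A-allele
#'   frequency, names `super`, `medium`, `non-taster`.
#' @param noise_sd band-size jitter SD (bp; default 0).
#' @param dropout sub-floor fragment dropout probability (default 0).
#' @param floor detectability floor for dropout (default 40 bp).
#' @param seed RNG seed.
#' @return list with `cohort` (data.frame: sample_id, diplotype,
#'   taster_class, genotypes per SNP, ca6) and `bands` (data.frame:
#'   sample_id, enzyme, fragments, uncut_lane).
#' @export
simulate_cohort <- function(n = NULL, ratio = c(20L, 20L, 20L),
                            pav_freq = NULL,
                            designs = NULL, ca6_model = NULL,
                            noise_sd = 0, dropout = 0, floor = 40L,
                            seed = 1L) {
  if (is.null(designs)) designs <- tas2r38_reference_assays()
  names(designs) <- vapply(designs, function(d) d$snp$id, character(1))
  if (!all(names(HAPLOTYPE_CODE) %in% names(designs))) {
    stop("designs must cover the three TAS2R38 SNPs", call. = FALSE)
  }
  if (!is.null(pav_freq)) {
    if (pav_freq < 0 || pav_freq > 1) {
      stop("pav_freq must lie in [0, 1]", call. = FALSE)
    }
    if (is.null(n)) stop("n is required with pav_freq", call. = FALSE)
  } else {
    ratio <- as.integer(ratio)
    if (length(ratio) != 3L || any(ratio < 0L)) {
      stop("ratio must be three nonnegative counts", call. = FALSE)
    }
    if (is.null(n)) n <- sum(ratio)
    if (n != sum(ratio)) {
      stop("n (", n, ") inconsistent with ratio total (", sum(ratio), ")",
           call. = FALSE)
    }
  }
  with_seed(seed, {
    diplotypes <- if (!is.null(pav_freq)) {
      haps <- matrix(sample(c("PAV", "AVI"), 2L * n, replace = TRUE,
                            prob = c(pav_freq, 1 - pav_freq)), ncol = 2L)
      apply(haps, 1L, function(h) paste(sort(h, decreasing = TRUE),
                                        collapse = "/"))
    } else {
      rep(names(DIPLOTYPE_CLASSES), times = ratio)
    }
    gt_lookup <- do.call(rbind, lapply(names(DIPLOTYPE_CLASSES), function(d) {
      as.data.frame(as.list(diplotype_genotypes(d)), stringsAsFactors = FALSE)
    }))
    rownames(gt_lookup) <- names(DIPLOTYPE_CLASSES)
    nsub <- length(diplotypes)
    cohort <- data.frame(
      sample_id = sprintf("S%05d", seq_len(nsub)),
      diplotype = diplotypes,
      taster_class = unname(DIPLOTYPE_CLASSES[diplotypes]),
      rs713598 = gt_lookup[diplotypes, "rs713598"],
      rs1726866 = gt_lookup[diplotypes, "rs1726866"],
      rs10246939 = gt_lookup[diplotypes, "rs10246939"],
      stringsAsFactors = FALSE)
    cohort$ca6 <- if (!is.null(ca6_model)) {
      vapply(cohort$taster_class, function(cls) {
        pa <- ca6_model[[cls]]
        if (is.null(pa)) stop("ca6_model missing class ", cls, call. = FALSE)
        paste(sort(sample(c("A", "G"), 2L, replace = TRUE,
                          prob = c(pa, 1 - pa))), collapse = "")
      }, character(1), USE.NAMES = FALSE)
    } else {
      NA_character_
    }
    bands <- do.call(rbind, lapply(names(designs), function(snp_id) {
      d <- designs[[snp_id]]
      gts <- cohort[[snp_id]]
      frag_str <- if (noise_sd > 0 || dropout > 0) {
        vapply(d$predicted_fragments[gts], function(frag) {
          if (noise_sd > 0) {
            frag <- pmax(1L, frag + as.integer(round(
              stats::rnorm(length(frag), 0, noise_sd))))
          }
          if (dropout > 0) {
            drop <- frag < floor & stats::runif(length(frag)) < dropout
            frag <- frag[!drop]
          }
          paste(sort(frag), collapse = ",")
        }, character(1), USE.NAMES = FALSE)
      } else {
        patterns <- vapply(d$predicted_fragments, function(f) {
          paste(sort(f), collapse = ",")
        }, character(1))
        unname(patterns[gts])
      }
      data.frame(sample_id = cohort$sample_id, enzyme = d$enzyme$name,
                 fragments = frag_str, uncut_lane = 1L,
                 stringsAsFactors = FALSE)
    }))
    bands <- bands[order(bands$sample_id, bands$enzyme), , drop = FALSE]
  })
  rownames(cohort) <- rownames(bands) <- NULL
  list(cohort = cohort, bands = bands)
}
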