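# From band patterns to genotypes, diplotypes and taster classes, plus the
# exact association statistics used on cohorts.

#' Observed band pattern for one sample/enzyme lane
#'
#' @param sample_id sample label.
#' @param enzyme enzyme name the lane was digested with.
#' @param fragments integer fragment sizes (bp); comigrating duplicates
#'   allowed.
#' @param includes_uncut_lane was an undigested-product lane run alongside
#'   (used to accept patterns missing sub-floor fragments)?
#' @return object of class `observed_bands`.
#' @export
observed_bands <- function(sample_id, enzyme, fragments,
                           includes_uncut_lane = TRUE) {
  fragments <- as.integer(fragments)
  if (any(is.na(fragments)) || any(fragments <= 0L)) {
    stop("fragment sizes must be positive integers", call. = FALSE)
  }
  structure(
    list(sample_id = as.character(sample_id), enzyme = as.character(enzyme),
         fragments = sort(fragments),
         includes_uncut_lane = isTRUE(includes_uncut_lane)),
    class = "observed_bands"
  )
}

# multiset match within +/- tol after sorting; returns "exact", "tolerant"
# or NA (no match)
match_multiset <- function(obs, pred, tol) {
  if (length(obs) != length(pred)) return(NA_character_)
  d <- abs(sort(obs) - sort(pred))
  if (all(d == 0L)) "exact" else if (all(d <= tol)) "tolerant" else NA_character_
}

#' Call a SNP genotype from an observed band pattern
#'
#' The observed fragment multiset is matched (within `size_tolerance_bp`)
#' against the three patterns predicted by the design: cut-allele
#' homozygote, non-cut homozygote (full length only) and heterozygote
#' (their union). Fragments below `detect_floor` may escape detection on a
#' gel (the reference assays eluted their 45/47 bp fragments separately),
#' so when the lane set includes an uncut control, patterns with sub-floor
#' fragments are additionally matched with those fragments removed; such
#' calls are reported with `confidence = "tolerant"`. Ties and non-matches
#' yield a no-call carrying the candidate set.
#'
#' @param design an `assay_design`.
#' @param bands an [observed_bands()].
#' @param size_tolerance_bp band-size matching tolerance (default 5 bp).
#' @param detect_floor gel detectability floor (default 40 bp).
#' @return object of class `genotype_call` with `snp_id`, `genotype`
#'   (e.g. `"C/G"`, or `NA` for no-call), `confidence`
#'   (`"exact"`/`"tolerant"`/`"no-call"`) and `candidates`.
#' @export
call_snp_genotype <- function(design, bands, size_tolerance_bp = 5L,
                              detect_floor = 40L) {
  stopifnot(inherits(design, "assay_design"), inherits(bands, "observed_bands"))
  if (!identical(bands$enzyme, design$enzyme$name)) {
    stop("bands were digested with ", bands$enzyme, " but the design uses ",
         design$enzyme$name, call. = FALSE)
  }
  tol <- as.integer(size_tolerance_bp)
  stopifnot(tol >= 0L)
  hits <- list()
  for (g in names(design$predicted_fragments)) {
    pred <- design$predicted_fragments[[g]]
    conf <- match_multiset(bands$fragments, pred, tol)
    if (is.na(conf) && bands$includes_uncut_lane && any(pred < detect_floor)) {
      vis <- pred[pred >= detect_floor]
      if (length(vis) && !is.na(match_multiset(bands$fragments, vis, tol))) {
        conf <- "tolerant"  # sub-floor fragment possibly unobserved
      }
    }
    if (!is.na(conf)) hits[[g]] <- conf
  }
  no_call <- function(candidates) {
    structure(list(snp_id = design$snp$id, genotype = NA_character_,
                   confidence = "no-call", candidates = candidates,
                   evidence = bands$fragments),
              class = "genotype_call")
  }
  if (!length(hits)) return(no_call(character(0)))
  exact <- names(hits)[vapply(hits, identical, logical(1), "exact")]
  chosen <- if (length(exact) == 1L) exact
            else if (length(exact) > 1L) return(no_call(exact))
            else if (length(hits) == 1L) names(hits)
            else return(no_call(names(hits)))
  structure(list(snp_id = design$snp$id, genotype = chosen,
                 confidence = hits[[chosen]], candidates = names(hits),
                 evidence = bands$fragments),
            class = "genotype_call")
}

#' @export
print.genotype_call <- function(x, ...) {
  cat(sprintf("<call> %s: %s (%s)\n", x$snp_id,
              if (is.na(x$genotype)) "no-call" else x$genotype,
              x$confidence))
  invisible(x)
}

# residue code per locus allele; haplotype names follow residues 49/262/296
HAPLOTYPE_CODE <- list(
  rs713598  = c(C = "P", G = "A"),
  rs1726866 = c(C = "A", T = "V"),
  rs10246939 = c(G = "V", A = "I")
)
CANONICAL_HAPLOTYPES <- c("PAV", "AVI")

as_genotype_string <- function(x) {
  if (inherits(x, "genotype_call")) x$genotype else as.character(x)
}

#' Call a TAS2R38 diplotype from the three SNP genotypes
#'
#' Under the two-haplotype model, C145/C785/G886 composes PAV and
#' G145/T785/A886 composes AVI. Every pair of haplotypes consistent with
#' the three unphased genotypes is enumerated; when a pair drawn entirely
#' from \{PAV, AVI\} exists the call is canonical and phased
#' deterministically. Combinations requiring a third haplotype are flagged
#' non-canonical and carry the implied haplotype pair that shares the most
#' members with \{PAV, AVI\} (ties broken alphabetically) — they are
#' reported, never silently coerced.
#'
#' @param g145,g785,g886 genotype calls (from [call_snp_genotype()]) or
#'   strings like `"C/G"` for rs713598, rs1726866, rs10246939.
#' @return object of class `diplotype_call` with `haplotypes` (length-2
#'   character, e.g. `c("PAV","AVI")` or `NA`), `canonical` and `status`
#'   (`"canonical"`, `"non-canonical"` or `"undetermined"`).
#' @export
call_diplotype <- function(g145, g785, g886) {
  gts <- lapply(list(g145, g785, g886), as_genotype_string)
  if (any(vapply(gts, function(g) is.na(g) || !nzchar(g), logical(1)))) {
    return(structure(list(haplotypes = c(NA_character_, NA_character_),
                          canonical = FALSE, status = "undetermined",
                          genotypes = gts),
                     class = "diplotype_call"))
  }
  loci <- names(HAPLOTYPE_CODE)
  pairs <- lapply(seq_along(loci), function(i) {
    alleles <- strsplit(gts[[i]], "/", fixed = TRUE)[[1L]]
    if (length(alleles) != 2L ||
        !all(alleles %in% names(HAPLOTYPE_CODE[[i]]))) {
      stop("invalid genotype '", gts[[i]], "' for ", loci[[i]], call. = FALSE)
    }
    alleles
  })
  hap_name <- function(alleles) {
    paste(vapply(seq_along(alleles), function(i) {
      HAPLOTYPE_CODE[[i]][[alleles[[i]]]]
    }, character(1)), collapse = "")
  }
  # enumerate phasings: haplotype 1 takes one allele per locus, haplotype 2
  # the other; 2^3 assignments, deduplicated as unordered name pairs
  consistent <- unique(t(vapply(0:7, function(mask) {
    pick <- as.logical(bitwAnd(mask, c(1L, 2L, 4L)))
    h1 <- hap_name(mapply(function(p, a) if (p) a[[2L]] else a[[1L]],
                          pick, pairs))
    h2 <- hap_name(mapply(function(p, a) if (p) a[[1L]] else a[[2L]],
                          pick, pairs))
    sort(c(h1, h2))
  }, character(2))))
  score <- apply(consistent, 1L, function(p) sum(p %in% CANONICAL_HAPLOTYPES))
  ord <- order(-score, consistent[, 1L], consistent[, 2L])
  best <- consistent[ord[[1L]], ]
  canonical <- all(best %in% CANONICAL_HAPLOTYPES)
  if (canonical) {
    best <- best[order(match(best, CANONICAL_HAPLOTYPES))]  # PAV before AVI
  }
  structure(list(haplotypes = unname(best), canonical = canonical,
                 status = if (canonical) "canonical" else "non-canonical",
                 genotypes = gts),
            class = "diplotype_call")
}

#' @export
print.diplotype_call <- function(x, ...) {
  cat(sprintf("<diplotype> %s (%s)\n",
              paste(x$haplotypes, collapse = "/"), x$status))
  invisible(x)
}

#' PROP taster class from a TAS2R38 diplotype
#'
#' Base mapping: PAV/PAV is super-taster, PAV/AVI medium taster, AVI/AVI
#' non-taster. When a CA6 rs2274333 genotype is supplied, a PAV/AVI
#' heterozygote carrying at least one A allele is annotated
#' "super-compatible" (the A allele is associated with super-taster status
#' in such heterozygotes in a Sardinian isolate); the annotation never
#' changes the base class — the association is reported, not enforced.
#'
#' @param diplotype a `diplotype_call` or a string like `"PAV/AVI"`.
#' @param ca6_genotype optional `"AA"`, `"AG"` or `"GG"`.
#' @return list with `taster_class`
#'   (`"super"`/`"medium"`/`"non-taster"`/`"undetermined"`) and
#'   `annotation`.
#' @export
classify_taster <- function(diplotype, ca6_genotype = NULL) {
  dip <- if (inherits(diplotype, "diplotype_call")) {
    if (!diplotype$canonical) {
      return(list(taster_class = "undetermined",
                  annotation = paste0("non-canonical haplotype set {",
                                      paste(diplotype$haplotypes,
                                            collapse = ", "), "}")))
    }
    paste(diplotype$haplotypes, collapse = "/")
  } else {
    paste(sort(strsplit(as.character(diplotype), "/", fixed = TRUE)[[1L]]),
          collapse = "/")
  }
  cls <- switch(dip,
                "AVI/PAV" = "medium", "PAV/AVI" = "medium",
                "PAV/PAV" = "super", "AVI/AVI" = "non-taster",
                NULL)
  if (is.null(cls)) {
    return(list(taster_class = "undetermined",
                annotation = paste0("unrecognized diplotype ", dip)))
  }
  annotation <- ""
  if (!is.null(ca6_genotype)) {
    ca6 <- toupper(ca6_genotype)
    if (!ca6 %in% c("AA", "AG", "GA", "GG")) {
      stop("ca6_genotype must be AA, AG or GG", call. = FALSE)
    }
    if (cls == "medium" && grepl("A", ca6, fixed = TRUE)) {
      annotation <- "super-compatible (PAV + CA6 A-allele)"
    }
  }
  list(taster_class = cls, annotation = annotation)
}

#' Allele frequencies at one locus of a cohort
#'
#' @param cohort data.frame with one genotype column per locus (strings
#'   like `"C/G"`), or a plain character vector of genotypes.
#' @param locus column name, required when `cohort` is a data.frame.
#' @return list with `frequencies` (named numeric, summing to 1),
#'   `allele_counts` and `genotype_counts`.
#' @export
allele_frequencies <- function(cohort, locus = NULL) {
  gts <- if (is.data.frame(cohort)) {
    stopifnot(!is.null(locus), locus %in% names(cohort))
    cohort[[locus]]
  } else {
    as.character(cohort)
  }
  gts <- gts[!is.na(gts) & nzchar(gts)]
  if (!length(gts)) stop("no genotype calls at this locus", call. = FALSE)
  alleles <- unlist(strsplit(gts, "/", fixed = TRUE))
  counts <- table(alleles)
  freqs <- as.numeric(counts) / sum(counts)
  names(freqs) <- names(counts)
  list(frequencies = freqs,
       allele_counts = stats::setNames(as.integer(counts), names(counts)),
       genotype_counts = table(gts))
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact p-value by summing hypergeometric probabilities of all tables
#' with the observed margins whose probability does not exceed that of the
#' observed table (with a small relative tolerance against floating-point
#' ties, as is conventional).
#'
#' @param tab 2x2 matrix (or length-4 vector, filled by column) of
#'   nonnegative integer counts, total >= 1.
#' @return two-sided p-value.
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- matrix(as.numeric(tab), 2L, 2L)
  if (any(is.na(tab)) || any(tab < 0) || any(tab != round(tab))) {
    stop("counts must be nonnegative integers", call. = FALSE)
  }
  if (sum(tab) < 1) stop("table total must be >= 1", call. = FALSE)
  r1 <- sum(tab[1L, ]); c1 <- sum(tab[, 1L]); n <- sum(tab)
  kmin <- max(0, c1 - (n - r1)); kmax <- min(r1, c1)
  ks <- kmin:kmax
  logp <- lchoose(r1, ks) + lchoose(n - r1, c1 - ks) - lchoose(n, c1)
  p <- exp(logp - max(logp)); p <- p / sum(p)
  p_obs <- p[ks == tab[1L, 1L]]
  min(1, sum(p[p <= p_obs * (1 + 1e-7)]))
}

#' Exact Hardy-Weinberg test from genotype counts
#'
#' Exact conditional test: all heterozygote counts compatible with the
#' observed allele counts are enumerated and the probabilities of
#' configurations no more likely than the observed one are summed.
#'
#' @param genotype_counts length-3 integer vector `(n_AA, n_AB, n_BB)`.
#' @return exact p-value.
#' @export
hwe_exact <- function(genotype_counts) {
  gc <- as.numeric(genotype_counts)
  if (length(gc) != 3L || any(is.na(gc)) || any(gc < 0) ||
      any(gc != round(gc))) {
    stop("genotype_counts must be three nonnegative integers", call. = FALSE)
  }
  n <- sum(gc)
  if (n < 1) stop("total count must be >= 1", call. = FALSE)
  nA <- 2 * gc[[1L]] + gc[[2L]]
  nabs <- seq(nA %% 2, min(nA, 2 * n - nA), by = 2)
  logp <- vapply(nabs, function(nab) {
    naa <- (nA - nab) / 2
    nbb <- n - naa - nab
    nab * log(2) - lfactorial(naa) - lfactorial(nab) - lfactorial(nbb)
  }, numeric(1))
  p <- exp(logp - max(logp)); p <- p / sum(p)
  p_obs <- p[nabs == gc[[2L]]]
  min(1, sum(p[p <= p_obs * (1 + 1e-7)]))
}

#' Call a whole cohort from band patterns
#'
#' @param designs list of three `assay_design`s covering rs713598,
#'   rs1726866 and rs10246939 (names taken from each design's SNP).
#' @param bands data.frame with columns `sample_id`, `enzyme`, `fragments`
#'   (comma-joined integers) and `uncut_lane` (0/1), as written/read by
#'   [read_bands_tsv()].
#' @param ca6 optional data.frame with columns `sample_id`, `ca6`.
#' @param size_tolerance_bp band-matching tolerance (default 5 bp).
#' @param detect_floor gel detectability floor (default 40 bp).
#' @return data.frame: `sample_id`, one genotype column per SNP,
#'   `diplotype`, `taster_class`, `ca6`, `annotation`.
#' @export
call_cohort <- function(designs, bands, ca6 = NULL, size_tolerance_bp = 5L,
                        detect_floor = 40L) {
  names(designs) <- vapply(designs, function(d) d$snp$id, character(1))
  required <- names(HAPLOTYPE_CODE)
  if (!all(required %in% names(designs))) {
    stop("designs must cover ", paste(required, collapse = ", "),
         call. = FALSE)
  }
  by_enzyme <- stats::setNames(
    vapply(designs, function(d) d$enzyme$name, character(1)), names(designs))
  samples <- unique(bands$sample_id)
  rows <- lapply(samples, function(sid) {
    calls <- lapply(required, function(snp_id) {
      enz <- by_enzyme[[snp_id]]
      lane <- bands[bands$sample_id == sid & bands$enzyme == enz, , drop = FALSE]
      if (nrow(lane) != 1L) {
        return(structure(list(snp_id = snp_id, genotype = NA_character_,
                              confidence = "no-call",
                              candidates = character(0), evidence = integer(0)),
                         class = "genotype_call"))
      }
      frag <- as.integer(strsplit(lane$fragments[[1L]], ",", fixed = TRUE)[[1L]])
      ob <- observed_bands(sid, enz, frag,
                           includes_uncut_lane = lane$uncut_lane[[1L]] != 0)
      call_snp_genotype(designs[[snp_id]], ob, size_tolerance_bp, detect_floor)
    })
    dip <- call_diplotype(calls[[1L]], calls[[2L]], calls[[3L]])
    ca6_gt <- if (!is.null(ca6)) {
      m <- ca6$ca6[match(sid, ca6$sample_id)]
      if (is.na(m)) NULL else m
    }
    cls <- classify_taster(dip, ca6_gt)
    data.frame(
      sample_id = sid,
      rs713598 = calls[[1L]]$genotype,
      rs1726866 = calls[[2L]]$genotype,
      rs10246939 = calls[[3L]]$genotype,
      diplotype = paste(dip$haplotypes, collapse = "/"),
      taster_class = cls$taster_class,
      ca6 = if (is.null(ca6_gt)) NA_character_ else as.character(ca6_gt),
      annotation = cls$annotation,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
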