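# ACRS assay design: enumerate enzyme-site placements over a SNP, derive
# the primer-embedded substitutions that complete the recognition site for
# exactly one allele, build the mutagenic primer pair, validate
# diagnosability by simulation, and rank candidate assays.

#' Biallelic SNP specification
#'
#' @param id SNP identifier (e.g. `"rs713598"`).
#' @param position 1-based template coordinate.
#' @param alleles character vector of two distinct single bases.
#' @param cut_allele optional: the allele intended to complete the
#'   engineered restriction site (set by the designer).
#' @return object of class `snp_spec`.
#' @export
snp_spec <- function(id, position, alleles, cut_allele = NULL) {
  position <- as.integer(position)
  stopifnot(length(position) == 1L, position >= 1L)
  alleles <- toupper(as.character(alleles))
  if (length(alleles) != 2L || anyDuplicated(alleles) ||
      !all(alleles %in% c("A", "C", "G", "T"))) {
    stop("alleles must be two distinct bases from A/C/G/T", call. = FALSE)
  }
  if (!is.null(cut_allele)) {
    cut_allele <- toupper(cut_allele)
    stopifnot(cut_allele %in% alleles)
  }
  structure(
    list(id = as.character(id), position = position,
         alleles = sort(alleles), cut_allele = cut_allele),
    class = "snp_spec"
  )
}

#' @export
print.snp_spec <- function(x, ...) {
  cat(sprintf("<snp> %s %s/%s @ %d%s\n", x$id, x$alleles[[1L]],
              x$alleles[[2L]], x$position,
              if (is.null(x$cut_allele)) ""
              else paste0(" (cut allele ", x$cut_allele, ")")))
  invisible(x)
}

#' Enumerate allele-discriminating site placements over a SNP
#'
#' Slides the enzyme's recognition window across every offset that covers
#' the SNP, on both strands (palindromic patterns are enumerated once).
#' A placement is kept when exactly one of the two alleles satisfies the
#' site code at the SNP's slot. The substitutions required to complete the
#' rest of the site are computed from the template: positions already
#' satisfying the code need no change; positions that fail it are set to
#' the lexicographically smallest base in the code's expansion. Placements
#' whose substitutions fall on both sides of the SNP are discarded — all
#' engineered bases must be deliverable by a single mutagenic primer.
#'
#' @param template template sequence.
#' @param snp a [snp_spec()].
#' @param enz an `enzyme`.
#' @return list of `placement` objects (possibly empty); each has fields
#'   `enzyme`, `site_span`, `strand`, `snp_slot`, `matching_allele`,
#'   `required_substitutions` (data.frame template_pos/template_base/
#'   new_base), `side` (`"forward"`/`"reverse"`) and `cut_after_template`.
#' @export
enumerate_site_placements <- function(template, snp, enz) {
  template <- dna(template, what = "template")
  stopifnot(inherits(snp, "snp_spec"), inherits(enz, "enzyme"))
  n <- nchar(template)
  if (snp$position > n) stop("SNP position outside template", call. = FALSE)
  tchars <- seq_chars(template)
  L <- nchar(enz$site)
  patterns <- list(list(chars = seq_chars(enz$site), strand = "+",
                        cut_from_start = enz$cut_offset))
  if (!is_palindromic(enz)) {
    patterns <- c(patterns, list(list(
      chars = seq_chars(revcomp(enz$site, pattern = TRUE)), strand = "-",
      cut_from_start = L - enz$cut_offset
    )))
  }
  out <- list()
  for (pat in patterns) {
    for (slot in seq_len(L)) {
      start <- snp$position - slot + 1L
      end <- start + L - 1L
      if (start < 1L || end > n) next
      code <- pat$chars[[slot]]
      match_a <- vapply(snp$alleles, function(a) {
        a %in% IUPAC_SETS[[code]]
      }, logical(1))
      if (sum(match_a) != 1L) next
      subs <- list()
      ok <- TRUE
      for (j in seq_len(L)) {
        if (j == slot) next
        tpos <- start + j - 1L
        tbase <- tchars[[tpos]]
        cj <- pat$chars[[j]]
        if (tbase %in% IUPAC_SETS[[cj]]) next   # template-first: no change
        subs[[length(subs) + 1L]] <- data.frame(
          template_pos = tpos, template_base = tbase,
          new_base = sort(IUPAC_SETS[[cj]])[[1L]]
        )
      }
      subs <- if (length(subs)) do.call(rbind, subs) else
        data.frame(template_pos = integer(0), template_base = character(0),
                   new_base = character(0))
      if (nrow(subs)) {
        below <- subs$template_pos < snp$position
        if (any(below) && any(!below)) next   # split across the SNP
        side <- if (all(below)) "forward" else "reverse"
      } else {
        side <- "forward"  # site pre-completed: either side would do
      }
      out[[length(out) + 1L]] <- structure(
        list(enzyme = enz,
             site_span = c(start, end),
             strand = pat$strand,
             snp_slot = slot,
             matching_allele = snp$alleles[[which(match_a)]],
             required_substitutions = subs,
             side = side,
             cut_after_template = start + pat$cut_from_start - 1L),
        class = "placement"
      )
    }
  }
  out
}

#' @export
print.placement <- function(x, ...) {
  cat(sprintf(
    "<placement> %s %d..%d (%s) allele %s, %d substitution(s), %s side\n",
    x$enzyme$name, x$site_span[[1L]], x$site_span[[2L]], x$strand,
    x$matching_allele, nrow(x$required_substitutions), x$side))
  invisible(x)
}

#' Design constraints
#'
#' Defaults: Tm window 58-70 degC (nearest-neighbor model), primer length
#' 18-50 nt, engineered substitutions at offsets 2-6 from the 3' terminus
#' (never the terminal base, which must prime extension), at most 2
#' engineered mismatches per primer, amplicon 120-400 bp, fragments >= 40
#' bp and pairwise resolvable by >= 10 bp or 10% of the larger fragment.
#'
#' @param tm_min,tm_max acceptable primer Tm window (degC).
#' @param tm_target ranking target Tm (degC); default window midpoint.
#' @param len_min,len_max primer length bounds (nt).
#' @param offset_min,offset_max allowed 3'-end offsets for engineered
#'   substitutions (offset 1 is the terminal base and always forbidden).
#' @param max_engineered maximum engineered mismatches per primer.
#' @param amp_min,amp_max amplicon size bounds (bp).
#' @param min_fragment smallest reportable/designable fragment (bp).
#' @param min_resolvable minimum absolute fragment-size difference (bp);
#'   effective threshold is `max(min_resolvable, 0.1 * larger)`.
#' @param tm_method Tm model passed to [compute_tm()].
#' @return named list of constraints.
#' @export
design_constraints <- function(tm_min = 58, tm_max = 70, tm_target = NULL,
                               len_min = 18L, len_max = 50L,
                               offset_min = 2L, offset_max = 6L,
                               max_engineered = 2L,
                               amp_min = 120L, amp_max = 400L,
                               min_fragment = 40L, min_resolvable = 10L,
                               tm_method = "nearest_neighbor") {
  if (offset_min < 2L) {
    stop("engineered substitutions may never occupy the 3'-terminal base",
         call. = FALSE)
  }
  list(tm_min = tm_min, tm_max = tm_max,
       tm_target = if (is.null(tm_target)) (tm_min + tm_max) / 2 else tm_target,
       len_min = as.integer(len_min), len_max = as.integer(len_max),
       offset_min = as.integer(offset_min), offset_max = as.integer(offset_max),
       max_engineered = as.integer(max_engineered),
       amp_min = as.integer(amp_min), amp_max = as.integer(amp_max),
       min_fragment = as.integer(min_fragment),
       min_resolvable = as.integer(min_resolvable),
       tm_method = tm_method)
}

#' Constraints matching the TAS2R38 reference assays
#'
#' The reference assays deliberately use long mutagenic oligos (46-47 nt)
#' so that the diagnostic cut releases a fragment above the 40 bp
#' detectability floor; nearest-neighbor Tm of such oligos exceeds 70 degC,
#' so the Tm ceiling is raised accordingly.
#'
#' @param ... overrides passed to [design_constraints()].
#' @return named list of constraints.
#' @export
tas2r38_constraints <- function(...) {
  defaults <- list(tm_min = 58, tm_max = 84, tm_target = 63,
                   amp_min = 120L, amp_max = 320L)
  args <- utils::modifyList(defaults, list(...))
  do.call(design_constraints, args)
}

apply_subs <- function(chars, subs, offset0 = 0L) {
  if (nrow(subs)) chars[subs$template_pos - offset0] <- subs$new_base
  chars
}

# Extend a primer 5'-ward from a fixed 3' end until Tm enters the window.
# For forward primers the 3' end is the template position `end3`; for
# reverse primers it is template position `end3` and extension grows the
# footprint to the right. Returns footprint c(start, end) or NULL.
extend_for_tm <- function(tchars, end3, orientation, len_floor, cons,
                          subs = NULL) {
  n <- length(tchars)
  for (len in seq(max(cons$len_min, len_floor), cons$len_max)) {
    fp <- if (orientation == "forward") c(end3 - len + 1L, end3)
          else c(end3, end3 + len - 1L)
    if (fp[[1L]] < 1L || fp[[2L]] > n) return(NULL)
    chars <- tchars[fp[[1L]]:fp[[2L]]]
    if (!is.null(subs) && nrow(subs)) {
      chars[subs$template_pos - fp[[1L]] + 1L] <- subs$new_base
    }
    seq5to3 <- if (orientation == "forward") paste(chars, collapse = "")
               else revcomp(paste(chars, collapse = ""))
    tm <- compute_tm(seq5to3, method = cons$tm_method)
    if (tm >= cons$tm_min) {
      if (tm > cons$tm_max) return(NULL)   # overshot before entering window
      return(list(footprint = fp, bases = seq5to3, tm = tm))
    }
  }
  NULL
}

#' Build a mutagenic primer pair for a site placement
#'
#' The mutagenic-side primer terminates at the template base adjacent to
#' the SNP (the SNP itself stays outside both primers) and carries every
#' required substitution in its 3' region, at offsets within
#' `[offset_min, offset_max]` from the 3' terminus. Its length is the
#' smallest that (i) reaches the Tm window and (ii) keeps the diagnostic
#' cut fragment at or above `min_fragment`. The opposite primer is a
#' perfect-match primer; candidate placements are scanned outward and the
#' first whose amplicon carries the engineered site exactly once on the
#' cut allele and never on the other allele is chosen.
#'
#' @param template template sequence.
#' @param placement a `placement` from [enumerate_site_placements()].
#' @param snp the [snp_spec()] the placement was computed for.
#' @param constraints see [design_constraints()].
#' @return list with `fwd`, `rev` (`primer` objects; the mutagenic one is
#'   on `placement$side`), `tm_fwd`, `tm_rev`.
#' @export
build_primers <- function(template, placement, snp,
                          constraints = design_constraints()) {
  template <- dna(template, what = "template")
  stopifnot(inherits(placement, "placement"), inherits(snp, "snp_spec"))
  cons <- constraints
  subs <- placement$required_substitutions
  if (nrow(subs) > cons$max_engineered) {
    stop("design infeasible: ", nrow(subs), " engineered mismatches exceed ",
         "max_engineered = ", cons$max_engineered, call. = FALSE)
  }
  tchars <- seq_chars(template)
  n <- length(tchars)
  tcut <- placement$cut_after_template
  if (placement$side == "forward") {
    end3 <- snp$position - 1L
    offs <- end3 - subs$template_pos + 1L
  } else {
    end3 <- snp$position + 1L
    offs <- subs$template_pos - end3 + 1L
  }
  if (nrow(subs) &&
      (any(offs < cons$offset_min) || any(offs > cons$offset_max))) {
    stop("design infeasible: engineered substitution at 3' offset ",
         paste(sort(offs), collapse = ","), " outside [", cons$offset_min,
         ", ", cons$offset_max, "]", call. = FALSE)
  }
  # length floor keeping the diagnostic cut fragment >= min_fragment
  len_floor <- if (placement$side == "forward") {
    (end3 - tcut) + cons$min_fragment
  } else {
    (tcut + cons$min_fragment) - end3 + 1L
  }
  mut <- extend_for_tm(tchars, end3, placement$side, len_floor, cons, subs)
  if (is.null(mut)) {
    stop("design infeasible: no primer length in [", cons$len_min, ", ",
         cons$len_max, "] reaches the Tm window on the mutagenic side",
         call. = FALSE)
  }
  mut_primer <- primer(mut$bases, placement$side,
                       name = paste0(snp$id, "_", placement$enzyme$name, "_",
                                     if (placement$side == "forward") "F" else "R",
                                     "mut"),
                       intended_span = mut$footprint)
  # simulate both allele amplicons for a candidate span; count enzyme sites
  clean_span <- function(amp_start, amp_end) {
    for (allele in snp$alleles) {
      chars <- tchars[amp_start:amp_end]
      if (nrow(subs)) chars[subs$template_pos - amp_start + 1L] <- subs$new_base
      chars[snp$position - amp_start + 1L] <- allele
      hits <- find_sites(paste(chars, collapse = ""), placement$enzyme)
      expected <- if (allele == placement$matching_allele) 1L else 0L
      if (nrow(hits) != expected) return(FALSE)
      if (expected == 1L &&
          hits$start[[1L]] != placement$site_span[[1L]] - amp_start + 1L) {
        return(FALSE)
      }
    }
    TRUE
  }
  opp_orientation <- if (placement$side == "forward") "reverse" else "forward"
  candidates <- if (opp_orientation == "reverse") {
    seq(snp$position + 1L, n)          # reverse primer 3' end, ascending
  } else {
    seq(snp$position - 1L, 1L)         # forward primer 3' end, descending
  }
  fallback <- NULL
  for (g in candidates) {
    opp <- extend_for_tm(tchars, g, opp_orientation, cons$len_min, cons)
    if (is.null(opp)) next
    if (opp_orientation == "reverse") {
      amp_start <- mut$footprint[[1L]]
      amp_end <- opp$footprint[[2L]]
    } else {
      amp_start <- opp$footprint[[1L]]
      amp_end <- mut$footprint[[2L]]
    }
    amp_len <- amp_end - amp_start + 1L
    if (amp_len < cons$amp_min) next
    if (amp_len > cons$amp_max) break
    cand <- primer(opp$bases, opp_orientation,
                   name = paste0(snp$id, "_", placement$enzyme$name, "_",
                                 if (opp_orientation == "forward") "F" else "R"),
                   intended_span = opp$footprint)
    if (clean_span(amp_start, amp_end)) {
      fallback <- list(opp = cand, tm = opp$tm)
      break
    }
    if (is.null(fallback)) fallback <- list(opp = cand, tm = opp$tm)
  }
  if (is.null(fallback)) {
    stop("design infeasible: no opposite-primer placement yields an ",
         "amplicon within [", cons$amp_min, ", ", cons$amp_max, "] bp",
         call. = FALSE)
  }
  if (placement$side == "forward") {
    list(fwd = mut_primer, rev = fallback$opp,
         tm_fwd = mut$tm, tm_rev = fallback$tm)
  } else {
    list(fwd = fallback$opp, rev = mut_primer,
         tm_fwd = fallback$tm, tm_rev = mut$tm)
  }
}

genotype_label <- function(a, b) paste(sort(c(a, b)), collapse = "/")

#' Validate an assay design by simulation
#'
#' Re-derives everything from the primers and template (nothing is trusted
#' from construction): (a) the cut-allele amplicon contains exactly one
#' recognition site for the design's enzyme, coinciding with the
#' engineered placement; (b) the other allele's amplicon contains none;
#' (c) every predicted fragment is at least `min_fragment` bp and distinct
#' fragments are pairwise resolvable by `max(min_resolvable, 10%)`;
#' (d) the SNP lies outside both primer footprints.
#'
#' @param template template sequence.
#' @param design an `assay_design` (or a list with fields `fwd`, `rev`,
#'   `enzyme`, `placement`, `snp`).
#' @param constraints see [design_constraints()].
#' @return list with `pass`, per-clause results in `clauses`, and the
#'   recomputed `predicted_fragments`, `amplicon_length`, `amplicon`.
#' @export
validate_design <- function(template, design,
                            constraints = design_constraints()) {
  cons <- constraints
  snp <- design$snp
  enz <- design$enzyme
  clause <- function(pass, detail) list(pass = pass, detail = detail)
  clauses <- list()
  n_eng <- nrow(design$placement$required_substitutions)
  amp <- tryCatch(
    simulate_pcr(template, design$fwd, design$rev,
                 pcr_params(max_mismatches = max(2L, n_eng)),
                 snps = list(snp)),
    error = function(e) e
  )
  if (inherits(amp, "error")) {
    clauses$amplification <- clause(FALSE, conditionMessage(amp))
    return(list(pass = FALSE, clauses = clauses,
                predicted_fragments = NULL, amplicon_length = NA_integer_,
                amplicon = NULL))
  }
  clauses$amplification <- clause(TRUE, sprintf("unique %d bp product",
                                                nchar(amp$bases)))
  in_fp <- function(fp) snp$position >= fp[[1L]] && snp$position <= fp[[2L]]
  clauses$d_snp_outside_primers <- clause(
    !in_fp(amp$fwd_footprint) && !in_fp(amp$rev_footprint),
    sprintf("SNP at %d; footprints %d..%d and %d..%d", snp$position,
            amp$fwd_footprint[[1L]], amp$fwd_footprint[[2L]],
            amp$rev_footprint[[1L]], amp$rev_footprint[[2L]]))
  if (!clauses$d_snp_outside_primers$pass) {
    return(list(pass = FALSE, clauses = clauses, predicted_fragments = NULL,
                amplicon_length = nchar(amp$bases), amplicon = amp))
  }
  variants <- amplicon_allele_variants(amp, snp)
  cut_allele <- design$placement$matching_allele
  other <- setdiff(snp$alleles, cut_allele)
  hits_cut <- find_sites(variants[[cut_allele]], enz)
  expected_start <- design$placement$site_span[[1L]] - amp$template_span[[1L]] + 1L
  clauses$a_cut_allele_single_site <- clause(
    nrow(hits_cut) == 1L && hits_cut$start[[1L]] == expected_start,
    sprintf("cut-allele sites at amplicon position(s) [%s]; engineered at %d",
            paste(hits_cut$start, collapse = ", "), expected_start))
  hits_other <- find_sites(variants[[other]], enz)
  clauses$b_other_allele_no_site <- clause(
    nrow(hits_other) == 0L,
    sprintf("non-cut-allele sites at amplicon position(s) [%s]",
            paste(hits_other$start, collapse = ", ")))
  len <- nchar(amp$bases)
  frags_cut <- digest_linear(variants[[cut_allele]], enz)$fragments
  predicted <- list()
  predicted[[genotype_label(cut_allele, cut_allele)]] <- frags_cut
  predicted[[genotype_label(other, other)]] <- len
  predicted[[genotype_label(cut_allele, other)]] <- sort(c(frags_cut, len))
  sizes <- sort(unique(unlist(predicted)))
  resolvable <- TRUE
  if (length(sizes) > 1L) {
    for (i in seq_len(length(sizes) - 1L)) {
      need <- max(cons$min_resolvable, 0.1 * sizes[[i + 1L]])
      if (sizes[[i + 1L]] - sizes[[i]] < need) resolvable <- FALSE
    }
  }
  clauses$c_fragments <- clause(
    all(sizes >= cons$min_fragment) && resolvable,
    sprintf("fragment sizes [%s]; floor %d bp", paste(sizes, collapse = ", "),
            cons$min_fragment))
  pass <- all(vapply(clauses, `[[`, logical(1), "pass"))
  list(pass = pass, clauses = clauses, predicted_fragments = predicted,
       amplicon_length = len, amplicon = amp)
}

new_assay_design <- function(snp, placement, prm, validation) {
  subs <- placement$required_substitutions
  end3 <- if (placement$side == "forward") snp$position - 1L
          else snp$position + 1L
  offs <- if (!nrow(subs)) integer(0)
          else if (placement$side == "forward") end3 - subs$template_pos + 1L
          else subs$template_pos - end3 + 1L
  structure(
    list(snp = snp_spec(snp$id, snp$position, snp$alleles,
                        cut_allele = placement$matching_allele),
         enzyme = placement$enzyme,
         placement = placement,
         fwd = prm$fwd, rev = prm$rev,
         tm_fwd = prm$tm_fwd, tm_rev = prm$tm_rev,
         amplicon_length = validation$amplicon_length,
         predicted_fragments = validation$predicted_fragments,
         n_engineered_mismatches = nrow(subs),
         mismatch_offsets_3p = sort(as.integer(offs)),
         diagnostics = validation[c("pass", "clauses")]),
    class = "assay_design"
  )
}

#' @export
print.assay_design <- function(x, ...) {
  cat(sprintf("<assay> %s via %s: %d bp amplicon, %d engineered mismatch(es) at 3'-offset(s) %s\n",
              x$snp$id, x$enzyme$name, x$amplicon_length,
              x$n_engineered_mismatches,
              paste(x$mismatch_offsets_3p, collapse = ",")))
  for (g in names(x$predicted_fragments)) {
    cat(sprintf("  %s -> {%s}\n", g,
                paste(x$predicted_fragments[[g]], collapse = ", ")))
  }
  invisible(x)
}

#' Design ACRS assays for a SNP
#'
#' Cross product of [enumerate_site_placements()] over the catalog,
#' [build_primers()] and [validate_design()], keeping only fully valid
#' designs. Ranking: fewest engineered mismatches, then largest minimum
#' fragment, then smallest deviation of mean primer Tm from
#' `constraints$tm_target`, then enzyme name (deterministic tie-break).
#'
#' @param template template sequence.
#' @param snp a [snp_spec()].
#' @param catalog list of `enzyme`s (default [default_enzyme_catalog()]).
#' @param constraints see [design_constraints()].
#' @return list of `assay_design`s, best first; empty when no
#'   allele-discriminating design exists.
#' @export
design_assays <- function(template, snp, catalog = default_enzyme_catalog(),
                          constraints = design_constraints()) {
  if (!length(catalog)) stop("empty enzyme catalog", call. = FALSE)
  template <- dna(template, what = "template")
  designs <- list()
  for (enz in catalog) {
    placements <- enumerate_site_placements(template, snp, enz)
    for (pl in placements) {
      if (nrow(pl$required_substitutions) > constraints$max_engineered) next
      prm <- tryCatch(build_primers(template, pl, snp, constraints),
                      error = function(e) NULL)
      if (is.null(prm)) next
      dsg <- list(snp = snp, enzyme = enz, placement = pl,
                  fwd = prm$fwd, rev = prm$rev)
      val <- validate_design(template, dsg, constraints)
      if (!val$pass) next
      designs[[length(designs) + 1L]] <- new_assay_design(snp, pl, prm, val)
    }
  }
  if (!length(designs)) return(list())
  key <- vapply(designs, function(d) {
    min_frag <- min(unlist(d$predicted_fragments))
    tm_dev <- abs(mean(c(d$tm_fwd, d$tm_rev)) - constraints$tm_target)
    sprintf("%02d|%06d|%08.3f|%s", d$n_engineered_mismatches,
            999999L - min_frag, tm_dev, d$enzyme$name)
  }, character(1))
  designs[order(key)]
}
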