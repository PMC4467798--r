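# In-silico PCR with mismatch-tolerant, 3'-anchored primer binding.
# The amplicon inherits primer-encoded substitutions; that inheritance is
# the mechanism that creates the artificial restriction site.

#' PCR primer
#'
#' Primers are stored 5'->3' as synthesized. A forward primer's sequence
#' equals the amplicon's 5' segment; a reverse primer equals the reverse
#' complement of the amplicon's 3' segment.
#'
#' @param bases primer sequence, 5'->3' (strict ACGT).
#' @param orientation `"forward"` or `"reverse"`.
#' @param name optional label.
#' @param intended_span optional 1-based closed interval on the template
#'   top strand (documentation only; binding is always searched).
#' @return object of class `primer`.
#' @export
primer <- function(bases, orientation = c("forward", "reverse"),
                   name = NULL, intended_span = NULL) {
  bases <- dna(bases, what = "primer")
  orientation <- match.arg(orientation)
  n <- nchar(bases)
  if (n < 15L || n > 60L) {
    stop("primer length must be in [15, 60], got ", n, call. = FALSE)
  }
  if (!is.null(intended_span)) {
    intended_span <- as.integer(intended_span)
    stopifnot(length(intended_span) == 2L, diff(intended_span) == n - 1L)
  }
  structure(
    list(bases = bases, orientation = orientation,
         name = if (is.null(name)) NA_character_ else as.character(name),
         intended_span = intended_span),
    class = "primer"
  )
}

#' @export
print.primer <- function(x, ...) {
  cat(sprintf("<primer%s> %s (%s, %d nt)\n",
              if (is.na(x$name)) "" else paste0(" ", x$name),
              x$bases, x$orientation, nchar(x$bases)))
  invisible(x)
}

#' Find primer binding sites on a template
#'
#' End-to-end alignment only (no indels, no partial annealing). A site is
#' extendable when the mismatch count is within `max_mismatches`, the
#' 3'-terminal base matches, and at least `min_3prime_perfect` consecutive
#' bases match at the 3' terminus. Engineered and accidental mismatches
#' count together against `max_mismatches` (conservative amplification
#' prediction).
#'
#' For a reverse primer the search is performed against the bottom strand;
#' reported spans are top-strand coordinates, and the primer's 3' terminus
#' corresponds to the span's left edge.
#'
#' @param template template sequence.
#' @param prm a `primer`.
#' @param max_mismatches maximum tolerated mismatches (default 2).
#' @param min_3prime_perfect minimum consecutive 3'-terminal matches
#'   (default 1, i.e. the terminal base itself).
#' @return list of binding sites, each a list with `span` (c(start, end)),
#'   `strand`, `mismatches` (data.frame template_pos/template_base/
#'   primer_base) and `three_prime_terminal_match`; sorted by position.
#' @export
find_primer_binding <- function(template, prm, max_mismatches = 2L,
                                min_3prime_perfect = 1L) {
  template <- dna(template, what = "template")
  stopifnot(inherits(prm, "primer"), max_mismatches >= 0L,
            min_3prime_perfect >= 1L)
  m <- nchar(prm$bases)
  n <- nchar(template)
  if (m > n) stop("primer longer than template", call. = FALSE)
  tchars <- seq_chars(template)
  # Compare the primer (or its revcomp, for reverse primers) to top-strand
  # windows; track which window offset is the primer's 3' terminus.
  if (prm$orientation == "forward") {
    qchars <- seq_chars(prm$bases)
    three_prime_index <- m            # rightmost window position
  } else {
    qchars <- seq_chars(revcomp(prm$bases))
    three_prime_index <- 1L           # leftmost window position
  }
  starts <- seq_len(n - m + 1L)
  mm_count <- integer(length(starts))
  match_mat <- matrix(FALSE, nrow = length(starts), ncol = m)
  for (j in seq_len(m)) {
    match_mat[, j] <- tchars[starts + j - 1L] == qchars[[j]]
  }
  mm_count <- m - rowSums(match_mat)
  run3 <- if (prm$orientation == "forward") {
    # consecutive matches ending at the last window position
    r <- integer(length(starts))
    acc <- rep(TRUE, length(starts))
    for (j in rev(seq_len(m))) {
      acc <- acc & match_mat[, j]
      r <- r + acc
    }
    r
  } else {
    r <- integer(length(starts))
    acc <- rep(TRUE, length(starts))
    for (j in seq_len(m)) {
      acc <- acc & match_mat[, j]
      r <- r + acc
    }
    r
  }
  keep <- which(mm_count <= max_mismatches &
                match_mat[, three_prime_index] &
                run3 >= min_3prime_perfect)
  lapply(keep, function(i) {
    span <- c(starts[[i]], starts[[i]] + m - 1L)
    mmj <- which(!match_mat[i, ])
    mism <- data.frame(
      template_pos = span[[1L]] + mmj - 1L,
      template_base = tchars[span[[1L]] + mmj - 1L],
      primer_base = vapply(mmj, function(j) {
        # report the base as synthesized (bottom-strand for reverse primers)
        if (prm$orientation == "forward") qchars[[j]]
        else unname(IUPAC_COMPLEMENT[qchars[[j]]])
      }, character(1))
    )
    list(span = as.integer(span),
         strand = if (prm$orientation == "forward") "+" else "-",
         mismatches = mism,
         three_prime_terminal_match = TRUE)
  })
}

#' Default PCR simulation parameters
#'
#' @param max_mismatches per-primer mismatch tolerance.
#' @param min_3prime_perfect required consecutive 3'-terminal matches.
#' @param size_min,size_max accepted product size bounds (bp).
#' @return named list of parameters.
#' @export
pcr_params <- function(max_mismatches = 2L, min_3prime_perfect = 1L,
                       size_min = 50L, size_max = 5000L) {
  list(max_mismatches = as.integer(max_mismatches),
       min_3prime_perfect = as.integer(min_3prime_perfect),
       size_min = as.integer(size_min), size_max = as.integer(size_max))
}

#' Simulate PCR on a linear template
#'
#' Requires exactly one convergent forward/reverse binding-site pair whose
#' product lies within the configured size bounds; zero products raise a
#' no-amplification error and multiple products an ambiguous-amplification
#' error (a diagnostic assay requires a single product). The amplicon
#' equals the template span with each primer footprint overwritten by the
#' primer's own bases, so engineered primer mismatches propagate into the
#' product.
#'
#' @param template template sequence.
#' @param fwd,rev forward and reverse `primer`s.
#' @param params see [pcr_params()].
#' @param snps optional list of [snp_spec()]s; amplicon offsets are
#'   recorded for those inside the product span.
#' @return object of class `amplicon`: fields `bases`, `template_span`,
#'   `fwd_footprint`, `rev_footprint`, `substitutions` (data.frame
#'   amplicon_pos/template_base/product_base) and `snp_offsets`
#'   (named integer vector of 1-based amplicon positions).
#' @export
simulate_pcr <- function(template, fwd, rev, params = pcr_params(),
                         snps = NULL) {
  template <- dna(template, what = "template")
  stopifnot(inherits(fwd, "primer"), inherits(rev, "primer"))
  if (fwd$orientation != "forward" || rev$orientation != "reverse") {
    stop("simulate_pcr() needs one forward and one reverse primer",
         call. = FALSE)
  }
  fsites <- find_primer_binding(template, fwd, params$max_mismatches,
                                params$min_3prime_perfect)
  rsites <- find_primer_binding(template, rev, params$max_mismatches,
                                params$min_3prime_perfect)
  pairs <- list()
  for (f in fsites) {
    for (r in rsites) {
      if (r$span[[1L]] > f$span[[2L]]) {  # convergent, non-overlapping
        len <- r$span[[2L]] - f$span[[1L]] + 1L
        if (len >= params$size_min && len <= params$size_max) {
          pairs[[length(pairs) + 1L]] <- list(f = f, r = r, len = len)
        }
      }
    }
  }
  if (!length(pairs)) {
    stop("no amplification: no convergent primer pair yields a product ",
         "within [", params$size_min, ", ", params$size_max, "] bp",
         call. = FALSE)
  }
  if (length(pairs) > 1L) {
    desc <- vapply(pairs, function(p) {
      sprintf("%d..%d (%d bp)", p$f$span[[1L]], p$r$span[[2L]], p$len)
    }, character(1))
    stop("ambiguous amplification: ", length(pairs), " candidate products: ",
         paste(desc, collapse = "; "), call. = FALSE)
  }
  p <- pairs[[1L]]
  span <- c(p$f$span[[1L]], p$r$span[[2L]])
  tchars <- seq_chars(template)
  prod_chars <- tchars[span[[1L]]:span[[2L]]]
  # overwrite footprints with primer-encoded bases
  fidx <- seq(p$f$span[[1L]], p$f$span[[2L]]) - span[[1L]] + 1L
  prod_chars[fidx] <- seq_chars(fwd$bases)
  ridx <- seq(p$r$span[[1L]], p$r$span[[2L]]) - span[[1L]] + 1L
  prod_chars[ridx] <- seq_chars(revcomp(rev$bases))
  orig_chars <- tchars[span[[1L]]:span[[2L]]]
  diffpos <- which(prod_chars != orig_chars)
  subs <- data.frame(
    amplicon_pos = as.integer(diffpos),
    template_base = orig_chars[diffpos],
    product_base = prod_chars[diffpos]
  )
  snp_offsets <- integer(0)
  if (!is.null(snps)) {
    if (inherits(snps, "snp_spec")) snps <- list(snps)
    inside <- Filter(function(s) {
      s$position >= span[[1L]] && s$position <= span[[2L]]
    }, snps)
    snp_offsets <- vapply(inside, function(s) {
      s$position - span[[1L]] + 1L
    }, integer(1))
    names(snp_offsets) <- vapply(inside, `[[`, character(1), "id")
  }
  structure(
    list(bases = paste(prod_chars, collapse = ""),
         template_span = as.integer(span),
         fwd_footprint = as.integer(p$f$span),
         rev_footprint = as.integer(p$r$span),
         substitutions = subs,
         snp_offsets = snp_offsets),
    class = "amplicon"
  )
}

#' @export
print.amplicon <- function(x, ...) {
  cat(sprintf("<amplicon> %d bp, template %d..%d, %d engineered base(s)\n",
              nchar(x$bases), x$template_span[[1L]], x$template_span[[2L]],
              nrow(x$substitutions)))
  invisible(x)
}

#' Per-allele variants of an amplicon at a SNP
#'
#' The SNP must lie inside the amplicon but outside both primer footprints;
#' a primer overlapping the SNP would overwrite the genotype information
#' and is reported as a design violation.
#'
#' @param amp an `amplicon`.
#' @param snp a [snp_spec()].
#' @return named list `allele -> sequence`, differing only at the SNP's
#'   amplicon offset.
#' @export
amplicon_allele_variants <- function(amp, snp) {
  stopifnot(inherits(amp, "amplicon"), inherits(snp, "snp_spec"))
  span <- amp$template_span
  if (snp$position < span[[1L]] || snp$position > span[[2L]]) {
    stop("SNP ", snp$id, " (position ", snp$position,
         ") lies outside the amplicon span ", span[[1L]], "..", span[[2L]],
         call. = FALSE)
  }
  in_fp <- function(fp) snp$position >= fp[[1L]] && snp$position <= fp[[2L]]
  if (in_fp(amp$fwd_footprint) || in_fp(amp$rev_footprint)) {
    stop("design violation: SNP ", snp$id, " lies under a primer footprint; ",
         "genotype information would be erased by the primer", call. = FALSE)
  }
  offset <- snp$position - span[[1L]] + 1L
  chars <- seq_chars(amp$bases)
  out <- lapply(snp$alleles, function(a) {
    chars[offset] <- a
    paste(chars, collapse = "")
  })
  names(out) <- snp$alleles
  out
}
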