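# Sequence substrate: strict ACGT templates, IUPAC-degenerate enzyme
# patterns, recognition-site scanning and linear digestion.
#
# Coordinates throughout the package are 1-based, fully closed intervals:
# a feature "from nucleotide 98 to nucleotide 300" has length 300 - 98 + 1.

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T")
)

IUPAC_COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A",
  R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
  B = "V", D = "H", H = "D", V = "B", N = "N"
)

#' Validate and normalize a nucleotide sequence
#'
#' Templates and primers are plain uppercase character scalars over
#' `{A,C,G,T}`. Degenerate IUPAC letters are legal only in enzyme
#' recognition patterns (`pattern = TRUE`), never in templates: the
#' allele-discrimination logic needs concrete template bases, so sequences
#' containing `N` (or any other ambiguity code) are rejected with an error.
#'
#' @param x character scalar, any case.
#' @param pattern allow degenerate IUPAC codes (for enzyme sites).
#' @param what label used in error messages.
#' @return the normalized uppercase sequence.
#' @examples
#' dna("acgt")
#' @export
dna <- function(x, pattern = FALSE, what = "sequence") {
  if (!is.character(x) || length(x) != 1L || is.na(x)) {
    stop(what, " must be a single character string", call. = FALSE)
  }
  x <- toupper(x)
  if (nchar(x) < 1L) stop(what, " must have length >= 1", call. = FALSE)
  alphabet <- if (pattern) names(IUPAC_SETS) else c("A", "C", "G", "T")
  chars <- strsplit(x, "", fixed = TRUE)[[1L]]
  bad <- setdiff(unique(chars), alphabet)
  if (length(bad)) {
    stop(what, " contains invalid character(s): ",
         paste(bad, collapse = ", "),
         if (!pattern) " (only A/C/G/T allowed in templates)",
         call. = FALSE)
  }
  x
}

seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1L]]

#' Reverse complement
#'
#' Works on strict ACGT sequences and (with `pattern = TRUE`) on degenerate
#' IUPAC patterns, so that palindromy of recognition sites can be tested.
#'
#' @param x sequence (character scalar).
#' @param pattern whether degenerate codes are allowed.
#' @return the reverse complement, same case convention (uppercase).
#' @examples
#' revcomp("ATG")   # "CAT"
#' revcomp("GGCC")  # palindrome
#' @export
revcomp <- function(x, pattern = FALSE) {
  x <- dna(x, pattern = pattern)
  chars <- IUPAC_COMPLEMENT[rev(seq_chars(x))]
  paste(chars, collapse = "")
}

#' Does a template base satisfy an IUPAC pattern code?
#'
#' @param template_base single base in `{A,C,G,T}`.
#' @param pattern_code single valid IUPAC code.
#' @return logical: is `template_base` in the code's expansion set?
#' @examples
#' iupac_match("G", "N")  # TRUE
#' iupac_match("A", "Y")  # FALSE
#' @export
iupac_match <- function(template_base, pattern_code) {
  template_base <- dna(template_base, what = "template_base")
  pattern_code <- dna(pattern_code, pattern = TRUE, what = "pattern_code")
  if (nchar(template_base) != 1L || nchar(pattern_code) != 1L) {
    stop("iupac_match() takes single characters", call. = FALSE)
  }
  template_base %in% IUPAC_SETS[[pattern_code]]
}

#' Restriction enzyme
#'
#' An enzyme is its recognition pattern (IUPAC, length >= 4) plus the
#' top-strand cut offset: `cut_offset = k` severs the top strand after the
#' k-th site base (`GG^CC` is `cut_offset = 2`). Only top-strand cut
#' positions are modeled; fragment lengths, the assay observable, are
#' strand-independent for the blunt palindromic cutters used here.
#'
#' @param name enzyme name.
#' @param site recognition pattern (IUPAC allowed).
#' @param cut_offset integer in `[0, nchar(site)]`.
#' @return an object of class `enzyme`.
#' @examples
#' enzyme("HaeIII", "GGCC", 2)
#' @export
enzyme <- function(name, site, cut_offset) {
  site <- dna(site, pattern = TRUE, what = "recognition site")
  if (nchar(site) < 4L) stop("recognition site must be >= 4 bp", call. = FALSE)
  cut_offset <- suppressWarnings(as.integer(cut_offset))
  if (is.na(cut_offset) || cut_offset < 0L || cut_offset > nchar(site)) {
    stop("cut_offset must lie in [0, site length]", call. = FALSE)
  }
  structure(
    list(name = as.character(name), site = site, cut_offset = cut_offset),
    class = "enzyme"
  )
}

#' @export
print.enzyme <- function(x, ...) {
  cat(sprintf("<enzyme> %s  %s^%s\n", x$name,
              substr(x$site, 1, x$cut_offset),
              substr(x$site, x$cut_offset + 1, nchar(x$site))))
  invisible(x)
}

#' Is a recognition pattern palindromic?
#'
#' @param enz an `enzyme`.
#' @return logical.
#' @export
is_palindromic <- function(enz) {
  stopifnot(inherits(enz, "enzyme"))
  identical(enz$site, revcomp(enz$site, pattern = TRUE))
}

#' Built-in enzyme catalog
#'
#' The three blunt palindromic cutters used by the TAS2R38 reference
#' assays: HaeIII (GG^CC), Eco47III (AGC^GCT) and RsaI (GT^AC).
#'
#' @return named list of `enzyme` objects.
#' @export
default_enzyme_catalog <- function() {
  list(
    HaeIII   = enzyme("HaeIII", "GGCC", 2L),
    Eco47III = enzyme("Eco47III", "AGCGCT", 3L),
    RsaI     = enzyme("RsaI", "GTAC", 2L)
  )
}

#' Read an enzyme catalog from TSV
#'
#' Tab-separated columns `name`, `site`, `cut_offset`; lines starting with
#' `#` are comments. Malformed rows abort with their line number.
#'
#' @param path file path.
#' @return named list of `enzyme` objects.
#' @export
read_enzyme_tsv <- function(path) {
  if (!file.exists(path)) stop("enzyme catalog not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  if (!length(keep)) stop("enzyme catalog is empty: ", path, call. = FALSE)
  out <- list()
  for (i in keep) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L) {
      stop(sprintf("%s:%d: expected 3 tab-separated fields", path, i),
           call. = FALSE)
    }
    if (identical(tolower(fields[[1L]]), "name")) next  # header row
    enz <- tryCatch(enzyme(fields[[1L]], fields[[2L]], fields[[3L]]),
                    error = function(e) {
                      stop(sprintf("%s:%d: %s", path, i, conditionMessage(e)),
                           call. = FALSE)
                    })
    out[[enz$name]] <- enz
  }
  out
}

# Logical vector over window starts: does pattern match at each start?
# Vectorized over starts; one pass per pattern position.
match_starts <- function(chars, pattern_chars) {
  n <- length(chars)
  L <- length(pattern_chars)
  if (L > n) return(logical(0))
  starts <- seq_len(n - L + 1L)
  ok <- rep(TRUE, length(starts))
  for (j in seq_len(L)) {
    ok <- ok & chars[starts + j - 1L] %in% IUPAC_SETS[[pattern_chars[[j]]]]
  }
  ok
}

#' Find recognition sites on a linear sequence
#'
#' Scans both strands. A hit is reported in top-strand coordinates:
#' `start` is the 1-based position of the site's first base and
#' `cut_after` the position such that the top strand is severed between
#' `cut_after` and `cut_after + 1`. For palindromic patterns each genomic
#' locus yields exactly one hit (strand fixed to `+`).
#'
#' @param seq template sequence (strict ACGT).
#' @param enz an `enzyme`.
#' @return data.frame with columns `start`, `strand`, `cut_after`, sorted
#'   by `start`; zero rows when nothing matches.
#' @export
find_sites <- function(seq, enz) {
  seq <- dna(seq, what = "template")
  stopifnot(inherits(enz, "enzyme"))
  chars <- seq_chars(seq)
  L <- nchar(enz$site)
  pat <- seq_chars(enz$site)
  hits <- list()
  ok <- match_starts(chars, pat)
  if (any(ok)) {
    starts <- which(ok)
    hits[["+"]] <- data.frame(
      start = starts, strand = "+",
      cut_after = starts + enz$cut_offset - 1L
    )
  }
  if (!is_palindromic(enz)) {
    # site on the bottom strand <=> top strand matches revcomp(site)
    ok <- match_starts(chars, seq_chars(revcomp(enz$site, pattern = TRUE)))
    if (any(ok)) {
      starts <- which(ok)
      hits[["-"]] <- data.frame(
        start = starts, strand = "-",
        cut_after = starts + (L - enz$cut_offset) - 1L
      )
    }
  }
  if (!length(hits)) {
    return(data.frame(start = integer(0), strand = character(0),
                      cut_after = integer(0)))
  }
  out <- do.call(rbind, hits)
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Digest a linear molecule in silico
#'
#' Fragments are the maximal runs between top-strand cut points. Cut
#' points falling at the extreme ends (offset 0 at position 1, or after the
#' last base) would create empty fragments and are ignored. Fragment
#' lengths always sum to the input length.
#'
#' @param seq sequence to digest (strict ACGT).
#' @param enz an `enzyme`.
#' @return list with `fragments` (sorted integer lengths, bp) and
#'   `cut_positions` (sorted `cut_after` values actually used).
#' @examples
#' digest_linear("GGCCAA", enzyme("HaeIII", "GGCC", 2))$fragments  # 2 4
#' @export
digest_linear <- function(seq, enz) {
  seq <- dna(seq, what = "template")
  n <- nchar(seq)
  hits <- find_sites(seq, enz)
  cuts <- sort(unique(hits$cut_after))
  cuts <- cuts[cuts >= 1L & cuts <= n - 1L]
  fragments <- sort(as.integer(diff(c(0L, cuts, n))))
  list(fragments = fragments, cut_positions = as.integer(cuts))
}
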