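# Melting-temperature estimation for primer design. Two models:
#  - wallace: the 2+4 rule, adequate only as a quick screen;
#  - nearest_neighbor: two-state duplex model with the unified NN
#    parameter set of SantaLucia (1998) PNAS 95:1460-1465, including
#    terminal initiation terms and the entropic salt correction
#    dS += 0.368 * (N-1) * ln[Na+] of the same publication.

# dH in kcal/mol, dS in cal/(mol K); keys are top-strand dinucleotides.
NN_DH <- c(
  AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2,
  CA = -8.5, TG = -8.5, GT = -8.4, AC = -8.4,
  CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
  CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0
)
NN_DS <- c(
  AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3,
  CA = -22.7, TG = -22.7, GT = -22.4, AC = -22.4,
  CT = -21.0, AG = -21.0, GA = -22.2, TC = -22.2,
  CG = -27.2, GC = -24.4, GG = -19.9, CC = -19.9
)
NN_INIT_DH <- c(GC = 0.1, AT = 2.3)   # per terminal base pair
NN_INIT_DS <- c(GC = -2.8, AT = 4.1)

#' Primer melting temperature
#'
#' @param prm a `primer` or a plain sequence string.
#' @param method `"wallace"` (2(A+T) + 4(G+C); defined for any length but
#'   only meaningful as an estimate for short oligos, roughly 8-25 nt) or
#'   `"nearest_neighbor"` (two-state model, SantaLucia 1998 unified
#'   parameters with salt correction).
#' @param conditions for `nearest_neighbor`: list with `Na` (monovalent
#'   cation, mol/L; default 0.05) and `primer_conc` (total strand
#'   concentration, mol/L; default 5e-7). The duplex is treated as
#'   non-self-complementary (CT/4 in the initiation term).
#' @return melting temperature in degrees Celsius.
#' @examples
#' compute_tm("ACGTACGT", "wallace")  # 24
#' @export
compute_tm <- function(prm, method = c("nearest_neighbor", "wallace"),
                       conditions = list(Na = 0.05, primer_conc = 5e-7)) {
  seq <- if (inherits(prm, "primer")) prm$bases else dna(prm, what = "primer")
  method <- match.arg(method)
  chars <- seq_chars(seq)
  n <- length(chars)
  if (method == "wallace") {
    at <- sum(chars %in% c("A", "T"))
    gc <- sum(chars %in% c("G", "C"))
    return(2 * at + 4 * gc)
  }
  if (n < 2L) stop("nearest_neighbor needs length >= 2", call. = FALSE)
  Na <- conditions$Na %||% 0.05
  ct <- conditions$primer_conc %||% 5e-7
  steps <- paste0(chars[-n], chars[-1L])
  dH <- sum(NN_DH[steps])
  dS <- sum(NN_DS[steps])
  term <- function(b) if (b %in% c("G", "C")) "GC" else "AT"
  dH <- dH + NN_INIT_DH[[term(chars[[1L]])]] + NN_INIT_DH[[term(chars[[n]])]]
  dS <- dS + NN_INIT_DS[[term(chars[[1L]])]] + NN_INIT_DS[[term(chars[[n]])]]
  dS <- dS + 0.368 * (n - 1L) * log(Na)
  tm_k <- (dH * 1000) / (dS + 1.987 * log(ct / 4))
  unname(tm_k - 273.15)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
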