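# Independent oracles. These deliberately share no code with the package:
# naive sliding-window matching for site scanning, direct factorial
# arithmetic (no logs) for the exact tests.

oracle_iupac <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)
oracle_comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R",
                 S = "S", W = "W", K = "M", M = "K", B = "V", D = "H",
                 H = "D", V = "B", N = "N")

oracle_revcomp <- function(s) {
  paste(rev(oracle_comp[strsplit(s, "")[[1]]]), collapse = "")
}

# brute-force window scan; returns data.frame(start, strand, cut_after)
oracle_find_sites <- function(seq, site, cut_offset) {
  chars <- strsplit(seq, "")[[1]]
  L <- nchar(site)
  palindromic <- identical(site, oracle_revcomp(site))
  scan <- function(pattern, strand, cut_from_start) {
    pat <- strsplit(pattern, "")[[1]]
    hits <- NULL
    for (i in seq_len(max(0, length(chars) - L + 1))) {
      ok <- TRUE
      for (j in seq_len(L)) {
        if (!chars[i + j - 1] %in% oracle_iupac[[pat[j]]]) { ok <- FALSE; break }
      }
      if (ok) hits <- rbind(hits, data.frame(start = i, strand = strand,
                                             cut_after = i + cut_from_start - 1))
    }
    hits
  }
  out <- scan(site, "+", cut_offset)
  if (!palindromic) {
    out <- rbind(out, scan(oracle_revcomp(site), "-", L - cut_offset))
  }
  if (is.null(out)) {
    return(data.frame(start = integer(0), strand = character(0),
                      cut_after = integer(0)))
  }
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# full enumeration of 2x2 tables at fixed margins, direct choose() products
oracle_fisher_2x2 <- function(tab) {
  tab <- matrix(tab, 2, 2)
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  ks <- max(0, c1 - (n - r1)):min(r1, c1)
  w <- choose(r1, ks) * choose(n - r1, c1 - ks)
  p <- w / sum(w)
  p_obs <- p[ks == tab[1, 1]]
  min(1, sum(p[p <= p_obs * (1 + 1e-7)]))
}

# enumeration over heterozygote counts, direct factorial weights
oracle_hwe <- function(naa, nab, nbb) {
  n <- naa + nab + nbb
  nA <- 2 * naa + nab
  cand <- seq(nA %% 2, min(nA, 2 * n - nA), by = 2)
  w <- vapply(cand, function(h) {
    a <- (nA - h) / 2
    b <- n - a - h
    2^h / (factorial(a) * factorial(h) * factorial(b))
  }, numeric(1))
  p <- w / sum(w)
  p_obs <- p[cand == nab]
  min(1, sum(p[p <= p_obs * (1 + 1e-7)]))
}
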