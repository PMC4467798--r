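# Shared fixtures, computed once per test run.

fixture_env <- new.env(parent = emptyenv())

fixture_template <- function() {
  if (is.null(fixture_env$template)) {
    fixture_env$template <- tas2r38_template(seed = 17L)
  }
  fixture_env$template
}

fixture_assays <- function() {
  if (is.null(fixture_env$assays)) {
    fixture_env$assays <- tas2r38_reference_assays(fixture_template())
  }
  fixture_env$assays
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# a random sequence guaranteed not to contain `motif` on either strand
random_dna_without <- function(motif, n) {
  repeat {
    s <- random_dna(n)
    if (!grepl(motif, s, fixed = TRUE) &&
        !grepl(oracle_revcomp(motif), s, fixed = TRUE)) {
      return(s)
    }
  }
}

withr_local_tempfile <- function(env = parent.frame()) {
  path <- tempfile(fileext = ".txt")
  withr::defer(unlink(path), envir = env)
  path
}
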