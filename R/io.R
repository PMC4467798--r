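# Readers and writers: FASTA (via Biostrings), minimal VCF, bands/calls
# TSV, and the JSON/TSV design report. All parsers reject rather than
# coerce on malformed input, with file/line context in the message. All
# coordinates in reports are 1-based closed.

#' Read a FASTA file
#'
#' @param path file path.
#' @return named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA not found: ", path, call. = FALSE)
  set <- Biostrings::readDNAStringSet(path)
  stats::setNames(toupper(as.character(set)), names(set))
}

#' Write sequences as FASTA (60-column wrapped)
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @export
write_fasta <- function(seqs, path) {
  set <- Biostrings::DNAStringSet(unlist(seqs))
  Biostrings::writeXStringSet(set, filepath = path, width = 60L)
  invisible(path)
}

#' Read SNPs from a minimal VCF
#'
#' Tab-separated with at least the five standard leading columns CHROM,
#' POS, ID, REF, ALT; `##` headers and the `#CHROM` line are skipped.
#' POS is 1-based per the VCF standard. Multiallelic rows (comma in ALT)
#' and non-SNP rows (REF or ALT longer than one base) are rejected with
#' their line number; so are malformed rows.
#'
#' @param path file path.
#' @return list of [snp_spec()]s.
#' @export
read_vcf_minimal <- function(path) {
  if (!file.exists(path)) stop("VCF not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  out <- list()
  for (i in seq_along(lines)) {
    line <- lines[[i]]
    if (grepl("^#", line) || !nzchar(trimws(line))) next
    fields <- strsplit(line, "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 5L) {
      stop(sprintf("%s:%d: expected >= 5 tab-separated columns, got %d",
                   path, i, length(fields)), call. = FALSE)
    }
    pos <- suppressWarnings(as.integer(fields[[2L]]))
    if (is.na(pos) || pos < 1L) {
      stop(sprintf("%s:%d: POS '%s' is not a positive integer",
                   path, i, fields[[2L]]), call. = FALSE)
    }
    ref <- toupper(fields[[4L]]); alt <- toupper(fields[[5L]])
    if (grepl(",", alt, fixed = TRUE)) {
      stop(sprintf("%s:%d: multiallelic row (ALT '%s') rejected",
                   path, i, alt), call. = FALSE)
    }
    if (nchar(ref) != 1L || nchar(alt) != 1L ||
        !ref %in% c("A", "C", "G", "T") || !alt %in% c("A", "C", "G", "T")) {
      stop(sprintf("%s:%d: non-SNP row (REF '%s', ALT '%s') rejected",
                   path, i, ref, alt), call. = FALSE)
    }
    out[[length(out) + 1L]] <- snp_spec(fields[[3L]], pos, c(ref, alt))
  }
  out
}

#' Read observed band patterns from TSV
#'
#' Columns `sample_id`, `enzyme`, `fragments` (comma-joined integers) and
#' `uncut_lane` (0/1); `#` comment lines allowed.
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_bands_tsv <- function(path) {
  if (!file.exists(path)) stop("bands TSV not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("sample_id", "enzyme", "fragments", "uncut_lane")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop(path, ": missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  df$fragments <- as.character(df$fragments)
  for (i in seq_len(nrow(df))) {
    frag <- suppressWarnings(
      as.integer(strsplit(df$fragments[[i]], ",", fixed = TRUE)[[1L]]))
    if (any(is.na(frag)) || any(frag <= 0L)) {
      stop(sprintf("%s: row %d: fragments '%s' are not positive integers",
                   path, i, df$fragments[[i]]), call. = FALSE)
    }
  }
  df
}

#' Write a data.frame as TSV
#'
#' @param df data.frame (bands, cohort or calls).
#' @param path output path.
#' @param header_comment optional `#` comment line written first.
#' @export
write_tsv <- function(df, path, header_comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_comment)) writeLines(paste0("# ", header_comment), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

design_to_list <- function(d) {
  list(
    snp = list(id = d$snp$id, position = d$snp$position,
               alleles = d$snp$alleles, cut_allele = d$snp$cut_allele),
    enzyme = list(name = d$enzyme$name, site = d$enzyme$site,
                  cut_offset = d$enzyme$cut_offset),
    placement = list(site_span = d$placement$site_span,
                     strand = d$placement$strand,
                     snp_slot = d$placement$snp_slot,
                     matching_allele = d$placement$matching_allele,
                     required_substitutions = d$placement$required_substitutions,
                     side = d$placement$side,
                     cut_after_template = d$placement$cut_after_template),
    fwd = list(bases = d$fwd$bases, name = d$fwd$name,
               footprint = d$fwd$intended_span),
    rev = list(bases = d$rev$bases, name = d$rev$name,
               footprint = d$rev$intended_span),
    tm_fwd = d$tm_fwd, tm_rev = d$tm_rev,
    amplicon_length = d$amplicon_length,
    predicted_fragments = d$predicted_fragments,
    n_engineered_mismatches = d$n_engineered_mismatches,
    mismatch_offsets_3p = d$mismatch_offsets_3p,
    diagnostics = d$diagnostics
  )
}

design_from_list <- function(x) {
  snp <- snp_spec(x$snp$id, x$snp$position, unlist(x$snp$alleles),
                  cut_allele = x$snp$cut_allele)
  enz <- enzyme(x$enzyme$name, x$enzyme$site, x$enzyme$cut_offset)
  subs <- as.data.frame(x$placement$required_substitutions)
  if (!nrow(subs)) {
    subs <- data.frame(template_pos = integer(0), template_base = character(0),
                       new_base = character(0))
  }
  pl <- structure(
    list(enzyme = enz, site_span = as.integer(unlist(x$placement$site_span)),
         strand = x$placement$strand, snp_slot = as.integer(x$placement$snp_slot),
         matching_allele = x$placement$matching_allele,
         required_substitutions = subs, side = x$placement$side,
         cut_after_template = as.integer(x$placement$cut_after_template)),
    class = "placement")
  fwd_span <- as.integer(unlist(x$fwd$footprint))
  rev_span <- as.integer(unlist(x$rev$footprint))
  structure(
    list(snp = snp, enzyme = enz, placement = pl,
         fwd = primer(x$fwd$bases, "forward", x$fwd$name,
                      intended_span = if (length(fwd_span)) fwd_span),
         rev = primer(x$rev$bases, "reverse", x$rev$name,
                      intended_span = if (length(rev_span)) rev_span),
         tm_fwd = x$tm_fwd, tm_rev = x$tm_rev,
         amplicon_length = as.integer(x$amplicon_length),
         predicted_fragments = lapply(x$predicted_fragments,
                                      function(f) as.integer(unlist(f))),
         n_engineered_mismatches = as.integer(x$n_engineered_mismatches),
         mismatch_offsets_3p = as.integer(unlist(x$mismatch_offsets_3p)),
         diagnostics = x$diagnostics),
    class = "assay_design")
}

#' Write a design report
#'
#' JSON round-trips losslessly through the internal model (see
#' [read_design_report()]); TSV carries one design per row with fragment
#' lists serialized as comma-joined integers.
#'
#' @param designs list of `assay_design`s (possibly empty).
#' @param path output path.
#' @param format `"json"` or `"tsv"`.
#' @export
write_design_report <- function(designs, path, format = c("json", "tsv")) {
  format <- match.arg(format)
  if (format == "json") {
    payload <- list(
      coordinate_convention = "1-based, fully closed intervals",
      designs = lapply(unname(designs), design_to_list)
    )
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         null = "null", pretty = TRUE)
  } else {
    rows <- lapply(unname(designs), function(d) {
      frag_cols <- vapply(d$predicted_fragments, paste, character(1),
                          collapse = ",")
      data.frame(snp_id = d$snp$id, enzyme = d$enzyme$name,
                 cut_allele = d$snp$cut_allele,
                 fwd_primer = d$fwd$bases, rev_primer = d$rev$bases,
                 amplicon_length = d$amplicon_length,
                 n_engineered = d$n_engineered_mismatches,
                 offsets_3p = paste(d$mismatch_offsets_3p, collapse = ","),
                 genotypes = paste(names(d$predicted_fragments),
                                   collapse = ";"),
                 fragments = paste(frag_cols, collapse = ";"),
                 valid = d$diagnostics$pass,
                 stringsAsFactors = FALSE)
    })
    df <- if (length(rows)) do.call(rbind, rows) else
      data.frame(snp_id = character(0), enzyme = character(0),
                 cut_allele = character(0), fwd_primer = character(0),
                 rev_primer = character(0), amplicon_length = integer(0),
                 n_engineered = integer(0), offsets_3p = character(0),
                 genotypes = character(0), fragments = character(0),
                 valid = logical(0))
    write_tsv(df, path,
              header_comment = "coordinates are 1-based, fully closed")
  }
  invisible(path)
}

#' Read a design report
#'
#' @param path file path.
#' @param format `"json"` (returns `assay_design` objects) or `"tsv"`
#'   (returns the tabular form, fragments as comma-joined strings).
#' @return list of `assay_design`s, or a data.frame for TSV.
#' @export
read_design_report <- function(path, format = c("json", "tsv")) {
  format <- match.arg(format)
  if (format == "json") {
    payload <- jsonlite::read_json(path)
    lapply(payload$designs, design_from_list)
  } else {
    utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  }
}
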