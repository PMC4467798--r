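Package: acrskit
Title: Design and Interpretation of Amplification-Created Restriction Site
    (ACRS) PCR-RFLP Assays
Version: 0.1.0
Authors@R:
    person("acrskit", "maintainers", email = "acrskit@example.org",
           role = c("aut", "cre"))
Description: A toolkit for genotyping single-nucleotide polymorphisms by
    PCR-RFLP when no natural restriction site distinguishes the alleles.
    Mismatch ("mutagenic") primers embed substitutions in the amplicon so
    that a restriction site is completed by exactly one allele, in the
    spirit of dCAPS markers. The package enumerates candidate enzyme/site
    placements over a SNP, builds mutagenic primer pairs, simulates PCR and
    restriction digestion per allele, validates and ranks assay designs,
    calls genotypes from observed band patterns, and reconstructs TAS2R38
    PAV/AVI diplotypes and PROP taster classes, optionally annotated with a
    CA6 rs2274333 co-genotype. A constraint-based synthetic template and
    cohort simulator make the whole pipeline testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
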