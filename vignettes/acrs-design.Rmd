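---
title: "ACRS assay design and genotyping: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ACRS assay design and genotyping: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acrskit)
```

## The model

An amplification-created restriction site (ACRS) assay genotypes a
biallelic SNP in three steps:

1. **Mutagenic PCR.** A primer pair amplifies a window containing the
   SNP. One primer — the *mutagenic* primer — deliberately mismatches the
   template at one or two internal positions near its 3' end. Because a
   primer's own sequence is copied into every product, those engineered
   bases appear in 100% of amplicons regardless of allele.
2. **Allele-conditional site completion.** The engineered bases supply
   all but one position of a restriction enzyme's recognition site; the
   remaining position is the SNP itself. Exactly one allele completes the
   site, so the enzyme cuts the amplicon if and only if that allele is
   present on that chromosome.
3. **Fragment readout.** A homozygote for the cut allele shows only the
   two digestion fragments, the other homozygote only the full-length
   product, and a heterozygote the union of both patterns.

Everything in this package is organized around making that construction
automatic and checkable. The designer (`design_assays`) treats it as a
search problem; the simulator (`simulate_pcr` + `digest_linear`) treats
it as a prediction problem; the caller (`call_snp_genotype` onward)
inverts the prediction.

Key assumptions, stated explicitly:

- **End-to-end primer binding, no indels.** A binding site is an
  ungapped alignment of the whole primer with at most `max_mismatches`
  mismatches (default 2), a matching 3'-terminal base, and at least
  `min_3prime_perfect` consecutive terminal matches (default 1).
  Engineered and accidental mismatches count together — a conservative
  model of whether amplification will work. There is no thermodynamic
  annealing simulation; the published designs place every engineered
  mismatch at offset >= 2 from the 3' terminus, which this model encodes
  as a hard rule.
- **Complete digestion of linear products.** `digest_linear` cuts at
  every recognized site (no partial digests, no methylation or star
  activity) and models only top-strand cut positions: the assay
  observable is fragment *length*, which is strand-independent for the
  blunt palindromic cutters in the default catalog (HaeIII GG^CC,
  Eco47III AGC^GCT, RsaI GT^AC). Non-palindromic and degenerate sites
  are supported in user catalogs; both strands are always scanned and
  palindromic hits deduplicated.
- **Two-haplotype diplotype model.** For TAS2R38, C145/C785/G886 = PAV
  and G145/T785/A886 = AVI. `call_diplotype` enumerates every haplotype
  pair consistent with the three unphased genotypes; if a pair within
  {PAV, AVI} exists, the call is canonical and deterministic. Anything
  requiring a third haplotype is *flagged*, never coerced — the
  two-haplotype model describes the studied population, it is not a law.
- **CA6 is an annotation.** A PAV/AVI heterozygote with a CA6 rs2274333
  A allele is annotated "super-compatible"; the base taster class is
  never overridden, because the underlying evidence is an association,
  not a deterministic rule.

## Coordinates

All coordinates are 1-based and fully closed ("from nucleotide 98 to
nucleotide 300" has length 203), matching the convention in which the
reference assays were described, so published positions can be used
verbatim. `cut_after = k` means the top strand is severed between
positions *k* and *k+1*; cut points that would produce empty fragments
(at either molecule end) are ignored, preserving the invariant
`sum(fragments) == length(input)`.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `max_mismatches` (PCR) | 2 | count | matches the maximum the reference designs use per primer |
| `min_3prime_perfect` | 1 | nt | the 3'-terminal base must prime extension; engineered bases sit at offset >= 2 |
| product size bounds | 50–5000 | bp | sanity window for diagnostic PCR; >1 candidate product is an error, not a choice |
| `offset_min..offset_max` | 2–6 | nt from 3' end | offset 1 would abolish extension; beyond ~6 the mutation risks escaping the re-synthesized primer region; reference designs use 2 and 4 |
| `max_engineered` | 2 | count | amplification reliability |
| Tm window | 58–70 °C | °C | conventional diagnostic-PCR window (nearest-neighbor model, 50 mM Na⁺, 0.5 µM oligo) |
| `min_fragment` | 40 | bp | smallest band reliably scored on a 10% polyacrylamide gel |
| `min_resolvable` | max(10, 10%) | bp | two bands closer than this comigrate |
| `size_tolerance_bp` (caller) | 5 | bp | gel sizing error; fragment pairs in the reference assays differ by >= 45 bp, so ±5 is safe by an order of magnitude |
| `detect_floor` (caller) | 40 | bp | bands below this may run off the gel; patterns missing only sub-floor bands are accepted at `confidence = "tolerant"` when an uncut control lane exists |

**Why `tas2r38_constraints()` raises `tm_max` to 84 °C.** The fragment
floor couples primer length to fragment size: the diagnostic cut falls
*inside or just beyond* the mutagenic primer's footprint, so releasing a
>= 40 bp fragment forces the mutagenic primer to be ~40+ nt. The
nearest-neighbor Tm of a 40–47-mer exceeds 70 °C — the reference assays'
own 46–47-mers do (they were annealed at 63 and 68 °C, well below their
Tm, which is standard practice for long mutagenic oligos). With the
stock 58–70 °C window those designs would be rejected as infeasible;
`tas2r38_constraints()` is therefore the constraint set under which the
designer provably rediscovers the reference geometry, while
`design_constraints()` keeps conservative defaults for short-oligo
designs.

## The designer's open choices

The construction leaves several decisions unspecified; the package
resolves them deterministically:

- **Degenerate site codes**: substitution bases are chosen
  *template-first* (no change if the template base already satisfies the
  code), then lexicographically smallest — the default catalog never
  needs this, but user catalogs may.
- **Placements split by the SNP** (substitutions required on both sides)
  are discarded: a single mutagenic primer cannot deliver them.
- **Mutagenic primer geometry**: the primer always ends at the template
  base adjacent to the SNP, keeping the SNP outside both primers (a
  primer overlapping the SNP would overwrite the genotype). Length is
  the smallest that reaches the Tm window *and* satisfies the fragment
  floor.
- **Opposite primer**: perfect-match, placed by scanning candidate
  positions outward and accepting the first whose amplicon contains the
  engineered site exactly once on the cut allele and never on the other
  allele (stray native sites make a design undiagnostic; this scan is
  why a valid design can exist on one template and not on another).
- **Ranking**: fewest engineered mismatches, then largest minimum
  fragment, then smallest |mean primer Tm − target|, then enzyme name.
  The reference study hand-made single designs and never ranked; this
  order simply prefers reliable amplification, readable gels and round
  numbers, and ends with a deterministic tie-break.
- **Validation trusts nothing from construction**: `validate_design`
  re-amplifies, re-scans and re-digests both allele amplicons, and the
  test suite additionally re-checks every returned design by simulation
  (including that the two homozygote patterns differ and that the
  heterozygote pattern is their exact union).

## What the synthetic template is — and is not

`tas2r38_template()` does **not** transcribe the real gene sequence.
It generates a surrogate in which every constraint the reference assays
depend on is pinned: the four primer footprints (with engineered bases
reverted to their genomic state: 143 = A, 781 = T, 783 = T, 888 = C),
the SNP positions (145, 785, 886) carrying PAV reference alleles, and
the site-completing neighbors (146 = C, 786 = T). Filler bases are
rejection-sampled so that, inside either future amplicon and under any
allele state, no catalog enzyme finds a site other than the engineered
ones; motifs outside the amplicons are harmless and left alone. Every
published number (203/194 bp products; 47+156, 45+149, 149+45 fragments)
is a deterministic consequence of the pinned spans, which is why the
fixture reproduces them for *every* seed.

Consequently, a green test establishes that the machinery — binding,
mutagenesis inheritance, site formation, digestion, calling — is
correct, and that the published numbers follow from the published
primers. It does not establish anything about sequence context the
reference study did not print (unpinned filler is arbitrary by design),
and users genotyping real DNA should supply the real template (GenBank
AY258597/AY258598) wherever a template is accepted.

The cohort simulator is similarly honest about its scope: diplotypes
come either as deterministic class counts (default 20:20:20
super:medium:non-taster, the reference cohort's structure) or from
Hardy-Weinberg sampling of a PAV frequency; bands are the designs'
predicted patterns with optional integer jitter (SD in bp) and Bernoulli
dropout of sub-floor fragments. That is a model of *gel observables*,
not of gel physics: no smiling lanes, no partial digests, no
heteroduplexes. The CA6 co-genotype model is per-class A-allele
frequencies; the defaults used in examples (super 0.75 / medium 0.50 /
non-taster 0.25) encode only the reported direction of the association
(A enriched in super-tasters, G in non-tasters) — the study's per-subject
tables are unpublished, so no frequency estimate is reproduced and the
cohort statistics helpers (`fisher_exact_2x2`, `hwe_exact`) are verified
against enumeration oracles instead of against published p-values.

## Numerical and degenerate-input choices

- Exact tests sum probabilities `<= p_obs * (1 + 1e-7)`; the relative
  tolerance absorbs floating-point ties, the conventional treatment.
  Both tests normalize in log space and are checked against direct
  factorial-arithmetic oracles on every table/configuration with total
  <= 30.
- Nearest-neighbor Tm uses the SantaLucia (1998) unified parameter set
  (PNAS 95:1460) with the entropic salt correction
  `dS += 0.368 (N−1) ln[Na+]` and the CT/4 initiation term for
  non-self-complementary duplexes. The Wallace 2+4 rule is computed for
  any length (the documented examples include 4-mers) but is only a
  meaningful estimate for roughly 8–25 nt.
- Zero-row inputs: no placements, no designs and no band matches are
  empty results or no-calls, not errors; malformed *files* are always
  errors with file/line context.
- Templates must be concrete A/C/G/T; degenerate letters are legal only
  in enzyme patterns. Circular molecules are unsupported.

## Known limitations

- No thermodynamic annealing, primer-dimer or hairpin screening — a
  design accepted here can still fail wet-lab PCR for reasons outside
  the binding model.
- Multiplexing is limited to the shared-amplicon case (two enzymes, one
  primer pair), expressed as two independent designs; there is no
  general k-plex optimizer.
- The reference study's reported cohort associations (taster status vs haplotype,
  and the CA6 interaction) are not reproducible without the per-subject
  data and are deliberately out of scope; only the statistical machinery
  is provided.
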