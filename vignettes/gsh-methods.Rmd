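---
title: "Methods: knowledge-based genomic safe harbor selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: knowledge-based genomic safe harbor selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gshmapper)
```

## The selection problem

Transgene integration sites for gene therapy and genome engineering must
satisfy two competing demands: minimal disturbance of host-cell function
and durable transgene expression. `gshmapper` operationalizes this as a
filtering problem over candidate loci marked by common polymorphic
mobile-element insertions (pMEIs). The population-genetic argument is
that a locus where healthy individuals segregate a 300 bp–6 kb insertion
at appreciable frequency has already passed a natural insertion
experiment; what remains is to remove candidates with regulatory,
three-dimensional-structural, or chromatin-state evidence of risk in the
tissue of interest.

Every filter is an independent per-variant annotation; the final verdict
is their conjunction. This "annotate then conjoin" design means the
candidate set is invariant to filter order (which the tests assert), and
per-filter contribution fractions are well defined even though a variant
can fail several filters at once.

## Filters, parameters and defaults

| Filter | Rule | Parameter(s), default |
|---|---|---|
| Allele frequency | fail unless `lo < AF < hi` | `af_lo = 0.1`, `af_hi = 0.9` (strict) |
| cis-eQTL | fail if per-variant FDR `< t` | `eqtl_threshold = 0.1`; cis window 500 kb; testable at `0.01 < AF < 0.99` |
| Dangerous-gene TAD | fail if any assigned TAD holds an oncogene / tumor suppressor / pLI `> 0.9` gene | `pli_threshold = 0.9` (strict) |
| Intra-TAD loop | fail on any loop contact to a promoter inside an assigned TAD | `promoter_flank = 2000` bp; `intra_loop_genes = "all"` |
| Gene density | fail if any assigned TAD density `>` threshold | threshold = unweighted mean density over all TADs |
| Inter-TAD dangerous loop | fail on loop contact to a dangerous-gene promoter outside the variant's TADs | — |
| Repressive chromatin | fail on overlap with a repressive ChromHMM state | `repressive = {9_Het, 13_ReprPC, 14_ReprPCWk, 15_Quies}`, `combine_mode = "any"` |

Active-state overlap (`1_TssA`, `2_TssAFlnk`, `4_Tx`, `5_TxWk`) is an
annotation, not a hard filter: published candidate sets all carry active
labels, so a strict `require_active` switch exists but defaults to off.

The AF band is strict at both ends deliberately: published tables round
frequencies for display (a printed "0.1" can be 10.4%), so equality at
the bound is not evidence of passing.

### The cis-eQTL stage

The association model is ordinary least squares of expression on allele
dosage plus covariates,
$y = \beta_0 + \beta_1 g + X\gamma + \varepsilon$, with the two-sided
Student *t* test on $\hat\beta_1$ (df = n − p). Categorical covariates
(population, sex) are one-hot encoded with the first level dropped.
Missing dosages are dropped pairwise, never imputed. Multiple testing is
controlled by Benjamini–Hochberg applied **globally across all tested
cis pairs** (the procedure is exposed so per-gene or per-variant
grouping can be emulated by calling `bh_fdr()` on subsets); each variant
then inherits the minimum adjusted value over its cis genes, because a
variant is disqualified when *any* nearby association is significant.
The cis distance is anchored on the gene body (closest edge), with a
`"tss"` anchor available, since the 500 kb rule is stated between a
variant and "a gene" without further anchoring. Variants outside the
1–99% AF testability bounds, or with no gene within 500 kb, remain in
the downstream analysis as *untested* (`FDR = NA`, printed `n.s.`) —
untested is distinct from not-significant, and both pass the filter.

A degenerate perfect fit (zero residual variance) is flagged and its
p-value reported as 0; a dosage vector constant after missing-data
removal is flagged untestable and excluded from testing rather than
fabricating a statistic.

### Intervals and coordinates

All internal coordinates are 0-based half-open (BED convention); every
reader converts on ingest (arrowhead and generic loop tables are taken
as 0-based spans, promoter-capture matrices as 1-based inclusive) and
chromosome names are normalized to the `chr` prefix. Display positions
print the half-open span directly, so a 1 bp insertion appears as two
numbers (`chr3:37361602-37361603`), matching published tables
byte-for-byte. Whether intersections treat intervals as closed or
half-open is unstated in the source material; we fix half-open
(abutment is not overlap) and note that a 1 bp difference cannot change
any packaged-table result. Overlap queries are delegated to
`GenomicRanges::findOverlaps()` and verified in the test suite against
per-base brute-force oracles.

### TADs, loops, chromatin states — resolved ambiguities

Several procedural details are underdetermined by the source material;
the package fixes each one explicitly:

* A gene is "in" a TAD on any body overlap (the bedtools-intersect
  default), not full containment. The mean density is unweighted by TAD
  length (a weighted option exists). All provided TAD records are pooled
  before averaging.
* A variant overlapping several TAD records applies every TAD-level
  filter against all of them (conservative OR). The report displays the
  maximum density among assigned TADs.
* The intra-TAD loop filter targets contacts with **any** gene promoter
  by default; a dangerous-genes-only variant is available as
  `intra_loop_genes = "dangerous"` because the narrative accounting of
  filter contributions suggests that reading. Both behaviors are tested.
* For a TAD-less variant every loop contact is inter-TAD (the same-TAD
  concept is undefined without a TAD), so only dangerous-gene contacts
  disqualify it — consistent with most published candidates lying
  outside TADs yet surviving.
* A promoter is "within the same TAD" when the promoter interval (not
  the gene body) overlaps the TAD, since loops are promoter-anchored.
  Loops whose far anchor hits no promoter and names no bait gene
  contribute no contact. Loop contacts to gene names absent from the
  annotation are logged and treated as non-dangerous.
* Repressive hits combine across epigenomes with `"any"` by default
  (disqualify on a hit in any provided epigenome): safety-conservative
  and consistent with repressive overlap being the dominant removal
  factor at genome scale. `"all"` is available.
* Location classification requires an exon track to distinguish
  `Intron` from `Exon`; without one the honest coarser label `Genic` is
  emitted. Ties between overlapping genes go to the longest overlap.

## The synthetic-data generator

`simulate_bundle()` lays out one 1 Mb slot per variant on a toy
chromosome: a 600 kb TAD, a 10 kb host gene with two terminal exons, and
the variant jittered inside the intron. Nine planted classes each
violate exactly one filter (`clean`, `af_low`, `af_high`, `eqtl_hit`,
`dangerous_tad`, `intra_loop`, `high_density`, `inter_loop_dangerous`,
`repressive`); a distant "danger island" TAD supplies the inter-TAD loop
target. Defaults — 3 variants per class, cohort n = 200, planted effect
β = 1.5 with residual sd 1, Hardy–Weinberg `Binomial(2, AF)` genotypes,
population and sex covariates, 50 kb ChromHMM tiles drawn from
non-repressive states with planted overrides at variant positions — are
the stated simulation conditions of the eQTL power analysis plus
geometry chosen once to keep every class satisfiable (the constructor
rejects configurations where it is not, e.g. too few filler genes to
push a "high-density" TAD above the mean). The same seed yields
byte-identical bundles.

The generator's `variants.tsv` carries the planted per-variant FDR
column, mirroring the real input format (ID, position, eQTL FDR, AF)
in which eQTL results arrive precomputed; the cohort matrices are
emitted alongside so `run_eqtl()` can be exercised on real fitted
statistics. The generator emulates the *statistical structure* of the
inputs — additive dosage effects, covariate shifts, state tiling, loop
wiring — but not linkage disequilibrium, demography, realistic Hi-C
contact decay, or expression count noise; passing its planted-truth
tests therefore demonstrates correct filter logic and calibrated
inference, not performance on real population data.

## Verification and problem sizes

The test suite checks each primitive against an independent oracle
(per-base interval scans, the step-up FDR definition, explicit normal
equations), asserts the planted-class/filter bijection, and runs
property suites: monotone safety (tightening any threshold never
enlarges the candidate set; 50 bundles of 9 variants), null calibration
of the additive test (1,000 fits at n = 200; rejection rate at
α = 0.05 within [0.035, 0.065]), power at the planted effect (one β = 1.5
signal among 50 nulls, n = 200; detected at FDR < 0.1 in ≥ 95% of 20
seeds), and exact planted-truth recovery of the full file-based pipeline
across 10 seeds. These sizes are the package's chosen balance between
statistical resolution and a test suite that runs in minutes.

The packaged blood (19-row) and brain (5-row) candidate tables are
verbatim transcriptions of published results used as structural
fixtures; `compare_gsh_sets()` reproduces their dataset bookkeeping
(16 vs 9 with 6 shared within 15 bp, i.e. 66.7% of the smaller set).
The genome-wide mean TAD gene density of ~28 genes/Mbp reported for
GM12878 arrowhead domains is reproducible with `read_tads()` +
`read_genes()` + `mean_gene_density()` given the external domain list
and gene annotation, which are not packaged.

## Known limitations

* Single-assembly tool: coordinates are carried as given (hg19 in the
  packaged tables); no liftover.
* The VCF reader covers only the structural-variant dialect with
  symbolic mobile-element ALT alleles; it is not a general VCF parser.
* No alias resolution for gene names in the oncogene/TSG/pLI lists;
  unmatched names are logged.
* Trans effects, permutation-based empirical FDR, and relatedness or
  expression-PC covariates are out of scope for the eQTL stage.
* Loop scores are carried through but never thresholded; the expectation
  is a pre-filtered interaction matrix.
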