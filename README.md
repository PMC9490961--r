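# gshmapper

Knowledge-based selection of genomic safe harbor (GSH) sites.

A genomic safe harbor is a locus that tolerates transgene integration
without disrupting host-cell function while sustaining transgene
expression. `gshmapper` implements a tissue-aware selection framework
that starts from common polymorphic mobile-element insertions (pMEIs) —
loci where healthy genomes demonstrably tolerate multi-kilobase
insertions — and removes every candidate with evidence of regulatory or
structural risk:

1. **Allele frequency**: keep only common insertions, `0.1 < AF < 0.9`
   (strict band).
2. **cis-eQTL**: remove variants associated with expression of any gene
   within 500 kb (additive linear model `y = b0 + b1·g + covariates + e`,
   two-sided t test on `b1`, Benjamini–Hochberg FDR < 0.1 across all cis
   pairs).
3. **TAD co-residence**: remove variants sharing a topologically
   associating domain (TAD) with an oncogene, tumor suppressor, or
   dosage-sensitive gene (pLI > 0.9).
4. **Intra-TAD loops**: remove variants that form promoter-capture Hi-C
   loops with gene promoters (TSS ± 2 kb) in their own TAD.
5. **TAD gene density**: remove variants in TADs whose gene density
   (genes per Mbp = count / length × 10⁶) exceeds the mean over all TADs.
6. **Inter-TAD dangerous loops**: remove variants looping to promoters of
   dangerous genes in other TADs.
7. **Chromatin state**: remove variants overlapping repressive ChromHMM
   states (`9_Het`, `13_ReprPC`, `14_ReprPCWk`, `15_Quies`) in any
   reference epigenome; overlap with active states (`1_TssA`,
   `2_TssAFlnk`, `4_Tx`, `5_TxWk`) is recorded as an annotation.

All filters are computed independently per variant and conjoined, so the
output ledger supports per-filter contribution accounting, and the final
candidate set is identical to sequential removal in any order.

## Worked example

Generate a synthetic input bundle with planted ground truth, run the
pipeline, and compare against the truth manifest:

```r
library(gshmapper)

sim <- simulate_inputs(simulation_config(seed = 4), "sim_bundle")
res <- run_pipeline(c(sim$config, list(out_dir = "sim_out")))
#> 3/27 variants pass all filters
head(res$report[, 1:8], 3)
#>      GSH_ID             Position   FDR     AF TAD gene density Active regions    Gene Location
#> 1 SIM_GSH_1   chr1:155514-155515 0.991 0.7392             1.67           4_Tx HOST001   Intron
#> 2 SIM_GSH_2 chr1:1152053-1152054  n.s. 0.5096             1.67    4_Tx,5_TxWk HOST002   Intron
#> 3 SIM_GSH_3 chr1:2153762-2153763 0.943 0.5208             1.67           4_Tx HOST003   Intron
round(res$stats, 3)
#>                   fail_af                 fail_eqtl   fail_same_tad_dangerous
#>                     0.222                     0.111                     0.111
#>           fail_intra_loop              fail_density fail_inter_loop_dangerous
#>                     0.111                     0.111                     0.111
#>           fail_repressive             fail_any_loop                 candidate
#>                     0.111                     0.222                     0.111
```

Each reported row is a surviving candidate: its display position
(`chrN:start-end`, the two printed numbers spanning a 1 bp insertion),
eQTL FDR (`n.s.` = never significant/untested), allele frequency, the
gene density of its TAD (`NA` = outside every TAD), its active-state
annotation, and its host-gene context. `res$stats` gives the fraction of
input variants failing each filter (non-exclusive, so fractions can sum
above 1). The written `annotation.tsv` keeps one boolean column per
filter for every input variant; `candidates.bed` holds candidate loci.

The packaged transcriptions of the published blood (19 sites) and brain
(5 sites) candidate tables are available via `table_fixtures()` and can
be compared with `compare_gsh_sets()` (sites shared when within 15 bp).

A thin command-line driver ships in `inst/cli/gshmap.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "gshmap.R", package = "gshmapper"))')" \
    run --config sim_bundle/config.yaml --out sim_out
```

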