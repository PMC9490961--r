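Package: gshmapper
Title: Knowledge-Based Selection of Genomic Safe Harbor Sites
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies candidate genomic safe harbor (GSH) sites for
    transgene integration starting from common polymorphic mobile-element
    insertions (pMEIs). Candidate loci are screened with a sequence of
    knowledge-based filters: population allele frequency, cis-eQTL
    association (additive linear model with covariates and
    Benjamini-Hochberg FDR), co-residence in topologically associating
    domains (TADs) with oncogenes, tumor suppressors or dosage-sensitive
    genes, TAD gene density, promoter-capture Hi-C loop contacts, and
    ChromHMM chromatin-state overlap. Every filter outcome is recorded in
    a per-variant ledger with full provenance, and surviving loci are
    reported with tissue-prefixed identifiers. Includes readers for the
    common input dialects (TSV, structural-variant VCF, BED, Juicer
    arrowhead domain lists, promoter-capture interaction matrices, GTF),
    a deterministic synthetic-data generator with a planted-truth
    manifest for end-to-end testing, and a small command-line driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    vcfR,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
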