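Package: hrdscreen
Title: In Silico Screening for Null Mutations in Recessive Retinal Degeneration Genes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Screens cohorts of whole-genome variant calls for null
    (loss-of-function) alleles in a panel of genes associated with recessive
    hereditary retinal degeneration (HRD). Provides stranded multi-exon
    transcript models with genomic/CDS coordinate arithmetic, classification
    of variants into consequence categories (nonsense, frameshift, canonical
    splice-site and benign classes) with HGVS-style c. and p. naming,
    carrier-frequency estimation with binomial confidence intervals,
    extrapolation of aggregate carrier rates to missense alleles and
    unidentified genes, a consanguinity risk model, and a synthetic-data
    module that generates reference sequences, transcript models and diploid
    cohort VCFs (including a deterministic fixture cohort) so the whole
    pipeline runs without external downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
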