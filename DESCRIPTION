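Package: vartriage
Title: Consequence Classification and Private-Variant Triage for Inbred Mouse Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: An analysis pipeline for prioritizing candidate variants from
    whole-genome sequencing of an inbred mouse strain (developed around the
    TALLYHO/Jng obesity/type-2-diabetes model). Ingests consequence-annotated
    VCFs, classifies variants by Sequence Ontology term with a
    pathogenicity-priority representative-term scheme, determines variants
    private to the target strain against a multi-strain reference panel under
    a quality/depth/quorum rule, applies SIFT/PROVEAN deleteriousness
    consensus to missense variants, filters variants to QTL intervals, and
    intersects candidate variants with GWAS-trait and Mendelian-obesity
    ortholog gene sets. Includes a synthetic-data generator that emits
    annotated cohorts, strain panels, and catalogs with recorded ground truth
    so every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    stringr,
    readr,
    rlang,
    vcfR,
    rtracklayer,
    GenomicRanges,
    IRanges,
    Biostrings,
    jsonlite,
    withr,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
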