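#!/usr/bin/env Rscript
# Candidate-gene reports: intersect potentially pathogenic variants with
# trait gene sets from the synthetic GWAS catalog (via Entrez -> Ensembl ->
# mouse ortholog mapping) and with the Mendelian obesity gene list, and
# verify against the generator's expected reports.

suppressPackageStartupMessages(library(vartriage))

out <- "results/candidates"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
syn <- "results/synthetic"

hom <- filter_homozygous(read_variant_vcf(file.path(syn, "cohort.vcf")))$vset
flags <- call_private_set(hom, read_panel_calls(file.path(syn, "panel.tsv")),
                          panel_config())$flags

catalog <- read_gwas_catalog(file.path(syn, "gwas_catalog.tsv"))
e2e <- readr::read_tsv(file.path(syn, "entrez_to_ensembl.tsv"),
                       show_col_types = FALSE)
orth <- readr::read_tsv(file.path(syn, "orthologs.tsv"),
                        show_col_types = FALSE)

trait_rows <- lapply(c("obesity", "diabetes", "metabolic"), function(kw) {
  mouse <- to_mouse_genes(map_ids(trait_gene_ids(catalog, kw), e2e), orth)
  candidate_report(hom, mouse, flags, source_label = kw)
})
mend_sets <- mendelian_gene_sets(file.path(syn, "mendelian_genes.tsv"), orth)
mend_rows <- lapply(names(mend_sets), function(label) {
  candidate_report(hom, mend_sets[[label]], flags, source_label = label)
})
reports <- dplyr::bind_rows(c(trait_rows, mend_rows))
readr::write_tsv(reports, file.path(out, "candidate_reports.tsv"))
message("candidate reports:")
print(reports)

expected <- readr::read_tsv(file.path(syn, "expected_candidate_reports.tsv"),
                            show_col_types = FALSE)
same <- isTRUE(all.equal(as.data.frame(reports[order(reports$source), ]),
                         as.data.frame(expected[order(expected$source), ]),
                         check.attributes = FALSE))
message("reports equal planted expectations: ", same)
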