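#!/usr/bin/env Rscript
# Generate the synthetic study inputs: an annotated 1000-variant cohort for
# the target strain, 28-strain panel calls at every site, and the trait
# catalog / ortholog / Mendelian gene-list bundle, all with recorded ground
# truth. Everything downstream (02-05) consumes these files only.

suppressPackageStartupMessages(library(vartriage))

out <- "results/synthetic"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cfg <- sim_config(seed = 1L)          # study conditions: see sim_config()
cohort <- gen_cohort(cfg, out)
invisible(gen_panel(cohort, cfg, path = file.path(out, "panel.tsv")))
bundle <- gen_catalog_and_orthologs(cfg, cohort$truth, out)
readr::write_tsv(bundle$expected_reports,
                 file.path(out, "expected_candidate_reports.tsv"))

message("cohort:  ", cohort$vcf, "  (", cfg$n_variants, " variants, ",
        sum(cohort$truth$variant_class == "SNP"), " SNPs / ",
        sum(cohort$truth$variant_class == "INDEL"), " indels)")
message("panel:   ", file.path(out, "panel.tsv"), "  (",
        cfg$n_strains, " strains, quorum ", cfg$quorum, ")")
message("catalog: ", bundle$catalog)
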