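#!/usr/bin/env Rscript
# Consequence classification of the synthetic cohort: drop heterozygous
# calls, tabulate SO classification sets and final representative terms,
# and write sliding-window density tracks.

suppressPackageStartupMessages(library(vartriage))

out <- "results/classification"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

vset_all <- read_variant_vcf("results/synthetic/cohort.vcf")
hom <- filter_homozygous(vset_all)
message("heterozygous fractions (dropped from all further stages):")
print(hom$het_fraction)

tabs <- tabulate_sets(hom$vset)
readr::write_tsv(hom$het_fraction, file.path(out, "het_fraction.tsv"))
readr::write_tsv(tabs$set_table, file.path(out, "classification_sets.tsv"))
readr::write_tsv(tabs$final_table, file.path(out, "final_terms.tsv"))
readr::write_tsv(tabs$multi_pathogenic,
                 file.path(out, "multiset_pathogenic.tsv"))

cls <- classify_variants(hom$vset)
readr::write_tsv(cls, file.path(out, "classification.tsv"))
message(sum(cls$pathogenic), " of ", nrow(cls),
        " homozygous variants are potentially pathogenic; ",
        sum(cls$multi_set), " carry multiple classification sets")

for (chrom in names(sim_chroms())) {
  track <- window_density(hom$vset$variants, chrom,
                          sim_chroms()[[chrom]], 1e6, 1e5)
  write_density_tsv(track, file.path(out, paste0("density_", chrom, ".tsv")))
}
message("density tracks written (1 Mb windows, 100 kb steps)")
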