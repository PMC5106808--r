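---
title: "Variant triage for an inbred mouse genome: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Variant triage for an inbred mouse genome: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vartriage)
```

## The problem

Whole-genome sequencing of an inbred mouse strain such as TALLYHO/Jng
against the C57BL/6 reference produces on the order of five million SNPs
and indels. Almost all are irrelevant to any particular phenotype: they are
shared with other laboratory strains, sit in intergenic or intronic
sequence, or do not change a protein. `vartriage` implements the triage
funnel that turns this call set into a short candidate-gene list: drop
heterozygous calls, classify consequences, find variants private to the
strain, score missense changes, and intersect what remains with QTL
intervals and trait gene sets. The package deliberately starts *after*
alignment, duplicate removal, genotype calling, and consequence annotation:
it consumes an annotated VCF, not reads, and it never re-derives SO terms
or SIFT/PROVEAN scores.

## Data model and coordinate conventions

A cohort is a pair of tibbles. `variants` holds one row per (site, alt
allele): multiallelic records are decomposed, and every allele pair is
trimmed to a canonical representation (`normalize_variant()`: shared
suffix, then shared prefix, keeping one anchor base and advancing the
position). `annotations` holds one row per transcript annotation, parsed
from a pipe-delimited CSQ-style INFO field whose layout is declared by
`csq_spec()` rather than hard-coded.

All positions are 1-based (VCF convention); named intervals are 1-based and
inclusive at *both* ends, because that is how QTL boundaries are printed
(`tabw2a` = chr6:80,217,217–125,356,646, `tabw2b` =
chr6:133,853,029–144,639,629, both relative to GRCm38). Density windows are
half-open `[s, s + W)` so that tiling windows partition a chromosome
exactly. BED input is converted from its native 0-based half-open form on
read.

Trimming is representation canonicalisation only. Full left-alignment of
indels through repeat tracts requires the reference sequence and belongs to
the caller/normaliser upstream; the same-location comparison used by the
private-indel rule therefore assumes its inputs were called by the same
pipeline, which is exactly the setting the rule was designed for.

Zygosity comes from the GT field alone (`1/1` and equivalents are
`HOM_ALT`; any mixed genotype is `HET`). Heterozygous records are kept in
the data model so the heterozygosity rate is measurable —
`filter_homozygous()` reports it per class — and are then excluded from
every later stage. In an inbred strain residual heterozygosity is mostly
calling error or unfixed recent mutation, and the analyses downstream all
assume homozygous differences.

## Consequence classification

The classifier is a priority scheme, not an ontology traversal. Its inputs
are the per-transcript SO term *sets* emitted by the annotator.

- `representative_term()` collapses one set to its earliest-ranked member
  under the 19-term ordering (`so_default_order()`); e.g.
  `{intron_variant, splice_region_variant}` collapses to
  `splice_region_variant`.
- `final_classification()` applies this per distinct set and then takes the
  earliest-ranked representative across sets — the "most pathogenic" rule —
  so a variant that is missense in one transcript and intronic in another
  is finally missense. Variants with two or more distinct sets are flagged
  `multi_set` and pooled into a single "multiple classification sets" row
  in the set table, each variant counted exactly once there (whether such
  variants should additionally appear per-set is ambiguous in the source
  material; counting once keeps the table a partition).
- `is_potentially_pathogenic()` uses *any-transcript* semantics against the
  10-term set (`so_default_pathogenic()`): one frameshift transcript among
  ten intronic ones is enough. This is deliberately more sensitive than
  final-term semantics and is the filter used for candidate reports.

Terms not in the 19-term ordering (regulatory terms, for instance) rank
after all listed terms, with lexicographic tie-breaking so output is
deterministic regardless of set enumeration order. Annotation-free variants
classify as `intergenic_variant`, matching annotator behaviour for sites
outside any feature. The ordering and the pathogenic set are data, not
code: `read_so_priority()` accepts a two-column TSV so alternative dialects
can be dropped in.

## Private variants

`StrainSiteCall`-shaped panel input (one row per strain per target site,
with `status`, `qual`, `depth`) supports the asymmetric rule pair:

- SNPs: private iff **no strain has the same allele** at the location and
  the quorum holds. A strain with a *different* variant at the position
  does not disqualify a SNP.
- Indels: private iff **no strain has any variant** at the location and the
  quorum holds — stricter, because indel allele identity across call sets
  is less reliable than SNP allele identity even after normalisation.

The quorum requires ≥ 21 of 28 strains informative, where informative means
call quality ≥ 20 *and* depth ≥ 5, both inclusive ("at least"). Two
consequences worth noting. First, tightening the QC thresholds can only
shrink the informative set, so it can never make a non-private variant
private (property-tested). Second, the thresholds are applied to the
*location*, not to the disqualifying call: a low-quality matching call
still disqualifies by default. Whether that is the right reading is
genuinely open, so `panel_config(strict = TRUE)` switches to requiring the
disqualifying call itself to pass QC.

## Deleteriousness

SIFT < 0.05 and PROVEAN < −2.5, both strict. Strictness matters at the
boundary: the bundled chromosome-6 missense table contains a row scored
exactly 0.05 / −2.5, and only the strict reading reproduces the published
both-deleterious counts (5 SNPs in tabw2a, 2 in tabw2b). The text
accompanying that table also reports "29 genes deleterious by either
algorithm", which is not reachable from the printed scores under strict
thresholds (e.g. a 0.05/−1.27 row); the table was likely assembled with ≤
for inclusion but < for the bolded both-test. The package does not guess:
both thresholds are parameters, and only the strict-both counts are treated
as reproducible anchors.

Missing (N/A) scores yield no call and are excluded from the consensus:
`both` is false when either score is absent, `either` is `NA` only when
both are. When a variant is missense in several transcripts, the minimum
SIFT and minimum PROVEAN across transcripts decide — the most deleterious
transcript — with per-transcript detail retained in the annotations.

`translate_codon_change()` maps a CDS-position/codon-pair annotation to an
amino-acid substitution label via the standard genetic code, with residue
index `ceiling(cds_position / 3)` (the Cidec change, 136 C>A CGT→AGT, gives
R46S). The codons are validated for alphabet, length and inequality; the
within-codon offset is *not* checked against the CDS position, because
annotation sources are not consistent about whether the position refers to
the changed base or the codon start.

## GWAS and Mendelian gene sets

Trait gene sets are built by case-insensitive substring match on the
catalog's `DISEASE/TRAIT` column (a regex option exists), taking the union
of the `MAPPED GENE(S)`, `UPSTREAM_GENE_ID` and `DOWNSTREAM_GENE_ID`
columns without deduplication subtleties — union semantics are the only
defensible reading when a variant's mapped and flanking genes overlap. ID
conversion (Entrez→Ensembl, human→mouse ortholog) is consumed as two-column
mapping files rather than live service queries, for reproducibility;
unmapped IDs are dropped with a logged count, never fatal. A variant
annotated to several candidate genes counts once per gene in the gene
tally but once overall in the variant tallies, so `n_private_* ≤ n_*` and
`n_genes ≤ |gene_set|` always hold.

## The synthetic generator

`gen_cohort()` / `gen_panel()` / `gen_catalog_and_orthologs()` define the
study conditions used throughout the tests and the analysis scripts, with
defaults chosen once to match the target-strain setting:

- heterozygous fractions 1.37 % (SNPs) and 12.24 % (indels);
- private fractions 2.29 % (SNPs) and 15.4 % (indels);
- SNP:indel ratio ≈ 0.78 : 0.22;
- a consequence-profile library weighted to ≈ 50 % intergenic and ≈ 26 %
  intronic SNPs, with small coding, splice-region and multi-set
  components, each profile carrying a *hand-recorded* final term and
  pathogenicity flag — truth written down independently of the classifier
  it validates;
- a 28-strain panel with quorum 21 and planted privacy mechanisms: private
  sites get a clean panel (optionally with `OTHER_VARIANT` strains at SNP
  sites, exercising the rule asymmetry), non-private sites get either a
  shared allele or a quorum failure (1:3 odds by default);
- SIFT/PROVEAN scores drawn from mixtures whose components sit strictly
  inside the decision regions, so planted flags are unambiguous; a small
  fraction of scores is withheld (N/A) to exercise no-call handling;
- variant placement weighted across tabw2a, tabw2b, the rest of
  chromosome 6, and chromosome 11 (40 % of the tabw2 mass in tabw2a),
  using real GRCm38 chromosome lengths.

Every generator is a deterministic function of `sim_config(seed)`, with
offset seeds per substream so adding one generator does not perturb
another; outputs are byte-identical across runs. The generator emulates
the *statistical* structure the pipeline consumes, not real data: there is
no linkage structure, no repeat-context indel ambiguity, no correlated
panel genotypes (real strains share ancestry), and annotation sets are
drawn from a finite profile library rather than a genome annotation.
Passing tests therefore demonstrate that the rules are implemented exactly
and recover planted structure — not that the rules themselves are optimal
for real cohorts.

## Problem sizes and numerical choices

The test suite and analysis scripts run cohorts of 1,000 variants with
28-strain panels, and property suites of 50–200 randomized instances per
invariant — sizes at which every deterministic stage is exactly checkable
against brute force or planted truth in seconds. Density tracks default to
1 Mb windows; the analysis scripts step them at 100 kb, and the window
convention (unclipped terminal windows, half-open spans) is recorded in
the track header since the choice is not universal. Ties, degenerate
inputs and empty sets are all defined: empty cohorts give zero-row tables,
an empty input to the heterozygosity report is "absent", not 0 %, and an
empty term set is an error rather than a silent `intergenic_variant`.

## Limitations

- No reference-based indel left-alignment (upstream concern; see above).
- "In a protein-coding gene" is approximated by "has a gene-bearing
  annotation"; with a full annotation source one would filter on gene
  biotype.
- The supplementary set→representative mapping tables that accompany the
  original analysis are not reproduced row-for-row; the implemented rule
  ("highest-priority member") matches every printed example, and a TSV
  override hook exists for exact dialects.
- Genome-scale tallies (millions of variants, true MGP panel calls) are
  out of desk-side reach; the package reproduces the *procedure* exactly
  and the in-table worked results (tabw2 counts, R46S), not the
  genome-wide numbers.
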