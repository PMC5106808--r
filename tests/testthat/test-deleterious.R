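test_that("score thresholds are strict and handle missing values", {
  expect_true(sift_call(0.03))
  expect_false(sift_call(0.05))
  expect_true(is.na(sift_call(NA_real_)))
  expect_error(sift_call(1.2), "outside")
  expect_true(provean_call(-5.85))
  expect_false(provean_call(-2.04))
  expect_false(provean_call(-2.5))
  expect_true(is.na(provean_call(NA_real_)))
})

missense_vset <- function(sift, provean) {
  build_vset(list(list(chrom = "6", pos = 1, ref = "C", alt = "A",
                       sets = list("missense_variant"), gene = "G1",
                       sift = sift, provean = provean)))
}

test_that("consensus combines the two calls with missing-score exclusion", {
  both <- consensus_calls(missense_vset(0, -5.41))
  expect_true(both$both)
  expect_true(both$either)

  either <- consensus_calls(missense_vset(0.09, -2.66))
  expect_false(either$both)
  expect_true(either$either)

  half_na <- consensus_calls(missense_vset(NA_real_, -4.67))
  expect_false(half_na$both)
  expect_true(half_na$either)

  all_na <- consensus_calls(missense_vset(NA_real_, NA_real_))
  expect_true(is.na(all_na$either))
  expect_false(all_na$both)

  expect_error(consensus(build_vset(list(
    list(chrom = "6", pos = 1, ref = "C", alt = "A",
         sets = list("intron_variant"), gene = "G1"))), "6:1:C:A"),
    "no missense")
})

test_that("both implies either over random score pairs", {
  withr::with_seed(31, {
    sift <- sample(c(round(stats::runif(80), 3), rep(NA_real_, 20)))
    prov <- sample(c(round(stats::runif(80, -10, 4), 2), rep(NA_real_, 20)))
    for (i in seq_along(sift)) {
      out <- consensus_calls(missense_vset(sift[i], prov[i]))
      if (out$both) expect_true(out$either)
    }
  })
})

test_that("most-deleterious transcript decides multi-transcript consensus", {
  vset <- build_vset(list(list(
    chrom = "6", pos = 1, ref = "C", alt = "A",
    sets = list("missense_variant", "missense_variant&intron_variant"),
    gene = "G1")))
  vset$annotations$sift_score <- c(0.4, 0.01)
  vset$annotations$provean_score <- c(-1, -3.2)
  out <- consensus_calls(vset)
  expect_equal(out$sift_score, 0.01)
  expect_equal(out$provean_score, -3.2)
  expect_true(out$both)
})

test_that("codon changes translate through the standard genetic code", {
  r46s <- translate_codon_change(136, "CGT", "AGT")
  expect_equal(r46s$label, "R46S")
  expect_equal(r46s$residue, 46)

  d2g <- translate_codon_change(4, "GAC", "GGC")
  expect_equal(d2g$ref_aa, "D")
  expect_equal(d2g$alt_aa, "G")
  expect_equal(d2g$residue, 2)

  syn <- translate_codon_change(3, "AAA", "AAG")
  expect_true(syn$synonymous)
  expect_equal(syn$ref_aa, syn$alt_aa)

  expect_error(translate_codon_change(1, "AXA", "AAA"), "3 bases")
  expect_error(translate_codon_change(1, "AAA", "AAA"), "differ")
})

test_that("translation agrees with an independent translation oracle", {
  bases <- c("A", "C", "G", "T")
  withr::with_seed(32, {
    for (rep in 1:60) {
      ref <- paste(sample(bases, 3, replace = TRUE), collapse = "")
      alt <- ref
      while (alt == ref) {
        alt <- paste(sample(bases, 3, replace = TRUE), collapse = "")
      }
      cds <- sample.int(300, 1)
      got <- translate_codon_change(cds, ref, alt)
      oracle_ref <- as.character(
        Biostrings::translate(Biostrings::DNAString(ref),
                              no.init.codon = TRUE))
      oracle_alt <- as.character(
        Biostrings::translate(Biostrings::DNAString(alt),
                              no.init.codon = TRUE))
      expect_equal(got$ref_aa, oracle_ref)
      expect_equal(got$alt_aa, oracle_alt)
      expect_equal(got$synonymous, oracle_ref == oracle_alt)
      expect_equal(got$residue, ceiling(cds / 3))
    }
  })
})

test_that("interval summaries count planted composition and add over disjoint intervals", {
  vset <- build_vset(list(
    list(chrom = "6", pos = 90e6, ref = "C", alt = "A",
         sets = list("missense_variant"), gene = "G1",
         sift = 0.01, provean = -4),
    list(chrom = "6", pos = 95e6, ref = "C", alt = "A",
         sets = list("intron_variant"), gene = "G1"),
    list(chrom = "6", pos = 101e6, ref = "CA", alt = "C", class = "INDEL",
         sets = list("frameshift_variant"), gene = "G2"),
    list(chrom = "6", pos = 140e6, ref = "C", alt = "A",
         sets = list("missense_variant"), gene = "G3",
         sift = 0.5, provean = -3),
    list(chrom = "6", pos = 20e6, ref = "C", alt = "A")))
  out <- interval_summary(vset, tabw2_intervals())
  a <- out[out$interval == "tabw2a", ]
  b <- out[out$interval == "tabw2b", ]
  expect_equal(a$n_snps, 2)
  expect_equal(a$n_indels, 1)
  expect_equal(a$n_snps_genic, 2)
  expect_equal(a$n_snps_pathogenic, 1)
  expect_equal(a$n_snps_sift_deleterious, 1)
  expect_equal(a$n_snps_both_deleterious, 1)
  expect_equal(a$n_indels_pathogenic, 1)
  expect_equal(b$n_snps, 1)
  expect_equal(b$n_snps_provean_deleterious, 1)
  expect_equal(b$n_snps_both_deleterious, 0)

  # additivity over the two disjoint halves of tabw2a
  halves <- dplyr::bind_rows(
    genomic_interval("a1", "6", 80217217, 100e6),
    genomic_interval("a2", "6", 100e6 + 1, 125356646))
  hsum <- interval_summary(vset, halves)
  expect_equal(sum(hsum$n_snps), a$n_snps)
  expect_equal(sum(hsum$n_indels), a$n_indels)

  empty <- interval_summary(vset, genomic_interval("z", "19", 1, 1e6))
  expect_true(all(empty[, -1] == 0))
})

test_that("per-gene counts respect filters and multi-gene annotation", {
  vset <- build_vset(list(
    list(chrom = "6", pos = 1, ref = "C", alt = "A",
         sets = list("missense_variant"), gene = "A", sift = 0.01,
         provean = -4),
    list(chrom = "6", pos = 2, ref = "C", alt = "A",
         sets = list("stop_gained"), gene = "A"),
    list(chrom = "6", pos = 3, ref = "C", alt = "A",
         sets = list("missense_variant"), gene = "B", sift = 0.5,
         provean = 0),
    list(chrom = "6", pos = 4, ref = "C", alt = "A",
         sets = list("intron_variant"), gene = "B")))
  counts <- per_gene_counts(vset)
  expect_equal(counts$n[counts$gene_id == "A"], 2)
  expect_equal(counts$n[counts$gene_id == "B"], 1)

  both_only <- per_gene_counts(vset, deleterious = "both")
  expect_equal(both_only$gene_id, "A")
  expect_equal(both_only$n, 1)

  priv <- tibble::tibble(variant_id = c("6:2:C:A"), private = TRUE)
  priv_counts <- per_gene_counts(vset, private_flags = priv)
  expect_equal(priv_counts$gene_id, "A")
  expect_equal(priv_counts$n, 1)

  # a variant annotated to two genes counts once per gene
  multi <- build_vset(list(
    list(chrom = "6", pos = 9, ref = "C", alt = "A",
         sets = list("missense_variant"), gene = "A")))
  extra <- multi$annotations
  extra$gene_id <- "B"
  extra$transcript_id <- "other.t1"
  multi$annotations <- rbind(multi$annotations, extra)
  mcounts <- per_gene_counts(multi)
  expect_equal(sort(mcounts$gene_id), c("A", "B"))
  expect_equal(sum(mcounts$n), 2)
})

test_that("bundled tabw2 missense table behaves under the dual filter", {
  snps <- tabw2_missense_snps()
  expect_equal(nrow(snps), 41)
  expect_true(all(snps$chrom == "6"))
  cidec <- snps[snps$gene == "Cidec", ]
  expect_equal(cidec$sift_score, 0)
  expect_equal(cidec$provean_score, -5.85)
  aa <- translate_codon_change(136, cidec$ref_codon, cidec$alt_codon)
  expect_equal(aa$label, "R46S")
  # boundary row is excluded by strictness
  gcfc2_boundary <- snps[snps$pos == 81923813, ]
  expect_false(sift_call(gcfc2_boundary$sift_score))
  expect_false(provean_call(gcfc2_boundary$provean_score))
})
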