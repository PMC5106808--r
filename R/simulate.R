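#' Configuration for the synthetic cohort generator
#'
#' Defaults emulate the statistical structure of a deeply sequenced inbred
#' mouse strain compared against the C57BL/6 reference: a mostly homozygous
#' call set with a small heterozygous residue (1.37 % of SNPs, 12.24 % of
#' indels), a consequence mix dominated by intergenic and intronic variants,
#' a small strain-private fraction (2.29 % of SNPs, 15.4 % of indels), and a
#' 28-strain reference panel genotyped with occasional quality/depth
#' failures. All fractions are in `[0, 1]`.
#'
#' @param seed Integer seed; every generator output is a deterministic
#'   function of it.
#' @param n_variants Cohort size.
#' @param snp_fraction Fraction of variants that are SNPs (the remainder are
#'   indels).
#' @param het_fraction Named vector `c(snp = , indel = )` of heterozygous
#'   fractions per class.
#' @param private_fraction Named vector `c(snp = , indel = )` of planted
#'   strain-private fractions per class.
#' @param n_strains,quorum,min_qual,min_depth Panel geometry and QC rule
#'   (see [panel_config()]).
#' @param qc_informative_range For planted-private sites, the number of
#'   informative strains is drawn uniformly from `[quorum, n_strains]`; for
#'   planted-non-private sites failing by quorum, from `[0, quorum - 1]`.
#' @param quorum_fail_mechanism Probability that a planted-non-private
#'   variant is non-private because of quorum failure rather than a shared
#'   panel allele.
#' @param other_variant_rate Probability that a private SNP site carries a
#'   different variant in some panel strain (exercises the SNP/indel rule
#'   asymmetry; never applied to private indels).
#' @param deleterious_mix Named probabilities over missense score
#'   categories: `both`, `sift_only`, `provean_only`, `neither`,
#'   `na_sift`, `na_provean` (must sum to 1).
#' @param interval_mix Named probabilities for variant placement:
#'   `tabw2a`, `tabw2b`, `chr6_outside`, `chr11`.
#' @param n_genes Size of the mouse gene pool used for annotations.
#' @param ortholog_coverage Fraction of catalog genes given an ortholog
#'   mapping by [gen_catalog_and_orthologs()].
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_variants = 1000L,
                       snp_fraction = 0.78,
                       het_fraction = c(snp = 0.0137, indel = 0.1224),
                       private_fraction = c(snp = 0.0229, indel = 0.154),
                       n_strains = 28L, quorum = 21L,
                       min_qual = 20, min_depth = 5,
                       qc_informative_range = NULL,
                       quorum_fail_mechanism = 0.25,
                       other_variant_rate = 0.15,
                       deleterious_mix = c(both = 0.15, sift_only = 0.10,
                                           provean_only = 0.10,
                                           neither = 0.55, na_sift = 0.05,
                                           na_provean = 0.05),
                       interval_mix = c(tabw2a = 0.35, tabw2b = 0.10,
                                        chr6_outside = 0.15, chr11 = 0.40),
                       n_genes = 50L,
                       ortholog_coverage = 0.9) {
  fracs <- c(snp_fraction, het_fraction, private_fraction,
             quorum_fail_mechanism, other_variant_rate, ortholog_coverage)
  stopifnot(all(fracs >= 0 & fracs <= 1))
  stopifnot(abs(sum(deleterious_mix) - 1) < 1e-8,
            abs(sum(interval_mix) - 1) < 1e-8)
  stopifnot(quorum > 0, quorum <= n_strains)
  structure(list(
    seed = as.integer(seed), n_variants = as.integer(n_variants),
    snp_fraction = snp_fraction, het_fraction = het_fraction,
    private_fraction = private_fraction,
    n_strains = as.integer(n_strains), quorum = as.integer(quorum),
    min_qual = min_qual, min_depth = min_depth,
    quorum_fail_mechanism = quorum_fail_mechanism,
    other_variant_rate = other_variant_rate,
    deleterious_mix = deleterious_mix, interval_mix = interval_mix,
    n_genes = as.integer(n_genes), ortholog_coverage = ortholog_coverage),
    class = "sim_config")
}

# consequence-set profile library; `sets` holds the per-transcript SO term
# sets a variant of that profile carries, and `final`/`pathogenic` are the
# hand-recorded truth used to validate the classifier (independent of it)
so_profiles <- function() {
  p <- function(name, sets, final, pathogenic, missense, w_snp, w_indel) {
    tibble::tibble(name = name, sets = list(sets), final = final,
                   pathogenic = pathogenic, missense = missense,
                   w_snp = w_snp, w_indel = w_indel)
  }
  dplyr::bind_rows(
    p("intergenic", list(), "intergenic_variant", FALSE, FALSE, 0.50, 0.49),
    p("intron", list("intron_variant"), "intron_variant", FALSE, FALSE,
      0.255, 0.28),
    p("upstream", list("upstream_gene_variant"), "upstream_gene_variant",
      FALSE, FALSE, 0.08, 0.08),
    p("downstream", list("downstream_gene_variant"),
      "downstream_gene_variant", FALSE, FALSE, 0.07, 0.07),
    p("utr3", list("3_prime_UTR_variant"), "3_prime_UTR_variant", FALSE,
      FALSE, 0.01, 0.01),
    p("noncoding", list("non_coding_transcript_variant"),
      "non_coding_transcript_variant", FALSE, FALSE, 0.01, 0.03),
    p("synonymous", list("synonymous_variant"), "synonymous_variant",
      FALSE, FALSE, 0.02, 0),
    p("missense", list("missense_variant"), "missense_variant", TRUE, TRUE,
      0.02, 0),
    p("splice_region", list(c("intron_variant", "splice_region_variant")),
      "splice_region_variant", TRUE, FALSE, 0.01, 0.005),
    p("multi_missense_intron",
      list("missense_variant", "intron_variant"),
      "missense_variant", TRUE, TRUE, 0.015, 0),
    p("multi_up_down",
      list("upstream_gene_variant", "downstream_gene_variant"),
      "upstream_gene_variant", FALSE, FALSE, 0.015, 0.01),
    p("stop_gained", list("stop_gained"), "stop_gained", TRUE, FALSE,
      0.005, 0),
    p("frameshift", list("frameshift_variant"), "frameshift_variant", TRUE,
      FALSE, 0, 0.01),
    p("inframe_del", list("inframe_deletion"), "inframe_deletion", TRUE,
      FALSE, 0, 0.0025),
    p("inframe_ins", list("inframe_insertion"), "inframe_insertion", TRUE,
      FALSE, 0, 0.0025),
    p("multi_frameshift_intron",
      list("frameshift_variant", "intron_variant"),
      "frameshift_variant", TRUE, FALSE, 0, 0.01)
  )
}

# non-synonymous codon templates: ref codon, alt codon, changed offset
codon_templates <- function() {
  tibble::tibble(
    ref = c("CGT", "GAC", "ACC", "CGG", "TCG", "AGT"),
    alt = c("AGT", "GGC", "ATC", "TGG", "TTG", "TGT"),
    offset = c(1L, 2L, 2L, 1L, 2L, 1L))
}

#' Chromosomes of the synthetic genome
#'
#' Named lengths (GRCm38 sizes for chromosomes 6 and 11) used by the
#' generator and as the default density-track geometry.
#'
#' @return Named numeric vector of chromosome lengths.
#' @export
sim_chroms <- function() {
  c("6" = 149736546, "11" = 122082543)
}

draw_positions <- function(config, n) {
  iv <- tabw2_intervals()
  region <- sample(names(config$interval_mix), n, replace = TRUE,
                   prob = config$interval_mix)
  pos <- integer(n)
  chrom <- character(n)
  for (i in seq_len(n)) {
    if (region[i] == "tabw2a") {
      chrom[i] <- "6"
      pos[i] <- iv$start[1] - 1L +
        sample.int(iv$end[1] - iv$start[1] + 1L, 1)
    } else if (region[i] == "tabw2b") {
      chrom[i] <- "6"
      pos[i] <- iv$start[2] - 1L +
        sample.int(iv$end[2] - iv$start[2] + 1L, 1)
    } else if (region[i] == "chr6_outside") {
      chrom[i] <- "6"
      repeat {
        cand <- sample.int(sim_chroms()[["6"]], 1)
        inside <- any(cand >= iv$start & cand <= iv$end)
        if (!inside) break
      }
      pos[i] <- cand
    } else {
      chrom[i] <- "11"
      pos[i] <- sample.int(sim_chroms()[["11"]], 1)
    }
  }
  tibble::tibble(chrom = chrom, pos = pos, region = region)
}

draw_scores <- function(category) {
  sift_del <- function(n) round(stats::runif(n, 0, 0.049), 3)
  sift_tol <- function(n) round(stats::runif(n, 0.06, 1), 3)
  prov_del <- function(n) round(stats::runif(n, -8, -2.6), 2)
  prov_tol <- function(n) round(stats::runif(n, -2.4, 2), 2)
  n <- length(category)
  sift <- rep(NA_real_, n)
  prov <- rep(NA_real_, n)
  for (cat in unique(category)) {
    idx <- which(category == cat)
    k <- length(idx)
    sift[idx] <- switch(cat,
      both = sift_del(k), sift_only = sift_del(k),
      provean_only = sift_tol(k), neither = sift_tol(k),
      na_sift = rep(NA_real_, k), na_provean = sift_tol(k))
    prov[idx] <- switch(cat,
      both = prov_del(k), provean_only = prov_del(k),
      sift_only = prov_tol(k), neither = prov_tol(k),
      na_sift = prov_tol(k), na_provean = rep(NA_real_, k))
  }
  tibble::tibble(sift_score = sift, provean_score = prov)
}

#' Generate an annotated synthetic cohort
#'
#' Emits a consequence-annotated VCF plus a ground-truth table recording,
#' per variant, the planted zygosity, consequence profile, final SO term,
#' pathogenicity, gene assignment, SIFT/PROVEAN scores and flags, interval
#' membership, and strain-privacy flag. The emitted VCF re-parses through
#' [read_variant_vcf()] into exactly the planted records. Byte-identical
#' across runs for a fixed config.
#'
#' @param config A [sim_config()].
#' @param dir Output directory (created if needed).
#' @return List: `vcf` (path), `truth` (tibble), `config`.
#' @export
gen_cohort <- function(config = sim_config(), dir = tempfile("cohort")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  truth <- withr::with_seed(config$seed, gen_cohort_truth(config))
  vcf <- file.path(dir, "cohort.vcf")
  write_cohort_vcf(truth, vcf)
  readr::write_tsv(truth |> dplyr::select(-"sets"),
                   file.path(dir, "truth.tsv"))
  list(vcf = vcf, truth = truth, config = config)
}

gen_cohort_truth <- function(config) {
  n <- config$n_variants
  profs <- so_profiles()
  loc <- draw_positions(config, 3L * n)  # oversample, then dedupe
  loc <- loc[!duplicated(paste(loc$chrom, loc$pos)), ][seq_len(n), ]
  is_snp <- stats::runif(n) < config$snp_fraction
  class <- ifelse(is_snp, "SNP", "INDEL")

  # alleles
  bases <- c("A", "C", "G", "T")
  ref <- character(n)
  alt <- character(n)
  for (i in seq_len(n)) {
    if (is_snp[i]) {
      pick <- sample(bases, 2)
      ref[i] <- pick[1]; alt[i] <- pick[2]
    } else {
      anchor <- sample(bases, 1)
      tail_seq <- paste(sample(bases, sample(1:5, 1), replace = TRUE),
                        collapse = "")
      if (stats::runif(1) < 0.5) {  # insertion
        ref[i] <- anchor; alt[i] <- paste0(anchor, tail_seq)
      } else {                      # deletion
        ref[i] <- paste0(anchor, tail_seq); alt[i] <- anchor
      }
    }
  }

  # zygosity per class
  zyg <- ifelse(
    stats::runif(n) < ifelse(is_snp, config$het_fraction[["snp"]],
                             config$het_fraction[["indel"]]),
    "HET", "HOM_ALT")

  # consequence profile per class
  profile <- character(n)
  profile[is_snp] <- sample(profs$name, sum(is_snp), replace = TRUE,
                            prob = profs$w_snp)
  profile[!is_snp] <- sample(profs$name, sum(!is_snp), replace = TRUE,
                             prob = profs$w_indel)
  pi <- match(profile, profs$name)

  gene_pool <- sprintf("MGENE%03d", seq_len(config$n_genes))
  gene <- ifelse(profile == "intergenic", NA_character_,
                 sample(gene_pool, n, replace = TRUE))

  # missense scores
  cat <- rep(NA_character_, n)
  mis <- profs$missense[pi]
  cat[mis] <- sample(names(config$deleterious_mix), sum(mis),
                     replace = TRUE, prob = config$deleterious_mix)
  scores <- draw_scores(ifelse(is.na(cat), "neither", cat))
  scores$sift_score[!mis] <- NA_real_
  scores$provean_score[!mis] <- NA_real_

  sift_flag <- ifelse(is.na(scores$sift_score), NA,
                      scores$sift_score < 0.05)
  prov_flag <- ifelse(is.na(scores$provean_score), NA,
                      scores$provean_score < -2.5)

  # codon changes for missense variants
  tmpl <- codon_templates()
  ti <- sample.int(nrow(tmpl), n, replace = TRUE)
  residue <- sample.int(400L, n, replace = TRUE)
  cds_pos <- 3L * (residue - 1L) + tmpl$offset[ti]

  priv <- ifelse(
    stats::runif(n) < ifelse(is_snp, config$private_fraction[["snp"]],
                             config$private_fraction[["indel"]]),
    TRUE, FALSE)

  iv <- tabw2_intervals()
  tibble::tibble(
    variant_id = make_variant_id(loc$chrom, loc$pos, ref, alt),
    chrom = loc$chrom, pos = loc$pos, ref = ref, alt = alt,
    variant_class = class, zygosity = zyg,
    qual = round(stats::runif(n, 30, 200), 1),
    depth = sample(10:80, n, replace = TRUE),
    profile = profile,
    sets = profs$sets[pi],
    final_term = profs$final[pi],
    pathogenic = profs$pathogenic[pi],
    multi_set = lengths(profs$sets[pi]) >= 2,
    missense = mis,
    gene_id = gene,
    sift_score = scores$sift_score,
    provean_score = scores$provean_score,
    sift_deleterious = sift_flag,
    provean_deleterious = prov_flag,
    both_deleterious = isTRUE_vec(sift_flag) & isTRUE_vec(prov_flag),
    either_deleterious = ifelse(is.na(sift_flag) & is.na(prov_flag), NA,
                                isTRUE_vec(sift_flag) |
                                  isTRUE_vec(prov_flag)),
    ref_codon = ifelse(mis, tmpl$ref[ti], NA_character_),
    alt_codon = ifelse(mis, tmpl$alt[ti], NA_character_),
    cds_position = ifelse(mis, cds_pos, NA_integer_),
    residue = ifelse(mis, residue, NA_integer_),
    in_tabw2a = loc$chrom == iv$chrom[1] & loc$pos >= iv$start[1] &
      loc$pos <= iv$end[1],
    in_tabw2b = loc$chrom == iv$chrom[2] & loc$pos >= iv$start[2] &
      loc$pos <= iv$end[2],
    private = priv
  ) |> dplyr::arrange(.data$chrom, .data$pos)
}

csq_for_variant <- function(row) {
  sets <- row$sets[[1]]
  if (length(sets) == 0) return(NA_character_)
  code <- Biostrings::GENETIC_CODE
  entries <- vapply(seq_along(sets), function(k) {
    terms <- sets[[k]]
    is_mis <- "missense_variant" %in% terms
    tx <- sprintf("%s.t%d", row$gene_id, k)
    paste(
      row$alt, row$gene_id, tx, paste(terms, collapse = "&"),
      if (is_mis && !is.na(row$sift_score)) row$sift_score else "",
      if (is_mis && !is.na(row$provean_score)) row$provean_score else "",
      if (is_mis) row$cds_position else "",
      if (is_mis) paste0(row$ref_codon, "/", row$alt_codon) else "",
      if (is_mis) paste0(code[[row$ref_codon]], "/",
                         code[[row$alt_codon]]) else "",
      if (is_mis) row$residue else "",
      sep = "|")
  }, character(1))
  paste(entries, collapse = ",")
}

write_cohort_vcf <- function(truth, path) {
  chroms <- sim_chroms()
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", names(chroms),
            as.integer(chroms)),
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste0("##INFO=<ID=CSQ,Number=.,Type=String,Description=\"",
           "Consequence annotations: Allele|Gene|Feature|Consequence|",
           "SIFT|PROVEAN|CDS_position|Codons|Amino_acids|",
           "Protein_position\">"),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "TARGET", sep = "\t"))
  body <- vapply(seq_len(nrow(truth)), function(i) {
    row <- truth[i, ]
    csq <- csq_for_variant(row)
    info <- paste0("DP=", row$depth,
                   if (!is.na(csq)) paste0(";CSQ=", csq) else "")
    gt <- if (row$zygosity == "HOM_ALT") "1/1" else "0/1"
    paste(row$chrom, format(row$pos, scientific = FALSE, trim = TRUE), ".",
          row$ref, row$alt,
          format(row$qual, nsmall = 1, trim = TRUE), "PASS", info,
          "GT:DP", paste0(gt, ":", row$depth), sep = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Generate panel calls consistent with planted privacy
#'
#' For each cohort variant, emits one call per panel strain such that the
#' private-variant rules recover the planted flag exactly: private sites
#' have no disqualifying strain call and meet the informative quorum
#' (private SNPs may still see `OTHER_VARIANT` strains, which the SNP rule
#' ignores); non-private sites either carry the same allele in at least one
#' strain or fail the quorum, chosen per `config$quorum_fail_mechanism`.
#'
#' @param cohort Output of [gen_cohort()] (or its `truth` tibble).
#' @param config The [sim_config()] used for the cohort.
#' @param path Optional path to also write the calls as TSV.
#' @return Tibble of panel calls (`chrom`, `pos`, `strain`, `status`,
#'   `qual`, `depth`).
#' @export
gen_panel <- function(cohort, config = sim_config(), path = NULL) {
  truth <- if (is.data.frame(cohort)) cohort else cohort$truth
  strains <- sprintf("strain%02d", seq_len(config$n_strains))
  calls <- withr::with_seed(config$seed + 1L, {
    purrr::map(seq_len(nrow(truth)), function(i) {
      row <- truth[i, ]
      gen_panel_site(row, strains, config)
    }) |> dplyr::bind_rows()
  })
  if (!is.null(path)) readr::write_tsv(calls, path)
  calls
}

gen_panel_site <- function(row, strains, config) {
  ns <- length(strains)
  qual_pass <- function(k) round(stats::runif(k, config$min_qual, 90), 1)
  depth_pass <- function(k) sample(config$min_depth:60, k, replace = TRUE)
  status <- rep("NO_VARIANT", ns)
  if (row$private) {
    n_inf <- sample(config$quorum:ns, 1)
    if (row$variant_class == "SNP" &&
        stats::runif(1) < config$other_variant_rate) {
      status[sample.int(ns, sample(1:2, 1))] <- "OTHER_VARIANT"
    }
  } else {
    if (stats::runif(1) < config$quorum_fail_mechanism) {
      n_inf <- sample(0:(config$quorum - 1L), 1)
    } else {
      n_inf <- sample(config$quorum:ns, 1)
      k_shared <- sample(1:3, 1)
      if (row$variant_class == "SNP") {
        status[sample.int(ns, k_shared)] <- "SAME_ALLELE"
      } else {
        # any variant at the location disqualifies an indel
        disq <- sample(c("SAME_ALLELE", "OTHER_VARIANT"), k_shared,
                       replace = TRUE)
        status[sample.int(ns, k_shared)] <- disq
      }
    }
  }
  informative <- rep(FALSE, ns)
  informative[sample.int(ns, n_inf)] <- TRUE
  qual <- numeric(ns)
  depth <- integer(ns)
  qual[informative] <- qual_pass(sum(informative))
  depth[informative] <- depth_pass(sum(informative))
  if (any(!informative)) {
    k <- sum(!informative)
    mode <- sample(c("qual", "depth", "both"), k, replace = TRUE)
    qual[!informative] <- ifelse(mode %in% c("qual", "both"),
                                 round(stats::runif(k, 0,
                                                    config$min_qual - 0.5),
                                       1),
                                 qual_pass(k))
    depth[!informative] <- ifelse(mode %in% c("depth", "both"),
                                  sample(0:(config$min_depth - 1L), k,
                                         replace = TRUE),
                                  depth_pass(k))
  }
  tibble::tibble(chrom = row$chrom, pos = row$pos, strain = strains,
                 status = status, qual = qual, depth = depth)
}

#' Generate a trait catalog, ID maps and Mendelian gene list
#'
#' Plants trait keywords (`obesity`, `diabetes`, `metabolic`) into a
#' GWAS-catalog-format table whose gene columns carry synthetic Entrez IDs,
#' together with an Entrez-to-Ensembl map, a human-to-mouse ortholog map
#' covering `config$ortholog_coverage` of the genes, and a Mendelian
#' obesity gene list. The ground truth records the mouse gene set each
#' trait should resolve to and the expected candidate-report rows computed
#' from the cohort truth.
#'
#' @param config A [sim_config()].
#' @param truth Cohort truth tibble from [gen_cohort()].
#' @param dir Output directory for the TSVs.
#' @return List: paths `catalog`, `entrez_to_ensembl`, `orthologs`,
#'   `mendelian`; `expected_gene_sets` (named list of mouse gene IDs);
#'   `expected_reports` (tibble of candidate-report rows).
#' @export
gen_catalog_and_orthologs <- function(config = sim_config(), truth,
                                      dir = tempfile("catalog")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gene_pool <- sprintf("MGENE%03d", seq_len(config$n_genes))
  out <- withr::with_seed(config$seed + 2L, {
    # a synthetic ID universe: one Entrez and one human Ensembl ID per
    # mouse pool gene, orthology dropped for a (1 - coverage) fraction
    n <- config$n_genes
    entrez <- sprintf("%d", 1000L + seq_len(n))
    ensg <- sprintf("ENSG%011d", seq_len(n))
    covered <- stats::runif(n) < config$ortholog_coverage
    traits <- list(
      obesity = c("Obesity (adult)", "Obesity-related traits",
                  "Childhood obesity"),
      diabetes = c("Type 2 diabetes", "Gestational diabetes"),
      metabolic = c("Metabolic syndrome", "Metabolic traits"))
    decoys <- c("Height", "Asthma", "Eye color")
    trait_genes <- lapply(c(obesity = 1, diabetes = 2, metabolic = 3),
                          function(dummy) sort(sample.int(n, 6)))
    rows <- list()
    for (tn in names(traits)) {
      idx <- trait_genes[[tn]]
      labels <- sample(traits[[tn]], length(idx), replace = TRUE)
      for (j in seq_along(idx)) {
        where <- sample(c("mapped", "upstream", "downstream"), 1)
        rows[[length(rows) + 1L]] <- tibble::tibble(
          `DISEASE/TRAIT` = labels[j],
          `MAPPED GENE(S)` = if (where == "mapped") entrez[idx[j]] else
            NA_character_,
          UPSTREAM_GENE_ID = if (where == "upstream") entrez[idx[j]] else
            NA_character_,
          DOWNSTREAM_GENE_ID = if (where == "downstream") entrez[idx[j]]
          else NA_character_)
      }
    }
    for (d in decoys) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        `DISEASE/TRAIT` = d,
        `MAPPED GENE(S)` = entrez[sample.int(n, 1)],
        UPSTREAM_GENE_ID = NA_character_,
        DOWNSTREAM_GENE_ID = NA_character_)
    }
    catalog <- dplyr::bind_rows(rows)

    mend_categories <- c("syndromic obesity", "non-syndromic obesity",
                         "non-syndromic lipodystrophy")
    mend_idx <- sample.int(n, 6)
    mendelian <- tibble::tibble(
      gene = ensg[mend_idx],
      category = rep(mend_categories, each = 2))

    list(catalog = catalog, entrez = entrez, ensg = ensg,
         covered = covered, trait_genes = trait_genes,
         mendelian = mendelian, mend_idx = mend_idx)
  })

  catalog_path <- file.path(dir, "gwas_catalog.tsv")
  e2e_path <- file.path(dir, "entrez_to_ensembl.tsv")
  orth_path <- file.path(dir, "orthologs.tsv")
  mend_path <- file.path(dir, "mendelian_genes.tsv")
  readr::write_tsv(out$catalog, catalog_path)
  readr::write_tsv(tibble::tibble(entrez_id = out$entrez,
                                  ensembl_id = out$ensg), e2e_path)
  readr::write_tsv(tibble::tibble(human_id = out$ensg[out$covered],
                                  mouse_id = gene_pool[out$covered]),
                   orth_path)
  readr::write_tsv(out$mendelian, mend_path)

  expected_sets <- lapply(out$trait_genes, function(idx) {
    sort(gene_pool[intersect(idx, which(out$covered))])
  })
  mend_by_cat <- split(out$mend_idx,
                       rep(c("syndromic obesity", "non-syndromic obesity",
                             "non-syndromic lipodystrophy"), each = 2))
  expected_sets <- c(expected_sets, lapply(mend_by_cat, function(idx) {
    sort(gene_pool[intersect(idx, which(out$covered))])
  }))

  expected_reports <- purrr::imap(expected_sets, function(gs, label) {
    expected_report_from_truth(truth, gs, label)
  }) |> dplyr::bind_rows()

  list(catalog = catalog_path, entrez_to_ensembl = e2e_path,
       orthologs = orth_path, mendelian = mend_path,
       expected_gene_sets = expected_sets,
       expected_reports = expected_reports)
}

# candidate-report truth computed directly from planted flags (no pipeline
# code involved); restricted to homozygous variants as the pipeline is
expected_report_from_truth <- function(truth, gene_set, label) {
  sub <- truth[truth$zygosity == "HOM_ALT" & truth$pathogenic &
                 !is.na(truth$gene_id) & truth$gene_id %in% gene_set, ]
  tibble::tibble(
    source = label,
    n_genes = length(unique(sub$gene_id)),
    n_snps = sum(sub$variant_class == "SNP"),
    n_indels = sum(sub$variant_class == "INDEL"),
    n_private_snps = sum(sub$variant_class == "SNP" & sub$private),
    n_private_indels = sum(sub$variant_class == "INDEL" & sub$private))
}
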