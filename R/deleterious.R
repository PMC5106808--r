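#' SIFT and PROVEAN deleteriousness calls
#'
#' Strict thresholds as conventionally reported: SIFT deleterious when
#' score < 0.05, PROVEAN deleterious when score < -2.5. A missing score
#' yields `NA` (no call) and is excluded from consensus.
#'
#' @param score Numeric vector of scores (`NA` allowed). SIFT scores must lie
#'   in `[0, 1]`.
#' @param threshold Decision threshold (exposed so alternative conventions,
#'   e.g. `<=`, can be emulated by nudging it).
#' @return Logical vector with `NA` where the score is missing.
#' @export
sift_call <- function(score, threshold = 0.05) {
  bad <- !is.na(score) & (score < 0 | score > 1)
  if (any(bad)) stop("SIFT score outside [0, 1]", call. = FALSE)
  ifelse(is.na(score), NA, score < threshold)
}

#' @rdname sift_call
#' @export
provean_call <- function(score, threshold = -2.5) {
  ifelse(is.na(score), NA, score < threshold)
}

#' Per-variant SIFT/PROVEAN consensus
#'
#' For each variant carrying at least one missense annotation, takes the
#' minimum SIFT and minimum PROVEAN score across its missense transcripts
#' (the most deleterious transcript decides) and combines the two calls:
#' `both` requires both scores present and both deleterious; `either` is
#' TRUE when any available score is deleterious, and `NA` only when neither
#' score is available.
#'
#' @param vset Variant set.
#' @param sift_threshold,provean_threshold Passed to [sift_call()] /
#'   [provean_call()].
#' @return Tibble: `variant_id`, `sift_score`, `provean_score`
#'   (per-variant minima), `sift_deleterious`, `provean_deleterious`,
#'   `either`, `both` — missense variants only.
#' @export
consensus_calls <- function(vset, sift_threshold = 0.05,
                            provean_threshold = -2.5) {
  ann <- vset$annotations
  missense <- ann |>
    dplyr::filter(purrr::map_lgl(.data$so_terms, function(s) {
      "missense_variant" %in% split_set(s)
    }))
  if (nrow(missense) == 0) {
    return(tibble::tibble(variant_id = character(), sift_score = numeric(),
                          provean_score = numeric(),
                          sift_deleterious = logical(),
                          provean_deleterious = logical(),
                          either = logical(), both = logical()))
  }
  min_or_na <- function(x) if (all(is.na(x))) NA_real_ else min(x, na.rm = TRUE)
  missense |>
    dplyr::group_by(.data$variant_id) |>
    dplyr::summarise(sift_score = min_or_na(.data$sift_score),
                     provean_score = min_or_na(.data$provean_score),
                     .groups = "drop") |>
    dplyr::mutate(
      sift_deleterious = sift_call(.data$sift_score, sift_threshold),
      provean_deleterious = provean_call(.data$provean_score,
                                         provean_threshold),
      either = dplyr::case_when(
        is.na(.data$sift_deleterious) & is.na(.data$provean_deleterious) ~ NA,
        TRUE ~ isTRUE_vec(.data$sift_deleterious) |
          isTRUE_vec(.data$provean_deleterious)),
      both = isTRUE_vec(.data$sift_deleterious) &
        isTRUE_vec(.data$provean_deleterious))
}

isTRUE_vec <- function(x) !is.na(x) & x

#' Consensus for a single missense variant
#'
#' Convenience wrapper over [consensus_calls()] for one variant; errors if
#' the variant carries no missense annotation.
#'
#' @param vset Variant set.
#' @param variant_id The variant to assess.
#' @inheritParams consensus_calls
#' @return One-row consensus tibble.
#' @export
consensus <- function(vset, variant_id, sift_threshold = 0.05,
                      provean_threshold = -2.5) {
  out <- consensus_calls(vset, sift_threshold, provean_threshold)
  row <- dplyr::filter(out, .data$variant_id == !!variant_id)
  if (nrow(row) == 0) {
    stop("variant ", variant_id, " has no missense annotation",
         call. = FALSE)
  }
  row
}

#' Translate a codon change into an amino-acid substitution
#'
#' Residue index is `ceiling(cds_position / 3)`; amino acids come from the
#' standard genetic code. Identical translations are reported as synonymous.
#'
#' @param cds_position 1-based nucleotide position of the change in the
#'   coding sequence.
#' @param ref_codon,alt_codon 3-base codons over A/C/G/T (case-insensitive;
#'   must differ).
#' @return List: `ref_aa`, `alt_aa` (single-letter), `residue`,
#'   `synonymous`, and `label` (e.g. `"R46S"`, or `"K46K (synonymous)"`).
#' @export
translate_codon_change <- function(cds_position, ref_codon, alt_codon) {
  ref_codon <- toupper(ref_codon)
  alt_codon <- toupper(alt_codon)
  ok <- function(x) nchar(x) == 3 && grepl("^[ACGT]{3}$", x)
  if (!ok(ref_codon) || !ok(alt_codon)) {
    stop("codons must be 3 bases over A/C/G/T", call. = FALSE)
  }
  if (ref_codon == alt_codon) {
    stop("ref and alt codons must differ", call. = FALSE)
  }
  stopifnot(cds_position >= 1)
  code <- Biostrings::GENETIC_CODE
  ref_aa <- unname(code[[ref_codon]])
  alt_aa <- unname(code[[alt_codon]])
  residue <- ceiling(cds_position / 3)
  synonymous <- ref_aa == alt_aa
  label <- if (synonymous) {
    sprintf("%s%d%s (synonymous)", ref_aa, residue, alt_aa)
  } else {
    sprintf("%s%d%s", ref_aa, residue, alt_aa)
  }
  list(ref_aa = ref_aa, alt_aa = alt_aa, residue = residue,
       synonymous = synonymous, label = label)
}

# variant_ids having >=1 annotation with a gene (proxy for "in a
# protein-coding gene"; the generator and VEP both leave gene_id empty for
# intergenic consequences)
genic_variant_ids <- function(vset) {
  unique(vset$annotations$variant_id[!is.na(vset$annotations$gene_id)])
}

#' Per-interval variant summary
#'
#' One row per interval with the counts used for QTL triage: total SNPs and
#' indels, how many lie in genes, how many are potentially pathogenic, and
#' for SNPs how many are SIFT- or PROVEAN-deleterious (per-variant minima
#' across missense transcripts, strict thresholds).
#'
#' @param vset Variant set.
#' @param intervals Interval tibble ([genomic_interval()] rows).
#' @param priority An [so_priority()].
#' @inheritParams consensus_calls
#' @return Tibble, one row per interval.
#' @export
interval_summary <- function(vset, intervals, priority = so_priority(),
                             sift_threshold = 0.05,
                             provean_threshold = -2.5) {
  cls <- classify_variants(vset, priority)
  cons <- consensus_calls(vset, sift_threshold, provean_threshold)
  genic <- genic_variant_ids(vset)
  v <- vset$variants |>
    dplyr::left_join(cls, by = "variant_id") |>
    dplyr::left_join(cons, by = "variant_id") |>
    dplyr::mutate(genic = .data$variant_id %in% genic)
  purrr::map(seq_len(nrow(intervals)), function(i) {
    iv <- intervals[i, ]
    sub <- v[in_interval(v, iv), ]
    snp <- dplyr::filter(sub, .data$variant_class == "SNP")
    ind <- dplyr::filter(sub, .data$variant_class == "INDEL")
    tibble::tibble(
      interval = iv$name,
      n_snps = nrow(snp),
      n_snps_genic = sum(snp$genic),
      n_snps_pathogenic = sum(snp$pathogenic),
      n_snps_sift_deleterious = sum(isTRUE_vec(snp$sift_deleterious)),
      n_snps_provean_deleterious = sum(isTRUE_vec(snp$provean_deleterious)),
      n_snps_both_deleterious = sum(isTRUE_vec(snp$both)),
      n_indels = nrow(ind),
      n_indels_genic = sum(ind$genic),
      n_indels_pathogenic = sum(ind$pathogenic))
  }) |> dplyr::bind_rows()
}

#' Count qualifying variants per gene
#'
#' Counts, per gene, the variants that pass a caller-chosen combination of
#' filters. A variant annotated to several genes counts once in each; genes
#' with no qualifying variant are omitted.
#'
#' @param vset Variant set.
#' @param pathogenic_only Keep only potentially pathogenic variants
#'   (any-transcript semantics).
#' @param private_flags Optional tibble (`variant_id`, `private`); when
#'   given, only private variants are counted.
#' @param deleterious One of `"none"`, `"sift"`, `"provean"`, `"either"`,
#'   `"both"`: additionally require the corresponding consensus flag.
#' @param priority An [so_priority()].
#' @inheritParams consensus_calls
#' @return Tibble (`gene_id`, `n`), descending by count.
#' @export
per_gene_counts <- function(vset, pathogenic_only = TRUE,
                            private_flags = NULL,
                            deleterious = c("none", "sift", "provean",
                                            "either", "both"),
                            priority = so_priority(),
                            sift_threshold = 0.05,
                            provean_threshold = -2.5) {
  deleterious <- match.arg(deleterious)
  keep <- vset$variants$variant_id
  if (pathogenic_only) {
    cls <- classify_variants(vset, priority)
    keep <- intersect(keep, cls$variant_id[cls$pathogenic])
  }
  if (!is.null(private_flags)) {
    keep <- intersect(keep,
                      private_flags$variant_id[private_flags$private])
  }
  if (deleterious != "none") {
    cons <- consensus_calls(vset, sift_threshold, provean_threshold)
    col <- switch(deleterious, sift = "sift_deleterious",
                  provean = "provean_deleterious",
                  either = "either", both = "both")
    keep <- intersect(keep, cons$variant_id[isTRUE_vec(cons[[col]])])
  }
  vset$annotations |>
    dplyr::filter(.data$variant_id %in% keep, !is.na(.data$gene_id)) |>
    dplyr::distinct(.data$variant_id, .data$gene_id) |>
    dplyr::count(.data$gene_id, name = "n") |>
    dplyr::arrange(dplyr::desc(.data$n), .data$gene_id)
}

#' Scored missense SNPs in the tabw2 QTL intervals
#'
#' Loads the bundled table of chromosome-6 missense SNPs in the tabw2a and
#' tabw2b obesity-QTL intervals of the TALLYHO/Jng mouse (GRCm38
#' coordinates), with their ref/alt codons, amino-acid changes and
#' SIFT/PROVEAN scores. `N/A` scores are read as missing.
#'
#' @return Tibble: `gene`, `chrom`, `pos`, `ref_codon`, `alt_codon`,
#'   `aa_ref`, `aa_alt`, `exon`, `sift_score`, `provean_score`.
#' @export
tabw2_missense_snps <- function() {
  path <- system.file("extdata", "tabw2_missense_snps.tsv",
                      package = "vartriage", mustWork = TRUE)
  readr::read_tsv(path, na = "N/A", comment = "#", col_types = readr::cols(
    gene = readr::col_character(), chrom = readr::col_character(),
    pos = readr::col_double(), ref_codon = readr::col_character(),
    alt_codon = readr::col_character(), aa_ref = readr::col_character(),
    aa_alt = readr::col_character(), exon = readr::col_character(),
    sift_score = readr::col_double(),
    provean_score = readr::col_double()))
}

#' Both-deleterious SNP counts in the tabw2 intervals
#'
#' Applies the strict dual-threshold consensus (SIFT < `sift_threshold` and
#' PROVEAN < `provean_threshold`) to the bundled tabw2 missense table and
#' counts qualifying SNPs (and the distinct genes carrying them) per
#' interval.
#'
#' @inheritParams consensus_calls
#' @param snps Scored missense table; defaults to [tabw2_missense_snps()].
#' @param intervals Interval tibble; defaults to [tabw2_intervals()].
#' @return Tibble: `interval`, `n_snps_both_deleterious`, `n_genes`.
#' @export
tabw2_deleterious_counts <- function(sift_threshold = 0.05,
                                     provean_threshold = -2.5,
                                     snps = tabw2_missense_snps(),
                                     intervals = tabw2_intervals()) {
  both <- isTRUE_vec(sift_call(snps$sift_score, sift_threshold)) &
    isTRUE_vec(provean_call(snps$provean_score, provean_threshold))
  purrr::map(seq_len(nrow(intervals)), function(i) {
    iv <- intervals[i, ]
    hit <- both & in_interval(snps, iv)
    tibble::tibble(interval = iv$name,
                   n_snps_both_deleterious = sum(hit),
                   n_genes = dplyr::n_distinct(snps$gene[hit]))
  }) |> dplyr::bind_rows()
}

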