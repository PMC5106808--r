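#' Consequence-annotation field layout
#'
#' Declares how the pipe-delimited per-transcript annotation sub-field
#' (CSQ-style INFO tag) maps onto annotation columns. Defaults match the
#' layout the synthetic generator emits; real VEP output can be adapted by
#' renaming entries.
#'
#' @param tag INFO tag holding the annotation string (one comma-separated
#'   entry per transcript).
#' @param fields Character vector naming the pipe-delimited sub-fields in
#'   order. Recognised names: `Allele`, `Gene`, `Feature`, `Consequence`
#'   (ampersand-joined SO terms), `SIFT`, `PROVEAN`, `CDS_position`,
#'   `Codons` (ref/alt), `Amino_acids` (ref/alt), `Protein_position`.
#' @return A list of class `csq_spec`.
#' @export
csq_spec <- function(tag = "CSQ",
                     fields = c("Allele", "Gene", "Feature", "Consequence",
                                "SIFT", "PROVEAN", "CDS_position", "Codons",
                                "Amino_acids", "Protein_position")) {
  stopifnot("Consequence" %in% fields, "Feature" %in% fields)
  structure(list(tag = tag, fields = fields), class = "csq_spec")
}

# numeric score possibly wrapped VEP-style, e.g. "deleterious(0.03)"
parse_score <- function(x) {
  x[x %in% c("", ".", "NA", "N/A")] <- NA_character_
  inner <- stringr::str_match(x, "\\(([-0-9.eE+]+)\\)")[, 2]
  out <- suppressWarnings(as.numeric(ifelse(is.na(inner), x, inner)))
  out
}

#' Canonical representation of a variant allele pair
#'
#' Trims shared ref/alt sequence so equivalent padded representations
#' compare equal: first the common suffix, then the common prefix (advancing
#' `pos`), always keeping at least one base of each allele. Reference-based
#' left-alignment through repeat tracts is a caller/normaliser concern
#' upstream of this pipeline.
#'
#' @param pos 1-based position of the first reference base.
#' @param ref,alt Allele strings.
#' @return List with `pos`, `ref`, `alt`.
#' @export
normalize_variant <- function(pos, ref, alt) {
  r <- strsplit(ref, "")[[1]]
  a <- strsplit(alt, "")[[1]]
  # common suffix
  while (length(r) > 1 && length(a) > 1 && r[length(r)] == a[length(a)]) {
    r <- r[-length(r)]
    a <- a[-length(a)]
  }
  # common prefix
  while (length(r) > 1 && length(a) > 1 && r[1] == a[1]) {
    r <- r[-1]
    a <- a[-1]
    pos <- pos + 1
  }
  list(pos = pos, ref = paste(r, collapse = ""),
       alt = paste(a, collapse = ""))
}

variant_class_of <- function(ref, alt) {
  ifelse(nchar(ref) == 1L & nchar(alt) == 1L, "SNP", "INDEL")
}

make_variant_id <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

zygosity_from_gt <- function(gt_alleles, alt_index) {
  # gt_alleles: integer vector of allele indices from GT; alt_index: which
  # ALT (1-based) this decomposed record carries
  n_alt <- sum(gt_alleles == alt_index, na.rm = TRUE)
  if (n_alt == length(gt_alleles[!is.na(gt_alleles)]) && n_alt > 0) "HOM_ALT"
  else "HET"
}

new_variant_set <- function(variants, annotations) {
  structure(list(variants = variants, annotations = annotations),
            class = "variant_set")
}

#' Construct a variant set from tibbles
#'
#' Escape hatch for building cohorts programmatically (tests, simulations,
#' adapters for other annotation formats). `variants` needs columns
#' `variant_id`, `chrom`, `pos`, `ref`, `alt`, `variant_class`, `zygosity`
#' (plus optional `qual`, `depth`); `annotations` needs `variant_id`,
#' `transcript_id`, `so_terms` and may carry the score/codon columns.
#' Missing optional columns are filled with `NA`.
#'
#' @param variants Variant tibble.
#' @param annotations Annotation tibble; default empty.
#' @return A `variant_set`.
#' @export
variant_set <- function(variants, annotations = NULL) {
  need_v <- c("variant_id", "chrom", "pos", "ref", "alt", "variant_class",
              "zygosity")
  stopifnot(all(need_v %in% names(variants)))
  for (col in c("qual", "depth")) {
    if (!col %in% names(variants)) variants[[col]] <- NA_real_
  }
  empty <- empty_annotations()
  if (is.null(annotations) || nrow(annotations) == 0) {
    annotations <- empty
  } else {
    stopifnot(all(c("variant_id", "transcript_id", "so_terms") %in%
                    names(annotations)))
    for (col in setdiff(names(empty), names(annotations))) {
      annotations[[col]] <- empty[[col]][NA_integer_][seq_len(nrow(annotations))]
    }
  }
  new_variant_set(tibble::as_tibble(variants),
                  tibble::as_tibble(annotations))
}

#' @export
print.variant_set <- function(x, ...) {
  tab <- table(x$variants$variant_class)
  cat("<variant_set> ", nrow(x$variants), " variants (",
      paste(names(tab), as.integer(tab), sep = ": ", collapse = ", "),
      "), ", nrow(x$annotations), " transcript annotations\n", sep = "")
  invisible(x)
}

empty_annotations <- function() {
  tibble::tibble(variant_id = character(), transcript_id = character(),
                 gene_id = character(), so_terms = character(),
                 sift_score = numeric(), provean_score = numeric(),
                 cds_position = integer(), ref_codon = character(),
                 alt_codon = character(), aa_ref = character(),
                 aa_alt = character(), protein_position = integer())
}

#' Read an annotated VCF into a variant set
#'
#' Parses a VCF 4.x file (plain or gzipped) into a pair of tibbles:
#' `variants` (one row per site x alt allele; multiallelic records are
#' decomposed) and `annotations` (one row per transcript annotation, parsed
#' from the CSQ-style INFO tag according to `spec`). Zygosity is derived
#' from the first sample's GT (`1/1` and equivalents are `HOM_ALT`,
#' anything mixed is `HET`); records without GT are skipped with a warning.
#' Alleles are trimmed to canonical form via [normalize_variant()].
#'
#' @param path Path to the VCF.
#' @param spec A [csq_spec()] describing the annotation layout.
#' @return A `variant_set`: list of tibbles `variants` and `annotations`.
#' @export
read_variant_vcf <- function(path, spec = csq_spec()) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) {
    return(new_variant_set(
      tibble::tibble(variant_id = character(), chrom = character(),
                     pos = integer(), ref = character(), alt = character(),
                     variant_class = character(), zygosity = character(),
                     qual = numeric(), depth = integer()),
      empty_annotations()))
  }
  gt_raw <- if (ncol(vcf@gt) >= 2) {
    vcfR::extract.gt(vcf, element = "GT")[, 1]
  } else rep(NA_character_, nrow(fix))
  dp_fmt <- if (ncol(vcf@gt) >= 2 &&
                any(grepl("DP", vcf@gt[, 1], fixed = TRUE))) {
    suppressWarnings(as.integer(vcfR::extract.gt(vcf, element = "DP")[, 1]))
  } else rep(NA_integer_, nrow(fix))
  dp_info <- suppressWarnings(
    as.integer(stringr::str_match(fix$INFO, "(?:^|;)DP=([0-9]+)")[, 2]))
  depth <- dplyr::coalesce(dp_fmt, dp_info)
  csq_raw <- stringr::str_match(
    fix$INFO, paste0("(?:^|;)", spec$tag, "=([^;]+)"))[, 2]

  variants <- vector("list", nrow(fix))
  annotations <- vector("list", nrow(fix))
  n_skipped <- 0L
  for (i in seq_len(nrow(fix))) {
    gt <- gt_raw[i]
    if (is.na(gt) || gt %in% c(".", "./.", ".|.")) {
      n_skipped <- n_skipped + 1L
      next
    }
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    gt_idx <- suppressWarnings(
      as.integer(strsplit(gt, "[/|]")[[1]]))
    csq_entries <- if (is.na(csq_raw[i])) character(0) else
      strsplit(csq_raw[i], ",", fixed = TRUE)[[1]]
    pos0 <- as.integer(fix$POS[i])
    qual0 <- suppressWarnings(as.numeric(fix$QUAL[i]))
    rows <- list()
    anns <- list()
    for (k in seq_along(alts)) {
      norm <- normalize_variant(pos0, fix$REF[i], alts[k])
      vid <- make_variant_id(fix$CHROM[i], norm$pos, norm$ref, norm$alt)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        variant_id = vid, chrom = fix$CHROM[i], pos = norm$pos,
        ref = norm$ref, alt = norm$alt,
        variant_class = variant_class_of(norm$ref, norm$alt),
        zygosity = zygosity_from_gt(gt_idx, k),
        qual = qual0, depth = depth[i])
      if (length(csq_entries)) {
        parsed <- parse_csq_entries(csq_entries, spec, alts[k], vid)
        if (nrow(parsed)) anns[[length(anns) + 1L]] <- parsed
      }
    }
    if (length(rows)) variants[[i]] <- dplyr::bind_rows(rows)
    if (length(anns)) annotations[[i]] <- dplyr::bind_rows(anns)
  }
  if (n_skipped > 0) {
    warning(n_skipped, " record(s) without GT skipped", call. = FALSE)
  }
  variants <- dplyr::bind_rows(variants)
  annotations <- if (length(purrr::compact(annotations))) {
    dplyr::bind_rows(annotations)
  } else empty_annotations()
  new_variant_set(variants, annotations)
}

# split CSQ entries for one alt allele into annotation rows
parse_csq_entries <- function(entries, spec, allele, variant_id) {
  nf <- length(spec$fields)
  # right-pad rows whose trailing empty fields were dropped by strsplit
  mat <- t(vapply(strsplit(entries, "|", fixed = TRUE), function(p) {
    length(p) <- nf
    ifelse(is.na(p), "", p)
  }, character(nf)))
  colnames(mat) <- spec$fields
  df <- tibble::as_tibble(mat)
  if ("Allele" %in% spec$fields) {
    df <- dplyr::filter(df, .data$Allele == allele | .data$Allele == "")
  }
  if (nrow(df) == 0) return(empty_annotations())
  get <- function(nm) if (nm %in% names(df)) df[[nm]] else
    rep(NA_character_, nrow(df))
  codons <- stringr::str_split_fixed(get("Codons"), "/", 2)
  aas <- stringr::str_split_fixed(get("Amino_acids"), "/", 2)
  blank_na <- function(x) ifelse(x == "" | x == ".", NA_character_, x)
  tibble::tibble(
    variant_id = variant_id,
    transcript_id = get("Feature"),
    gene_id = blank_na(get("Gene")),
    so_terms = get("Consequence"),
    sift_score = parse_score(get("SIFT")),
    provean_score = parse_score(get("PROVEAN")),
    cds_position = suppressWarnings(as.integer(blank_na(get("CDS_position")))),
    ref_codon = toupper(blank_na(codons[, 1])),
    alt_codon = toupper(blank_na(codons[, 2])),
    aa_ref = blank_na(aas[, 1]),
    aa_alt = blank_na(aas[, 2]),
    protein_position = suppressWarnings(
      as.integer(blank_na(get("Protein_position"))))
  ) |> dplyr::filter(.data$so_terms != "")
}

#' Restrict a variant set to homozygous-alternate calls
#'
#' Heterozygous calls are retained in the data model up to this point so the
#' heterozygosity rate is measurable, then dropped from all downstream
#' stages.
#'
#' @param vset A variant set.
#' @return List with `vset` (homozygous subset, annotations filtered to
#'   match) and `het_fraction`, a tibble of per-class heterozygous
#'   percentages (`NA` for a class absent from the input; zero-row tibble for
#'   empty input).
#' @export
filter_homozygous <- function(vset) {
  v <- vset$variants
  if (nrow(v) == 0) {
    return(list(vset = vset,
                het_fraction = tibble::tibble(variant_class = character(),
                                              het_pct = numeric())))
  }
  het_fraction <- v |>
    dplyr::group_by(.data$variant_class) |>
    dplyr::summarise(
      het_pct = 100 * mean(.data$zygosity == "HET"), .groups = "drop")
  hom <- dplyr::filter(v, .data$zygosity == "HOM_ALT")
  ann <- dplyr::filter(vset$annotations,
                       .data$variant_id %in% hom$variant_id)
  list(vset = new_variant_set(hom, ann), het_fraction = het_fraction)
}
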