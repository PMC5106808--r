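#' Reference-panel configuration for private-variant calling
#'
#' Defaults encode the published rule: a variant may be declared private to
#' the target strain only when at least 21 of the 28 panel strains are
#' confidently genotyped at the site (call quality >= 20 and read depth >= 5,
#' both inclusive).
#'
#' @param n_strains Panel size.
#' @param quorum Minimum number of informative strains, `0 < quorum <= n_strains`.
#' @param min_qual Minimum call quality for a strain to count as informative.
#' @param min_depth Minimum read depth for a strain to count as informative.
#' @param strict If TRUE, a disqualifying panel call (same allele for SNPs,
#'   any variant for indels) only disqualifies when that call itself passes
#'   the quality/depth thresholds. Default FALSE: a matching call disqualifies
#'   regardless of its own QC, the quorum applying to the location.
#' @return A list of class `panel_config`.
#' @export
panel_config <- function(n_strains = 28L, quorum = 21L,
                         min_qual = 20, min_depth = 5, strict = FALSE) {
  stopifnot(quorum > 0, quorum <= n_strains)
  structure(list(n_strains = as.integer(n_strains),
                 quorum = as.integer(quorum),
                 min_qual = min_qual, min_depth = min_depth,
                 strict = strict),
            class = "panel_config")
}

#' Is a panel strain's call informative?
#'
#' @param qual,depth Vectors of call quality and read depth.
#' @param config A [panel_config()].
#' @return Logical vector: quality and depth both at or above threshold.
#' @export
strain_informative <- function(qual, depth, config = panel_config()) {
  !is.na(qual) & !is.na(depth) &
    qual >= config$min_qual & depth >= config$min_depth
}

check_panel_site <- function(panel_calls, config) {
  if (nrow(panel_calls) != config$n_strains) {
    stop("panel has ", nrow(panel_calls), " strains at this site; config says ",
         config$n_strains, call. = FALSE)
  }
  if (!all(panel_calls$status %in%
           c("SAME_ALLELE", "OTHER_VARIANT", "NO_VARIANT"))) {
    stop("unknown panel call status", call. = FALSE)
  }
}

private_at_site <- function(panel_calls, config, disqualifying) {
  check_panel_site(panel_calls, config)
  informative <- strain_informative(panel_calls$qual, panel_calls$depth,
                                    config)
  disq <- panel_calls$status %in% disqualifying
  if (config$strict) disq <- disq & informative
  !any(disq) && sum(informative) >= config$quorum
}

#' Private-variant rules
#'
#' A target SNP is private when no panel strain carries the same allele at
#' the same location (strains with a different variant at the position do not
#' disqualify it) and the informative-strain quorum is met. The indel rule is
#' stricter: any variant at the same (normalised) location in any strain
#' disqualifies.
#'
#' @param target One-row variant tibble (used to check `variant_class`).
#' @param panel_calls Tibble with one row per panel strain at this site:
#'   columns `strain`, `status` (`SAME_ALLELE`/`OTHER_VARIANT`/`NO_VARIANT`),
#'   `qual`, `depth`.
#' @param config A [panel_config()].
#' @return Logical scalar.
#' @export
is_private_snp <- function(target, panel_calls, config = panel_config()) {
  stopifnot(target$variant_class == "SNP")
  private_at_site(panel_calls, config, "SAME_ALLELE")
}

#' @rdname is_private_snp
#' @export
is_private_indel <- function(target, panel_calls, config = panel_config()) {
  stopifnot(target$variant_class == "INDEL")
  private_at_site(panel_calls, config, c("SAME_ALLELE", "OTHER_VARIANT"))
}

#' Read pre-joined panel calls
#'
#' TSV with columns `chrom`, `pos`, `strain`, `status`, `qual`, `depth`; one
#' row per (target site, panel strain).
#'
#' @param path Path to the TSV.
#' @return Tibble of panel calls.
#' @export
read_panel_calls <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    chrom = readr::col_character(), pos = readr::col_double(),
    strain = readr::col_character(), status = readr::col_character(),
    qual = readr::col_double(), depth = readr::col_double()))
}

#' Build panel calls from per-strain VCFs
#'
#' For each panel strain VCF, target sites are matched by normalised
#' location; a strain call at a target location with the identical
#' (ref, alt) is `SAME_ALLELE`, with a different allele `OTHER_VARIANT`, and
#' absence of any record is `NO_VARIANT` (qual/depth then taken as `site_qual`
#' defaults, emulating a confident homozygous-reference pileup).
#'
#' @param variants Target variant tibble.
#' @param vcf_paths Named character vector of per-strain VCF paths (names =
#'   strain labels).
#' @param default_qual,default_depth Quality/depth assigned to strains with
#'   no record at a site (their pileup QC must come from upstream; defaults
#'   pass the standard thresholds).
#' @return Panel-call tibble as in [read_panel_calls()].
#' @export
panel_from_vcfs <- function(variants, vcf_paths,
                            default_qual = 99, default_depth = 20) {
  stopifnot(!is.null(names(vcf_paths)), all(names(vcf_paths) != ""))
  purrr::imap(vcf_paths, function(path, strain) {
    sv <- read_variant_vcf(path)$variants
    key <- paste(sv$chrom, sv$pos)
    id <- sv$variant_id
    tkey <- paste(variants$chrom, variants$pos)
    hit <- match(tkey, key)
    status <- dplyr::case_when(
      is.na(hit) ~ "NO_VARIANT",
      id[hit] == variants$variant_id ~ "SAME_ALLELE",
      TRUE ~ "OTHER_VARIANT")
    tibble::tibble(chrom = variants$chrom, pos = variants$pos,
                   strain = strain, status = status,
                   qual = ifelse(is.na(hit), default_qual, sv$qual[hit]),
                   depth = ifelse(is.na(hit), default_depth, sv$depth[hit]))
  }) |> dplyr::bind_rows()
}

#' Flag private variants across a cohort
#'
#' Applies [is_private_snp()] / [is_private_indel()] at every target site and
#' summarises counts and fractions per variant class.
#'
#' @param vset Variant set (typically the homozygous subset).
#' @param panel Panel-call tibble covering every target site
#'   (`chrom`, `pos`, `strain`, `status`, `qual`, `depth`).
#' @param config A [panel_config()].
#' @return List with `flags` (tibble `variant_id`, `private`) and `summary`
#'   (tibble per class: `n_total`, `n_private`, `pct_private`).
#' @export
call_private_set <- function(vset, panel, config = panel_config()) {
  v <- vset$variants
  if (nrow(v) == 0) stop("empty variant set", call. = FALSE)
  if (is.null(panel) || nrow(panel) == 0) {
    stop("empty panel call set", call. = FALSE)
  }
  panel_by_site <- split(panel, paste(panel$chrom, panel$pos))
  private <- vapply(seq_len(nrow(v)), function(i) {
    site <- panel_by_site[[paste(v$chrom[i], v$pos[i])]]
    if (is.null(site)) {
      stop("no panel calls at ", v$chrom[i], ":", v$pos[i], call. = FALSE)
    }
    if (v$variant_class[i] == "SNP") {
      is_private_snp(v[i, ], site, config)
    } else {
      is_private_indel(v[i, ], site, config)
    }
  }, logical(1))
  flags <- tibble::tibble(variant_id = v$variant_id, private = private)
  summary <- v |>
    dplyr::mutate(private = private) |>
    dplyr::group_by(.data$variant_class) |>
    dplyr::summarise(n_total = dplyr::n(),
                     n_private = sum(.data$private),
                     pct_private = 100 * mean(.data$private),
                     .groups = "drop")
  list(flags = flags, summary = summary)
}
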