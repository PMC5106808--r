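#' Read a GWAS-catalog-format TSV
#'
#' Expects the EBI column headers verbatim: `DISEASE/TRAIT`,
#' `MAPPED GENE(S)`, `UPSTREAM_GENE_ID`, `DOWNSTREAM_GENE_ID`. Other columns
#' are carried through untouched.
#'
#' @param path Path to the catalog TSV.
#' @return Tibble with the catalog columns.
#' @export
read_gwas_catalog <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(
    .default = readr::col_character()))
  need <- c("DISEASE/TRAIT", "MAPPED GENE(S)", "UPSTREAM_GENE_ID",
            "DOWNSTREAM_GENE_ID")
  missing <- setdiff(need, names(tab))
  if (length(missing)) {
    stop("catalog lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  tab
}

split_gene_field <- function(x) {
  out <- unlist(strsplit(x[!is.na(x)], "[,;]\\s*|\\s+-\\s+"))
  out <- out[out != "" & out != "-"]
  unique(out)
}

#' Human gene IDs for a disease/trait keyword
#'
#' Case-insensitive substring match (or regular expression with
#' `regex = TRUE`) against the `DISEASE/TRAIT` column; returns the union of
#' IDs listed in `MAPPED GENE(S)`, `UPSTREAM_GENE_ID` and
#' `DOWNSTREAM_GENE_ID` over matching records.
#'
#' @param catalog Catalog tibble from [read_gwas_catalog()].
#' @param keyword Non-empty trait keyword, e.g. `"obesity"`.
#' @param regex Treat `keyword` as a regular expression.
#' @return Character vector of human gene IDs (possibly empty).
#' @export
trait_gene_ids <- function(catalog, keyword, regex = FALSE) {
  stopifnot(is.character(keyword), nzchar(keyword))
  hit <- if (regex) {
    stringr::str_detect(catalog$`DISEASE/TRAIT`,
                        stringr::regex(keyword, ignore_case = TRUE))
  } else {
    stringr::str_detect(catalog$`DISEASE/TRAIT`,
                        stringr::fixed(keyword, ignore_case = TRUE))
  }
  sub <- catalog[hit & !is.na(hit), ]
  out <- unique(c(split_gene_field(sub$`MAPPED GENE(S)`),
                  split_gene_field(sub$UPSTREAM_GENE_ID),
                  split_gene_field(sub$DOWNSTREAM_GENE_ID)))
  if (is.null(out)) character(0) else sort(out)
}

#' Map gene IDs through a two-column table
#'
#' Generic many-to-many ID mapping used both for Entrez-to-Ensembl
#' conversion and for human-to-mouse ortholog projection. Input IDs with no
#' mapping are dropped; their number is reported as a message.
#'
#' @param ids Character vector of source IDs.
#' @param map Tibble whose first column is the source ID and second column
#'   the target ID.
#' @return Sorted character vector of distinct target IDs.
#' @export
map_ids <- function(ids, map) {
  if (length(ids) == 0) return(character(0))
  src <- map[[1]]
  dst <- map[[2]]
  hit <- ids %in% src
  n_unmapped <- sum(!hit)
  if (n_unmapped > 0) {
    message(n_unmapped, " ID(s) had no mapping and were dropped")
  }
  sort(unique(dst[src %in% ids]))
}

#' Project human gene IDs onto mouse orthologs
#'
#' @param human_ids Character vector of human gene IDs.
#' @param ortholog_map Two-column tibble (human ID, mouse ID); many-to-many
#'   pairs allowed.
#' @return Sorted character vector of mouse gene IDs.
#' @export
to_mouse_genes <- function(human_ids, ortholog_map) {
  map_ids(human_ids, ortholog_map)
}

#' Mendelian obesity gene sets
#'
#' Reads a two-column table (`gene`, `category`) of human genes known to
#' cause monogenic obesity phenotypes and projects each category onto mouse
#' orthologs. Categories are restricted to the three canonical ones.
#'
#' @param gene_list Path to a TSV with columns `gene`, `category`, or an
#'   equivalent tibble.
#' @param ortholog_map Two-column tibble (human ID, mouse ID).
#' @return Named list of mouse gene ID vectors, one per category.
#' @export
mendelian_gene_sets <- function(gene_list, ortholog_map) {
  if (is.character(gene_list)) {
    gene_list <- readr::read_tsv(gene_list, col_types = readr::cols(
      gene = readr::col_character(), category = readr::col_character()))
  }
  allowed <- c("syndromic obesity", "non-syndromic obesity",
               "non-syndromic lipodystrophy")
  bad <- setdiff(unique(gene_list$category), allowed)
  if (length(bad)) {
    stop("unknown Mendelian category: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  sets <- split(gene_list$gene, gene_list$category)
  lapply(sets[intersect(allowed, names(sets))],
         to_mouse_genes, ortholog_map = ortholog_map)
}

#' Candidate-gene report for one gene set
#'
#' Filters the potentially pathogenic variants (any-transcript semantics) to
#' those annotated to genes in `gene_set` and reports the counts that make
#' up one row of a candidate table: distinct genes hit, pathogenic SNPs and
#' indels, and their private sub-counts. A variant annotated to several
#' genes in the set is counted once in the variant tallies but contributes
#' each gene to `n_genes`.
#'
#' @param vset Variant set.
#' @param gene_set Character vector of (mouse) gene IDs.
#' @param private_flags Optional tibble (`variant_id`, `private`); absent
#'   private information yields zero private counts.
#' @param priority An [so_priority()].
#' @param source_label Label for the report row.
#' @return One-row tibble: `source`, `n_genes`, `n_snps`, `n_indels`,
#'   `n_private_snps`, `n_private_indels`.
#' @export
candidate_report <- function(vset, gene_set, private_flags = NULL,
                             priority = so_priority(),
                             source_label = "gene_set") {
  cls <- classify_variants(vset, priority)
  path_ids <- cls$variant_id[cls$pathogenic]
  hits <- vset$annotations |>
    dplyr::filter(.data$variant_id %in% path_ids,
                  .data$gene_id %in% gene_set) |>
    dplyr::distinct(.data$variant_id, .data$gene_id)
  hit_variants <- vset$variants |>
    dplyr::filter(.data$variant_id %in% hits$variant_id)
  priv <- if (is.null(private_flags)) {
    character(0)
  } else {
    private_flags$variant_id[private_flags$private]
  }
  tibble::tibble(
    source = source_label,
    n_genes = dplyr::n_distinct(hits$gene_id),
    n_snps = sum(hit_variants$variant_class == "SNP"),
    n_indels = sum(hit_variants$variant_class == "INDEL"),
    n_private_snps = sum(hit_variants$variant_class == "SNP" &
                           hit_variants$variant_id %in% priv),
    n_private_indels = sum(hit_variants$variant_class == "INDEL" &
                             hit_variants$variant_id %in% priv))
}
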