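#' Sequence Ontology consequence priority
#'
#' The ordered consequence vocabulary used to summarise per-transcript SO term
#' sets and to resolve variants hit by several transcripts. The default
#' ordering runs from the most disruptive coding consequences
#' (`stop_gained`, `stop_lost`, `frameshift_variant`, ...) down to
#' `intergenic_variant`; the default "potentially pathogenic" subset is the
#' ten coding/splice-disrupting terms used throughout the pipeline's
#' candidate filters.
#'
#' @param ordered_terms Character vector of SO terms, most pathogenic first.
#'   Must contain no duplicates.
#' @param pathogenic_terms Character vector, a subset of `ordered_terms`,
#'   flagged as potentially pathogenic.
#'
#' @return An object of class `so_priority`: a list with elements
#'   `ordered_terms` and `pathogenic_terms`.
#' @export
#'
#' @examples
#' pr <- so_priority()
#' head(pr$ordered_terms)
so_priority <- function(ordered_terms = so_default_order(),
                        pathogenic_terms = so_default_pathogenic()) {
  stopifnot(is.character(ordered_terms), length(ordered_terms) > 0)
  if (anyDuplicated(ordered_terms)) {
    stop("`ordered_terms` must not contain duplicates", call. = FALSE)
  }
  if (!all(pathogenic_terms %in% ordered_terms)) {
    stop("`pathogenic_terms` must be a subset of `ordered_terms`",
         call. = FALSE)
  }
  structure(
    list(ordered_terms = ordered_terms,
         pathogenic_terms = pathogenic_terms),
    class = "so_priority"
  )
}

#' @rdname so_priority
#' @export
so_default_order <- function() {
  c("stop_gained", "stop_lost", "frameshift_variant", "missense_variant",
    "inframe_insertion", "inframe_deletion", "splice_acceptor_variant",
    "splice_donor_variant", "splice_region_variant",
    "initiator_codon_variant", "synonymous_variant", "5_prime_UTR_variant",
    "3_prime_UTR_variant", "mature_miRNA_variant", "upstream_gene_variant",
    "downstream_gene_variant", "intron_variant",
    "non_coding_transcript_variant", "intergenic_variant")
}

#' @rdname so_priority
#' @export
so_default_pathogenic <- function() {
  c("frameshift_variant", "inframe_deletion", "inframe_insertion",
    "missense_variant", "stop_gained", "stop_lost",
    "initiator_codon_variant", "splice_region_variant",
    "splice_acceptor_variant", "splice_donor_variant")
}

#' Read a priority configuration from a TSV file
#'
#' Two-column TSV (`term`, `pathogenic` with values 0/1), rows in priority
#' order. Lets alternative orderings or representative-term dialects be
#' dropped in without code changes.
#'
#' @param path Path to the TSV file.
#' @return An [so_priority()] object.
#' @export
read_so_priority <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(
    term = readr::col_character(),
    pathogenic = readr::col_integer()
  ))
  so_priority(ordered_terms = tab$term,
              pathogenic_terms = tab$term[tab$pathogenic == 1L])
}

# rank of each term under a priority; unlisted terms rank after all listed
# ones, ties among unlisted terms broken lexicographically so output is
# deterministic regardless of set enumeration order
so_term_rank <- function(terms, priority) {
  r <- match(terms, priority$ordered_terms)
  unlisted <- is.na(r)
  if (any(unlisted)) {
    n <- length(priority$ordered_terms)
    # lexicographic order over the full universe of unlisted strings
    r[unlisted] <- n + xtfrm(terms[unlisted]) / (length(terms) + 1) + 1
  }
  r
}

#' Representative SO term for one term set
#'
#' Collapses the set of SO terms a single transcript annotation carries to
#' the one term ranked earliest in the priority ordering (e.g.
#' `{intron_variant, splice_region_variant}` -> `splice_region_variant`).
#' Terms absent from the ordering rank after all listed terms.
#'
#' @param so_term_set Non-empty character vector of SO terms.
#' @param priority An [so_priority()] object.
#' @return A single SO term string.
#' @export
representative_term <- function(so_term_set, priority = so_priority()) {
  so_term_set <- unique(so_term_set)
  if (length(so_term_set) == 0 || all(is.na(so_term_set))) {
    stop("`so_term_set` must be non-empty", call. = FALSE)
  }
  so_term_set[which.min(so_term_rank(so_term_set, priority))]
}

# canonical "&"-joined form of an SO term set (order-insensitive identity)
canonical_set <- function(so_term_set) {
  paste(sort(unique(so_term_set)), collapse = "&")
}

split_set <- function(set_string) {
  strsplit(set_string, "&", fixed = TRUE)[[1]]
}

#' Final classification of one variant across transcripts
#'
#' Each distinct SO term set observed across the variant's transcript
#' annotations is collapsed to its representative term; the final term is the
#' earliest-priority representative ("most pathogenic"). A variant with no
#' annotations is intergenic. `multi_set` flags variants with two or more
#' distinct term sets.
#'
#' @param annotations A tibble of transcript annotations for ONE variant,
#'   with columns `transcript_id` and `so_terms` ("&"-joined SO term string).
#'   May have zero rows.
#' @param priority An [so_priority()] object.
#' @return A list with `final_term`, `multi_set`, `pathogenic`, and
#'   `per_transcript_reps` (tibble of transcript_id, representative term).
#' @export
final_classification <- function(annotations, priority = so_priority()) {
  if (is.null(annotations) || nrow(annotations) == 0) {
    return(list(final_term = "intergenic_variant", multi_set = FALSE,
                pathogenic = "intergenic_variant" %in% priority$pathogenic_terms,
                per_transcript_reps = tibble::tibble(
                  transcript_id = character(), representative = character())))
  }
  sets <- vapply(annotations$so_terms,
                 function(s) canonical_set(split_set(s)), character(1))
  reps_per_tx <- vapply(annotations$so_terms,
                        function(s) representative_term(split_set(s), priority),
                        character(1))
  distinct_sets <- unique(sets)
  reps <- vapply(distinct_sets,
                 function(s) representative_term(split_set(s), priority),
                 character(1))
  final <- reps[which.min(so_term_rank(reps, priority))]
  list(
    final_term = unname(final),
    multi_set = length(distinct_sets) >= 2,
    pathogenic = is_potentially_pathogenic(annotations, priority),
    per_transcript_reps = tibble::tibble(
      transcript_id = annotations$transcript_id,
      representative = unname(reps_per_tx))
  )
}

#' Is a variant potentially pathogenic?
#'
#' Any-transcript semantics: TRUE iff any transcript's SO term set intersects
#' the priority's pathogenic term set. This deliberately differs from
#' representative-term semantics so that, e.g., a frameshift in one of many
#' transcripts is kept even when the final term is milder.
#'
#' @inheritParams final_classification
#' @return Logical scalar.
#' @export
is_potentially_pathogenic <- function(annotations, priority = so_priority()) {
  if (is.null(annotations) || nrow(annotations) == 0) return(FALSE)
  any(vapply(annotations$so_terms, function(s) {
    any(split_set(s) %in% priority$pathogenic_terms)
  }, logical(1)))
}

#' Classify every variant in a variant set
#'
#' Vectorised driver over [final_classification()]: one row per variant with
#' its final SO term, multi-set flag and potentially-pathogenic flag.
#'
#' @param vset A variant set from [read_variant_vcf()] or [gen_cohort()].
#' @param priority An [so_priority()] object.
#' @return Tibble with columns `variant_id`, `final_term`, `multi_set`,
#'   `pathogenic`, `n_sets`.
#' @export
classify_variants <- function(vset, priority = so_priority()) {
  ann <- vset$annotations
  base <- tibble::tibble(variant_id = vset$variants$variant_id)
  if (nrow(ann) == 0) {
    return(dplyr::mutate(base,
                         final_term = "intergenic_variant",
                         multi_set = FALSE, pathogenic = FALSE, n_sets = 0L))
  }
  per_ann <- ann |>
    dplyr::mutate(
      set = vapply(.data$so_terms, function(s) canonical_set(split_set(s)),
                   character(1)),
      path_hit = vapply(.data$so_terms, function(s) {
        any(split_set(s) %in% priority$pathogenic_terms)
      }, logical(1))
    )
  rep_lookup <- per_ann |>
    dplyr::distinct(.data$set) |>
    dplyr::mutate(
      rep = vapply(.data$set,
                   function(s) representative_term(split_set(s), priority),
                   character(1), USE.NAMES = FALSE),
      rep_rank = so_term_rank(.data$rep, priority))
  summarised <- per_ann |>
    dplyr::left_join(rep_lookup, by = "set") |>
    dplyr::group_by(.data$variant_id) |>
    dplyr::summarise(
      n_sets = dplyr::n_distinct(.data$set),
      final_term = .data$rep[which.min(.data$rep_rank)],
      pathogenic = any(.data$path_hit),
      .groups = "drop") |>
    dplyr::mutate(multi_set = .data$n_sets >= 2L)
  base |>
    dplyr::left_join(summarised, by = "variant_id") |>
    dplyr::mutate(
      final_term = dplyr::coalesce(.data$final_term, "intergenic_variant"),
      multi_set = dplyr::coalesce(.data$multi_set, FALSE),
      pathogenic = dplyr::coalesce(.data$pathogenic, FALSE),
      n_sets = dplyr::coalesce(.data$n_sets, 0L)) |>
    dplyr::select("variant_id", "final_term", "multi_set", "pathogenic",
                  "n_sets")
}

#' Tabulate classification sets and final terms
#'
#' Produces the three summary tables used to describe a cohort's consequence
#' landscape: (A) counts per distinct SO term set, with variants carrying two
#' or more distinct sets pooled into a single "multiple classification sets"
#' row (each variant counted exactly once); (B) counts per final
#' representative term; (C) for the multi-set variants only, the number
#' classified under each potentially pathogenic term for at least one
#' transcript (a variant can contribute to several terms in C).
#'
#' @param vset A variant set.
#' @param priority An [so_priority()] object.
#' @param by_class Split tables by variant class (SNP/INDEL)? Default TRUE.
#' @return List of tibbles `set_table`, `final_table`, `multi_pathogenic`.
#' @export
tabulate_sets <- function(vset, priority = so_priority(), by_class = TRUE) {
  cls <- classify_variants(vset, priority)
  variants <- dplyr::left_join(vset$variants, cls, by = "variant_id")
  grp <- if (by_class) "variant_class" else character(0)

  single_sets <- vset$annotations |>
    dplyr::mutate(set = vapply(.data$so_terms,
                               function(s) canonical_set(split_set(s)),
                               character(1))) |>
    dplyr::distinct(.data$variant_id, .data$set)

  set_label <- variants |>
    dplyr::left_join(
      single_sets |> dplyr::group_by(.data$variant_id) |>
        dplyr::summarise(one_set = dplyr::first(.data$set),
                         k = dplyr::n(), .groups = "drop"),
      by = "variant_id") |>
    dplyr::mutate(set_label = dplyr::case_when(
      is.na(.data$k) ~ "intergenic_variant",
      .data$k >= 2 ~ "multiple classification sets",
      TRUE ~ .data$one_set))

  set_table <- set_label |>
    dplyr::count(dplyr::across(dplyr::all_of(c(grp, "set_label"))),
                 name = "n") |>
    dplyr::arrange(dplyr::across(dplyr::all_of(grp)), dplyr::desc(.data$n))

  final_table <- variants |>
    dplyr::count(dplyr::across(dplyr::all_of(c(grp, "final_term"))),
                 name = "n") |>
    dplyr::arrange(dplyr::across(dplyr::all_of(grp)), dplyr::desc(.data$n))

  multi_ids <- set_label$variant_id[set_label$set_label ==
                                      "multiple classification sets"]
  multi_hits <- vset$annotations |>
    dplyr::filter(.data$variant_id %in% multi_ids) |>
    dplyr::mutate(terms = lapply(.data$so_terms, split_set)) |>
    tidyr::unnest_longer("terms") |>
    dplyr::filter(.data$terms %in% priority$pathogenic_terms) |>
    dplyr::distinct(.data$variant_id, .data$terms) |>
    dplyr::left_join(dplyr::select(variants, "variant_id",
                                   dplyr::all_of(grp)),
                     by = "variant_id") |>
    dplyr::count(dplyr::across(dplyr::all_of(c(grp, "terms"))), name = "n") |>
    dplyr::rename(so_term = "terms")

  list(set_table = set_table, final_table = final_table,
       multi_pathogenic = multi_hits)
}
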