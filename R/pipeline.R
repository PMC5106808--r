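#' Run the full triage pipeline
#'
#' Orchestrates every stage over one annotated VCF and writes the report
#' bundle: the homozygous-filtered variant table and heterozygosity rates,
#' the classification-set / final-term / multi-set-pathogenic tables, the
#' private flags and summary (when a panel is supplied), the per-variant
#' deleteriousness table, the per-interval summary, candidate-gene reports
#' for each trait keyword and Mendelian category (when catalog inputs are
#' supplied), sliding-window density tracks, and a JSON run manifest with
#' input checksums, configuration, and per-stage record counts. Outputs are
#' pure functions of the inputs, so a rerun is byte-identical.
#'
#' @param vcf Path to the annotated target-strain VCF.
#' @param out_dir Output directory (created if needed).
#' @param panel Optional path to a pre-joined panel-call TSV
#'   ([read_panel_calls()] format) or a panel tibble.
#' @param intervals Interval tibble; default [tabw2_intervals()]. A BED path
#'   is also accepted.
#' @param catalog,entrez_to_ensembl,orthologs,mendelian Optional paths for
#'   the candidate-report stage; all four are required together.
#' @param trait_keywords Keywords filtered against the catalog's
#'   `DISEASE/TRAIT` column.
#' @param priority An [so_priority()].
#' @param pconfig A [panel_config()].
#' @param sift_threshold,provean_threshold Deleteriousness thresholds.
#' @param chrom_lengths Named vector of chromosome lengths for the density
#'   stage (default: the synthetic genome's chromosomes).
#' @param density_window,density_step Density track geometry in bases.
#' @param csq Annotation layout ([csq_spec()]).
#' @return Invisibly, a list of the in-memory stage results.
#' @export
run_pipeline <- function(vcf, out_dir,
                         panel = NULL,
                         intervals = tabw2_intervals(),
                         catalog = NULL, entrez_to_ensembl = NULL,
                         orthologs = NULL, mendelian = NULL,
                         trait_keywords = c("obesity", "diabetes",
                                            "metabolic"),
                         priority = so_priority(),
                         pconfig = panel_config(),
                         sift_threshold = 0.05, provean_threshold = -2.5,
                         chrom_lengths = sim_chroms(),
                         density_window = 1e6, density_step = 1e3,
                         csq = csq_spec()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  inputs <- c(vcf = vcf,
              panel = if (is.character(panel)) panel,
              catalog = catalog, entrez_to_ensembl = entrez_to_ensembl,
              orthologs = orthologs, mendelian = mendelian)
  counts <- list()
  results <- list()

  if (is.character(intervals)) intervals <- read_bed_intervals(intervals)

  vset_all <- stage("parse", read_variant_vcf(vcf, csq))
  hom <- stage("filter_homozygous", filter_homozygous(vset_all))
  vset <- hom$vset
  readr::write_tsv(vset$variants, file.path(out_dir, "homozygous_variants.tsv"))
  readr::write_tsv(hom$het_fraction, file.path(out_dir, "het_fraction.tsv"))
  counts$variants_total <- nrow(vset_all$variants)
  counts$variants_homozygous <- nrow(vset$variants)
  results$vset <- vset
  results$het_fraction <- hom$het_fraction

  tabs <- stage("classify", tabulate_sets(vset, priority))
  cls <- classify_variants(vset, priority)
  readr::write_tsv(tabs$set_table, file.path(out_dir, "classification_sets.tsv"))
  readr::write_tsv(tabs$final_table, file.path(out_dir, "final_terms.tsv"))
  readr::write_tsv(tabs$multi_pathogenic,
                   file.path(out_dir, "multiset_pathogenic.tsv"))
  readr::write_tsv(cls, file.path(out_dir, "classification.tsv"))
  results$classification <- cls
  results$tables <- tabs

  private <- NULL
  if (!is.null(panel)) {
    panel_tab <- if (is.character(panel)) {
      stage("private", read_panel_calls(panel))
    } else panel
    private <- stage("private", call_private_set(vset, panel_tab, pconfig))
    readr::write_tsv(private$flags, file.path(out_dir, "private_flags.tsv"))
    readr::write_tsv(private$summary,
                     file.path(out_dir, "private_summary.tsv"))
    counts$private <- sum(private$flags$private)
    results$private <- private
  }

  cons <- stage("deleterious",
                consensus_calls(vset, sift_threshold, provean_threshold))
  gene_of <- vset$annotations |>
    dplyr::filter(!is.na(.data$gene_id)) |>
    dplyr::distinct(.data$variant_id, .data$gene_id)
  readr::write_tsv(dplyr::left_join(cons, gene_of, by = "variant_id"),
                   file.path(out_dir, "deleteriousness.tsv"))
  results$deleteriousness <- cons

  isum <- stage("intervals",
                interval_summary(vset, intervals, priority,
                                 sift_threshold, provean_threshold))
  readr::write_tsv(isum, file.path(out_dir, "interval_summary.tsv"))
  results$interval_summary <- isum

  if (!is.null(catalog)) {
    if (is.null(entrez_to_ensembl) || is.null(orthologs) ||
        is.null(mendelian)) {
      stop("stage 'candidates' failed: catalog, entrez_to_ensembl, ",
           "orthologs and mendelian must be supplied together",
           call. = FALSE)
    }
    reports <- stage("candidates", {
      cat_tab <- read_gwas_catalog(catalog)
      e2e <- readr::read_tsv(entrez_to_ensembl,
                             col_types = readr::cols(.default = "c"))
      orth <- readr::read_tsv(orthologs,
                              col_types = readr::cols(.default = "c"))
      flags <- if (is.null(private)) NULL else private$flags
      trait_rows <- purrr::map(trait_keywords, function(kw) {
        mouse <- to_mouse_genes(
          map_ids(trait_gene_ids(cat_tab, kw), e2e), orth)
        candidate_report(vset, mouse, flags, priority, kw)
      })
      mend_sets <- mendelian_gene_sets(mendelian, orth)
      mend_rows <- purrr::imap(mend_sets, function(gs, label) {
        candidate_report(vset, gs, flags, priority, label)
      })
      dplyr::bind_rows(c(trait_rows, unname(mend_rows)))
    })
    readr::write_tsv(reports, file.path(out_dir, "candidate_reports.tsv"))
    results$candidate_reports <- reports
  }

  stage("density", {
    for (chrom in names(chrom_lengths)) {
      track <- window_density(vset$variants, chrom, chrom_lengths[[chrom]],
                              density_window, density_step)
      write_density_tsv(track,
                        file.path(out_dir, paste0("density_", chrom,
                                                  ".tsv")))
    }
  })

  manifest <- list(
    package = "vartriage",
    version = as.character(utils::packageVersion("vartriage")),
    inputs = {
      paths <- inputs[!is.na(inputs)]
      md5 <- as.list(unname(tools::md5sum(paths)))
      names(md5) <- names(paths)  # role names, not run-specific paths
      md5
    },
    config = list(
      quorum = pconfig$quorum, n_strains = pconfig$n_strains,
      min_qual = pconfig$min_qual, min_depth = pconfig$min_depth,
      sift_threshold = sift_threshold,
      provean_threshold = provean_threshold,
      density_window = density_window, density_step = density_step,
      trait_keywords = trait_keywords,
      intervals = intervals),
    counts = counts)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(results)
}
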