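test_that("representative term follows the priority ordering", {
  pr <- so_priority()
  expect_equal(representative_term(c("intron_variant",
                                     "splice_region_variant"), pr),
               "splice_region_variant")
  expect_equal(representative_term("synonymous_variant", pr),
               "synonymous_variant")
  expect_equal(representative_term(c("missense_variant",
                                     "splice_region_variant"), pr),
               "missense_variant")
  expect_error(representative_term(character(0), pr), "non-empty")
})

test_that("representative term is idempotent and order-independent", {
  pr <- so_priority()
  withr::with_seed(5, {
    universe <- c(pr$ordered_terms, "regulatory_region_variant",
                  "TF_binding_site_variant")
    for (rep in 1:100) {
      set <- sample(universe, sample(1:5, 1))
      r1 <- representative_term(set, pr)
      r2 <- representative_term(sample(set), pr)
      expect_identical(r1, r2)
      expect_identical(representative_term(r1, pr), r1)
    }
  })
})

test_that("terms outside the ordering rank last, ties lexicographic", {
  pr <- so_priority()
  expect_equal(representative_term(c("zeta_novel_term",
                                     "intergenic_variant"), pr),
               "intergenic_variant")
  expect_equal(representative_term(c("beta_novel", "alpha_novel"), pr),
               "alpha_novel")
})

test_that("final classification picks the most pathogenic representative", {
  pr <- so_priority()
  ann <- tibble::tibble(
    transcript_id = c("t1", "t2"),
    so_terms = c("missense_variant", "intron_variant"))
  out <- final_classification(ann, pr)
  expect_equal(out$final_term, "missense_variant")
  expect_true(out$multi_set)

  one <- final_classification(
    tibble::tibble(transcript_id = "t1",
                   so_terms = "intron_variant&splice_region_variant"), pr)
  expect_equal(one$final_term, "splice_region_variant")
  expect_false(one$multi_set)

  updown <- final_classification(
    tibble::tibble(transcript_id = c("t1", "t2"),
                   so_terms = c("upstream_gene_variant",
                                "downstream_gene_variant")), pr)
  expect_equal(updown$final_term, "upstream_gene_variant")

  none <- final_classification(NULL, pr)
  expect_equal(none$final_term, "intergenic_variant")
  expect_false(none$multi_set)
})

test_that("final classification equals a brute-force priority minimum", {
  pr <- so_priority()
  brute_final <- function(sets) {
    # global minimum of per-set minima over all (set, member) pairs
    reps <- vapply(sets, function(s) {
      ranks <- match(s, pr$ordered_terms)
      s[which.min(ranks)]
    }, character(1))
    reps[which.min(match(reps, pr$ordered_terms))]
  }
  withr::with_seed(8, {
    for (rep in 1:100) {
      n_tx <- sample(1:4, 1)
      sets <- lapply(seq_len(n_tx), function(i) {
        sample(pr$ordered_terms, sample(1:3, 1))
      })
      ann <- tibble::tibble(
        transcript_id = paste0("t", seq_len(n_tx)),
        so_terms = vapply(sets, paste, character(1), collapse = "&"))
      expect_equal(final_classification(ann, pr)$final_term,
                   brute_final(sets))
    }
  })
})

test_that("potentially pathogenic uses any-transcript semantics", {
  pr <- so_priority()
  ann <- tibble::tibble(
    transcript_id = c("t1", "t2", "t3"),
    so_terms = c("frameshift_variant", "intron_variant", "intron_variant"))
  expect_true(is_potentially_pathogenic(ann, pr))
  expect_false(is_potentially_pathogenic(
    tibble::tibble(transcript_id = c("t1", "t2"),
                   so_terms = c("intron_variant", "intergenic_variant")),
    pr))
  expect_true(is_potentially_pathogenic(
    tibble::tibble(transcript_id = "t1",
                   so_terms = "intron_variant&splice_region_variant"), pr))
})

test_that("adding a transcript annotation never un-flags a variant", {
  pr <- so_priority()
  withr::with_seed(13, {
    for (rep in 1:50) {
      n_tx <- sample(1:3, 1)
      ann <- tibble::tibble(
        transcript_id = paste0("t", seq_len(n_tx)),
        so_terms = vapply(seq_len(n_tx), function(i) {
          paste(sample(pr$ordered_terms, sample(1:3, 1)), collapse = "&")
        }, character(1)))
      before <- is_potentially_pathogenic(ann, pr)
      extra <- tibble::tibble(
        transcript_id = "t_extra",
        so_terms = paste(sample(pr$ordered_terms, 2), collapse = "&"))
      after <- is_potentially_pathogenic(rbind(ann, extra), pr)
      if (before) expect_true(after)
    }
  })
})

test_that("classification tables partition the cohort", {
  vset <- build_vset(list(
    list(chrom = "6", pos = 1, ref = "C", alt = "A",
         sets = list("intron_variant"), gene = "G1"),
    list(chrom = "6", pos = 2, ref = "C", alt = "A",
         sets = list("intron_variant"), gene = "G1"),
    list(chrom = "6", pos = 3, ref = "C", alt = "A",
         sets = list("intron_variant"), gene = "G2"),
    list(chrom = "6", pos = 4, ref = "C", alt = "A",
         sets = list("missense_variant", "intron_variant"), gene = "G2"),
    list(chrom = "6", pos = 5, ref = "C", alt = "A")))
  tabs <- tabulate_sets(vset, by_class = FALSE)

  expect_equal(tabs$set_table$n[tabs$set_table$set_label ==
                                  "intron_variant"], 3)
  expect_equal(tabs$set_table$n[tabs$set_table$set_label ==
                                  "multiple classification sets"], 1)
  expect_equal(sum(tabs$set_table$n), 5)   # each variant counted once
  expect_equal(sum(tabs$final_table$n), 5) # final terms partition too
  expect_equal(tabs$final_table$n[tabs$final_table$final_term ==
                                    "missense_variant"], 1)
  expect_equal(tabs$multi_pathogenic$n[
    tabs$multi_pathogenic$so_term == "missense_variant"], 1)
})

test_that("a priority TSV round-trips through read_so_priority", {
  pr <- so_priority()
  path <- tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(
    term = pr$ordered_terms,
    pathogenic = as.integer(pr$ordered_terms %in% pr$pathogenic_terms)),
    path)
  back <- read_so_priority(path)
  expect_identical(back$ordered_terms, pr$ordered_terms)
  expect_setequal(back$pathogenic_terms, pr$pathogenic_terms)
})
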