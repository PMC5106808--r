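test_that("informative thresholds are inclusive", {
  cfg <- panel_config()
  expect_true(strain_informative(20, 5, cfg))
  expect_false(strain_informative(19.9, 50, cfg))
  expect_false(strain_informative(60, 4, cfg))
})

test_that("SNP privacy: same allele disqualifies, other variants do not", {
  cfg <- panel_config()
  tgt <- snp_target()
  expect_true(is_private_snp(tgt, panel_site(), cfg))
  expect_false(is_private_snp(
    tgt, panel_site(override = list(list(i = 5, status = "SAME_ALLELE"))),
    cfg))
  expect_true(is_private_snp(
    tgt, panel_site(override = list(list(i = 5, status = "OTHER_VARIANT"))),
    cfg))
})

test_that("quorum is enforced at its inclusive boundary", {
  cfg <- panel_config()
  low_quorum <- panel_site(override = lapply(1:8, function(i) {
    list(i = i, qual = 10)  # 20 informative strains left
  }))
  expect_false(is_private_snp(snp_target(), low_quorum, cfg))
  at_quorum <- panel_site(override = lapply(1:7, function(i) {
    list(i = i, depth = 2)  # exactly 21 informative
  }))
  expect_true(is_private_snp(snp_target(), at_quorum, cfg))
  expect_true(is_private_indel(indel_target(), at_quorum, cfg))
})

test_that("indel privacy is stricter: any variant at the location disqualifies", {
  cfg <- panel_config()
  tgt <- indel_target()
  expect_true(is_private_indel(tgt, panel_site(), cfg))
  expect_false(is_private_indel(
    tgt, panel_site(override = list(list(i = 3, status = "OTHER_VARIANT"))),
    cfg))
  expect_false(is_private_indel(
    tgt, panel_site(override = list(list(i = 3, status = "SAME_ALLELE"))),
    cfg))
})

test_that("panel size mismatch and unknown status are errors", {
  cfg <- panel_config()
  expect_error(is_private_snp(snp_target(), panel_site(n = 27), cfg),
               "27 strains")
  bad <- panel_site()
  bad$status[1] <- "MYSTERY"
  expect_error(is_private_snp(snp_target(), bad, cfg), "status")
})

test_that("a low-QC matching call still disqualifies unless strict", {
  site <- panel_site(override = list(
    list(i = 1, status = "SAME_ALLELE", qual = 5, depth = 1)))
  expect_false(is_private_snp(snp_target(), site, panel_config()))
  expect_true(is_private_snp(snp_target(), site,
                             panel_config(strict = TRUE)))
})

test_that("raising QC thresholds never makes a variant private", {
  withr::with_seed(21, {
    for (rep in 1:100) {
      site <- panel_site(
        status = sample(c("NO_VARIANT", "SAME_ALLELE", "OTHER_VARIANT"),
                        28, replace = TRUE, prob = c(0.8, 0.1, 0.1)),
        qual = round(stats::runif(28, 0, 60), 1),
        depth = sample(0:20, 28, replace = TRUE))
      base <- panel_config()
      tighter <- panel_config(min_qual = 30, min_depth = 8)
      tgt <- snp_target()
      if (!is_private_snp(tgt, site, base)) {
        expect_false(is_private_snp(tgt, site, tighter))
      }
      ti <- indel_target()
      if (!is_private_indel(ti, site, base)) {
        expect_false(is_private_indel(ti, site, tighter))
      }
    }
  })
})

test_that("rules agree with a literal scan of all panel calls", {
  brute_private <- function(site, cfg, indel) {
    informative <- 0L
    disq <- FALSE
    for (i in seq_len(nrow(site))) {
      ok <- site$qual[i] >= cfg$min_qual && site$depth[i] >= cfg$min_depth
      if (ok) informative <- informative + 1L
      hit <- if (indel) {
        site$status[i] %in% c("SAME_ALLELE", "OTHER_VARIANT")
      } else {
        site$status[i] == "SAME_ALLELE"
      }
      if (hit) disq <- TRUE
    }
    !disq && informative >= cfg$quorum
  }
  withr::with_seed(22, {
    cfg <- panel_config()
    for (rep in 1:200) {
      site <- panel_site(
        status = sample(c("NO_VARIANT", "SAME_ALLELE", "OTHER_VARIANT"),
                        28, replace = TRUE, prob = c(0.85, 0.05, 0.1)),
        qual = round(stats::runif(28, 0, 50), 1),
        depth = sample(0:15, 28, replace = TRUE))
      expect_equal(is_private_snp(snp_target(), site, cfg),
                   brute_private(site, cfg, indel = FALSE))
      expect_equal(is_private_indel(indel_target(), site, cfg),
                   brute_private(site, cfg, indel = TRUE))
    }
  })
})

test_that("any site private under the indel rule is private under the SNP rule", {
  withr::with_seed(23, {
    cfg <- panel_config()
    n_indel_private <- 0L
    for (rep in 1:200) {
      site <- panel_site(
        status = sample(c("NO_VARIANT", "SAME_ALLELE", "OTHER_VARIANT"),
                        28, replace = TRUE, prob = c(0.96, 0.02, 0.02)),
        qual = round(stats::runif(28, 15, 60), 1),
        depth = sample(3:30, 28, replace = TRUE))
      indel_priv <- is_private_indel(indel_target(), site, cfg)
      snp_priv <- is_private_snp(snp_target(), site, cfg)
      if (indel_priv) {
        n_indel_private <- n_indel_private + 1L
        expect_true(snp_priv)
      }
    }
    expect_gt(n_indel_private, 0)  # the implication was actually exercised
  })
})

test_that("cohort-level flags and summary come out right", {
  vset <- variant_set(dplyr::bind_rows(
    snp_target("6", 100), snp_target("6", 200), indel_target("6", 300)))
  panel <- dplyr::bind_rows(
    panel_site(pos = 100),
    panel_site(pos = 200,
               override = list(list(i = 1, status = "SAME_ALLELE"))),
    panel_site(pos = 300))
  out <- call_private_set(vset, panel, panel_config())
  expect_equal(out$flags$private,
               c(TRUE, FALSE, TRUE))
  snp_row <- out$summary[out$summary$variant_class == "SNP", ]
  expect_equal(snp_row$n_private, 1)
  expect_equal(snp_row$pct_private, 50)
  expect_error(call_private_set(vset, panel[0, ], panel_config()), "empty")
})

test_that("panel calls round-trip through the TSV reader", {
  panel <- panel_site(pos = 42)
  path <- tempfile(fileext = ".tsv")
  readr::write_tsv(panel, path)
  back <- read_panel_calls(path)
  expect_equal(as.data.frame(back), as.data.frame(panel))
})

test_that("panel construction from per-strain VCFs assigns statuses", {
  tgt_vcf <- write_toy_vcf(c(vcf_record("6", 1000, "C", "A"),
                             vcf_record("6", 2000, "G", "T")))
  target <- read_variant_vcf(tgt_vcf)$variants
  strain1 <- write_toy_vcf(vcf_record("6", 1000, "C", "A"))  # same allele
  strain2 <- write_toy_vcf(vcf_record("6", 1000, "C", "G"))  # other variant
  strain3 <- write_toy_vcf(vcf_record("7", 5000, "C", "G"))  # elsewhere
  panel <- panel_from_vcfs(target, c(s1 = strain1, s2 = strain2,
                                     s3 = strain3))
  get <- function(strain, pos) {
    panel$status[panel$strain == strain & panel$pos == pos]
  }
  expect_equal(get("s1", 1000), "SAME_ALLELE")
  expect_equal(get("s2", 1000), "OTHER_VARIANT")
  expect_equal(get("s3", 1000), "NO_VARIANT")
  expect_equal(get("s1", 2000), "NO_VARIANT")
})
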