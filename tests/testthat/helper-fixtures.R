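# shared fixture builders; everything is generated in code at test time

vcf_header <- function() {
  c("##fileformat=VCFv4.2",
    "##contig=<ID=6,length=149736546>",
    "##contig=<ID=7,length=145441459>",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste0("##INFO=<ID=CSQ,Number=.,Type=String,Description=\"",
           "Consequence annotations: Allele|Gene|Feature|Consequence|",
           "SIFT|PROVEAN|CDS_position|Codons|Amino_acids|",
           "Protein_position\">"),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "TARGET", sep = "\t"))
}

write_toy_vcf <- function(records, path = tempfile(fileext = ".vcf")) {
  writeLines(c(vcf_header(), records), path)
  path
}

vcf_record <- function(chrom, pos, ref, alt, gt = "1/1", qual = 60,
                       dp = 30, csq = NULL) {
  info <- paste0("DP=", dp, if (!is.null(csq)) paste0(";CSQ=", csq))
  paste(chrom, pos, ".", ref, alt, qual, "PASS", info, "GT:DP",
        paste0(gt, ":", dp), sep = "\t")
}

# bare-bones cohort builder for classifier/report tests: `spec` is a list of
# lists with fields chrom, pos, ref, alt, class, zyg, sets (list of SO term
# vectors), gene, sift, provean
build_vset <- function(spec) {
  variants <- purrr::map(spec, function(s) {
    tibble::tibble(
      variant_id = paste(s$chrom, s$pos, s$ref, s$alt, sep = ":"),
      chrom = s$chrom, pos = s$pos, ref = s$ref, alt = s$alt,
      variant_class = s$class %||% "SNP",
      zygosity = s$zyg %||% "HOM_ALT")
  }) |> dplyr::bind_rows()
  annotations <- purrr::map(spec, function(s) {
    sets <- s$sets %||% list()
    if (length(sets) == 0) return(NULL)
    vid <- paste(s$chrom, s$pos, s$ref, s$alt, sep = ":")
    purrr::imap(sets, function(terms, k) {
      tibble::tibble(
        variant_id = vid,
        transcript_id = paste0(vid, ".t", k),
        gene_id = s$gene %||% NA_character_,
        so_terms = paste(terms, collapse = "&"),
        sift_score = s$sift %||% NA_real_,
        provean_score = s$provean %||% NA_real_)
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
  variant_set(variants, annotations)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# uniform panel-call site: all strains share one status/qual/depth unless
# overridden per strain index
panel_site <- function(chrom = "6", pos = 100, n = 28,
                       status = "NO_VARIANT", qual = 60, depth = 30,
                       override = list()) {
  calls <- tibble::tibble(chrom = chrom, pos = pos,
                          strain = sprintf("strain%02d", seq_len(n)),
                          status = status, qual = qual, depth = depth)
  for (o in override) {
    calls$status[o$i] <- o$status %||% calls$status[o$i]
    calls$qual[o$i] <- o$qual %||% calls$qual[o$i]
    calls$depth[o$i] <- o$depth %||% calls$depth[o$i]
  }
  calls
}

snp_target <- function(chrom = "6", pos = 100, ref = "C", alt = "A") {
  tibble::tibble(variant_id = paste(chrom, pos, ref, alt, sep = ":"),
                 chrom = chrom, pos = pos, ref = ref, alt = alt,
                 variant_class = "SNP", zygosity = "HOM_ALT")
}

indel_target <- function(chrom = "6", pos = 100, ref = "CA", alt = "C") {
  tibble::tibble(variant_id = paste(chrom, pos, ref, alt, sep = ":"),
                 chrom = chrom, pos = pos, ref = ref, alt = alt,
                 variant_class = "INDEL", zygosity = "HOM_ALT")
}
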