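#' Named genomic intervals
#'
#' Intervals are 1-based and inclusive at both ends, matching how QTL
#' boundaries are reported. [tabw2_intervals()] ships the two obesity-QTL
#' sub-intervals on mouse chromosome 6 (GRCm38 coordinates) used as default
#' triage regions.
#'
#' @param name Interval label.
#' @param chrom Chromosome name.
#' @param start,end 1-based inclusive bounds, `start <= end`.
#' @return One-row tibble with columns `name`, `chrom`, `start`, `end`.
#' @export
genomic_interval <- function(name, chrom, start, end) {
  start <- as.numeric(start)
  end <- as.numeric(end)
  stopifnot(start >= 1, start <= end)
  tibble::tibble(name = name, chrom = as.character(chrom),
                 start = start, end = end)
}

#' @rdname genomic_interval
#' @export
tabw2_intervals <- function() {
  dplyr::bind_rows(
    genomic_interval("tabw2a", "6", 80217217, 125356646),
    genomic_interval("tabw2b", "6", 133853029, 144639629)
  )
}

#' Read intervals from a BED file
#'
#' BED is 0-based half-open; import converts to the package's 1-based
#' inclusive convention. Unnamed records are labelled `chrom:start-end`.
#'
#' @param path Path to a BED file.
#' @return Tibble of intervals as in [genomic_interval()].
#' @export
read_bed_intervals <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  nm <- gr$name
  if (is.null(nm)) nm <- rep(NA_character_, length(gr))
  nm <- ifelse(is.na(nm) | nm == "",
               paste0(GenomicRanges::seqnames(gr), ":",
                      GenomicRanges::start(gr), "-", GenomicRanges::end(gr)),
               nm)
  tibble::tibble(name = nm,
                 chrom = as.character(GenomicRanges::seqnames(gr)),
                 start = as.numeric(GenomicRanges::start(gr)),
                 end = as.numeric(GenomicRanges::end(gr)))
}

#' Write variant positions as BED
#'
#' Exports target positions (0-based half-open) for re-genotyping a strain
#' panel at exactly the target sites.
#'
#' @param variants Variant tibble (`chrom`, `pos`, plus `ref` for span).
#' @param path Output path.
#' @export
write_positions_bed <- function(variants, path) {
  span <- nchar(variants$ref)
  readr::write_tsv(
    tibble::tibble(chrom = variants$chrom,
                   start = variants$pos - 1L,
                   end = variants$pos - 1L + span),
    path, col_names = FALSE)
  invisible(path)
}

#' Interval membership
#'
#' TRUE iff the variant's first reference base lies inside the interval;
#' both endpoints inclusive. Vectorised over variants.
#'
#' @param variants Variant tibble with `chrom` and `pos`.
#' @param interval One-row interval tibble ([genomic_interval()]).
#' @return Logical vector, one element per variant.
#' @export
in_interval <- function(variants, interval) {
  stopifnot(nrow(interval) == 1)
  variants$chrom == interval$chrom &
    variants$pos >= interval$start &
    variants$pos <= interval$end
}

#' Sliding-window variant density along a chromosome
#'
#' Counts variants per window while sliding a `window_size`-base window in
#' `step`-base increments, the standard per-megabase density track. Windows
#' start at 1, 1+step, ... up to `chrom_length` (windows overhanging the
#' chromosome end are emitted rather than clipped; counts there simply
#' decline) and are half-open: a window starting at `s` covers positions
#' `[s, s + window_size)`. Counts are produced for all variants and per
#' class (SNP, indel).
#'
#' @param variants Variant tibble (`chrom`, `pos`, `variant_class`).
#' @param chrom Chromosome to scan.
#' @param chrom_length Chromosome length in bases (>= 1).
#' @param window_size Window width in bases, default 1 Mb.
#' @param step Slide increment in bases, default 1 kb; `window_size >= step >= 1`.
#' @return Tibble (`window_start`, `class`, `count`) with
#'   `class` in `all`, `SNP`, `INDEL`; attribute `window_size`, `step`,
#'   `chrom` recorded for writers.
#' @export
window_density <- function(variants, chrom, chrom_length,
                           window_size = 1e6, step = 1e3) {
  if (!is.numeric(chrom_length) || chrom_length < 1) {
    stop("`chrom_length` must be >= 1", call. = FALSE)
  }
  stopifnot(window_size >= step, step >= 1)
  starts <- seq(1, chrom_length, by = step)
  pos_for <- function(v) sort(v$pos[v$chrom == chrom])
  count_windows <- function(pos) {
    if (length(pos) == 0) return(integer(length(starts)))
    # variants with s <= pos < s + window_size
    hi <- findInterval(starts + window_size - 1e-9, pos)
    lo <- findInterval(starts - 1e-9, pos)
    as.integer(hi - lo)
  }
  classes <- list(all = variants,
                  SNP = dplyr::filter(variants, .data$variant_class == "SNP"),
                  INDEL = dplyr::filter(variants,
                                        .data$variant_class == "INDEL"))
  out <- purrr::imap(classes, function(v, nm) {
    tibble::tibble(window_start = starts, class = nm,
                   count = count_windows(pos_for(v)))
  }) |> dplyr::bind_rows()
  attr(out, "chrom") <- chrom
  attr(out, "window_size") <- window_size
  attr(out, "step") <- step
  out
}

#' Write a density track as TSV
#'
#' Three columns (`window_start`, `class`, `count`), plot-ready; window
#' convention recorded in comment header lines.
#'
#' @param track Output of [window_density()].
#' @param path Output path.
#' @export
write_density_tsv <- function(track, path) {
  hdr <- sprintf(
    "# chrom=%s window_size=%g step=%g windows_half_open=[start,start+window_size) terminal_windows=unclipped",
    attr(track, "chrom"), attr(track, "window_size"), attr(track, "step"))
  writeLines(hdr, path)
  readr::write_tsv(track, path, append = TRUE, col_names = TRUE)
  invisible(path)
}
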