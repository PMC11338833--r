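#' Per-position nucleotide counts and read-mismatch frequency
#'
#' Converts aligned reads into a per-reference-position pileup table and
#' computes the read-mismatch frequency: the ratio between the number of
#' aligned reads differing from the reference and the total alignment
#' coverage at each position. Only aligned (match/mismatch) bases are
#' counted; insertions contribute nothing and deleted positions contribute
#' nothing to coverage. Unmapped, secondary and supplementary records are
#' skipped. No base-quality or mapping-quality filtering is applied by
#' default, and duplicate reads are kept.
#'
#' @param alignments Path to a SAM (plain text) or BAM file.
#' @param reference Genome tibble, named character vector, or `DNAStringSet`
#'   matching the alignment header contigs.
#' @param intervals Optional tibble of intervals (`contig`, `start`, `end`) to
#'   restrict the table to; default is every position of every contig present
#'   in the alignment header.
#' @param min_baseq,min_mapq Minimum base and mapping quality (default 0).
#' @param sample_label Optional label stored as an attribute.
#' @return A tibble (one row per reference position) with columns `contig`,
#'   `pos` (1-based), `ref`, `A`, `C`, `G`, `T`, `coverage` and
#'   `mismatch_frequency`. The frequency is `NA` where coverage is zero or
#'   the reference base is `N` (mismatch to N is ill-defined). Attributes
#'   `sample_label` and `mean_coverage` are attached.
#' @export
build_pileup <- function(alignments, reference, intervals = NULL,
                         min_baseq = 0L, min_mapq = 0L, sample_label = NULL) {
  reference <- as_genome(reference)
  bam <- .as_sorted_bam(alignments)
  hdr <- Rsamtools::scanBamHeader(bam)[[1]]$targets
  missing <- setdiff(names(hdr), reference$name)
  if (length(missing)) {
    rlang::abort(sprintf(
      "alignment header contig(s) not present in reference: %s",
      paste(missing, collapse = ", ")))
  }
  bad_len <- names(hdr)[hdr != reference$length[match(names(hdr),
                                                      reference$name)]]
  if (length(bad_len)) {
    rlang::abort(sprintf(
      "contig length mismatch between alignment header and reference: %s",
      paste(bad_len, collapse = ", ")))
  }
  if (is.null(intervals)) {
    intervals <- tibble(contig = names(hdr), start = 1L,
                        end = unname(as.integer(hdr)))
  }
  gr <- GenomicRanges::GRanges(intervals$contig,
                               IRanges::IRanges(intervals$start,
                                                intervals$end))
  flags <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE)
  pp <- Rsamtools::PileupParam(
    max_depth = 1000000L, min_base_quality = as.integer(min_baseq),
    min_mapq = as.integer(min_mapq), min_nucleotide_depth = 0L,
    distinguish_strands = FALSE, distinguish_nucleotides = TRUE,
    ignore_query_Ns = FALSE, include_deletions = FALSE,
    include_insertions = FALSE)
  raw <- Rsamtools::pileup(
    bam, scanBamParam = Rsamtools::ScanBamParam(flag = flags, which = gr),
    pileupParam = pp)

  counts <- as_tibble(raw) |>
    dplyr::transmute(contig = as.character(.data$seqnames),
                     pos = as.integer(.data$pos),
                     nucleotide = as.character(.data$nucleotide),
                     count = as.integer(.data$count)) |>
    dplyr::filter(.data$nucleotide %in% c("A", "C", "G", "T")) |>
    dplyr::group_by(.data$contig, .data$pos, .data$nucleotide) |>
    dplyr::summarise(count = sum(.data$count), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "nucleotide", values_from = "count",
                       values_fill = 0L)

  grid <- intervals |>
    dplyr::rowwise() |>
    dplyr::reframe(contig = .data$contig, pos = .data$start:.data$end) |>
    dplyr::distinct() |>
    dplyr::arrange(.data$contig, .data$pos)
  for (b in c("A", "C", "G", "T")) if (!b %in% names(counts)) counts[[b]] <- 0L
  out <- grid |>
    dplyr::left_join(counts, by = c("contig", "pos")) |>
    dplyr::mutate(dplyr::across(dplyr::all_of(c("A", "C", "G", "T")),
                                ~ tidyr::replace_na(.x, 0L)))
  refchars <- stats::setNames(strsplit(reference$seq, ""), reference$name)
  out$ref <- purrr::map2_chr(out$contig, out$pos, ~ refchars[[.x]][.y])
  out$coverage <- out$A + out$C + out$G + out$T
  cnt <- as.matrix(out[, c("A", "C", "G", "T")])
  ref_count <- cnt[cbind(seq_len(nrow(out)),
                         match(out$ref, c("A", "C", "G", "T")))]
  out$mismatch_frequency <- ifelse(
    out$coverage > 0 & out$ref %in% c("A", "C", "G", "T"),
    (out$coverage - ref_count) / out$coverage, NA_real_)
  out <- dplyr::select(out, "contig", "pos", "ref", "A", "C", "G", "T",
                       "coverage", "mismatch_frequency")
  attr(out, "sample_label") <- sample_label
  attr(out, "mean_coverage") <- mean(out$coverage)
  out
}

# Accept SAM or BAM; return a coordinate-sorted, indexed BAM path.
.as_sorted_bam <- function(path) {
  if (!file.exists(path)) rlang::abort(sprintf("alignment file not found: %s",
                                               path))
  if (grepl("\\.bam$", path, ignore.case = TRUE)) {
    bam <- path
  } else {
    bam <- tryCatch(
      Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                       indexDestination = FALSE),
      error = function(e) rlang::abort(sprintf(
        "could not parse SAM file '%s': %s", path, conditionMessage(e))))
  }
  sorted <- Rsamtools::sortBam(bam, tempfile())
  Rsamtools::indexBam(sorted)
  sorted
}

#' Per-base nucleotide frequencies of pileup columns
#'
#' Normalises the A/C/G/T counts of each covered position to fractions
#' summing to one. The frequency of the reference base equals one minus the
#' read-mismatch frequency.
#'
#' @param pileup A pileup tibble from [build_pileup()].
#' @return A long tibble with columns `contig`, `pos`, `ref`, `base`,
#'   `frequency`, restricted to positions with coverage > 0.
#' @export
base_frequencies <- function(pileup) {
  if (all(pileup$coverage == 0)) {
    rlang::abort("no covered positions: base frequencies are undefined")
  }
  pileup |>
    dplyr::filter(.data$coverage > 0) |>
    tidyr::pivot_longer(dplyr::all_of(c("A", "C", "G", "T")),
                        names_to = "base", values_to = "count") |>
    dplyr::mutate(frequency = .data$count / .data$coverage) |>
    dplyr::select("contig", "pos", "ref", "base", "frequency")
}

#' Write a pileup table to TSV
#'
#' Positions are written 1-based inclusive.
#'
#' @param pileup Pileup tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pileup_tsv <- function(pileup, path) {
  readr::write_tsv(pileup, path)
  invisible(path)
}

#' Read a pileup table written by [write_pileup_tsv()]
#'
#' @param path TSV path.
#' @return Pileup tibble.
#' @export
read_pileup_tsv <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    contig = readr::col_character(), pos = readr::col_integer(),
    ref = readr::col_character(), A = readr::col_integer(),
    C = readr::col_integer(), G = readr::col_integer(),
    T = readr::col_integer(), coverage = readr::col_integer(),
    mismatch_frequency = readr::col_double()))
}
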