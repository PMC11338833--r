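#' Construct a genomic interval
#'
#' Coordinates are 1-based inclusive throughout the package.
#'
#' @param contig Contig name.
#' @param start,end 1-based inclusive bounds, `start <= end`.
#' @param strand `"+"` or `"-"`.
#' @return A one-row tibble with columns `contig`, `start`, `end`, `strand`.
#' @export
genomic_interval <- function(contig, start, end, strand = "+") {
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 1 || start > end) {
    rlang::abort("require 1 <= start <= end")
  }
  if (!strand %in% c("+", "-")) rlang::abort("strand must be '+' or '-'")
  tibble(contig = contig, start = start, end = end, strand = strand)
}

.get_contig <- function(genome, contig) {
  i <- match(contig, genome$name)
  if (is.na(i)) rlang::abort(sprintf("contig '%s' not found in genome", contig))
  genome$seq[i]
}

# Coding sequence (5'->3') of a CDS interval as a character vector of bases.
.extract_cds <- function(chars, cds) {
  s <- chars[cds$start:cds$end]
  if (cds$strand == "-") s <- rev(unname(.COMP[s]))
  s
}

# Codon index (1-based) of genomic position g within a CDS interval.
.codon_index <- function(cds, g) {
  off <- if (cds$strand == "+") g - cds$start else cds$end - g
  off %/% 3L + 1L
}

.codon_seq <- function(cds_chars, idx) {
  paste(cds_chars[(3L * (idx - 1L) + 1L):(3L * idx)], collapse = "")
}

# Tie-break ordering shared by the designers: smaller distance of the target
# edit to the window centre, then leftmost genomic start, then strand.
.order_designs <- function(designs, window) {
  centre <- mean(window)
  designs |>
    dplyr::mutate(.dist = purrr::map_dbl(
      strsplit(.data$edited_positions, ","),
      function(p) min(abs(as.integer(p) - centre)))) |>
    dplyr::arrange(.data$.dist, .data$start, .data$strand,
                   .data$edited_positions) |>
    dplyr::select(-".dist")
}

.empty_designs <- function() {
  tibble(contig = character(), start = integer(), end = integer(),
         strand = character(), protospacer = character(), pam = character(),
         goal = character(), design_class = character(),
         edited_positions = character(), codon_index = integer(),
         codon_from = character(), codon_to = character(),
         bystander_positions = character())
}

# Editable-base protospacer positions (oriented) over a position range.
.editable_positions <- function(chars, site, base, positions) {
  g <- .proto_pos_to_genomic(site$start, site$end, site$strand, positions)
  ok <- .oriented_base(chars, g, site$strand) == base
  positions[ok]
}

#' Design stop-codon-introducing CBE guides for a coding sequence
#'
#' Finds every PAM-adjacent protospacer (either strand) whose editing window
#' contains at least one cytosine whose C-to-T conversion creates an in-frame
#' premature stop codon in the target CDS. On the sense strand the productive
#' codons are CAA->TAA, CAG->TAG and CGA->TGA; TGG becomes a stop through
#' editing of the antisense CCA (one or both cytosines, giving TAG, TGA or
#' TAA). All edit subsets of in-window cytosines are enumerated and every
#' subset producing a stop is reported as its own design; each predicted codon
#' change is verified by re-translation of the edited CDS.
#'
#' @param genome Genome tibble, named character vector, or `DNAStringSet`.
#' @param cds CDS interval ([genomic_interval()]); length must be a multiple
#'   of 3.
#' @param spec A [guide_spec()] with `editor = "CBE"`.
#' @return A tibble of designs: site columns, `goal`, `design_class`,
#'   `edited_positions` (comma-joined protospacer positions),
#'   `codon_index`, `codon_from`, `codon_to` and `bystander_positions`
#'   (other editable cytosines over protospacer positions 1-12, where
#'   deaminase activity outside the canonical window has been observed).
#'   Ordered by distance of the edit to the window centre, then genomic start.
#' @export
design_cbe_stop_guides <- function(genome, cds, spec) {
  stopifnot(inherits(spec, "guide_spec"))
  if (spec$editor != "CBE") rlang::abort("spec$editor must be 'CBE'")
  genome <- as_genome(genome)
  cds <- as.list(cds[1, ])
  if ((cds$end - cds$start + 1L) %% 3L != 0L) {
    rlang::abort("CDS length is not a multiple of 3 (frame violation)")
  }
  seq <- .get_contig(genome, cds$contig)
  chars <- .chars(seq)
  sites <- enumerate_protospacers(genome, pam = spec$pam) |>
    dplyr::filter(.data$contig == cds$contig,
                  .data$start <= cds$end, .data$end >= cds$start)
  if (nrow(sites) == 0) return(.empty_designs())

  wpos <- spec$window[1]:spec$window[2]
  rows <- list()
  for (i in seq_len(nrow(sites))) {
    site <- as.list(sites[i, ])
    editable <- .editable_positions(chars, site, "C", wpos)
    g_ed <- .proto_pos_to_genomic(site$start, site$end, site$strand, editable)
    in_cds <- g_ed >= cds$start & g_ed <= cds$end
    editable <- editable[in_cds]
    g_ed <- g_ed[in_cds]
    if (!length(editable)) next
    bystanders <- setdiff(.editable_positions(chars, site, "C", 1:12), NULL)
    # all non-empty subsets of in-window editable Cs
    for (m in seq_len(2L^length(editable) - 1L)) {
      sel <- as.logical(bitwAnd(m, 2L^(seq_along(editable) - 1L)))
      gsub_pos <- g_ed[sel]
      mut <- chars
      # C->T on the protospacer strand; on the reference plus strand that is
      # C->T for plus-strand sites and G->A for minus-strand sites
      mut[gsub_pos] <- if (site$strand == "+") "T" else "A"
      cds_mut <- .extract_cds(mut, cds)
      cds_ref <- .extract_cds(chars, cds)
      idxs <- unique(.codon_index(cds, gsub_pos))
      hit <- NULL
      for (idx in idxs) {
        from <- .codon_seq(cds_ref, idx)
        to <- .codon_seq(cds_mut, idx)
        if (translate_codon(from) != "*" && translate_codon(to) == "*") {
          hit <- list(idx = idx, from = from, to = to)
          break
        }
      }
      if (is.null(hit)) next
      rows[[length(rows) + 1L]] <- tibble(
        contig = site$contig, start = site$start, end = site$end,
        strand = site$strand, protospacer = site$protospacer, pam = site$pam,
        goal = "STOP_INTRODUCTION",
        design_class = if (site$strand == cds$strand) "sense" else "antisense",
        edited_positions = paste(editable[sel], collapse = ","),
        codon_index = hit$idx, codon_from = hit$from, codon_to = hit$to,
        bystander_positions = paste(setdiff(bystanders, editable[sel]),
                                    collapse = ","))
    }
  }
  if (!length(rows)) return(.empty_designs())
  .order_designs(dplyr::bind_rows(rows), spec$window)
}

#' Design ABE guides disrupting a start codon
#'
#' Two design classes inactivate an ATG start with an adenine base editor:
#' (i) template-strand protospacers whose window covers the adenine of the
#' template-strand CAT (pairing the T of the coding ATG); editing it gives
#' ATG->ACG on the coding strand; and (ii) coding-strand protospacers whose
#' window covers the start adenine itself, giving ATG->GTG. Each design is
#' annotated with its class and with candidate bystander adenines over
#' protospacer positions 1-12.
#'
#' @inheritParams design_cbe_stop_guides
#' @param spec A [guide_spec()] with `editor = "ABE"`.
#' @return A design tibble as in [design_cbe_stop_guides()], with
#'   `design_class` in `"template_strand"` / `"coding_strand"` and
#'   `codon_from = "ATG"`.
#' @export
design_abe_start_disruption <- function(genome, cds, spec) {
  stopifnot(inherits(spec, "guide_spec"))
  if (spec$editor != "ABE") rlang::abort("spec$editor must be 'ABE'")
  genome <- as_genome(genome)
  cds <- as.list(cds[1, ])
  seq <- .get_contig(genome, cds$contig)
  chars <- .chars(seq)
  start_codon <- paste(.extract_cds(chars, cds)[1:3], collapse = "")
  if (start_codon != "ATG") {
    rlang::abort(sprintf("CDS does not start with ATG (found %s)", start_codon))
  }
  # genomic coordinates of the three start-codon bases, coding order
  gpos <- if (cds$strand == "+") cds$start + 0:2 else cds$end - 0:2
  sites <- enumerate_protospacers(genome, pam = spec$pam) |>
    dplyr::filter(.data$contig == cds$contig)
  if (nrow(sites) == 0) return(.empty_designs())

  rows <- list()
  for (i in seq_len(nrow(sites))) {
    site <- as.list(sites[i, ])
    template <- site$strand != cds$strand
    g_target <- if (template) gpos[2] else gpos[1] # T-pairing A vs start A
    if (g_target < site$start || g_target > site$end) next
    p <- which(.proto_pos_to_genomic(site$start, site$end, site$strand,
                                     1:20) == g_target)
    if (p < spec$window[1] || p > spec$window[2]) next
    stopifnot(.oriented_base(chars, g_target, site$strand) == "A")
    mut <- chars
    mut[g_target] <- if (site$strand == "+") "G" else "C"
    to <- paste(.extract_cds(mut, cds)[1:3], collapse = "")
    stopifnot(to != "ATG", to == if (template) "ACG" else "GTG")
    bystanders <- setdiff(.editable_positions(chars, site, "A", 1:12), p)
    rows[[length(rows) + 1L]] <- tibble(
      contig = site$contig, start = site$start, end = site$end,
      strand = site$strand, protospacer = site$protospacer, pam = site$pam,
      goal = "START_DISRUPTION",
      design_class = if (template) "template_strand" else "coding_strand",
      edited_positions = as.character(p), codon_index = 1L,
      codon_from = "ATG", codon_to = to,
      bystander_positions = paste(bystanders, collapse = ","))
  }
  if (!length(rows)) return(.empty_designs())
  .order_designs(dplyr::bind_rows(rows), spec$window)
}
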