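# IUPAC nucleotide codes. A genomic N is treated conservatively: it matches
# only the wildcard N of a pattern, and mismatches every concrete base.
.IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T", "N")
)

.check_iupac <- function(pattern) {
  pc <- .chars(toupper(pattern))
  bad <- setdiff(pc, names(.IUPAC))
  if (length(bad)) {
    rlang::abort(sprintf("invalid IUPAC code(s) in PAM pattern: %s",
                         paste(bad, collapse = ", ")))
  }
  pc
}

#' Guide and editor specification
#'
#' Bundles the spacer, PAM, editor chemistry and editing-window model used by
#' the design, off-target and quantification stages. Protospacer positions are
#' numbered 1-20 from the PAM-distal 5' end, so "position 7" is the seventh
#' base of the spacer and position 20 is adjacent to the PAM. The edited and
#' product bases follow the chemistry: A->G for adenine base editors (ABE),
#' C->T for cytosine base editors (CBE).
#'
#' @param spacer Optional 20-nt spacer sequence (protospacer strand, 5'->3').
#'   May be `NULL` for design operations, which produce spacers.
#' @param editor `"ABE"` or `"CBE"`.
#' @param pam IUPAC PAM pattern immediately 3' of the protospacer
#'   (default `"NGG"`).
#' @param window Inclusive protospacer-position range where the deaminase
#'   acts (default `c(4, 8)`).
#' @return An object of class `guide_spec`.
#' @export
#' @examples
#' guide_spec("ACGTACGTACGTACGTACGT", editor = "ABE")
guide_spec <- function(spacer = NULL, editor = c("ABE", "CBE"),
                       pam = "NGG", window = c(4L, 8L)) {
  editor <- match.arg(editor)
  if (!is.null(spacer)) {
    spacer <- toupper(spacer)
    .check_dna(spacer, "spacer")
    if (nchar(spacer) != 20) rlang::abort("spacer must be exactly 20 nt")
  }
  .check_iupac(pam)
  window <- as.integer(window)
  if (length(window) != 2 || window[1] > window[2] ||
      window[1] < 1 || window[2] > 20) {
    rlang::abort("window must be an inclusive range within [1, 20]")
  }
  structure(
    list(spacer = spacer, pam = toupper(pam), editor = editor, window = window,
         edited_base = if (editor == "ABE") "A" else "C",
         product_base = if (editor == "ABE") "G" else "T"),
    class = "guide_spec")
}

#' @export
print.guide_spec <- function(x, ...) {
  cat(sprintf("<guide_spec> %s (%s->%s), PAM %s, window %d-%d\n",
              x$editor, x$edited_base, x$product_base, x$pam,
              x$window[1], x$window[2]))
  if (!is.null(x$spacer)) cat("  spacer:", x$spacer, "\n")
  invisible(x)
}

# All PAM-anchored protospacer windows on one contig, both strands.
# Returns starts/ends of the protospacer (1-based inclusive, reference
# coordinates) plus the plus-strand window range used to extract sequence.
.pam_anchored_starts <- function(chars, pam_chars, len) {
  L <- length(chars)
  k <- length(pam_chars)
  out <- list()
  # plus strand: protospacer [s, s+len-1], PAM [s+len, s+len+k-1]
  if (L >= len + k) {
    s <- seq_len(L - len - k + 1L)
    ok <- rep(TRUE, length(s))
    for (j in seq_len(k)) {
      ok <- ok & chars[s + len + j - 1L] %in% .IUPAC[[pam_chars[j]]]
    }
    if (any(ok)) {
      out$plus <- tibble(start = s[ok], end = s[ok] + len - 1L, strand = "+",
                         pam_start = s[ok] + len, pam_end = s[ok] + len + k - 1L)
    }
    # minus strand: PAM occupies plus positions [q, q+k-1] with pam char j at
    # plus position q + (k - j); protospacer at plus [q+k, q+k+len-1].
    q <- seq_len(L - len - k + 1L)
    okm <- rep(TRUE, length(q))
    for (j in seq_len(k)) {
      pb <- chars[q + (k - j)]
      okm <- okm & unname(.COMP[pb]) %in% .IUPAC[[pam_chars[j]]]
    }
    if (any(okm)) {
      out$minus <- tibble(start = q[okm] + k, end = q[okm] + k + len - 1L,
                          strand = "-", pam_start = q[okm],
                          pam_end = q[okm] + k - 1L)
    }
  }
  if (!length(out)) {
    return(tibble(start = integer(), end = integer(), strand = character(),
                  pam_start = integer(), pam_end = integer()))
  }
  dplyr::bind_rows(out)
}

.window_string <- function(seq, start, end, strand) {
  s <- stringr::str_sub(seq, start, end)
  s[strand == "-"] <- revcomp(s[strand == "-"])
  s
}

#' Enumerate all PAM-adjacent protospacers in a genome
#'
#' Scans both strands of every contig for windows of `length` nucleotides
#' immediately followed (3', on the same strand) by a PAM match. Overlapping
#' sites are all reported.
#'
#' @param genome A genome tibble ([read_fasta()]), named character vector, or
#'   `DNAStringSet`.
#' @param pam IUPAC PAM pattern (default `"NGG"`).
#' @param length Protospacer length (default 20).
#' @return A tibble with columns `contig`, `start`, `end` (1-based inclusive,
#'   reference coordinates of the protospacer), `strand`, `protospacer`
#'   (strand-oriented sequence) and `pam`, sorted by contig, start, strand.
#' @export
enumerate_protospacers <- function(genome, pam = "NGG", length = 20L) {
  genome <- as_genome(genome)
  pam_chars <- .check_iupac(pam)
  length <- as.integer(length)
  res <- purrr::map2(genome$name, genome$seq, function(nm, sq) {
    hits <- .pam_anchored_starts(.chars(sq), pam_chars, length)
    if (nrow(hits) == 0) return(NULL)
    hits$contig <- nm
    hits$protospacer <- .window_string(sq, hits$start, hits$end, hits$strand)
    hits$pam <- .window_string(sq, hits$pam_start, hits$pam_end, hits$strand)
    hits
  })
  out <- dplyr::bind_rows(res)
  if (nrow(out) == 0) {
    return(tibble(contig = character(), start = integer(), end = integer(),
                  strand = character(), protospacer = character(),
                  pam = character()))
  }
  out |>
    dplyr::select("contig", "start", "end", "strand", "protospacer", "pam") |>
    dplyr::arrange(.data$contig, .data$start, .data$strand)
}
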