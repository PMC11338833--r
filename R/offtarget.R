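#' Genome-wide candidate off-target protospacer search
#'
#' Enumerates every protospacer occurrence (both strands, PAM-matched) whose
#' sequence differs from the spacer by at most `max_mm` mismatches overall and
#' at most `max_mm_proximal` mismatches within the `proximal_len` PAM-proximal
#' protospacer positions (positions `20 - proximal_len + 1` to 20; mismatches
#' there most strongly abolish Cas9 targeting). PAM bases are matched against
#' the PAM pattern but never counted as mismatches. A genomic `N` counts as a
#' mismatch to every spacer base. The exact-match (on-target) site is returned
#' and flagged, not suppressed.
#'
#' @param genome A genome tibble, named character vector, or `DNAStringSet`.
#' @param spec A [guide_spec()] with a 20-nt spacer.
#' @param max_mm Maximum total mismatches (default 7).
#' @param max_mm_proximal Maximum mismatches among the PAM-proximal positions
#'   (default 2).
#' @param proximal_len Number of PAM-proximal positions the proximal
#'   constraint applies to (default 10).
#' @return A tibble of candidate sites: `contig`, `start`, `end`, `strand`,
#'   `protospacer`, `pam`, `mm_total`, `mm_proximal`, `mismatch_positions`
#'   (comma-joined protospacer positions), `is_on_target`; sorted by contig,
#'   start, strand.
#' @seealso [brute_force_candidates()] for the unoptimised reference scan.
#' @export
find_candidates <- function(genome, spec, max_mm = 7L, max_mm_proximal = 2L,
                            proximal_len = 10L) {
  genome <- as_genome(genome)
  stopifnot(inherits(spec, "guide_spec"))
  if (is.null(spec$spacer)) rlang::abort("spec must carry a spacer")
  len <- nchar(spec$spacer)
  if (proximal_len > len) rlang::abort("proximal_len exceeds spacer length")
  pam_chars <- .check_iupac(spec$pam)
  spacer_chars <- .chars(spec$spacer)
  rc_spacer_chars <- .chars(revcomp(spec$spacer))
  prox_cols_plus <- (len - proximal_len + 1L):len
  prox_cols_minus <- seq_len(proximal_len) # reversed orientation

  res <- purrr::map2(genome$name, genome$seq, function(nm, sq) {
    chars <- .chars(sq)
    hits <- .pam_anchored_starts(chars, pam_chars, len)
    if (nrow(hits) == 0) return(NULL)
    # mismatch matrix over the plus-strand window, left to right
    idx <- outer(hits$start - 1L, seq_len(len), `+`)
    M <- matrix(chars[idx], nrow = nrow(hits))
    mm <- matrix(FALSE, nrow(hits), len)
    plus <- hits$strand == "+"
    for (j in seq_len(len)) {
      mm[plus, j] <- M[plus, j] != spacer_chars[j]
      mm[!plus, j] <- M[!plus, j] != rc_spacer_chars[j]
    }
    mm_total <- rowSums(mm)
    mm_prox <- numeric(nrow(hits))
    mm_prox[plus] <- rowSums(mm[plus, prox_cols_plus, drop = FALSE])
    mm_prox[!plus] <- rowSums(mm[!plus, prox_cols_minus, drop = FALSE])
    keep <- mm_total <= max_mm & mm_prox <= max_mm_proximal
    if (!any(keep)) return(NULL)
    hits <- hits[keep, , drop = FALSE]
    mmk <- mm[keep, , drop = FALSE]
    plusk <- plus[keep]
    pos_list <- lapply(seq_len(nrow(hits)), function(i) {
      cols <- which(mmk[i, ])
      p <- if (plusk[i]) cols else (len + 1L - cols)
      sort(p)
    })
    mmt <- as.integer(mm_total[keep])
    mmp <- as.integer(mm_prox[keep])
    tibble(
      contig = nm, start = hits$start, end = hits$end, strand = hits$strand,
      protospacer = .window_string(sq, hits$start, hits$end, hits$strand),
      pam = .window_string(sq, hits$pam_start, hits$pam_end, hits$strand),
      mm_total = mmt,
      mm_proximal = mmp,
      mismatch_positions = vapply(pos_list, paste, "", collapse = ","),
      is_on_target = mmt == 0L
    )
  })
  out <- dplyr::bind_rows(res)
  if (nrow(out) == 0) {
    return(tibble(contig = character(), start = integer(), end = integer(),
                  strand = character(), protospacer = character(),
                  pam = character(), mm_total = integer(),
                  mm_proximal = integer(), mismatch_positions = character(),
                  is_on_target = logical()))
  }
  dplyr::arrange(out, .data$contig, .data$start, .data$strand)
}

#' Brute-force reference scan for candidate off-target sites
#'
#' Literal per-window implementation of the same contract as
#' [find_candidates()]: every window on both strands is compared to the
#' spacer character by character with no optimisation or shared machinery.
#' Intended as an independent oracle in tests; output must be identical to
#' `find_candidates()`.
#'
#' @inheritParams find_candidates
#' @return As [find_candidates()].
#' @export
brute_force_candidates <- function(genome, spec, max_mm = 7L,
                                   max_mm_proximal = 2L, proximal_len = 10L) {
  genome <- as_genome(genome)
  stopifnot(inherits(spec, "guide_spec"))
  if (is.null(spec$spacer)) rlang::abort("spec must carry a spacer")
  len <- nchar(spec$spacer)
  if (proximal_len > len) rlang::abort("proximal_len exceeds spacer length")
  pam <- .check_iupac(spec$pam)
  k <- length(pam)
  spacer <- .chars(spec$spacer)
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  prox_from <- len - proximal_len + 1L

  rows <- list()
  for (ci in seq_len(nrow(genome))) {
    chars <- strsplit(genome$seq[ci], "")[[1]]
    L <- length(chars)
    if (L < len + k) next
    for (s in seq_len(L - len - k + 1L)) {
      # plus strand window at [s, s+len-1], PAM [s+len, s+len+k-1]
      pam_ok <- TRUE
      for (j in seq_len(k)) {
        if (!(chars[s + len + j - 1L] %in% .IUPAC[[pam[j]]])) {
          pam_ok <- FALSE
          break
        }
      }
      if (pam_ok) {
        w <- chars[s:(s + len - 1L)]
        mmpos <- which(w != spacer)
        if (length(mmpos) <= max_mm &&
            sum(mmpos >= prox_from) <= max_mm_proximal) {
          rows[[length(rows) + 1L]] <- tibble(
            contig = genome$name[ci], start = s, end = s + len - 1L,
            strand = "+", protospacer = paste(w, collapse = ""),
            pam = paste(chars[(s + len):(s + len + k - 1L)], collapse = ""),
            mm_total = length(mmpos), mm_proximal = sum(mmpos >= prox_from),
            mismatch_positions = paste(mmpos, collapse = ","),
            is_on_target = length(mmpos) == 0L)
        }
      }
      # minus strand: PAM on plus [s, s+k-1], protospacer plus [s+k, s+k+len-1]
      pam_ok <- TRUE
      for (j in seq_len(k)) {
        if (!(comp[[chars[s + (k - j)]]] %in% .IUPAC[[pam[j]]])) {
          pam_ok <- FALSE
          break
        }
      }
      if (pam_ok) {
        wplus <- chars[(s + k):(s + k + len - 1L)]
        w <- rev(unname(comp[wplus])) # protospacer 5'->3' on minus strand
        mmpos <- which(w != spacer)
        if (length(mmpos) <= max_mm &&
            sum(mmpos >= prox_from) <= max_mm_proximal) {
          pam_plus <- chars[s:(s + k - 1L)]
          rows[[length(rows) + 1L]] <- tibble(
            contig = genome$name[ci], start = s + k, end = s + k + len - 1L,
            strand = "-", protospacer = paste(w, collapse = ""),
            pam = paste(rev(unname(comp[pam_plus])), collapse = ""),
            mm_total = length(mmpos), mm_proximal = sum(mmpos >= prox_from),
            mismatch_positions = paste(mmpos, collapse = ","),
            is_on_target = length(mmpos) == 0L)
        }
      }
    }
  }
  if (!length(rows)) {
    return(tibble(contig = character(), start = integer(), end = integer(),
                  strand = character(), protospacer = character(),
                  pam = character(), mm_total = integer(),
                  mm_proximal = integer(), mismatch_positions = character(),
                  is_on_target = logical()))
  }
  out <- dplyr::bind_rows(rows)
  out$start <- as.integer(out$start)
  out$end <- as.integer(out$end)
  out$mm_total <- as.integer(out$mm_total)
  out$mm_proximal <- as.integer(out$mm_proximal)
  dplyr::arrange(out, .data$contig, .data$start, .data$strand)
}
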