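#' @importFrom rlang .data %||% abort
#' @importFrom tibble tibble as_tibble
#' @import dplyr
NULL

# Complement lookup used throughout; N stays N.
.COMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

.check_dna <- function(seq, what = "sequence") {
  bad <- grepl("[^ACGTN]", seq)
  if (any(bad)) {
    abort(sprintf("%s contains characters outside {A,C,G,T,N}: %s",
                  what, paste(utils::head(unique(unlist(
                    stringr::str_extract_all(seq[bad], "[^ACGTN]"))), 5),
                    collapse = ", ")))
  }
  invisible(seq)
}

#' Read a FASTA file into a genome table
#'
#' Returns one row per record with the sequence uppercased. Only DNA is
#' accepted: sequences containing U (RNA) or other non-`{A,C,G,T,N}`
#' characters are rejected with an error naming the offending record.
#'
#' @param path Path to a FASTA file (wrapped or unwrapped lines).
#' @return A tibble with columns `name`, `seq`, `length`, in file order.
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">chr1", "acgtACGT"), fa)
#' read_fasta(fa)
read_fasta <- function(path) {
  if (!file.exists(path)) abort(sprintf("FASTA file not found: %s", path))
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) abort(sprintf(
                    "malformed FASTA '%s': %s", path, conditionMessage(e))))
  if (length(set) == 0) abort(sprintf("FASTA '%s' contains no records", path))
  seqs <- toupper(as.character(set))
  names(seqs) <- sub("\\s.*$", "", names(set))
  empty <- !nzchar(seqs)
  if (any(empty)) {
    abort(sprintf("FASTA record '%s' has an empty sequence",
                  names(seqs)[which(empty)[1]]))
  }
  for (i in seq_along(seqs)) {
    if (grepl("U", seqs[[i]], fixed = TRUE)) {
      abort(sprintf("FASTA record '%s' contains U: RNA input is not supported",
                    names(seqs)[i]))
    }
    .check_dna(seqs[[i]], sprintf("FASTA record '%s'", names(seqs)[i]))
  }
  tibble(name = names(seqs), seq = unname(seqs),
         length = unname(nchar(seqs)))
}

#' Write a genome table to FASTA
#'
#' @param genome A genome tibble (`name`, `seq`) as returned by [read_fasta()],
#'   or a named character vector of sequences.
#' @param path Output path.
#' @param width Line width for wrapping (default 70).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genome, path, width = 70) {
  genome <- as_genome(genome)
  set <- Biostrings::DNAStringSet(stats::setNames(genome$seq, genome$name))
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Coerce to a genome tibble
#'
#' Accepts a genome tibble, a (named) character vector of sequences, or a
#' `Biostrings::DNAStringSet`, and returns a tibble with `name`, `seq`,
#' `length`. Unnamed single sequences are named `contig1`, `contig2`, ...
#'
#' @param x Object to coerce.
#' @return A genome tibble.
#' @export
as_genome <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(all(c("name", "seq") %in% names(x)))
    out <- as_tibble(x[, intersect(c("name", "seq"), names(x))])
  } else if (methods::is(x, "DNAStringSet")) {
    out <- tibble(name = names(x) %||% paste0("contig", seq_along(x)),
                  seq = as.character(x))
  } else if (is.character(x)) {
    nm <- names(x) %||% paste0("contig", seq_along(x))
    nm[!nzchar(nm)] <- paste0("contig", which(!nzchar(nm)))
    out <- tibble(name = nm, seq = toupper(unname(x)))
  } else {
    abort("cannot interpret input as a genome")
  }
  .check_dna(out$seq, "genome sequence")
  out$length <- nchar(out$seq)
  out
}

#' Reverse complement of a DNA sequence
#'
#' Vectorised over sequences. `N` maps to `N`; any character outside
#' `{A,C,G,T,N}` is an error.
#'
#' @param seq Character vector of DNA sequences.
#' @return Character vector of reverse complements.
#' @export
#' @examples
#' revcomp("AAACCC")  # "GGGTTT"
revcomp <- function(seq) {
  .check_dna(toupper(seq), "sequence")
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(toupper(seq))))
}

#' Translate a single codon
#'
#' Standard genetic code (identical to bacterial table 11 for all sense and
#' stop codons used here). Stop codons return `"*"`.
#'
#' @param codon A 3-base DNA string without N.
#' @return One-letter amino-acid symbol, or `"*"` for a stop codon.
#' @export
#' @examples
#' translate_codon("TAA")  # "*"
#' translate_codon("ATG")  # "M"
translate_codon <- function(codon) {
  codon <- toupper(codon)
  if (length(codon) != 1 || nchar(codon) != 3) {
    abort("codon must be a single 3-base string")
  }
  if (grepl("[^ACGT]", codon)) abort("codon must contain only A, C, G, T (no N)")
  unname(Biostrings::GENETIC_CODE[[codon]])
}

# Split one sequence into a character vector of bases.
.chars <- function(seq) strsplit(seq, "", fixed = TRUE)[[1]]

# Protospacer position p (1 = PAM-distal) -> genomic coordinate for a site
# given by start/end/strand (1-based inclusive). strand is a scalar.
.proto_pos_to_genomic <- function(start, end, strand, p) {
  if (strand == "+") start + p - 1L else end - p + 1L
}

# Strand-oriented base(s) of a plus-strand character vector; strand scalar.
.oriented_base <- function(chars, gpos, strand) {
  b <- chars[gpos]
  if (strand == "+") b else unname(.COMP[b])
}
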