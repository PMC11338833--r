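# Shared fixture builders. Everything is generated in code; no stored data.

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# Build a pileup tibble directly from a counts matrix (rows = positions,
# columns A/C/G/T), mirroring the build_pileup output contract.
make_pileup <- function(ref, counts, contig = "chr", start_pos = 1L) {
  refchars <- strsplit(ref, "")[[1]]
  stopifnot(nrow(counts) == length(refchars))
  coverage <- rowSums(counts)
  ref_count <- counts[cbind(seq_along(refchars),
                            match(refchars, c("A", "C", "G", "T")))]
  tibble::tibble(
    contig = contig, pos = seq_along(refchars) + start_pos - 1L,
    ref = refchars,
    A = counts[, 1], C = counts[, 2], G = counts[, 3], T = counts[, 4],
    coverage = coverage,
    mismatch_frequency = ifelse(coverage > 0 & refchars %in% c("A", "C", "G", "T"),
                                (coverage - ref_count) / coverage, NA_real_))
}

# Sequencing-noise counts: each position draws coverage reads of the
# reference base, each independently miscalled to one of the other three
# bases with probability error_rate.
noise_counts <- function(refchars, coverage, error_rate) {
  bases <- c("A", "C", "G", "T")
  n <- length(refchars)
  counts <- matrix(0L, n, 4, dimnames = list(NULL, bases))
  n_err <- stats::rbinom(n, coverage, error_rate)
  for (i in seq_len(n)) {
    ri <- match(refchars[i], bases)
    counts[i, ri] <- coverage - n_err[i]
    if (n_err[i] > 0) {
      alt <- sample(setdiff(1:4, ri), n_err[i], replace = TRUE)
      tab <- tabulate(alt, 4)
      counts[i, ] <- counts[i, ] + tab
    }
  }
  counts
}

# Apply a design's predicted edits to the genome and report the resulting
# protein, using Biostrings translation as an oracle independent of
# translate_codon-based verification inside the designers.
apply_design_and_translate <- function(genome_seq, design, cds, editor) {
  chars <- strsplit(genome_seq, "")[[1]]
  pos <- as.integer(strsplit(design$edited_positions, ",")[[1]])
  g <- if (design$strand == "+") design$start + pos - 1L else design$end - pos + 1L
  product_plus <- if (editor == "CBE") {
    if (design$strand == "+") "T" else "A"
  } else {
    if (design$strand == "+") "G" else "C"
  }
  chars[g] <- product_plus
  cds_seq <- paste(chars[cds$start:cds$end], collapse = "")
  if (cds$strand == "-") {
    cds_seq <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(cds_seq)))
  }
  as.character(Biostrings::translate(Biostrings::DNAString(cds_seq),
                                     if.fuzzy.codon = "X"))
}

# Literal brute-force CBE stop-guide designer used as a completeness oracle:
# scans every NGG protospacer via the unoptimised candidate scan, tries every
# subset of in-window/in-CDS cytosines, keeps subsets whose edited CDS gains
# a premature stop.
brute_force_cbe_designs <- function(genome, cds, spec) {
  any_spacer <- guide_spec(strrep("A", 20), editor = "CBE", pam = spec$pam,
                           window = spec$window)
  sites <- brute_force_candidates(genome, any_spacer, max_mm = 20,
                                  max_mm_proximal = 10)
  sites <- sites[sites$contig == cds$contig & sites$start <= cds$end &
                   sites$end >= cds$start, ]
  chars <- strsplit(genome$seq[match(cds$contig, genome$name)], "")[[1]]
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  out <- list()
  for (i in seq_len(nrow(sites))) {
    st <- sites[i, ]
    wpos <- spec$window[1]:spec$window[2]
    g <- if (st$strand == "+") st$start + wpos - 1L else st$end - wpos + 1L
    base_or <- if (st$strand == "+") chars[g] else unname(comp[chars[g]])
    ed <- wpos[base_or == "C" & g >= cds$start & g <= cds$end]
    if (!length(ed)) next
    for (m in seq_len(2^length(ed) - 1)) {
      sel <- ed[as.logical(bitwAnd(m, 2^(seq_along(ed) - 1)))]
      mut <- chars
      gm <- if (st$strand == "+") st$start + sel - 1L else st$end - sel + 1L
      mut[gm] <- if (st$strand == "+") "T" else "A"
      ref_cds <- paste(chars[cds$start:cds$end], collapse = "")
      mut_cds <- paste(mut[cds$start:cds$end], collapse = "")
      if (cds$strand == "-") {
        ref_cds <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(ref_cds)))
        mut_cds <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(mut_cds)))
      }
      p_ref <- as.character(Biostrings::translate(Biostrings::DNAString(ref_cds)))
      p_mut <- as.character(Biostrings::translate(Biostrings::DNAString(mut_cds)))
      pr <- strsplit(p_ref, "")[[1]]
      pm <- strsplit(p_mut, "")[[1]]
      if (any(pm == "*" & pr != "*")) {
        out[[length(out) + 1]] <- data.frame(
          start = st$start, strand = st$strand,
          edited_positions = paste(sel, collapse = ","))
      }
    }
  }
  if (!length(out)) {
    return(data.frame(start = integer(), strand = character(),
                      edited_positions = character()))
  }
  unique(do.call(rbind, out))
}

rscript_bin <- function() file.path(R.home("bin"), "Rscript")

cli_path <- function() system.file("cli", "baseditr.R", package = "baseditr")
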