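#' Simulation configuration
#'
#' Bundles the parameters of the synthetic-data generator. Defaults emulate
#' the sequencing conditions of a deep amplicon-style experiment on a small
#' bacterial locus: coverage 6,000-fold, 100-nt single-end reads, and a
#' uniform 0.3% per-base substitution error.
#'
#' @param seed Integer seed; identical configurations produce byte-identical
#'   outputs.
#' @param genome_length Genome length in bases (>= 1000).
#' @param gc GC content of the random background (default 0.5).
#' @param coverage Mean fold coverage (default 6000).
#' @param read_length Read length in bases (default 100).
#' @param error_rate Per-base substitution error probability (default 0.003).
#' @param decoy_sites Optional list of `c(total, proximal)` mismatch-count
#'   pairs; one near-match decoy protospacer is planted per entry.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, genome_length = 1000L, gc = 0.5,
                       coverage = 6000, read_length = 100L,
                       error_rate = 0.003, decoy_sites = list()) {
  if (genome_length < 1000L) rlang::abort("genome_length must be >= 1 kb")
  if (gc < 0 || gc > 1) rlang::abort("gc must lie in [0, 1]")
  if (error_rate < 0 || error_rate > 1) {
    rlang::abort("error_rate must lie in [0, 1]")
  }
  for (d in decoy_sites) {
    if (length(d) != 2 || d[2] > d[1]) {
      rlang::abort("each decoy must be c(total, proximal) with proximal <= total")
    }
    if (d[1] - d[2] > 10 || d[2] > 10) {
      rlang::abort("decoy mismatch counts cannot exceed the 10 positions of each half")
    }
  }
  structure(list(seed = as.integer(seed),
                 genome_length = as.integer(genome_length), gc = gc,
                 coverage = coverage, read_length = as.integer(read_length),
                 error_rate = error_rate, decoy_sites = decoy_sites),
            class = "sim_config")
}

#' Generate a random genome with a planted protospacer and decoys
#'
#' Draws an i.i.d. random genome at the requested GC content, plants the
#' spacer with a concrete PAM once (the on-target site) and plants one
#' near-match decoy per requested `c(total, proximal)` mismatch-count pair,
#' each with exactly that many mismatches to the spacer (proximal counted
#' over protospacer positions 11-20). Planted sites are non-overlapping and
#' all on the plus strand; a manifest of truth coordinates is attached.
#'
#' @param config A [sim_config()].
#' @param spec A [guide_spec()] carrying the spacer to plant.
#' @return A genome tibble (single contig `"sim1"`) with a `manifest`
#'   attribute: a tibble of planted sites with `role`, `start`, `end`,
#'   `strand`, `protospacer`, `mm_total`, `mm_proximal`.
#' @export
make_genome <- function(config, spec) {
  stopifnot(inherits(config, "sim_config"), inherits(spec, "guide_spec"))
  if (is.null(spec$spacer)) rlang::abort("spec must carry a spacer to plant")
  set.seed(config$seed)
  L <- config$genome_length
  p <- c(A = (1 - config$gc) / 2, C = config$gc / 2, G = config$gc / 2,
         T = (1 - config$gc) / 2)
  chars <- sample(names(p), L, replace = TRUE, prob = p)
  pam <- .concrete_pam(spec$pam)
  unit <- 20L + nchar(pam)
  n_sites <- 1L + length(config$decoy_sites)
  # interior, evenly spaced, non-overlapping plant positions (kept away from
  # the genome ends so read coverage over the sites is uniform)
  slots <- floor(seq_len(n_sites) / (n_sites + 1) * (L - unit))
  if (any(diff(c(0L, slots)) < unit + 20L)) {
    rlang::abort("genome too short for the requested number of planted sites")
  }
  manifest <- list()
  spacer_chars <- .chars(spec$spacer)
  for (k in seq_len(n_sites)) {
    s <- slots[k]
    planted <- spacer_chars
    if (k == 1L) {
      role <- "on_target"; mm <- 0L; mmp <- 0L
    } else {
      d <- config$decoy_sites[[k - 1L]]
      mm <- as.integer(d[1]); mmp <- as.integer(d[2])
      pos_prox <- sample(11:20, mmp)
      pos_dist <- sample(1:10, mm - mmp)
      for (q in c(pos_prox, pos_dist)) {
        planted[q] <- sample(setdiff(c("A", "C", "G", "T"), planted[q]), 1)
      }
      role <- "decoy"
    }
    chars[s:(s + 19L)] <- planted
    chars[(s + 20L):(s + unit - 1L)] <- .chars(pam)
    manifest[[k]] <- tibble(role = role, contig = "sim1",
                            start = as.integer(s), end = as.integer(s + 19L),
                            strand = "+",
                            protospacer = paste(planted, collapse = ""),
                            mm_total = mm, mm_proximal = mmp)
  }
  genome <- tibble(name = "sim1", seq = paste(chars, collapse = ""),
                   length = L)
  attr(genome, "manifest") <- dplyr::bind_rows(manifest)
  genome
}

# First concrete base of each IUPAC code, used to instantiate a planted PAM.
.concrete_pam <- function(pattern) {
  paste(vapply(.check_iupac(pattern),
               function(ch) setdiff(.IUPAC[[ch]], "N")[1], ""),
        collapse = "")
}

#' Truth model for simulated editing at one site
#'
#' @param site One-row tibble or list with `start`, `end`, `strand` of the
#'   edited protospacer (from the [make_genome()] manifest).
#' @param target_position Protospacer position of the intended edit.
#' @param target_fraction Fraction of molecules edited at the target.
#' @param bystander_fractions Named numeric vector: per-molecule edit
#'   fraction at each bystander protospacer position, e.g.
#'   `c("1" = 0.3, "8" = 0.3)`.
#' @param linkage `"independent"` (each position edited independently) or
#'   `"conditional_on_target"` (bystanders can occur only on molecules
#'   carrying the target edit; fractions are then conditional).
#' @return An object of class `edit_truth`.
#' @export
edit_truth <- function(site, target_position = 7L, target_fraction = 0.98,
                       bystander_fractions = numeric(),
                       linkage = c("independent", "conditional_on_target")) {
  linkage <- match.arg(linkage)
  site <- as.list(tibble::as_tibble(site)[1, ])
  fr <- c(target_fraction, unname(bystander_fractions))
  if (any(fr < 0 | fr > 1)) rlang::abort("edit fractions must lie in [0, 1]")
  structure(list(site = site, target_position = as.integer(target_position),
                 target_fraction = target_fraction,
                 bystander_fractions = bystander_fractions,
                 linkage = linkage),
            class = "edit_truth")
}

#' Simulate edited sequencing reads and their truth alignments
#'
#' Draws single-end reads uniformly from the genome. Each read (molecule)
#' overlapping the edited site carries the target edit with probability
#' `target_fraction` and each bystander edit according to the linkage model;
#' uniform substitution errors are then applied at `error_rate` (an error
#' replaces the base by one of the three other bases, uniformly). Since read
#' origins are known, exact truth alignments are emitted directly as a
#' minimal SAM file (M-only CIGARs) alongside the FASTQ, so no aligner is
#' needed downstream.
#'
#' @param genome Genome tibble from [make_genome()] (single contig).
#' @param truth An [edit_truth()], or `NULL` for an unedited sample.
#' @param config A [sim_config()].
#' @param fastq,sam Output paths; defaults under `tempdir()`.
#' @return Invisibly, a list with `fastq`, `sam`, `n_reads` and the per-read
#'   truth tibble (`read`, `start`, `edited_target`).
#' @export
simulate_reads <- function(genome, truth, config,
                           fastq = tempfile(fileext = ".fastq"),
                           sam = tempfile(fileext = ".sam")) {
  stopifnot(inherits(config, "sim_config"))
  genome <- as_genome(genome)
  stopifnot(nrow(genome) == 1)
  L <- genome$length
  rl <- config$read_length
  if (rl > L) rlang::abort("read_length exceeds genome length")
  set.seed(config$seed + 1L)
  n_reads <- ceiling(config$coverage * L / rl)
  starts <- sample.int(L - rl + 1L, n_reads, replace = TRUE)
  chars <- .chars(genome$seq)
  M <- matrix(chars[outer(starts - 1L, seq_len(rl), `+`)], nrow = n_reads)

  edited_target <- rep(FALSE, n_reads)
  if (!is.null(truth)) {
    stopifnot(inherits(truth, "edit_truth"))
    site <- truth$site
    positions <- c(truth$target_position,
                   as.integer(names(truth$bystander_fractions)))
    fractions <- c(truth$target_fraction, unname(truth$bystander_fractions))
    edited_target <- stats::runif(n_reads) < truth$target_fraction
    for (j in seq_along(positions)) {
      pj <- positions[j]
      g <- .proto_pos_to_genomic(site$start, site$end, site$strand, pj)
      covered <- starts <= g & g <= starts + rl - 1L
      if (j == 1L) {
        edit_this <- edited_target
      } else if (truth$linkage == "independent") {
        edit_this <- stats::runif(n_reads) < fractions[j]
      } else {
        edit_this <- edited_target & (stats::runif(n_reads) < fractions[j])
      }
      sel <- covered & edit_this
      if (any(sel)) {
        # product base written on the reference plus strand
        ref_b <- chars[g]
        new_b <- .product_on_plus(ref_b, site$strand)
        M[cbind(which(sel), g - starts[sel] + 1L)] <- new_b
      }
    }
  }
  # uniform substitution errors
  if (config$error_rate > 0) {
    n_cells <- n_reads * rl
    n_err <- stats::rbinom(1, n_cells, config$error_rate)
    if (n_err > 0) {
      cells <- sample.int(n_cells, n_err)
      cur <- M[cells]
      alt <- vapply(cur, function(b)
        sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
      M[cells] <- alt
    }
  }
  seqs <- do.call(paste0, as.data.frame(M, stringsAsFactors = FALSE))
  ids <- sprintf("read%06d", seq_len(n_reads))
  qual <- strrep("I", rl)
  writeLines(paste0("@", ids, "\n", seqs, "\n+\n", qual), fastq)
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", genome$name, L))
  recs <- paste(ids, 0L, genome$name, starts, 60L, paste0(rl, "M"),
                "*", 0L, 0L, seqs, qual, sep = "\t")
  writeLines(c(hdr, recs), sam)
  invisible(list(fastq = fastq, sam = sam, n_reads = n_reads,
                 reads = tibble(read = ids, start = starts,
                                edited_target = edited_target)))
}

# The ABE/CBE product base expressed on the reference plus strand, given the
# plus-strand reference base at the edited position and the site strand.
.product_on_plus <- function(ref_plus, strand) {
  # A->G and C->T on the protospacer strand; complements on the other strand
  map_plus <- c(A = "G", C = "T", G = "A", T = "C")
  if (strand == "+") unname(map_plus[ref_plus]) else
    unname(.COMP[map_plus[.COMP[ref_plus]]])
}

#' Simulate two-genotype droplet partitioning
#'
#' Each genotype's template copies are distributed independently and
#' uniformly over the partitions (multinomial loading); a channel is positive
#' in a partition iff at least one copy of its genotype landed there. FAM
#' reports the unedited allele, HEX the edited allele.
#'
#' @param copies_edited,copies_unedited Non-negative template copy numbers.
#' @param n_partitions Number of droplets.
#' @param seed Integer seed.
#' @param cross_talk Probability that a droplet positive only for the other
#'   genotype also lights this channel (default 0; for sensitivity analyses
#'   of the zero-cross-reactivity assumption made by [quantify_genotypes()]).
#' @return One-row tibble with `n_total`, `n_pos_fam`, `n_pos_hex`.
#' @export
simulate_droplets <- function(copies_edited, copies_unedited,
                              n_partitions = 20000L, seed = 1L,
                              cross_talk = 0) {
  if (n_partitions <= 0) rlang::abort("n_partitions must be positive")
  if (copies_edited < 0 || copies_unedited < 0) {
    rlang::abort("copy numbers must be non-negative")
  }
  if (cross_talk < 0 || cross_talk > 1) {
    rlang::abort("cross_talk must lie in [0, 1]")
  }
  set.seed(as.integer(seed))
  occupy <- function(copies) {
    if (copies == 0) return(logical(n_partitions))
    tabulate(sample.int(n_partitions, copies, replace = TRUE),
             nbins = n_partitions) > 0L
  }
  pos_hex <- occupy(copies_edited)
  pos_fam <- occupy(copies_unedited)
  if (cross_talk > 0) {
    leak_hex <- pos_fam & !pos_hex &
      stats::runif(n_partitions) < cross_talk
    leak_fam <- pos_hex & !pos_fam &
      stats::runif(n_partitions) < cross_talk
    pos_hex <- pos_hex | leak_hex
    pos_fam <- pos_fam | leak_fam
  }
  tibble(n_total = as.integer(n_partitions),
         n_pos_hex = sum(pos_hex),
         n_pos_fam = sum(pos_fam))
}

#' Simulate selective and non-selective plating of an edited population
#'
#' Editing inactivates the resistance gene, so only unedited cells grow on
#' the selective plate: the selective count is Binomial(`n_cells`,
#' `1 - edited_fraction`). The fold reduction is computed against an
#' unedited control of the same size plated identically. When the treated
#' selective count is zero the fold reduction is censored at `n_cells`.
#'
#' @param n_cells Cells plated.
#' @param edited_fraction True edited fraction in `[0, 1]`.
#' @param seed Integer seed.
#' @return One-row tibble with `cfu_selective_treated`,
#'   `cfu_selective_control`, `cfu_nonselective`, `fold_reduction`,
#'   `censored`.
#' @export
simulate_plating <- function(n_cells, edited_fraction, seed = 1L) {
  if (edited_fraction < 0 || edited_fraction > 1) {
    rlang::abort("edited_fraction must lie in [0, 1]")
  }
  set.seed(as.integer(seed))
  sel_treated <- stats::rbinom(1, n_cells, 1 - edited_fraction)
  sel_control <- n_cells
  censored <- sel_treated == 0
  fold <- if (censored) as.numeric(n_cells) else sel_control / sel_treated
  tibble(cfu_selective_treated = sel_treated,
         cfu_selective_control = sel_control,
         cfu_nonselective = n_cells,
         fold_reduction = fold, censored = censored)
}
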