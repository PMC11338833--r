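# Hand-built geometries: the genome strings are constructed so that exactly
# one protospacer carries the codon of interest at a known window position.

test_that("CBE designer finds a CAG->TAG stop at window position 5", {
  # protospacer: b1 ATG CAG then 13 filler bases, PAM AGG; CDS = ATG CAG TTT
  proto <- paste0("T", "ATG", "CAG", "TTTATTATTATTA")
  expect_equal(nchar(proto), 20L)
  genome <- c(chr = paste0("TTATTA", proto, "AGG", "TTATTA"))
  cds <- genomic_interval("chr", 8, 16, "+") # ATG CAG TTT
  spec <- guide_spec(NULL, editor = "CBE")
  designs <- design_cbe_stop_guides(genome, cds, spec)
  expect_equal(nrow(designs), 1L)
  expect_equal(designs$edited_positions, "5")
  expect_equal(designs$codon_from, "CAG")
  expect_equal(designs$codon_to, "TAG")
  expect_equal(designs$codon_index, 2L)
  expect_equal(designs$goal, "STOP_INTRODUCTION")
  # soundness via the independent translation oracle
  prot <- apply_design_and_translate(genome[["chr"]], designs[1, ],
                                     as.list(cds), "CBE")
  expect_equal(substr(prot, 2, 2), "*")
})

test_that("CBE designer returns nothing when no codon can become a stop", {
  # CDS of ATG + GCT repeats: no CAA/CAG/CGA/TGG anywhere in frame
  genome <- c(chr = paste0("TTATTA", "TATGGCTGCTGCTGCTGCTA", "AGG", "TTATTA"))
  cds <- genomic_interval("chr", 8, 22, "+")
  expect_equal(substr(genome[["chr"]], 8, 10), "ATG")
  designs <- design_cbe_stop_guides(genome, cds, guide_spec(NULL, editor = "CBE"))
  expect_equal(nrow(designs), 0L)
})

test_that("TGG codons are stopped through the antisense CCA, including TAA", {
  # TGG at t..t+2 with an antisense protospacer placing its two Cs at window
  # positions 4 and 5 (plus-strand PAM CCT = AGG on the minus strand)
  t0 <- 21L
  chars <- strsplit(strrep("T", 50), "")[[1]]
  chars[(t0 - 17):(t0 - 15)] <- c("C", "C", "T")
  chars[(t0 - 3):(t0 - 1)] <- c("A", "T", "G")
  chars[t0:(t0 + 2)] <- c("T", "G", "G")
  chars[(t0 + 3):(t0 + 5)] <- c("A", "A", "A")
  genome <- c(chr = paste(chars, collapse = ""))
  cds <- genomic_interval("chr", t0 - 3, t0 + 5, "+") # ATG TGG AAA
  designs <- design_cbe_stop_guides(genome, cds,
                                    guide_spec(NULL, editor = "CBE"))
  expect_gt(nrow(designs), 0)
  expect_true(all(designs$strand == "-"))
  expect_setequal(unique(designs$codon_from), "TGG")
  # single edits give TAG / TGA; editing both Cs gives TAA
  expect_true(all(c("TAG", "TGA", "TAA") %in% designs$codon_to))
  taa <- designs[designs$codon_to == "TAA", ][1, ]
  expect_true(all(c(4, 5) %in% as.integer(strsplit(taa$edited_positions, ",")[[1]])))
  for (i in seq_len(nrow(designs))) {
    prot <- apply_design_and_translate(genome[["chr"]], designs[i, ],
                                       as.list(cds), "CBE")
    expect_equal(substr(prot, 2, 2), "*")
  }
})

test_that("ABE start disruption finds the template-strand ACG design", {
  # template-strand protospacer placing the CAT adenine at window position 6
  s <- 30L
  chars <- strsplit(strrep("T", 60), "")[[1]]
  chars[(s - 16):(s - 15)] <- c("C", "C")
  chars[s:(s + 2)] <- c("A", "T", "G")
  chars[(s + 3):(s + 8)] <- c("A", "A", "A", "T", "T", "A") # ATG AAA TTA
  genome <- c(chr = paste(chars, collapse = ""))
  cds <- genomic_interval("chr", s, s + 8, "+")
  designs <- design_abe_start_disruption(genome, cds,
                                         guide_spec(NULL, editor = "ABE"))
  tmpl <- designs[designs$design_class == "template_strand", ]
  expect_equal(nrow(tmpl), 1L)
  expect_equal(tmpl$strand, "-")
  expect_equal(tmpl$edited_positions, "6")
  expect_equal(tmpl$codon_to, "ACG")
  prot_start <- apply_design_and_translate(genome[["chr"]], tmpl[1, ],
                                           as.list(cds), "ABE")
  expect_false(substr(prot_start, 1, 1) == "M")
})

test_that("ABE start disruption finds the coding-strand GTG design", {
  # coding-strand protospacer with the start adenine at window position 4
  s <- 10L
  chars <- strsplit(strrep("T", 60), "")[[1]]
  chars[s:(s + 2)] <- c("A", "T", "G")
  chars[(s + 3):(s + 14)] <- strsplit("TTATTATTATTA", "")[[1]]
  chars[(s + 17):(s + 19)] <- c("A", "G", "G") # PAM for protospacer at s-3
  genome <- c(chr = paste(chars, collapse = ""))
  # CDS must stay in frame: ATG TTA TTA TTA TTA AGG -> 18 nt
  cds <- genomic_interval("chr", s, s + 17, "+")
  designs <- design_abe_start_disruption(genome, cds,
                                         guide_spec(NULL, editor = "ABE"))
  cod <- designs[designs$design_class == "coding_strand", ]
  expect_equal(nrow(cod), 1L)
  expect_equal(cod$strand, "+")
  expect_equal(cod$start, s - 3L)
  expect_equal(cod$edited_positions, "4")
  expect_equal(cod$codon_to, "GTG")
})

test_that("designers validate frame, start codon and editor chemistry", {
  genome <- c(chr = strrep("ACGT", 30))
  expect_error(design_cbe_stop_guides(genome, genomic_interval("chr", 1, 10),
                                      guide_spec(NULL, editor = "CBE")),
               "multiple of 3")
  expect_error(design_cbe_stop_guides(genome, genomic_interval("chr", 1, 9),
                                      guide_spec(NULL, editor = "ABE")),
               "CBE")
  expect_error(design_abe_start_disruption(genome, genomic_interval("chr", 2, 10),
                                           guide_spec(NULL, editor = "ABE")),
               "ATG")
  # an isolated start codon with no PAM in reach yields no designs
  lone <- c(chr = paste0(strrep("T", 40), "ATGAAATTA", strrep("T", 40)))
  designs <- design_abe_start_disruption(
    lone, genomic_interval("chr", 41, 49, "+"), guide_spec(NULL, editor = "ABE"))
  expect_equal(nrow(designs), 0L)
})

test_that("CBE designs match a literal brute-force designer on random CDSs", {
  set.seed(33)
  spec <- guide_spec(NULL, editor = "CBE")
  n_checked <- 0
  for (rep in 1:15) {
    L <- 120L
    g <- c(chr = random_dna(L, gc = 0.55))
    cds_start <- 31L
    cds <- genomic_interval("chr", cds_start, cds_start + 59L,
                            sample(c("+", "-"), 1))
    designs <- design_cbe_stop_guides(as_genome(g), cds, spec)
    oracle <- brute_force_cbe_designs(as_genome(g), as.list(cds), spec)
    got <- unique(designs[, c("start", "strand", "edited_positions")])
    key <- function(d) sort(paste(d$start, d$strand, d$edited_positions))
    expect_equal(key(got), key(oracle))
    n_checked <- n_checked + nrow(oracle)
  }
  expect_gt(n_checked, 0) # the random CDSs really exercised the designer
})
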