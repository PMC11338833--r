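# Window profiling, bystander calling, off-target comparison, genome scan,
# plate-count conversion and the delivery model, on constructed pileups.

plus_site <- function(start = 11L) {
  tibble::tibble(contig = "chr", start = start, end = start + 19L, strand = "+")
}

test_that("window_profile reads the product-base fraction at each position", {
  # plus-strand protospacer with A at positions 3 and 7 (0-indexed genome 13, 17)
  ref <- paste0(strrep("T", 10), "TTATTTATTTTTTTTTTTTT", strrep("T", 10))
  refchars <- strsplit(ref, "")[[1]]
  counts <- matrix(0L, nchar(ref), 4, dimnames = list(NULL, c("A", "C", "G", "T")))
  counts[cbind(seq_len(nchar(ref)), match(refchars, c("A", "C", "G", "T")))] <- 100L
  counts[17, ] <- c(20L, 0L, 80L, 0L) # position 7 of the protospacer: 80% A->G
  pu <- make_pileup(ref, counts)
  spec <- guide_spec(NULL, editor = "ABE")
  prof <- window_profile(pu, plus_site(), spec, target_position = 7)
  expect_s3_class(prof, "edit_profile")
  expect_equal(prof$edit_fraction[prof$position == 7], 0.80)
  expect_equal(prof$edit_fraction[prof$position == 3], 0)
  # non-editable positions are NA, not zero
  expect_true(all(is.na(prof$edit_fraction[!prof$editable])))
  expect_equal(target_fraction(prof), 0.80)
})

test_that("minus-strand sites are complemented before counting", {
  # minus-strand protospacer: genome-strand T at the target means protospacer A;
  # genome counts {T:20, C:80} mean 80% A->G on the protospacer strand
  ref <- strrep("T", 40)
  refchars <- strsplit(ref, "")[[1]]
  counts <- matrix(0L, 40, 4)
  counts[cbind(1:40, match(refchars, c("A", "C", "G", "T")))] <- 100L
  site <- tibble::tibble(contig = "chr", start = 11L, end = 30L, strand = "-")
  # protospacer position 7 on a minus site sits at genomic pos end - 7 + 1 = 24
  counts[24, ] <- c(0L, 80L, 0L, 20L)
  pu <- make_pileup(ref, counts)
  prof <- window_profile(pu, site, guide_spec(NULL, editor = "ABE"),
                         target_position = 7)
  expect_equal(prof$edit_fraction[prof$position == 7], 0.80)
  expect_equal(prof$genomic_pos[prof$position == 7], 24L)
  expect_equal(prof$ref_base[prof$position == 7], "A")
})

test_that("zero coverage at the target position is a clear error", {
  ref <- strrep("A", 40)
  counts <- matrix(0L, 40, 4)
  counts[, 1] <- 50L
  counts[17, ] <- 0L
  pu <- make_pileup(ref, counts)
  expect_error(
    window_profile(pu, plus_site(), guide_spec(NULL, editor = "ABE"),
                   target_position = 7),
    "position 7")
})

test_that("bystander calling thresholds and orders positions", {
  ref <- strrep("A", 40)
  counts <- matrix(0L, 40, 4)
  counts[, 1] <- 1000L
  # protospacer at 11-30: positions 1, 8, 9 elevated; 7 is the target
  frac <- c("1" = 0.30, "7" = 0.95, "8" = 0.12, "9" = 0.07, "12" = 0.01)
  for (p in names(frac)) {
    g <- 11L + as.integer(p) - 1L
    counts[g, ] <- c(1000L - round(1000 * frac[[p]]), 0L,
                     round(1000 * frac[[p]]), 0L)
  }
  pu <- make_pileup(ref, counts)
  prof <- window_profile(pu, plus_site(), guide_spec(NULL, editor = "ABE"),
                         target_position = 7)
  expect_equal(call_bystanders(prof), c(1L, 8L, 9L))
  expect_equal(call_bystanders(prof, min_fraction = 0.5), integer(0))
  # degenerate threshold: every editable non-target position is called
  expect_equal(call_bystanders(prof, min_fraction = 0),
               setdiff(1:20, 7L))
})

test_that("offtarget_compare flags only genuinely elevated candidates", {
  set.seed(101)
  ref <- random_dna(200, gc = 0.5)
  refchars <- strsplit(ref, "")[[1]]
  cand <- tibble::tibble(
    contig = "chr", start = c(21L, 61L, 121L), end = c(40L, 80L, 140L),
    strand = c("+", "-", "+"), is_on_target = c(TRUE, FALSE, FALSE),
    mm_total = c(0L, 3L, 5L))
  treated <- make_pileup(ref, noise_counts(refchars, 6000, 0.003))
  control <- make_pileup(ref, noise_counts(refchars, 6000, 0.003))
  rep0 <- offtarget_compare(treated, treated, cand)
  expect_true(all(rep0$elevation == 0))
  expect_false(any(rep0$elevated))

  # 5% A->G spike at one position of the second candidate, treated only
  spiked <- treated
  gpos <- 70L
  ridx <- match(spiked$ref[gpos], c("A", "C", "G", "T"))
  n_spike <- round(0.05 * spiked$coverage[gpos])
  spiked[gpos, "G"] <- spiked[gpos, "G", drop = TRUE] + n_spike
  spiked[gpos, spiked$ref[gpos]] <-
    spiked[gpos, spiked$ref[gpos], drop = TRUE] - n_spike
  spiked$mismatch_frequency[gpos] <-
    (spiked$coverage[gpos] - spiked[gpos, spiked$ref[gpos], drop = TRUE]) /
    spiked$coverage[gpos]
  rep1 <- offtarget_compare(spiked, control, cand)
  expect_true(rep1$elevated[2])
  expect_false(any(rep1$elevated[-2]))
  expect_gt(rep1$max_freq_treated[2], 0.04)

  # insufficient coverage is reported, not dropped
  low <- treated
  low$A <- low$A %/% 100L; low$C <- low$C %/% 100L
  low$G <- low$G %/% 100L; low$T <- low$T %/% 100L
  low$coverage <- low$A + low$C + low$G + low$T
  rep2 <- offtarget_compare(low, control, cand, min_cov = 100)
  expect_true(all(rep2$status == "insufficient_coverage"))
  expect_false(any(rep2$elevated))
})

test_that("genome scan distinguishes symmetric noise from a real excess", {
  set.seed(77)
  ref <- random_dna(2000, gc = 0.5)
  refchars <- strsplit(ref, "")[[1]]
  treated <- make_pileup(ref, noise_counts(refchars, 6000, 0.003))
  control <- make_pileup(ref, noise_counts(refchars, 6000, 0.003))
  identical_scan <- genome_scan_compare(treated, treated)
  expect_equal(identical_scan$n_elevated_treated, 0L)
  expect_equal(identical_scan$n_elevated_control, 0L)
  expect_equal(identical_scan$verdict, "no_elevation")

  null_scan <- genome_scan_compare(treated, control)
  expect_equal(null_scan$verdict, "no_elevation")

  # genuine 1% A->G excess in treated at adenine positions
  excess <- treated
  is_a <- excess$ref == "A"
  add <- round(0.01 * excess$coverage[is_a])
  excess$G[is_a] <- excess$G[is_a] + add
  excess$A[is_a] <- excess$A[is_a] - add
  excess$mismatch_frequency[is_a] <-
    (excess$coverage[is_a] - excess$A[is_a]) / excess$coverage[is_a]
  alt_scan <- genome_scan_compare(excess, control, base_restrict = "A")
  expect_equal(alt_scan$verdict, "elevated")
  expect_gt(alt_scan$n_elevated_treated, alt_scan$n_elevated_control)
  expect_error(genome_scan_compare(treated[0, ], control), "commonly covered")
})

test_that("fold-reduction converts to edited fraction exactly", {
  expect_equal(edited_fraction_from_fold_reduction(1), 0)
  expect_equal(edited_fraction_from_fold_reduction(1e3), 0.999)
  expect_equal(edited_fraction_from_fold_reduction(1e4), 0.9999)
  expect_error(edited_fraction_from_fold_reduction(0.5), ">= 1")
  folds <- c(1, 2, 10, 100, 1e6)
  fr <- edited_fraction_from_fold_reduction(folds)
  expect_true(all(diff(fr) > 0))
  expect_true(all(fr < 1))
})

test_that("the single-hit delivery model fits and recovers its parameter", {
  fit <- fit_delivery_model(20, 0.90)
  expect_equal(fit$a, -log(0.1) / 20, tolerance = 1e-10)
  expect_equal(predict(fit, 0), 0)
  expect_equal(predict(fit, 20), 0.9, tolerance = 1e-10)

  set.seed(5)
  moi <- c(0.5, 1, 2, 5, 10, 20, 50)
  truth_a <- 0.2
  f_obs <- pmin(0.999, pmax(0, 1 - exp(-truth_a * moi) + rnorm(7, 0, 0.01)))
  fit2 <- fit_delivery_model(moi, f_obs)
  expect_lt(abs(fit2$a - truth_a) / truth_a, 0.05)
  td <- tidy(fit2)
  expect_equal(td$term, "a")
  expect_equal(td$estimate, fit2$a)
  expect_error(fit_delivery_model(c(1, 2), c(0, 0)), "fit failed")
})
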