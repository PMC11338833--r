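# Full-loop recovery: plant a protospacer, simulate per-molecule edited reads
# at deep coverage, pile up, and profile the editing window. Used by the
# estimator-consistency tests.
recover_profile <- function(spacer, editor, target_position, target_fraction,
                            bystander_fractions = numeric(), seed = 1L,
                            coverage = 6000, error_rate = 0.003) {
  spec <- guide_spec(spacer, editor = editor)
  cfg <- sim_config(seed = seed, genome_length = 1000, coverage = coverage,
                    read_length = 100, error_rate = error_rate)
  genome <- make_genome(cfg, spec)
  site <- attr(genome, "manifest")[1, ]
  truth <- edit_truth(site, target_position = target_position,
                      target_fraction = target_fraction,
                      bystander_fractions = bystander_fractions)
  sim <- simulate_reads(genome, truth, cfg)
  pileup <- build_pileup(
    sim$sam, genome,
    intervals = tibble::tibble(contig = site$contig, start = site$start,
                               end = site$end),
    sample_label = "treated")
  window_profile(pileup, site, spec, target_position = target_position)
}

# 99% acceptance interval for the estimated fraction: the estimator counts
# product-base reads, whose per-read probability under the simulation model
# is f(1-e) + (1-f)e/3 (an error converts the true base to each other base
# with probability e/3).
recovery_interval <- function(f, error_rate, n) {
  p <- f * (1 - error_rate) + (1 - f) * error_rate / 3
  stats::qbinom(c(0.005, 0.995), n, p) / n
}

expect_recovers <- function(profile, truth_fraction, error_rate = 0.003) {
  n <- profile$coverage[profile$is_target]
  est <- target_fraction(profile)
  ci <- recovery_interval(truth_fraction, error_rate, n)
  expect_gte(est, ci[1])
  expect_lte(est, ci[2])
  invisible(est)
}
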