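#' Editing-window profile of a protospacer site
#'
#' For each protospacer position (1-20, numbered from the PAM-distal end)
#' whose strand-oriented reference base equals the editor's substrate base
#' (A for ABE, C for CBE), computes the edit fraction: the fraction of
#' covering reads carrying the product base (G or T respectively) at that
#' position. Counts are complemented when the site lies on the minus strand
#' so that fractions are always reported on the protospacer strand.
#' Positions whose reference base is not editable carry `NA`, not 0.
#'
#' @param pileup Pileup tibble from [build_pileup()] covering the site.
#' @param site One-row tibble (or list) with `contig`, `start`, `end`,
#'   `strand` of the protospacer.
#' @param spec A [guide_spec()].
#' @param target_position Protospacer position of the intended edit
#'   (default 7).
#' @return A tibble of class `edit_profile` with one row per protospacer
#'   position: `position`, `genomic_pos`, `ref_base` (protospacer-oriented),
#'   `editable`, `edit_fraction`, `coverage`, `is_target`, `in_window`.
#' @export
window_profile <- function(pileup, site, spec, target_position = 7L) {
  stopifnot(inherits(spec, "guide_spec"))
  site <- as.list(tibble::as_tibble(site)[1, ])
  positions <- 1:20
  g <- .proto_pos_to_genomic(site$start, site$end, site$strand, positions)
  rows <- pileup[match(paste(site$contig, g),
                       paste(pileup$contig, pileup$pos)), ]
  if (anyNA(rows$pos)) {
    rlang::abort("pileup does not cover the full protospacer interval")
  }
  ref_or <- if (site$strand == "+") rows$ref else unname(.COMP[rows$ref])
  # counts of the product base, read on the protospacer strand
  product_on_ref <- if (site$strand == "+") spec$product_base else
    unname(.COMP[spec$product_base])
  prod_count <- rows[[product_on_ref]]
  editable <- ref_or == spec$edited_base
  frac <- ifelse(editable & rows$coverage > 0,
                 prod_count / rows$coverage, NA_real_)
  if (editable[target_position] && rows$coverage[target_position] == 0) {
    rlang::abort(sprintf(
      "zero coverage at target protospacer position %d (reference %s:%d)",
      target_position, site$contig, g[target_position]))
  }
  out <- tibble(
    position = positions, genomic_pos = g, ref_base = ref_or,
    editable = editable, edit_fraction = frac, coverage = rows$coverage,
    is_target = positions == target_position,
    in_window = positions >= spec$window[1] & positions <= spec$window[2])
  attr(out, "site") <- site
  attr(out, "spec") <- spec
  attr(out, "sample_label") <- attr(pileup, "sample_label")
  class(out) <- c("edit_profile", class(out))
  out
}

#' On-target edit fraction of a profile
#'
#' @param profile An `edit_profile` from [window_profile()].
#' @return The edit fraction at the target position.
#' @export
target_fraction <- function(profile) {
  profile$edit_fraction[profile$is_target]
}

#' Call bystander edits in an editing-window profile
#'
#' Bystanders are editable positions other than the target whose edit
#' fraction reaches `min_fraction`. The default of 0.05 separates genuine
#' bystander deamination from sequencing error at deep coverage.
#'
#' @param profile An `edit_profile` from [window_profile()].
#' @param min_fraction Minimum edit fraction to call (default 0.05).
#' @return Integer vector of protospacer positions, ascending.
#' @export
call_bystanders <- function(profile, min_fraction = 0.05) {
  sort(profile$position[
    !profile$is_target & profile$editable &
      !is.na(profile$edit_fraction) &
      profile$edit_fraction >= min_fraction])
}

# Highest per-base non-reference frequency over a set of pileup rows.
# Ties between bases are broken alphabetically (A < C < G < T).
.max_nonref_frequency <- function(rows) {
  bases <- c("A", "C", "G", "T")
  cnt <- as.matrix(rows[, bases])
  ridx <- match(rows$ref, bases)
  has_ref <- !is.na(ridx)
  cnt[cbind(which(has_ref), ridx[has_ref])] <- -1L
  covered <- rows$coverage > 0
  if (!any(covered)) return(list(frequency = NA_real_, base = NA_character_,
                                 pos = NA_integer_))
  freq <- sweep(cnt[covered, , drop = FALSE], 1,
                rows$coverage[covered], "/")
  best <- which(freq == max(freq), arr.ind = TRUE)
  best <- best[order(best[, 1], best[, 2]), , drop = FALSE][1, ]
  list(frequency = max(freq),
       base = bases[best[["col"]]],
       pos = rows$pos[covered][best[["row"]]])
}

#' Compare candidate off-target sites between treated and control samples
#'
#' For each candidate site, reports the mismatch frequency of the base with
#' the highest frequency across the 20 protospacer positions in each sample,
#' and flags the site as elevated when the treated value exceeds the control
#' value by more than `threshold`. Candidates with coverage below `min_cov`
#' at any protospacer position are reported with an insufficient-coverage
#' status rather than silently dropped.
#'
#' @param treated,control Pileup tibbles from [build_pileup()] covering all
#'   candidate intervals.
#' @param candidates Candidate tibble from [find_candidates()].
#' @param min_cov Minimum per-position coverage required (default 100).
#' @param threshold Elevation threshold on the frequency difference
#'   (default 0.005, about three times the per-base Illumina error scale).
#' @return A tibble of class `offtarget_report`: candidate columns plus
#'   `max_freq_treated`, `max_freq_control`, `max_base_treated`, `elevation`,
#'   `status` (`"ok"` or `"insufficient_coverage"`), `elevated`.
#' @export
offtarget_compare <- function(treated, control, candidates, min_cov = 100L,
                              threshold = 0.005) {
  res <- purrr::map(seq_len(nrow(candidates)), function(i) {
    cand <- candidates[i, ]
    g <- .proto_pos_to_genomic(cand$start, cand$end, cand$strand, 1:20)
    key <- paste(cand$contig, g)
    rt <- treated[match(key, paste(treated$contig, treated$pos)), ]
    rc <- control[match(key, paste(control$contig, control$pos)), ]
    if (anyNA(rt$pos) || anyNA(rc$pos)) {
      rlang::abort(sprintf(
        "pileup does not cover candidate %s:%d-%d", cand$contig, cand$start,
        cand$end))
    }
    low_cov <- any(rt$coverage < min_cov) || any(rc$coverage < min_cov)
    mt <- .max_nonref_frequency(rt)
    mc <- .max_nonref_frequency(rc)
    tibble(max_freq_treated = mt$frequency, max_freq_control = mc$frequency,
           max_base_treated = mt$base,
           elevation = mt$frequency - mc$frequency,
           status = if (low_cov) "insufficient_coverage" else "ok")
  })
  out <- dplyr::bind_cols(candidates, dplyr::bind_rows(res))
  out$elevated <- out$status == "ok" & !is.na(out$elevation) &
    out$elevation > threshold
  attr(out, "threshold") <- threshold
  attr(out, "min_cov") <- min_cov
  class(out) <- c("offtarget_report", class(out))
  out
}

#' Genome-wide mutation-rate comparison between treated and control
#'
#' Counts reference positions whose read-mismatch frequency is elevated in
#' the treated sample relative to the control by more than `threshold` (and
#' the symmetric count in the control direction), over positions covered at
#' `min_cov` or more in both samples. A deaminase-driven global increase in
#' mutation rate would produce an asymmetry between the two counts; the two
#' directions are compared with a two-sided binomial sign test at level 0.05
#' and the verdict is "no_elevation" when they are statistically
#' indistinguishable.
#'
#' @param treated,control Pileup tibbles on the same reference.
#' @param threshold Frequency-difference threshold (default 0.005).
#' @param min_cov Minimum coverage in both samples (default 100).
#' @param base_restrict Optional reference base (e.g. `"A"` for an adenine
#'   base editor) to restrict the scan to.
#' @return An object of class `genome_scan_result`: counts, test p-value and
#'   verdict (`"no_elevation"`, `"elevated"`, or `"elevated_in_control"`).
#' @export
genome_scan_compare <- function(treated, control, threshold = 0.005,
                                min_cov = 100L, base_restrict = NULL) {
  key_t <- paste(treated$contig, treated$pos)
  key_c <- paste(control$contig, control$pos)
  shared <- intersect(key_t, key_c)
  rt <- treated[match(shared, key_t), ]
  rc <- control[match(shared, key_c), ]
  ok <- rt$coverage >= min_cov & rc$coverage >= min_cov &
    !is.na(rt$mismatch_frequency) & !is.na(rc$mismatch_frequency)
  if (!is.null(base_restrict)) ok <- ok & rt$ref == base_restrict
  if (!any(ok)) rlang::abort("no commonly covered positions to compare")
  d <- rt$mismatch_frequency[ok] - rc$mismatch_frequency[ok]
  n_t <- sum(d > threshold)
  n_c <- sum(d < -threshold)
  p <- if (n_t + n_c == 0) 1 else
    stats::binom.test(n_t, n_t + n_c, 0.5)$p.value
  verdict <- if (p >= 0.05) "no_elevation" else
    if (n_t > n_c) "elevated" else "elevated_in_control"
  structure(list(n_elevated_treated = n_t, n_elevated_control = n_c,
                 n_positions = sum(ok), threshold = threshold,
                 min_cov = min_cov, base_restrict = base_restrict,
                 p_value = p, verdict = verdict),
            class = "genome_scan_result")
}

#' @export
print.genome_scan_result <- function(x, ...) {
  cat(sprintf(paste0(
    "<genome_scan_result> %d positions compared (min coverage %d)\n",
    "  elevated in treated: %d   elevated in control: %d ",
    "(|diff| > %.4g)\n  sign test p = %.3g -> verdict: %s\n"),
    x$n_positions, x$min_cov, x$n_elevated_treated, x$n_elevated_control,
    x$threshold, x$p_value, x$verdict))
  invisible(x)
}

#' Edited fraction implied by a selective-plating fold reduction
#'
#' A fold-reduction `F` in colony counts on selective plates (control over
#' treated) implies that a fraction `1 - 1/F` of the population carries the
#' inactivating edit: a 10^4-fold reduction corresponds to 99.99% edited.
#'
#' @param fold Fold reduction, `>= 1`. Vectorised.
#' @return Edited fraction in `[0, 1)`.
#' @export
#' @examples
#' edited_fraction_from_fold_reduction(1e4)  # 0.9999
edited_fraction_from_fold_reduction <- function(fold) {
  if (any(fold < 1)) rlang::abort("fold reduction must be >= 1")
  1 - 1 / fold
}

#' Fit a single-hit delivery dose-response model
#'
#' Models the delivered fraction of a bacterial population as
#' `f(MOI) = 1 - exp(-a * MOI)`, the single-hit Poisson form in which each
#' of `MOI` particles per cell independently delivers with probability `a`.
#' `f(0) = 0` is enforced by the model form. With a single observation the
#' closed-form solution `a = -log(1 - f) / MOI` is used; otherwise `a` is
#' estimated by least squares.
#'
#' @param moi Numeric vector of multiplicities of infection (particles per
#'   bacterium), `>= 0`.
#' @param delivered_fraction Observed delivered fractions in `[0, 1)`.
#' @return An object of class `delivery_fit` with the estimate `a`, its
#'   standard error (NA for the single-point fit) and the data.
#' @export
#' @examples
#' fit <- fit_delivery_model(20, 0.90)
#' fit$a  # about 0.115
fit_delivery_model <- function(moi, delivered_fraction) {
  stopifnot(length(moi) == length(delivered_fraction), length(moi) >= 1)
  if (any(moi < 0)) rlang::abort("MOI must be non-negative")
  if (any(delivered_fraction < 0 | delivered_fraction >= 1)) {
    rlang::abort("delivered fractions must lie in [0, 1)")
  }
  if (all(delivered_fraction == 0)) {
    rlang::abort("all delivered fractions are zero: delivery model fit failed")
  }
  data <- tibble(moi = moi, delivered_fraction = delivered_fraction)
  pos <- moi > 0 & delivered_fraction > 0
  a0 <- stats::median(-log(1 - delivered_fraction[pos]) / moi[pos])
  if (length(moi) == 1) {
    a <- a0
    se <- NA_real_
    rss <- 0
  } else {
    fit <- stats::nls(delivered_fraction ~ 1 - exp(-a * moi), data = data,
                      start = list(a = a0), algorithm = "port",
                      lower = 1e-12, upper = 1)
    a <- unname(stats::coef(fit)["a"])
    se <- tryCatch(unname(summary(fit)$coefficients["a", "Std. Error"]),
                   error = function(e) NA_real_)
    rss <- sum(stats::resid(fit)^2)
  }
  a <- min(max(a, 1e-12), 1)
  structure(list(a = a, se = se, rss = rss, n = length(moi), data = data),
            class = "delivery_fit")
}

#' Predicted delivered fraction under a fitted single-hit model
#'
#' @param object A `delivery_fit`.
#' @param newdata Optional tibble with an `moi` column, or a numeric vector
#'   of MOIs; defaults to the fitted data.
#' @param ... Unused.
#' @return Numeric vector of predicted delivered fractions.
#' @export
predict.delivery_fit <- function(object, newdata = NULL, ...) {
  moi <- if (is.null(newdata)) object$data$moi
         else if (is.numeric(newdata)) newdata else newdata$moi
  1 - exp(-object$a * moi)
}

#' @export
print.delivery_fit <- function(x, ...) {
  cat(sprintf(
    "<delivery_fit> f(MOI) = 1 - exp(-a MOI), a = %.4g (n = %d points)\n",
    x$a, x$n))
  invisible(x)
}
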