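#' Mean copies per partition from the negative-droplet fraction
#'
#' Under Poisson loading of template molecules into droplets, the mean
#' occupancy is recovered from the fraction of negative partitions as
#' `lambda = -log(n_neg / n_total)`.
#'
#' @param n_neg Number of negative partitions (must be positive: a channel
#'   with no negatives is saturated and lambda is unbounded).
#' @param n_total Total number of partitions.
#' @return Mean copies per partition. Vectorised.
#' @export
#' @examples
#' lambda_from_droplets(7358, 20000)  # about 1.0
lambda_from_droplets <- function(n_neg, n_total) {
  if (any(n_total <= 0)) rlang::abort("n_total must be positive")
  if (any(n_neg > n_total)) rlang::abort("n_neg cannot exceed n_total")
  if (any(n_neg <= 0)) {
    rlang::abort("channel saturated (no negative partitions): lambda is unbounded")
  }
  -log(n_neg / n_total)
}

#' Quantify two genotypes from dual-channel droplet counts
#'
#' The assay uses two competing probes on the same amplicon: FAM reports the
#' unedited allele and HEX the edited allele, each on distinct template
#' molecules. The two channels are therefore treated as independent Poisson
#' loadings and each channel's mean occupancy is estimated from its own
#' negative-partition count. The edited fraction is
#' `lambda_hex / (lambda_fam + lambda_hex)`, with a 95% confidence interval
#' by the delta method on the log-negative-fraction scale propagated to the
#' ratio.
#'
#' @param counts Tibble with columns `n_total`, `n_pos_fam`, `n_pos_hex` and
#'   optionally `sample` and `partition_volume_ul` (per-partition volume in
#'   microlitres; when present, absolute copies per microlitre are added).
#' @return The input tibble with `lambda_fam`, `lambda_hex`,
#'   `edited_fraction`, `ci_low`, `ci_high` (and `copies_per_ul_fam`,
#'   `copies_per_ul_hex` when a partition volume is given) appended.
#' @export
quantify_genotypes <- function(counts) {
  counts <- tibble::as_tibble(counts)
  needed <- c("n_total", "n_pos_fam", "n_pos_hex")
  if (!all(needed %in% names(counts))) {
    rlang::abort(sprintf("counts must have columns %s",
                         paste(needed, collapse = ", ")))
  }
  if (any(counts$n_pos_fam > counts$n_total |
          counts$n_pos_hex > counts$n_total |
          counts$n_pos_fam < 0 | counts$n_pos_hex < 0)) {
    rlang::abort("positive counts must lie in [0, n_total]")
  }
  neg_fam <- counts$n_total - counts$n_pos_fam
  neg_hex <- counts$n_total - counts$n_pos_hex
  if (any(neg_fam == 0 & neg_hex == 0)) {
    rlang::abort("both channels saturated: genotype ratio is undefined")
  }
  if (any(neg_fam == 0 | neg_hex == 0)) {
    rlang::abort("saturated channel (no negative partitions): dilute and re-run")
  }
  lf <- lambda_from_droplets(neg_fam, counts$n_total)
  lh <- lambda_from_droplets(neg_hex, counts$n_total)
  f <- lh / (lf + lh)
  # Var(lambda_hat) = (1 - p_neg) / (n * p_neg) for p_neg the negative fraction
  vf <- (1 - neg_fam / counts$n_total) / neg_fam
  vh <- (1 - neg_hex / counts$n_total) / neg_hex
  vfrac <- (lf^2 * vh + lh^2 * vf) / (lf + lh)^4
  half <- stats::qnorm(0.975) * sqrt(vfrac)
  out <- counts |>
    dplyr::mutate(lambda_fam = lf, lambda_hex = lh, edited_fraction = f,
                  ci_low = pmax(0, f - half), ci_high = pmin(1, f + half))
  if ("partition_volume_ul" %in% names(counts)) {
    out <- out |>
      dplyr::mutate(copies_per_ul_fam = lf / .data$partition_volume_ul,
                    copies_per_ul_hex = lh / .data$partition_volume_ul)
  }
  class(out) <- c("genotype_quant", class(out))
  out
}

#' Read a droplet-count CSV
#'
#' Expected columns: `sample`, `n_total`, `n_pos_fam`, `n_pos_hex` and
#' optionally `partition_volume_ul`.
#'
#' @param path CSV path.
#' @return A droplet-count tibble.
#' @export
read_droplet_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}
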