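#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a fitted single-hit delivery model
#'
#' @param x A `delivery_fit` from [fit_delivery_model()].
#' @param ... Unused.
#' @return One-row tibble with `term`, `estimate`, `std.error`.
#' @export
tidy.delivery_fit <- function(x, ...) {
  tibble(term = "a", estimate = x$a, std.error = x$se)
}

#' @rdname tidy.delivery_fit
#' @return For `glance()`: one-row tibble with `a`, `rss`, `nobs` and the
#'   MOI required for 50% and 90% delivery under the fit.
#' @export
glance.delivery_fit <- function(x, ...) {
  tibble(a = x$a, rss = x$rss, nobs = x$n,
         moi50 = -log(0.5) / x$a, moi90 = -log(0.1) / x$a)
}

#' Tidy an editing-window profile
#'
#' @param x An `edit_profile` from [window_profile()].
#' @param ... Unused.
#' @return The profile as a plain tibble, restricted to editable positions.
#' @export
tidy.edit_profile <- function(x, ...) {
  out <- as_tibble(x)[x$editable, ]
  class(out) <- setdiff(class(out), "edit_profile")
  out
}

#' @rdname tidy.edit_profile
#' @param min_fraction Bystander threshold passed to [call_bystanders()].
#' @return For `glance()`: one-row tibble with the on-target fraction, the
#'   number of bystander calls, and the mean coverage over the protospacer.
#' @export
glance.edit_profile <- function(x, min_fraction = 0.05, ...) {
  tibble(target_position = x$position[x$is_target],
         target_fraction = target_fraction(x),
         n_bystanders = length(call_bystanders(x, min_fraction)),
         mean_coverage = mean(x$coverage))
}

#' Tidy a genome-scan comparison
#'
#' @param x A `genome_scan_result` from [genome_scan_compare()].
#' @param ... Unused.
#' @return One-row tibble with the elevation counts, p-value and verdict.
#' @export
glance.genome_scan_result <- function(x, ...) {
  tibble(n_elevated_treated = x$n_elevated_treated,
         n_elevated_control = x$n_elevated_control,
         n_positions = x$n_positions, threshold = x$threshold,
         p_value = x$p_value, verdict = x$verdict)
}
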