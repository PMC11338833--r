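#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an editing-window profile
#'
#' Bar chart of the per-position edit fraction over the protospacer, with
#' the target position highlighted and the editing window shaded.
#'
#' @param object An `edit_profile` from [window_profile()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.edit_profile <- function(object, ...) {
  spec <- attr(object, "spec")
  df <- as_tibble(object)[object$editable, ]
  df$role <- ifelse(df$is_target, "target", "bystander candidate")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position,
                                   y = .data$edit_fraction,
                                   fill = .data$role)) +
    ggplot2::annotate("rect", xmin = spec$window[1] - 0.5,
                      xmax = spec$window[2] + 0.5, ymin = -Inf, ymax = Inf,
                      alpha = 0.12) +
    ggplot2::geom_col() +
    ggplot2::scale_x_continuous(breaks = 1:20, limits = c(0.5, 20.5)) +
    ggplot2::labs(x = "protospacer position (1 = PAM-distal)",
                  y = sprintf("%s->%s edit fraction", spec$edited_base,
                              spec$product_base),
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a treated-vs-control off-target report
#'
#' Paired bars of the highest-frequency mismatched base per candidate site
#' in the treated and control samples, candidates ordered by mismatch count.
#'
#' @param object An `offtarget_report` from [offtarget_compare()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.offtarget_report <- function(object, ...) {
  df <- as_tibble(object)
  df$label <- ifelse(df$is_on_target, "On",
                     sprintf("%s:%d(%s)", df$contig, df$start, df$strand))
  df$label <- factor(df$label,
                     levels = df$label[order(df$mm_total, df$start)])
  long <- tidyr::pivot_longer(
    df, dplyr::all_of(c("max_freq_treated", "max_freq_control")),
    names_to = "sample", values_to = "mismatch_frequency")
  long$sample <- sub("max_freq_", "", long$sample)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$label,
                                     y = .data$mismatch_frequency,
                                     fill = .data$sample)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "candidate site", y = "max base mismatch frequency",
                  fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot a fitted delivery dose-response
#'
#' @param object A `delivery_fit` from [fit_delivery_model()].
#' @param ... Unused.
#' @return A ggplot object with the observed points and the fitted
#'   `1 - exp(-a MOI)` curve.
#' @export
autoplot.delivery_fit <- function(object, ...) {
  grid <- tibble(moi = seq(0, max(object$data$moi) * 1.1, length.out = 200))
  grid$delivered_fraction <- predict(object, grid)
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$moi,
                                            y = .data$delivered_fraction)) +
    ggplot2::geom_line(data = grid, colour = "grey40") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "MOI (particles per bacterium)",
                  y = "delivered fraction") +
    ggplot2::theme_minimal()
}
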