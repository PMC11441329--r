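# Figures -----------------------------------------------------------------

#' Plot aligned mean profiles with SEM ribbons
#'
#' Mean +/- SEM intensity versus position relative to the PSD-95 peak, per
#' channel and condition, with a dashed reference line at the peak position.
#'
#' @param aligned An `aligned_profiles` object, or a summary tibble with
#'   columns `position_nm`, `channel`, `mean`, `sem` (and optionally
#'   `condition`).
#' @param channels Channels to show (default: all).
#' @return A ggplot object.
#' @export
plot_aligned_profiles <- function(aligned, channels = NULL) {
  df <- if (inherits(aligned, "aligned_profiles")) aligned$summary
        else as_tibble(aligned)
  if (!is.null(channels)) df <- df |> filter(.data$channel %in% channels)
  has_cond <- "condition" %in% names(df)
  aes_line <- if (has_cond) {
    ggplot2::aes(x = .data$position_nm, y = .data$mean,
                 color = .data$condition, fill = .data$condition)
  } else {
    ggplot2::aes(x = .data$position_nm, y = .data$mean)
  }
  ggplot2::ggplot(df, aes_line) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed",
                        color = "grey50") +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sem,
                                      ymax = .data$mean + .data$sem),
                         alpha = 0.25, color = NA) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~ channel, scales = "free_y") +
    ggplot2::labs(x = "position relative to PSD-95 peak (nm)",
                  y = "intensity (a.u.)") +
    ggplot2::theme_classic()
}

#' @rdname plot_aligned_profiles
#' @param object An `aligned_profiles` object.
#' @param ... Passed to [plot_aligned_profiles()].
#' @importFrom ggplot2 autoplot
#' @export
autoplot.aligned_profiles <- function(object, ...) {
  plot_aligned_profiles(object, ...)
}

#' Per-synapse peak levels by condition
#'
#' Open-circle scatter of per-synapse in-window peak values with the group
#' mean +/- SEM overlaid.
#'
#' @param peaks Tidy peak table with `condition` and `peak_value` columns
#'   (see [summarize_peaks()]).
#' @return A ggplot object.
#' @export
plot_peak_levels <- function(peaks) {
  ggplot2::ggplot(peaks, ggplot2::aes(x = .data$condition,
                                      y = .data$peak_value)) +
    ggplot2::geom_jitter(width = 0.15, shape = 1, alpha = 0.6) +
    ggplot2::stat_summary(fun.data = ggplot2::mean_se, geom = "pointrange",
                          color = "red") +
    ggplot2::labs(x = NULL, y = "peak level (a.u.)") +
    ggplot2::theme_classic()
}
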