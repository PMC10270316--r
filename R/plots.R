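#' Trial-latency histogram (array onset to button press)
#'
#' @param truth A `wd_truth` or a row-bound table of several.
#' @param binwidth Bin width in seconds.
#' @return A ggplot.
#' @export
plot_latency_histogram <- function(truth, binwidth = 0.25) {
  df <- tibble::tibble(latency = truth$press_s - truth$array_onset_s)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$latency,
                                   y = ggplot2::after_stat(!!rlang::sym("count")) /
                                     nrow(df) * 100)) +
    ggplot2::geom_histogram(binwidth = binwidth, fill = "steelblue",
                            colour = "white") +
    ggplot2::labs(x = "Trial response latency (s)", y = "% of trials") +
    ggplot2::theme_minimal()
}

#' Target reaction-time histogram
#'
#' @param truth A `wd_truth` or a row-bound table of several.
#' @param binwidth Bin width in seconds.
#' @return A ggplot.
#' @export
plot_rt_histogram <- function(truth, binwidth = 0.05) {
  df <- tibble::tibble(rt = truth$target_rt_s)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rt,
                                   y = ggplot2::after_stat(!!rlang::sym("count")) /
                                     nrow(df) * 100)) +
    ggplot2::geom_histogram(binwidth = binwidth, fill = "darkorange",
                            colour = "white") +
    ggplot2::labs(x = "Reaction time relative to target (s)",
                  y = "% of trials") +
    ggplot2::theme_minimal()
}

# Azimuthal-equidistant projection of unit-sphere electrode positions:
# distance from the vertex maps to planar radius, so the whole scalp
# flattens into a disc viewed from above (nose up).
project_montage <- function(montage) {
  r <- acos(pmin(1, pmax(-1, montage$z)))
  az <- atan2(montage$x, montage$y)  # 0 = anterior
  tibble::tibble(channel = montage$name,
                 px = r * sin(az), py = r * cos(az))
}

#' Scalp topography map
#'
#' Renders per-channel values at projected electrode positions with a
#' diverging colour scale symmetric about zero (scaled by the largest
#' absolute value across all facets).
#'
#' @param map Tibble with columns `channel`, `value`, optionally a facet
#'   column.
#' @param montage A `wd_montage`.
#' @param facet Optional name of a column in `map` to facet by.
#' @return A ggplot.
#' @export
plot_topography <- function(map, montage = default_montage(), facet = NULL) {
  pos <- project_montage(montage)
  df <- dplyr::inner_join(map, pos, by = "channel")
  lim <- max(abs(df$value), na.rm = TRUE)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$px, y = .data$py,
                                        fill = .data$value)) +
    ggplot2::geom_point(shape = 21, size = 5, colour = "grey30") +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red",
                                  limits = c(-lim, lim)) +
    ggplot2::coord_equal() +
    ggplot2::theme_void() +
    ggplot2::labs(fill = "value")
  if (!is.null(facet)) {
    p <- p + ggplot2::facet_wrap(stats::as.formula(paste("~", facet)), nrow = 1)
  }
  p
}

#' Plot a group decoding curve
#'
#' Group mean accuracy (smoothed for display) with an SE ribbon and the
#' chance reference line.
#'
#' @param object A `wd_decoding`.
#' @param smooth Apply the five-point display smoothing (default `TRUE`).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.wd_decoding <- function(object, smooth = TRUE, ...) {
  df <- tidy(object)
  df$acc <- if (smooth) df$acc_smoothed else df$mean_acc
  df <- df[!is.na(df$acc) & !is.na(df$se), ]  # edge timepoints have no window
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_ms, y = .data$acc)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$acc - .data$se,
                                      ymax = .data$acc + .data$se),
                         fill = "gold", alpha = 0.5) +
    ggplot2::geom_line(colour = "black") +
    ggplot2::geom_hline(yintercept = object$chance_level,
                        linetype = "dashed") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey40") +
    ggplot2::labs(x = "Time (ms)", y = "Decoding accuracy") +
    ggplot2::theme_minimal()
}

#' Plot cluster inference over the group decoding curve
#'
#' As [autoplot.wd_decoding()], with the timepoints inside significant
#' clusters (p < 0.05) shaded under the curve.
#'
#' @param object A `wd_clusters`.
#' @param ... Passed to the decoding autoplot.
#' @return A ggplot.
#' @export
autoplot.wd_clusters <- function(object, ...) {
  p <- autoplot(object$observed, ...)
  sig <- object$clusters[object$clusters$p < 0.05, , drop = FALSE]
  if (nrow(sig) > 0) {
    p <- p + ggplot2::geom_rect(
      data = as.data.frame(sig), inherit.aes = FALSE,
      ggplot2::aes(xmin = .data$start_ms, xmax = .data$end_ms,
                   ymin = object$observed$chance_level - 0.02,
                   ymax = object$observed$chance_level + 0.02),
      fill = "grey50", alpha = 0.5)
  }
  p
}

#' Plot an IRASA decomposition
#'
#' Total, fractal and oscillatory power spectra on a log power axis over
#' 2-30 Hz.
#'
#' @param object A `wd_irasa`.
#' @param freq_range Frequency range to display.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.wd_irasa <- function(object, freq_range = c(2, 30), ...) {
  df <- tidy(object)
  df <- df[df$freq >= freq_range[1] & df$freq <= freq_range[2], ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$freq, y = .data$psd,
                                   colour = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Frequency (Hz)", y = expression(PSD~(mu*V^2/Hz))) +
    ggplot2::theme_minimal()
}
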