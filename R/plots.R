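# ggplot2 figure helpers: rose plots, axial polarity histograms, FRAP
# recovery curves.

#' Rose plot of polarized follicle angles
#'
#' Circular histogram of growth angles with anterior (0 degrees) at the top
#' and angles increasing counterclockwise, the standard presentation for
#' follicle-orientation data.
#'
#' @param summary One-row tibble from [summarize_calls()] (uses the `rose`
#'   list-column), or the rose tibble itself.
#' @return A ggplot object.
#' @export
plot_rose <- function(summary) {
  rose <- if ("rose" %in% names(summary)) summary$rose[[1]] else summary
  ggplot2::ggplot(rose, ggplot2::aes(x = .data$bin_mid, y = .data$count)) +
    ggplot2::geom_col(width = diff(rose$bin_start[1:2]),
                      fill = "grey35", colour = "white") +
    ggplot2::coord_polar(start = 0, direction = -1) +
    ggplot2::scale_x_continuous(limits = c(0, 360),
                                breaks = seq(0, 315, by = 45)) +
    ggplot2::labs(x = "growth angle (deg, anterior = 0)", y = "follicles") +
    ggplot2::theme_minimal()
}

#' Axial histogram of per-cell polarity
#'
#' Displays the `[0, 180)` axial histogram from [aggregate_polarity()] on a
#' full circle by mirroring each axis to `axis + 180`, as circular polarity
#' histograms conventionally do, with the mean nematic vector overlaid.
#'
#' @param summary One-row tibble from [aggregate_polarity()].
#' @return A ggplot object.
#' @export
plot_polarity_histogram <- function(summary) {
  h <- summary$histogram[[1]]
  h2 <- dplyr::bind_rows(h, dplyr::mutate(h, bin_mid = .data$bin_mid + 180))
  width <- diff(h$bin_start[1:2])
  ggplot2::ggplot(h2, ggplot2::aes(x = .data$bin_mid, y = .data$count)) +
    ggplot2::geom_col(width = width, fill = "steelblue", colour = "white") +
    ggplot2::geom_vline(xintercept = summary$mean_axis_deg,
                        colour = "red", linewidth = 1) +
    ggplot2::coord_polar(direction = -1) +
    ggplot2::scale_x_continuous(limits = c(0, 360),
                                breaks = seq(0, 315, by = 45)) +
    ggplot2::labs(
      x = "polarity axis (deg)",
      y = "cells",
      subtitle = sprintf("mean axis %.1f deg, mean magnitude %.3f",
                         summary$mean_axis_deg, summary$mean_magnitude)
    ) +
    ggplot2::theme_minimal()
}

#' Plot FRAP recovery with its one-phase fit
#'
#' @param x A `"frap_fit"` object, or the `curve` tibble from
#'   [frap_summarize()] (mean with SD ribbon per condition).
#' @return A ggplot object.
#' @export
plot_frap <- function(x) {
  if (inherits(x, "frap_fit")) {
    df <- augment(x)
    return(
      ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s)) +
        ggplot2::geom_point(ggplot2::aes(y = .data$value),
                            colour = "grey40", size = 1) +
        ggplot2::geom_line(ggplot2::aes(y = .data$.fitted), colour = "red") +
        ggplot2::labs(
          x = "time after bleach (s)", y = "normalized intensity",
          subtitle = sprintf(
            "Plateau %.3f, k %.3g /s, immobile fraction %.3f, r2 %.3f",
            x$plateau, x$k, x$immobile_fraction, x$r_squared)
        ) +
        ggplot2::theme_minimal()
    )
  }
  ggplot2::ggplot(x, ggplot2::aes(x = .data$time_s, y = .data$mean,
                                  colour = .data$condition,
                                  fill = .data$condition)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sd,
                                      ymax = .data$mean + .data$sd),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time after bleach (s)", y = "normalized intensity") +
    ggplot2::theme_minimal()
}
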