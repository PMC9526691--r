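need_ggplot <- function() {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plotting requires the ggplot2 package", call. = FALSE)
  }
}

#' Plot a polar concentration or probability grid as a rose
#'
#' Renders a `polar_grid` as a filled polar tile plot (direction on the
#' angular axis, speed on the radial axis), the standard presentation for
#' NWR/SWIM surfaces and joint-probability wind roses.
#'
#' @param grid A `polar_grid`.
#' @param title Optional plot title.
#' @return A ggplot object.
#' @export
plot_polar_grid <- function(grid, title = NULL) {
  need_ggplot()
  ns <- length(grid$speed_breaks) - 1
  sb <- grid$speed_breaks
  sb[is.infinite(sb)] <- max(sb[is.finite(sb)]) * 1.5
  df <- data.frame(
    direction = rep(grid$dir_centers, times = ns),
    speed = rep((sb[-(ns + 1)] + sb[-1]) / 2, each = length(grid$dir_centers)),
    value = as.vector(grid$values))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$direction, y = .data$speed,
                                   fill = .data$value)) +
    ggplot2::geom_tile(width = 360 / length(grid$dir_centers)) +
    ggplot2::coord_polar(start = 0) +
    ggplot2::scale_x_continuous(limits = c(-360 / (2 * length(grid$dir_centers)),
                                           360 - 360 / (2 * length(grid$dir_centers))),
                                breaks = c(0, 90, 180, 270),
                                labels = c("N", "E", "S", "W")) +
    ggplot2::scale_fill_viridis_c(na.value = "grey95") +
    ggplot2::labs(x = NULL, y = "wind speed (km/h)", fill = grid$kind,
                  title = title) +
    ggplot2::theme_minimal()
}

#' Plot a pollen calendar
#'
#' Taxa as rows, the 60 month-sections as columns, tiles shaded by
#' flowering-period class and outlined by allergenicity class.
#'
#' @param cal Output of [build_calendar()].
#' @return A ggplot object.
#' @export
plot_pollen_calendar <- function(cal) {
  need_ggplot()
  df <- tibble::as_tibble(cal)
  df$slot <- (df$month - 1) * 5 + df$section
  ggplot2::ggplot(df, ggplot2::aes(x = .data$slot, y = .data$taxon,
                                   fill = .data$period_class,
                                   colour = .data$allergenicity)) +
    ggplot2::geom_tile(linewidth = 0.3) +
    ggplot2::scale_x_continuous(breaks = seq(3, 60, by = 5),
                                labels = month.abb) +
    ggplot2::scale_fill_manual(values = c(none = "white", possible = "grey85",
                                          early = "gold", late = "orange",
                                          main = "firebrick")) +
    ggplot2::labs(x = NULL, y = NULL, fill = "flowering period",
                  colour = "allergenicity") +
    ggplot2::theme_minimal()
}

#' Plot a diurnal profile
#'
#' @param profile Output of [mean_hourly_profile()].
#' @return A ggplot object.
#' @export
plot_diurnal_profile <- function(profile) {
  need_ggplot()
  mode <- attr(profile, "mode")
  ggplot2::ggplot(tibble::as_tibble(profile),
                  ggplot2::aes(x = .data$hour, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "hour of day",
                  y = if (identical(mode, "percent"))
                    "% of daily total" else "grains/m³") +
    ggplot2::theme_minimal()
}
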