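#' Heat map of a speed x distance correlation grid
#'
#' @param x a [bin_speed_distance()] result.
#' @param min_count cells with fewer observations are blanked.
#' @return a ggplot object (tiles coloured by mean directional correlation).
#' @export
plot_speed_distance_grid <- function(x, min_count = 10) {
  d <- as.data.frame(x, min_count = min_count)
  d$speed_mid <- (d$speed_lo + d$speed_hi) / 2
  d$distance_mid <- (d$distance_lo + d$distance_hi) / 2
  ggplot2::ggplot(d, ggplot2::aes(x = .data$distance_mid, y = .data$speed_mid,
                                  fill = .data$mean_r)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red",
                                  limits = c(-1, 1), na.value = "grey90",
                                  name = "r") +
    ggplot2::labs(x = "pair distance (mm)", y = "mutual speed (mm/s)") +
    ggplot2::theme_minimal()
}

#' Arrow-over-heat-map plot of a focal alignment map
#'
#' Tiles show the per-cell mean resultant length `R` of partner-minus-focal
#' heading differences; arrows show the circular mean direction. The focal
#' fish sits at the origin travelling along +x.
#'
#' @param x a [bin_focal_map()] result.
#' @param min_count cells with fewer observations are blanked.
#' @return a ggplot object.
#' @export
plot_focal_map <- function(x, min_count = 10) {
  d <- as.data.frame(x, min_count = min_count)
  d$x_mid <- (d$x_lo + d$x_hi) / 2
  d$y_mid <- (d$y_lo + d$y_hi) / 2
  cw <- min(diff(x$x_edges)) * 0.4
  d$xend <- d$x_mid + cw * cos(d$mean_direction)
  d$yend <- d$y_mid + cw * sin(d$mean_direction)
  ok <- !is.na(d$mean_direction)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x_mid, y = .data$y_mid)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$R)) +
    ggplot2::geom_segment(data = d[ok, ],
                          ggplot2::aes(xend = .data$xend, yend = .data$yend),
                          arrow = ggplot2::arrow(length = ggplot2::unit(1.5, "mm")),
                          linewidth = 0.3) +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), na.value = "grey90") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "relative x (mm)", y = "relative y (mm)") +
    ggplot2::theme_minimal()
}
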