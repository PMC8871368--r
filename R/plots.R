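#' Raster plot of spike trains with detected bursts
#'
#' @param spikes Spike table (`unit_id`, `time_s`).
#' @param bursts Optional `prehear_bursts` object; detected bursts are drawn
#'   as shaded windows.
#' @return A ggplot object.
#' @export
plot_spike_raster <- function(spikes, bursts = NULL) {
  p <- ggplot2::ggplot(spikes,
                       ggplot2::aes(x = .data$time_s, y = .data$unit_id)) +
    ggplot2::geom_point(shape = "|", size = 2) +
    ggplot2::labs(x = "time (s)", y = NULL)
  if (!is.null(bursts) && nrow(bursts$bursts)) {
    p <- p + ggplot2::geom_segment(
      data = bursts$bursts,
      ggplot2::aes(x = .data$start_s, xend = .data$end_s,
                   y = .data$unit_id, yend = .data$unit_id),
      colour = "red", linewidth = 2, alpha = 0.35)
  }
  p
}

#' Heatmap of a frequency response area
#'
#' @param object A `prehear_fra`.
#' @param ... Unused.
#' @return A ggplot object (rate in AP/s over frequency and level, log
#'   frequency axis).
#' @export
autoplot.prehear_fra <- function(object, ...) {
  r <- fra_rates(object)
  df <- tidyr::expand_grid(level_db = object$levels_db,
                           freq_khz = object$freqs_khz)
  df$rate_hz <- as.vector(r)
  ggplot2::ggplot(df, ggplot2::aes(.data$freq_khz, .data$level_db,
                                   fill = .data$rate_hz)) +
    ggplot2::geom_raster() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_fill_viridis_c(name = "AP/s") +
    ggplot2::labs(x = "frequency (kHz)", y = "level (dB SPL)")
}

#' Colour-coded uncaging input map
#'
#' Reproduces the site colour code: yellow for depolarizations > 2 mV,
#' orange for > 10 mV, red for action potentials, open squares otherwise,
#' with the nucleus outline overlaid.
#'
#' @param sites Classified site table (see [classify_sites()]).
#' @param polygon Outline tibble `x_um`, `y_um`.
#' @return A ggplot object.
#' @export
plot_input_map <- function(sites, polygon) {
  if (!"class" %in% names(sites)) sites <- classify_sites(sites)
  cols <- c(unresponsive = "white", responsive_2mV = "gold",
            responsive_10mV = "darkorange", action_potential = "red")
  ggplot2::ggplot(sites, ggplot2::aes(.data$x_um, .data$y_um)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$class),
                       width = 18, height = 18, colour = "grey40") +
    ggplot2::geom_path(data = rbind(polygon, polygon[1, ]),
                       linetype = "dotted") +
    ggplot2::scale_fill_manual(values = cols, drop = FALSE) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "mediolateral (µm)", y = "dorsoventral (µm)")
}
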