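#' Plot a cross-section through a concentration field
#'
#' A 2-D raster of one z-plane, the view in which the local 'hot-spots'
#' around release sites are visible.
#'
#' @param object A [da_field()].
#' @param slice_z z-index of the plane (default: middle of the grid).
#' @param trans Colour-scale transform (default `"sqrt"`, which keeps the
#'   hot-spots from saturating the palette).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot da_field
#' @export
autoplot.da_field <- function(object, slice_z = NULL, trans = "sqrt", ...) {
  g <- field_grid(object)
  slice_z <- slice_z %||% ceiling(g$shape[3] / 2)
  df <- tidy.da_field(object)
  df <- df[df$z == slice_z, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$conc_nM)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "[DA] (nM)", trans = trans) +
    ggplot2::coord_fixed() +
    ggplot2::labs(
      title = sprintf("Extracellular dopamine, z = %d um plane, t = %g s",
                      slice_z, field_time(object)),
      x = "x (um)", y = "y (um)") +
    ggplot2::theme_minimal()
}

#' Plot the volume-mean concentration trace of a trajectory
#'
#' @param object A `da_trajectory`.
#' @param thin Keep every `thin`-th step (plotting all ~8000 steps is
#'   wasteful).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot da_trajectory
#' @export
autoplot.da_trajectory <- function(object, thin = 10L, ...) {
  tr <- object$traces[seq(1, nrow(object$traces), by = thin), ]
  ggplot2::ggplot(tr, ggplot2::aes(x = .data$time, y = .data$mean_nM)) +
    ggplot2::geom_line(colour = "#2c7fb8") +
    ggplot2::labs(x = "time (s)", y = "volume-mean [DA] (nM)") +
    ggplot2::theme_minimal()
}

#' Plot distance-resolved concentration traces
#'
#' Mean (solid) and +/- one standard deviation (dashed) across release
#' sites, per probe radius — the canonical view of how far a phasic episode
#' reaches.
#'
#' @param object A `da_distance_trace` from [distance_timeseries()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot da_distance_trace
#' @export
autoplot.da_distance_trace <- function(object, ...) {
  df <- dplyr::mutate(object, radius = factor(.data$radius_um))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, colour = .data$radius)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$mean_nM)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$mean_nM + .data$sd_nM),
                       linetype = "dashed", alpha = 0.6) +
    ggplot2::geom_line(ggplot2::aes(y = pmax(.data$mean_nM - .data$sd_nM, 0)),
                       linetype = "dashed", alpha = 0.6) +
    ggplot2::scale_colour_manual(
      name = "distance (um)",
      values = c("1" = "#d7191c", "2" = "#fdae61", "5" = "#1a9641"),
      na.value = "grey40") +
    ggplot2::labs(x = "time (s)", y = "[DA] (nM)") +
    ggplot2::theme_minimal()
}
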