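#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_raster
#'   geom_abline facet_wrap labs scale_fill_viridis_c theme_minimal
NULL

#' @export
ggplot2::autoplot

#' Plot probe time series of a simulation record
#'
#' One panel per field (`K_o`, `nu`, `V`, ...), coloured by probe.
#'
#' @param object A `sim_record`.
#' @param fields Character vector of probe columns to show.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sim_record <- function(object, fields = c("K_o", "nu"), ...) {
  long <- tidy(object) |>
    tidyr::pivot_longer(dplyr::all_of(fields), names_to = "field")
  ggplot(long, aes(x = .data$t, y = .data$value, colour = .data$probe)) +
    geom_line(linewidth = 0.3) +
    facet_wrap(~field, ncol = 1, scales = "free_y") +
    labs(x = "time (s)", y = NULL) +
    theme_minimal()
}

#' Plot a field snapshot
#'
#' @param record A `sim_record` with snapshots.
#' @param t Time (s); the nearest snapshot is shown.
#' @param field One of `"K_o"`, `"V"`, `"phi"`, `"nu_env"`.
#' @return A ggplot object.
#' @export
plot_field <- function(record, t = 0, field = "K_o") {
  if (is.null(record$snapshots)) abort("record has no snapshots")
  k <- which.min(abs(record$snapshots$t - t))
  m <- record$snapshots[[field]][, , k]
  dom <- record$domain
  d <- tidyr::expand_grid(i = seq_len(dom$nx), j = seq_len(dom$ny)) |>
    mutate(x = (.data$i - 0.5) * dom$dx, y = (.data$j - 0.5) * dom$dx,
           value = m[cbind(.data$i, .data$j)])
  ggplot(d, aes(.data$x, .data$y, fill = .data$value)) +
    geom_raster() +
    scale_fill_viridis_c(name = field) +
    labs(x = "x (mm)", y = "y (mm)",
         title = sprintf("%s at t = %.3g s", field, record$snapshots$t[k])) +
    theme_minimal()
}

#' @describeIn wavefront_speed Arrival-time plot with the fitted front.
#' @param object A `wavefront_fit`.
#' @param ... Unused.
#' @export
autoplot.wavefront_fit <- function(object, ...) {
  ggplot(object$arrivals, aes(.data$t_arrive, .data$distance)) +
    geom_point() +
    geom_abline(intercept = object$intercept, slope = object$speed,
                colour = "red") +
    labs(x = "arrival time (s)", y = "distance (mm)",
         title = sprintf("front speed %.3g mm/s", object$speed)) +
    theme_minimal()
}

#' @describeIn space_time_pattern y-t raster of the strip potential.
#' @param object A `space_time_pattern`.
#' @param ... Unused.
#' @export
autoplot.space_time_pattern <- function(object, ...) {
  d <- tidyr::expand_grid(ti = seq_along(object$t),
                          yi = seq_along(object$y)) |>
    mutate(t = object$t[.data$ti], y = object$y[.data$yi],
           V = object$V[cbind(.data$ti, .data$yi)])
  ggplot(d, aes(.data$t, .data$y, fill = .data$V)) +
    geom_raster() +
    scale_fill_viridis_c(name = "V (mV)") +
    labs(x = "time (s)", y = "y (mm)") +
    theme_minimal()
}

#' @describeIn integrate_neuron Membrane-potential trace with spikes.
#' @param object A `spike_trace`.
#' @param ... Unused.
#' @export
autoplot.spike_trace <- function(object, ...) {
  ggplot(tidy(object), aes(.data$t, .data$U)) +
    geom_line(linewidth = 0.2) +
    labs(x = "time (s)", y = "U (mV)") +
    theme_minimal()
}
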