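#' Plot an atom's temporal waveform and activation profile
#'
#' @param atom a `csc_atom`.
#' @return A ggplot showing the temporal pattern `v` (seconds vs amplitude).
#' @export
plot_atom <- function(atom) {
  stopifnot(inherits(atom, "csc_atom"))
  df <- tibble(time_s = (seq_along(atom$v) - 1) / atom$sfreq,
               amplitude = atom$v)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s, y = .data$amplitude)) +
    ggplot2::geom_line(linewidth = 0.6) +
    ggplot2::labs(x = "time (s)", y = "temporal pattern v",
                  title = sprintf("atom %s (score %.2f, %d events)",
                                  atom$id %||% atom$k, atom$score,
                                  NROW(atom$assigned_events))) +
    ggplot2::theme_minimal()
}

#' Plot a cortical map as a 2-D projection of the source space
#'
#' Vertices are projected onto the x-y plane (a top view of the
#' hemisphere); active vertices are highlighted.
#'
#' @param map a [cortical_map()].
#' @return A ggplot.
#' @export
plot_cortical_map <- function(map) {
  stopifnot(inherits(map, "cortical_map"))
  df <- tibble(x = map$vertex_coords[, 1], y = map$vertex_coords[, 2],
               value = map$values)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   colour = .data$value)) +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_colour_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)", colour = map$kind,
                  title = sprintf("cortical map (%s)", map$kind)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.cortical_map <- function(object, ...) plot_cortical_map(object)

#' Dot plot of irritative-zone distances per subject and estimate
#'
#' Distance of each estimate from the resection border on the x-axis,
#' estimates on the y-axis, one colour per subject; when a `size_ratio`
#' column is present the dot size shows the IZ/RA size ratio.
#'
#' @param cmp an [compare_iz_estimates()] result.
#' @return A ggplot.
#' @export
plot_iz_distances <- function(cmp) {
  stopifnot(inherits(cmp, "iz_comparison"))
  df <- cmp$data
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$distance_mm,
                                        y = .data$estimate,
                                        colour = factor(.data$subject)))
  p <- if ("size_ratio" %in% names(df)) {
    p + ggplot2::geom_point(ggplot2::aes(size = .data$size_ratio), alpha = 0.8)
  } else {
    p + ggplot2::geom_point(size = 3, alpha = 0.8)
  }
  p + ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(x = "mean signed distance from resection border (mm)",
                  y = NULL, colour = "subject", size = "IZ/RA size") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
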