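#' Plot a metric series
#'
#' Time-indexed series are drawn as a line over steps with protocol
#' regions shaded; residue-indexed series (RMSF) as a line over residue
#' numbers.
#'
#' @param object A `metric_series`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.metric_series <- function(object, ...) {
  units <- attr(object, "units")
  metric <- attr(object, "metric")
  if ("resno" %in% names(object)) {
    p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$resno,
                                              y = .data$value,
                                              colour = .data$chain)) +
      ggplot2::geom_line() +
      ggplot2::labs(x = "residue", y = paste0(metric, " [", units, "]"))
    return(p)
  }
  aes <- if ("segment" %in% names(object))
    ggplot2::aes(x = .data$step, y = .data$value, colour = .data$segment)
  else ggplot2::aes(x = .data$step, y = .data$value)
  p <- ggplot2::ggplot(object, aes)
  if ("region" %in% names(object) && !all(is.na(object$region))) {
    bounds <- object |>
      filter(!is.na(.data$region)) |>
      group_by(.data$region) |>
      summarise(xmin = min(.data$step), xmax = max(.data$step))
    p <- p + ggplot2::geom_rect(
      data = bounds,
      ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                   ymin = -Inf, ymax = Inf, fill = .data$region),
      alpha = 0.12, inherit.aes = FALSE) +
      ggplot2::scale_fill_brewer(palette = "Set2")
  }
  p + ggplot2::geom_line() +
    ggplot2::labs(x = "step", y = paste0(metric, " [", units, "]"))
}

#' Plot the energy traces of a protocol trajectory
#'
#' @param object A `cg_trajectory`.
#' @param ... Unused.
#' @return A ggplot with potential and bias energy per recorded frame.
#' @exportS3Method ggplot2::autoplot
autoplot.cg_trajectory <- function(object, ...) {
  long <- object$frames |>
    tidyr::pivot_longer(c("bias_energy", "potential_energy"),
                        names_to = "term", values_to = "energy")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$step, y = .data$energy,
                                     colour = .data$term)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "step", y = "energy [kBT]")
}
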