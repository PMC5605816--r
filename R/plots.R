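#' Failure-rate curves against feedback density
#'
#' One line per noise level, faceted by damage level (and by memory set
#' and auxiliary size when several are present): the view that shows
#' whether a denser auxiliary-to-original interface lowers the failure
#' rate at a given damage level.
#'
#' @param result a `sweep_result` tibble.
#' @return A ggplot object.
#' @export
plot_failure_rate <- function(result) {
  ggplot2::ggplot(result,
                  ggplot2::aes(x = .data$density_B, y = .data$failure_rate,
                               colour = factor(.data$noise_level),
                               group = factor(.data$noise_level))) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_grid(
      rows = ggplot2::vars(.data$memory_set_kind, .data$n_aux),
      cols = ggplot2::vars(.data$damage_level),
      labeller = ggplot2::label_both
    ) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "density of feedback block B",
                  y = "failure rate",
                  colour = "cue noise") +
    ggplot2::theme_minimal()
}

#' Performance surface over damage and noise
#'
#' Heatmap of mean retrieval performance against damage level and cue
#' noise for one memory set / auxiliary size / feedback density slice
#' (facets appear automatically if several slices are present).
#'
#' @param result a `sweep_result` tibble (typically one density slice).
#' @return A ggplot object.
#' @export
plot_performance_surface <- function(result) {
  ggplot2::ggplot(result,
                  ggplot2::aes(x = .data$damage_level, y = .data$noise_level,
                               fill = .data$performance)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = "damage level", y = "cue noise",
                  fill = "performance") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.sweep_result <- function(object, type = c("failure", "performance"),
                                  ...) {
  type <- match.arg(type)
  if (type == "failure") plot_failure_rate(object)
  else plot_performance_surface(object)
}

#' Draw a memory pattern as a bitmap
#'
#' @param pattern a [memory_pattern()] or ±1 vector.
#' @param height,width bitmap shape.
#' @return A ggplot object (ink pixels dark).
#' @export
plot_pattern <- function(pattern, height = 40, width = 25) {
  if (height * width != length(pattern)) {
    stop("height * width must equal the pattern length", call. = FALSE)
  }
  df <- tibble::tibble(
    row = rep(seq_len(height), each = width),
    col = rep(seq_len(width), times = height),
    value = factor(as.integer(pattern), levels = c(-1, 1))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_manual(values = c(`-1` = "grey10", `1` = "white"),
                               guide = "none") +
    ggplot2::coord_equal() +
    ggplot2::theme_void()
}
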