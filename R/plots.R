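#' Plot a lift curve
#'
#' Lift against rate of positive prediction, with the random-expectation
#' line at 1.
#'
#' @param object A [lift_curve()] tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.lift_curve <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$rate, y = .data$lift)) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "rate of positive prediction", y = "lift") +
    ggplot2::theme_minimal()
}

#' Plot grouped lift curves
#'
#' For the long tibbles produced by [lift_by_relation()] (grouping column
#' `relation`) or [lift_by_distance()] (grouped by relation and distance
#' `category`).
#'
#' @param curves Long lift tibble.
#' @return A ggplot object.
#' @export
plot_lift <- function(curves) {
  has_cat <- "category" %in% names(curves)
  p <- ggplot2::ggplot(
    curves,
    if (has_cat) {
      ggplot2::aes(x = .data$rate, y = .data$lift,
                   colour = .data$category, group = .data$category)
    } else {
      ggplot2::aes(x = .data$rate, y = .data$lift,
                   colour = .data$relation, group = .data$relation)
    }
  ) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "rate of positive prediction", y = "lift") +
    ggplot2::theme_minimal()
  if (has_cat) p <- p + ggplot2::facet_wrap(ggplot2::vars(.data$relation))
  p
}

#' Plot a Pareto threshold search
#'
#' All evaluated thresholds in objective space, with the non-dominated
#' front and the selected point highlighted.
#'
#' @param object A [pareto_threshold()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pareto_result <- function(object, ...) {
  ox <- object$objectives[1]
  oy <- object$objectives[2]
  ggplot2::ggplot(object$grid,
                  ggplot2::aes(x = .data[[ox]], y = .data[[oy]])) +
    ggplot2::geom_point(colour = "grey60", size = 1) +
    ggplot2::geom_point(data = object$front, colour = "steelblue") +
    ggplot2::geom_point(data = object$selected, colour = "firebrick",
                        size = 3, shape = 17) +
    ggplot2::labs(x = ox, y = oy) +
    ggplot2::theme_minimal()
}

#' Plot an ADR-fraction curve
#'
#' Fraction of a relation's top-ranked pairs that are also ADR-disease
#' pairs, against the rate of positive prediction.
#'
#' @param object An [adr_fraction_curve()] tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.adr_fraction_curve <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$rate, y = .data$fraction)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "rate of positive prediction",
                  y = "fraction ADR-disease") +
    ggplot2::theme_minimal()
}
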