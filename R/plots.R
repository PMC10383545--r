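#' Plot factor profiles with explained-variation dots
#'
#' Bars show each factor's profile on a log scale; dots overlay the
#' explained-variation share of each species, the quantity tracer rules
#' act on.
#'
#' @param object A `pmf_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pmf_fit <- function(object, ...) {
  td <- tidy(object)
  ggplot2::ggplot(td, ggplot2::aes(x = .data$species)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$profile), fill = "steelblue") +
    ggplot2::geom_point(ggplot2::aes(y = .data$explained_variation),
                        colour = "firebrick", size = 1) +
    ggplot2::scale_y_sqrt() +
    ggplot2::facet_wrap(~factor, ncol = 1) +
    ggplot2::labs(x = NULL,
                  y = "profile fraction (bars) / explained variation (dots)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' Plot a factor-number scan
#'
#' Q/Qexp against the number of factors, with the suggested elbow marked.
#'
#' @param object A `pmf_scan`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pmf_scan <- function(object, ...) {
  p <- ggplot2::ggplot(object$summary,
                       ggplot2::aes(x = .data$k, y = .data$q_ratio)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "number of factors", y = "Q / Qexp") +
    ggplot2::theme_minimal()
  if (!is.na(object$suggested_k)) {
    p <- p + ggplot2::geom_vline(xintercept = object$suggested_k,
                                 linetype = "dashed", colour = "firebrick")
  }
  p
}

#' Plot source contribution time series
#'
#' @param model A `pmf_fit` with timestamps.
#' @param labels Optional labelling from [label_factors()].
#' @return A ggplot object (stacked area of ng/m3 contributions).
#' @export
plot_contributions <- function(model, labels = NULL) {
  cs <- contribution_series(model, labels)
  ggplot2::ggplot(cs, ggplot2::aes(x = .data$timestamp,
                                   y = .data$contribution,
                                   fill = .data$source)) +
    ggplot2::geom_area() +
    ggplot2::labs(x = NULL, y = "contribution (ng/m3)", fill = "source") +
    ggplot2::theme_minimal()
}

#' Plot the lifetime-risk index series
#'
#' @param risk Output of [risk_series()].
#' @return A ggplot object.
#' @export
plot_lifetime_index <- function(risk) {
  idx <- lifetime_risk_index(risk)
  ggplot2::ggplot(idx, ggplot2::aes(x = .data$timestamp,
                                    y = .data$lifetime_index)) +
    ggplot2::geom_line(colour = "firebrick") +
    ggplot2::labs(x = NULL, y = "lifetime-risk index") +
    ggplot2::theme_minimal()
}
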