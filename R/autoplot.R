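#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a Johnson-Neyman band
#'
#' Simple slope of the mediator on the outcome across the moderator, with its
#' confidence ribbon; regions where the band excludes zero are the regions of
#' significance, and the analytic crossover points are drawn as dashed lines.
#'
#' @param object A [johnson_neyman()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.jn_band <- function(object, ...) {
  crossings <- attr(object, "crossings")
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$z, y = .data$slope)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$ci_lower, ymax = .data$ci_upper),
      fill = "steelblue", alpha = 0.25
    ) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey40") +
    ggplot2::labs(
      x = "moderator (latent metric)",
      y = "simple slope b1 + b3 z",
      title = "Johnson-Neyman band"
    )
  if (length(crossings)) {
    p <- p + ggplot2::geom_vline(xintercept = crossings, linetype = 3)
  }
  p
}

#' Plot evaluation metrics of a simulation cell
#'
#' Dot plot of one evaluation measure per estimator and target parameter,
#' with its conventional acceptability band where one exists.
#'
#' @param object A [summarize_cell()] result.
#' @param measure One of `"bias"`, `"se_ratio"`, `"coverage"`, `"rate"`,
#'   `"completion_rate"`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mm_metrics <- function(object, measure = c("bias", "se_ratio",
                                                    "coverage", "rate",
                                                    "completion_rate"), ...) {
  measure <- match.arg(measure)
  df <- tibble::as_tibble(object)
  df$value <- df[[measure]]
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$term, y = .data$value,
                                        colour = .data$estimator)) +
    ggplot2::geom_point(position = ggplot2::position_dodge(width = 0.5)) +
    ggplot2::labs(x = "target parameter", y = measure)
  band <- switch(measure,
    bias = c(-0.10, 0.10),
    se_ratio = c(0.9, 1.1),
    coverage = c(0.90, NA),
    NULL
  )
  if (!is.null(band)) {
    p <- p + ggplot2::geom_hline(yintercept = band[is.finite(band)],
                                 linetype = 2, colour = "grey50")
  }
  p
}
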