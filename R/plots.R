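#' Plot a per-position efficiency profile
#'
#' Position-wise editing efficiencies per substitution class, optionally
#' with the editing window shaded.
#'
#' @param object An `efficiency_profile` tibble.
#' @param window Optional integer vector of window positions to shade.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot efficiency_profile
#' @export
autoplot.efficiency_profile <- function(object, window = NULL, ...) {
  p <- ggplot2::ggplot(object,
                       ggplot2::aes(x = .data$position, y = .data$efficiency,
                                    colour = .data$class)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "protospacer position", y = "editing efficiency",
                  colour = "class") +
    ggplot2::theme_minimal()
  if (!is.null(window) && length(window)) {
    p <- p + ggplot2::annotate("rect", xmin = min(window) - 0.5,
                               xmax = max(window) + 0.5, ymin = -Inf,
                               ymax = Inf, alpha = 0.1, fill = "grey30")
  }
  p
}

#' @describeIn quantify Plot the quantified profile with its window shaded.
#' @param object A `be_quant` object.
#' @param ... Unused.
#' @method autoplot be_quant
#' @export
autoplot.be_quant <- function(object, ...) {
  autoplot(object$profile, window = object$window)
}
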