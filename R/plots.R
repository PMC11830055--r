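# ggplot2 autoplot methods for the result objects

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a concentration profile
#'
#' @param object A `dkr_profile`.
#' @param ... Unused.
#' @return A ggplot: both species against the radial coordinate.
#' @export
autoplot.dkr_profile <- function(object, ...) {
  df <- tidy.dkr_profile(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$value,
                                   colour = .data$species)) +
    ggplot2::geom_line(linewidth = 0.7) +
    ggplot2::labs(x = "dimensionless radius x", y = "dimensionless concentration",
                  colour = NULL,
                  title = paste0("Concentration profiles (", object$method[1], ")")) +
    ggplot2::scale_colour_manual(
      values = c(s1 = "#1b6ca8", s2 = "#c0392b"),
      labels = c(s1 = "(S)-ester S1", s2 = "(R)-ester S2"))
}

#' Plot a series-vs-numeric comparison
#'
#' @param object A `dkr_comparison`.
#' @param ... Unused.
#' @return A ggplot: the numerical solution as a line, the series solution
#'   as points.
#' @export
autoplot.dkr_comparison <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$x)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$numeric,
                                    linetype = "collocation")) +
    ggplot2::geom_point(ggplot2::aes(y = .data$hpm, shape = "series"),
                        size = 2) +
    ggplot2::labs(x = "dimensionless radius x",
                  y = paste0("concentration ", attr(object, "species")),
                  linetype = NULL, shape = NULL,
                  title = sprintf("Series vs numeric (mean error %.4g%%)",
                                  attr(object, "average_pct_error")))
}

#' Plot a validity map
#'
#' @param object A `dkr_validity`.
#' @param fit Optional `dkr_validity_fit` whose frontier line is overlaid.
#' @param ... Unused.
#' @return A ggplot tile map of the valid region.
#' @export
autoplot.dkr_validity <- function(object, fit = NULL, ...) {
  df <- tibble::as_tibble(object)
  mod_lab <- if (identical(attr(object, "species"), "s2")) "gamma" else "Phi^2"
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$bulk, .data$modulus,
                                        fill = .data$valid)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#27ae60",
                                          `FALSE` = "grey92")) +
    ggplot2::labs(x = "bulk concentration", y = mod_lab, fill = "valid",
                  title = sprintf("Series validity region (X = %.3g)",
                                  attr(object, "x_conv")))
  if (!is.null(fit)) {
    p <- p + ggplot2::geom_abline(slope = fit$slope,
                                  intercept = fit$intercept,
                                  linetype = 2)
  }
  p
}

#' Plot a sensitivity report
#'
#' @param object A `dkr_sensitivity`.
#' @param ... Unused.
#' @return A ggplot bar chart of normalized sensitivities.
#' @export
autoplot.dkr_sensitivity <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$parameter <- stats::reorder(df$parameter, -df$normalized_pct)
  ggplot2::ggplot(df, ggplot2::aes(.data$parameter, .data$normalized_pct)) +
    ggplot2::geom_col(fill = "#1b6ca8") +
    ggplot2::labs(x = NULL, y = "normalized sensitivity (%)",
                  title = "Normalized sensitivity of the effectiveness factor")
}

#' Plot an effectiveness sweep
#'
#' @param object A `dkr_effectiveness` (typically from
#'   [effectiveness_sweep()]).
#' @param ... Unused.
#' @return A ggplot of `eta_m` against `phi2`, coloured by bulk
#'   concentration or Michaelis group when several are present.
#' @export
autoplot.dkr_effectiveness <- function(object, ...) {
  df <- tibble::as_tibble(object)
  colour_by <- if (length(unique(df$s1b)) > 1) "s1b"
               else if (length(unique(df$theta)) > 1) "theta" else NULL
  aes <- if (is.null(colour_by)) {
    ggplot2::aes(.data$phi2, .data$eta_m)
  } else {
    ggplot2::aes(.data$phi2, .data$eta_m,
                 colour = factor(.data[[colour_by]]))
  }
  ggplot2::ggplot(df, aes) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "Thiele modulus squared", y = "mean effectiveness",
                  colour = colour_by,
                  title = paste0("Mean integrated effectiveness (",
                                 attr(object, "variant"), ")"))
}
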