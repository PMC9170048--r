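#' Plot methods
#'
#' `autoplot()` methods for the package's result types, in the style used
#' throughout the tidyverse: each returns a ggplot that can be themed or
#' extended by the caller.
#'
#' @param object The object to plot.
#' @param ... Unused.
#' @return A ggplot.
#' @name behavdim-plots
NULL

#' @rdname behavdim-plots
#' @exportS3Method ggplot2::autoplot
autoplot.behav_ts <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time", y = "x(t)")
}

#' @rdname behavdim-plots
#' @exportS3Method ggplot2::autoplot
autoplot.behav_corr_est <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$lag, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "lag", y = "C(lag)")
}

#' @rdname behavdim-plots
#' @exportS3Method ggplot2::autoplot
autoplot.kpf_spectrum <- function(object, ...) {
  df <- tidy(object)
  df$magnitude <- pmax(abs(df$coefficient), .Machine$double.xmin)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mode, y = .data$magnitude)) +
    ggplot2::geom_point() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "rank order", y = "|a|",
                  title = sprintf("past-future spectrum (window %d)",
                                  object$window_len))
}

#' @rdname behavdim-plots
#' @exportS3Method ggplot2::autoplot
autoplot.rank_report <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$window, y = .data$rank)) +
    ggplot2::geom_step() +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "window (samples)", y = "effective rank",
                  subtitle = sprintf("verdict: %s", attr(object, "verdict")))
}

#' @rdname behavdim-plots
#' @exportS3Method ggplot2::autoplot
autoplot.predinfo_curve <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$window, y = .data$bits)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "window (samples)", y = "predictive information (bits)",
                  subtitle = sprintf("classification: %s",
                                     attr(object, "classification")))
}

#' @importFrom rlang .data
NULL
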