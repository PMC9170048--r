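#' Tidy and glance methods
#'
#' broom-style accessors for the package's result objects, so spectra,
#' rank reports, information curves and fitted chain models drop directly
#' into dplyr/ggplot2 pipelines.
#'
#' @param x A `kpf_spectrum`, `rank_report`, `predinfo_curve`, or
#'   `ising_chain`.
#' @param ... Unused.
#' @return A tibble: one row per coefficient / window / parameter
#'   (`tidy()`), or a one-row summary (`glance()`).
#' @name behavdim-tidiers
NULL

#' @rdname behavdim-tidiers
#' @exportS3Method generics::tidy
tidy.kpf_spectrum <- function(x, ...) {
  tibble(
    mode = seq_along(x$coeffs),
    coefficient = x$coeffs,
    window_len = x$window_len
  )
}

#' @rdname behavdim-tidiers
#' @exportS3Method generics::glance
glance.kpf_spectrum <- function(x, ...) {
  tibble(
    window_len = x$window_len,
    leading_coeff = x$coeffs[1],
    effective_rank = effective_rank(x, if (x$estimated) 1e-2 else 1e-6),
    estimated = x$estimated
  )
}

#' @rdname behavdim-tidiers
#' @exportS3Method generics::tidy
tidy.rank_report <- function(x, ...) {
  tibble(window = x$window, rank = x$rank)
}

#' @rdname behavdim-tidiers
#' @exportS3Method generics::glance
glance.rank_report <- function(x, ...) {
  tibble(
    verdict = attr(x, "verdict"),
    threshold = attr(x, "threshold"),
    n_windows = nrow(x)
  )
}

#' @rdname behavdim-tidiers
#' @exportS3Method generics::tidy
tidy.predinfo_curve <- function(x, ...) {
  tibble(window = x$window, bits = x$bits)
}

#' @rdname behavdim-tidiers
#' @exportS3Method generics::glance
glance.predinfo_curve <- function(x, ...) {
  tibble(
    classification = attr(x, "classification"),
    log_slope = attr(x, "log_slope"),
    max_bits = max(x$bits)
  )
}

#' @rdname behavdim-tidiers
#' @exportS3Method generics::tidy
tidy.ising_chain <- function(x, ...) {
  tibble(
    term = c("h", sprintf("J(%d)", seq_len(x$range))),
    estimate = c(x$h, x$couplings)
  )
}

#' @rdname behavdim-tidiers
#' @exportS3Method generics::glance
glance.ising_chain <- function(x, ...) {
  tibble(
    range = x$range,
    tau_c = ising_tau_c(x),
    residual = attr(x, "residual") %||% NA_real_,
    iterations = attr(x, "iterations") %||% NA_integer_
  )
}
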