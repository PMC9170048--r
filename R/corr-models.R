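#' Correlation-function models
#'
#' Analytic autocorrelation models for stationary scalar behavior. An
#' exponential mixture \eqn{C(\tau) = \sum_k A_k e^{-|\tau|/\tau_k}} is the
#' signature of finite-dimensional linear-Gaussian dynamics; a power law
#' \eqn{C(\tau) = \langle x^2\rangle\, t_0^\alpha / (t_0^\alpha +
#' |\tau|^\alpha)} has no characteristic timescale and produces a past-future
#' kernel whose rank grows without bound with the analysis window. White
#' noise is the memoryless limit: all mass at lag zero.
#'
#' @param amplitudes Positive amplitudes \eqn{A_k} (variance units); their sum
#'   is the process variance \eqn{C(0)}.
#' @param timescales Positive correlation times \eqn{\tau_k}, strictly
#'   increasing, same length as `amplitudes`.
#' @return An object of class `behav_corr_model` that [corr_value()] can
#'   evaluate on a grid of lags.
#' @seealso [corr_ou_analytic()], [corr_2d_analytic()], [corr_value()]
#' @examples
#' cm <- exp_mixture_corr(c(0.5, 0.5), c(1, 10))
#' corr_value(cm, c(0, 1, 10))
#' @export
exp_mixture_corr <- function(amplitudes, timescales) {
  if (length(amplitudes) != length(timescales) || length(amplitudes) < 1L) {
    stop_behavdim("`amplitudes` and `timescales` must be non-empty and of equal length.",
                  class = "behavdim_parameter_error")
  }
  if (any(!is.finite(amplitudes)) || any(amplitudes <= 0)) {
    stop_behavdim("all amplitudes must be positive and finite.",
                  class = "behavdim_parameter_error")
  }
  if (any(!is.finite(timescales)) || any(timescales <= 0)) {
    stop_behavdim("all timescales must be positive and finite.",
                  class = "behavdim_parameter_error")
  }
  if (is.unsorted(timescales, strictly = TRUE)) {
    stop_behavdim("timescales must be strictly increasing.",
                  class = "behavdim_parameter_error")
  }
  structure(
    list(amplitudes = as.numeric(amplitudes),
         timescales = as.numeric(timescales)),
    class = c("corr_expmix", "behav_corr_model")
  )
}

#' @rdname exp_mixture_corr
#' @param variance Process variance \eqn{\langle x^2 \rangle > 0}.
#' @param t0 Reference time \eqn{t_0 > 0} at which the power-law correlation
#'   has fallen to half its lag-zero value.
#' @param alpha Power-law exponent \eqn{\alpha \in (0, 2)}.
#' @export
powerlaw_corr <- function(variance, t0, alpha) {
  check_scalar_positive(variance, "variance")
  check_scalar_positive(t0, "t0")
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 2) {
    stop_behavdim("`alpha` must lie strictly inside (0, 2).",
                  class = "behavdim_parameter_error")
  }
  structure(
    list(variance = variance, t0 = t0, alpha = alpha),
    class = c("corr_powerlaw", "behav_corr_model")
  )
}

#' @rdname exp_mixture_corr
#' @export
white_noise_corr <- function(variance) {
  check_scalar_positive(variance, "variance")
  structure(list(variance = variance),
            class = c("corr_white", "behav_corr_model"))
}

#' Analytic correlation of the Ornstein-Uhlenbeck behavior model
#'
#' The relaxation process \eqn{\tau_c \dot x = -x + \eta} driven by white
#' noise has the single-exponential autocorrelation
#' \eqn{C_1(\tau) = \langle x^2\rangle e^{-|\tau|/\tau_c}}: the canonical
#' one-dimensional behavior.
#'
#' @param tau_c Correlation time \eqn{\tau_c > 0}.
#' @param variance Stationary variance \eqn{\langle x^2 \rangle > 0}.
#' @return A one-term [exp_mixture_corr()] model.
#' @export
corr_ou_analytic <- function(tau_c, variance) {
  check_scalar_positive(tau_c, "tau_c")
  check_scalar_positive(variance, "variance")
  exp_mixture_corr(amplitudes = variance, timescales = tau_c)
}

#' Analytic correlation of the two-variable latent linear model
#'
#' A symmetric two-variable relaxation in which the observable \eqn{x(t)}
#' couples with strength `a` to a hidden variable \eqn{y(t)} yields a
#' two-exponential autocorrelation
#' \deqn{C_2(\tau) = A_+ e^{-(1+a)|\tau|/\tau_c} + A_- e^{-(1-a)|\tau|/\tau_c},
#'  \qquad A_\pm = \frac{\langle x^2\rangle (1 - a^2)}{2\,(1 \pm a)}.}
#' The fast timescale \eqn{\tau_c/(1+a)} carries the rough motion, the slow
#' one \eqn{\tau_c/(1-a)} the smooth drift.
#'
#' @inheritParams corr_ou_analytic
#' @param a Hidden-variable coupling, \eqn{|a| < 1} and nonzero. At `a = 0`
#'   the two timescales merge and the model degenerates to the
#'   one-dimensional case; use [corr_ou_analytic()] instead.
#' @return A two-term [exp_mixture_corr()] model, terms ordered by
#'   increasing timescale.
#' @export
corr_2d_analytic <- function(tau_c, a, variance) {
  check_scalar_positive(tau_c, "tau_c")
  check_scalar_positive(variance, "variance")
  if (!is.numeric(a) || length(a) != 1L || !is.finite(a) || abs(a) >= 1) {
    stop_behavdim("`a` must satisfy |a| < 1 (stable symmetric drift).",
                  class = "behavdim_stability_error")
  }
  if (a == 0) {
    stop_behavdim(
      "a = 0 collapses the two timescales; use corr_ou_analytic() for the one-dimensional model.",
      class = "behavdim_degenerate_model_error"
    )
  }
  taus <- c(tau_c / (1 + a), tau_c / (1 - a))
  amps <- 0.5 * variance * (1 - a^2) / (1 + c(a, -a))
  ord <- order(taus)
  exp_mixture_corr(amplitudes = amps[ord], timescales = taus[ord])
}

#' Evaluate a correlation model on a grid of lags
#'
#' @param corr A correlation model ([exp_mixture_corr()], [powerlaw_corr()],
#'   [white_noise_corr()]) or an estimated correlation from [estimate_corr()].
#' @param lags Numeric lags (time units); sign is ignored since stationary
#'   autocorrelations are even.
#' @return Numeric vector of correlation values, one per lag.
#' @export
corr_value <- function(corr, lags) {
  UseMethod("corr_value")
}

#' @export
corr_value.corr_expmix <- function(corr, lags) {
  purrr::map_dbl(abs(lags), function(tt) {
    sum(corr$amplitudes * exp(-tt / corr$timescales))
  })
}

#' @export
corr_value.corr_powerlaw <- function(corr, lags) {
  corr$variance * corr$t0^corr$alpha /
    (corr$t0^corr$alpha + abs(lags)^corr$alpha)
}

#' @export
corr_value.corr_white <- function(corr, lags) {
  ifelse(abs(lags) == 0, corr$variance, 0)
}

#' @export
corr_value.behav_corr_est <- function(corr, lags) {
  dt <- attr(corr, "dt")
  at <- abs(lags)
  idx <- round(at / dt) + 1L
  off <- abs(at / dt - round(at / dt))
  if (any(off > 1e-6) || any(idx > nrow(corr))) {
    stop_behavdim(
      sprintf(
        "estimated correlation covers lags up to %g and only on its own grid (dt = %g).",
        max(corr$lag), dt
      ),
      class = "behavdim_coverage_error"
    )
  }
  corr$value[idx]
}

#' @export
print.behav_corr_model <- function(x, ...) {
  if (inherits(x, "corr_expmix")) {
    cat("<exponential-mixture correlation>\n")
    cat("  amplitudes:", signif(x$amplitudes, 6), "\n")
    cat("  timescales:", signif(x$timescales, 6), "\n")
    cat("  variance C(0):", signif(sum(x$amplitudes), 6), "\n")
  } else if (inherits(x, "corr_powerlaw")) {
    cat("<power-law correlation>\n")
    cat(sprintf("  variance = %g, t0 = %g, alpha = %g\n",
                x$variance, x$t0, x$alpha))
  } else {
    cat("<white-noise correlation>\n")
    cat(sprintf("  variance = %g\n", x$variance))
  }
  invisible(x)
}

# variance C(0) of any correlation input
corr_variance <- function(corr) {
  corr_value(corr, 0)
}
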