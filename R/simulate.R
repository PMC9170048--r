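#' Behavioral time-series container
#'
#' A uniformly sampled scalar trajectory, stored as a tibble with columns
#' `time` and `value` and attributes `dt` (sampling step) and `seed` (the
#' integer that generated it, if any). All simulators return this type.
#'
#' @param values Numeric values, length at least 2, all finite.
#' @param dt Sampling step, strictly positive.
#' @param seed Optional integer recorded for reproducibility.
#' @param t0 Time of the first sample (default 0).
#' @return A `behav_ts` tibble.
#' @export
behav_ts <- function(values, dt, seed = NULL, t0 = 0) {
  if (length(values) < 2L) {
    stop_behavdim("a time series needs at least 2 samples.",
                  class = "behavdim_size_error")
  }
  if (any(!is.finite(values))) {
    stop_behavdim("all values must be finite.",
                  class = "behavdim_parameter_error")
  }
  check_scalar_positive(dt, "dt")
  out <- tibble(
    time = t0 + dt * (seq_along(values) - 1L),
    value = as.numeric(values)
  )
  attr(out, "dt") <- dt
  attr(out, "seed") <- if (is.null(seed)) NULL else as.integer(seed)
  class(out) <- c("behav_ts", class(out))
  out
}

#' @export
print.behav_ts <- function(x, ...) {
  cat(sprintf("<behavioral time series: %d samples, dt = %g%s>\n",
              nrow(x), attr(x, "dt"),
              if (is.null(attr(x, "seed"))) "" else
                sprintf(", seed = %d", attr(x, "seed"))))
  NextMethod()
}

#' Simulate the Ornstein-Uhlenbeck behavior model
#'
#' Draws a stationary trajectory of \eqn{\tau_c \dot x = -x + \eta} with
#' white noise scaled so that the stationary variance is `variance`. The
#' discrete-time update is exact: an AR(1) recursion with coefficient
#' \eqn{\rho = e^{-\Delta t/\tau_c}} and innovation variance
#' \eqn{(1-\rho^2)\langle x^2\rangle}, with the first sample drawn from the
#' stationary distribution. No integration bias, no burn-in.
#'
#' @inheritParams corr_ou_analytic
#' @param dt Sampling step (time units), positive.
#' @param n Number of samples, at least 2.
#' @param seed Optional integer seed; recorded in the output.
#' @return A [behav_ts()] of length `n`.
#' @examples
#' x <- simulate_ou(tau_c = 1, variance = 1, dt = 0.1, n = 1000, seed = 1)
#' var(x$value)
#' @export
simulate_ou <- function(tau_c, variance, dt, n, seed = NULL) {
  check_scalar_positive(tau_c, "tau_c")
  check_scalar_positive(variance, "variance")
  check_scalar_positive(dt, "dt")
  n <- check_count(n, "n", min = 2L)
  rho <- exp(-dt / tau_c)
  vals <- with_seed_maybe(seed, {
    innov <- rnorm(n, sd = sqrt(variance * (1 - rho^2)))
    innov[1] <- rnorm(1, sd = sqrt(variance))  # stationary start
    as.numeric(stats::filter(innov, rho, method = "recursive"))
  })
  behav_ts(vals, dt = dt, seed = seed)
}

#' Latent linear-Gaussian behavior models
#'
#' Specification of a stationary \eqn{D}-variable linear stochastic system
#' \eqn{\dot z = -B z + \eta} with independent white noises
#' \eqn{\langle \eta_i(t)\eta_j(t')\rangle = c_i^2 \delta_{ij}\delta(t-t')},
#' of which a single coordinate is observed. Predicting the future of such a
#' system requires exactly \eqn{D} initial conditions, so it is the reference
#' family of finitely-dimensional behavior generators.
#'
#' @param dynamics \eqn{D \times D} drift matrix \eqn{B} (units 1/time); all
#'   eigenvalues must have positive real part (stationarity).
#' @param noise_amplitudes Length-\eqn{D} non-negative noise amplitudes
#'   \eqn{c_i} (so coordinate `i` is driven at spectral density \eqn{c_i^2}).
#' @param observed_index Which coordinate is the observable (default 1).
#' @return A `linear_gaussian_model` object.
#' @export
linear_gaussian_model <- function(dynamics, noise_amplitudes,
                                  observed_index = 1L) {
  dynamics <- as.matrix(dynamics)
  D <- nrow(dynamics)
  if (ncol(dynamics) != D || D < 1L) {
    stop_behavdim("`dynamics` must be a square matrix.",
                  class = "behavdim_parameter_error")
  }
  if (length(noise_amplitudes) != D || any(noise_amplitudes < 0)) {
    stop_behavdim("`noise_amplitudes` must be D non-negative values.",
                  class = "behavdim_parameter_error")
  }
  ev <- eigen(dynamics, only.values = TRUE)$values
  if (any(Re(ev) <= 0)) {
    stop_behavdim(
      sprintf("drift is not stable: eigenvalue real parts %s must all be positive.",
              paste(signif(Re(ev), 4), collapse = ", ")),
      class = "behavdim_stability_error"
    )
  }
  observed_index <- check_count(observed_index, "observed_index")
  if (observed_index > D) {
    stop_behavdim("`observed_index` exceeds the model dimension.",
                  class = "behavdim_parameter_error")
  }
  structure(
    list(dim = D, dynamics = dynamics,
         noise_amplitudes = as.numeric(noise_amplitudes),
         observed_index = observed_index),
    class = "linear_gaussian_model"
  )
}

# stationary covariance from the continuous Lyapunov relation
# B C + C B' = diag(c^2), solved by vectorization (D is small).
lyapunov_stationary_cov <- function(B, noise_amplitudes) {
  D <- nrow(B)
  Sigma <- diag(noise_amplitudes^2, D)
  A <- kronecker(diag(D), B) + kronecker(B, diag(D))
  C <- matrix(solve(A, as.vector(Sigma)), D, D)
  (C + t(C)) / 2
}

#' Simulate a latent linear-Gaussian model exactly
#'
#' Discretization is exact for linear drift: the one-step propagator is the
#' matrix exponential \eqn{\Phi = e^{-B\Delta t}} and the one-step noise
#' covariance is \eqn{Q = C - \Phi C \Phi^\top} with \eqn{C} the stationary
#' covariance from the continuous Lyapunov relation. The initial state is
#' drawn from the stationary distribution, and only the observed coordinate
#' is returned.
#'
#' @param model A [linear_gaussian_model()].
#' @inheritParams simulate_ou
#' @return A [behav_ts()] holding the observed coordinate.
#' @export
simulate_linear <- function(model, dt, n, seed = NULL) {
  if (!inherits(model, "linear_gaussian_model")) {
    stop_behavdim("`model` must be a linear_gaussian_model.",
                  class = "behavdim_parameter_error")
  }
  check_scalar_positive(dt, "dt")
  n <- check_count(n, "n", min = 2L)
  B <- model$dynamics
  D <- model$dim
  Phi <- as.matrix(Matrix::expm(-B * dt))
  C <- lyapunov_stationary_cov(B, model$noise_amplitudes)
  Q <- C - Phi %*% C %*% t(Phi)
  Q <- (Q + t(Q)) / 2
  Lc <- chol_psd(C)
  Lq <- chol_psd(Q)
  obs <- model$observed_index
  vals <- with_seed_maybe(seed, {
    z <- drop(t(Lc) %*% rnorm(D))
    eps <- matrix(rnorm(D * (n - 1L)), nrow = D)
    shocks <- t(Lq) %*% eps
    out <- numeric(n)
    out[1] <- z[obs]
    for (t in 2:n) {
      z <- Phi %*% z + shocks[, t - 1L]
      out[t] <- z[obs]
    }
    out
  })
  behav_ts(vals, dt = dt, seed = seed)
}

# Cholesky factor tolerant of semi-definite matrices (tiny negative
# curvature from round-off); returns upper-triangular R with R'R = M.
chol_psd <- function(M, rel_jitter = 1e-12) {
  out <- tryCatch(chol(M), error = function(e) NULL)
  if (!is.null(out)) return(out)
  scale <- mean(diag(M))
  jit <- rel_jitter * scale
  for (i in 1:5) {
    out <- tryCatch(chol(M + diag(jit, nrow(M))), error = function(e) NULL)
    if (!is.null(out)) return(out)
    jit <- jit * 10
  }
  stop_behavdim(
    sprintf("matrix is not positive semi-definite (smallest eigenvalue %g).",
            min(eigen(M, symmetric = TRUE, only.values = TRUE)$values)),
    class = "behavdim_model_error"
  )
}

#' Simulate the two-variable latent model
#'
#' The observable \eqn{x(t)} relaxes jointly with a hidden variable
#' \eqn{y(t)} under the symmetric drift \eqn{\begin{pmatrix} 1 & a \\ a & 1
#' \end{pmatrix}/\tau_c}, each driven by independent white noise of equal
#' strength \eqn{2\tau_c^{-1}\langle x^2\rangle(1-a^2)} chosen so the
#' observable's stationary variance is `variance`. Only \eqn{x(t)} is
#' returned; its autocorrelation is the two-exponential mixture of
#' [corr_2d_analytic()]. At `a = 0` the variables decouple and the output is
#' statistically identical to [simulate_ou()].
#'
#' @inheritParams simulate_ou
#' @param a Hidden-variable coupling, \eqn{|a| < 1}.
#' @return A [behav_ts()] of the observable.
#' @export
simulate_2d <- function(tau_c, a, variance, dt, n, seed = NULL) {
  check_scalar_positive(tau_c, "tau_c")
  check_scalar_positive(variance, "variance")
  if (!is.numeric(a) || length(a) != 1L || !is.finite(a) || abs(a) >= 1) {
    stop_behavdim("`a` must satisfy |a| < 1 (stable symmetric drift).",
                  class = "behavdim_stability_error")
  }
  B <- matrix(c(1, a, a, 1), 2, 2) / tau_c
  c_amp <- sqrt(2 * variance * (1 - a^2) / tau_c)
  model <- linear_gaussian_model(B, noise_amplitudes = c(c_amp, c_amp),
                                 observed_index = 1L)
  simulate_linear(model, dt = dt, n = n, seed = seed)
}

#' Simulate a Gaussian process with power-law correlations
#'
#' Exact finite-window draw: the \eqn{n \times n} covariance matrix is built
#' from the power-law correlation model, Cholesky-factorized, and applied to
#' standard normal draws. If the factorization fails numerically, a diagonal
#' jitter of up to \eqn{10^{-8}\langle x^2\rangle} is added (with a warning)
#' before giving up. `n` is capped at 4096 samples so the dense covariance
#' stays comfortably in memory; longer records should be analyzed through
#' the analytic model rather than simulated.
#'
#' @param corr A [powerlaw_corr()] model.
#' @inheritParams simulate_ou
#' @return A [behav_ts()] of length `n`.
#' @export
simulate_powerlaw <- function(corr, dt, n, seed = NULL) {
  if (!inherits(corr, "corr_powerlaw")) {
    stop_behavdim("`corr` must be a powerlaw_corr model.",
                  class = "behavdim_parameter_error")
  }
  check_scalar_positive(dt, "dt")
  n <- check_count(n, "n", min = 2L)
  if (n > 4096L) {
    stop_behavdim("n is capped at 4096 for exact dense-covariance draws.",
                  class = "behavdim_size_error")
  }
  C <- toeplitz(corr_value(corr, (0:(n - 1L)) * dt))
  R <- tryCatch(chol(C), error = function(e) NULL)
  if (is.null(R)) {
    jit <- 1e-12 * corr$variance
    while (is.null(R) && jit <= 1e-8 * corr$variance) {
      R <- tryCatch(chol(C + diag(jit, n)), error = function(e) NULL)
      if (is.null(R)) jit <- jit * 10
    }
    if (is.null(R)) {
      ev_min <- min(eigen(C, symmetric = TRUE, only.values = TRUE)$values)
      stop_behavdim(
        sprintf("power-law covariance not positive definite (smallest eigenvalue %g) even after maximum jitter.",
                ev_min),
        class = "behavdim_model_error"
      )
    }
    warn(sprintf("power-law covariance needed diagonal jitter %g to factorize.", jit))
  }
  vals <- with_seed_maybe(seed, drop(t(R) %*% rnorm(n)))
  behav_ts(vals, dt = dt, seed = seed)
}

#' Estimate the autocorrelation of a behavioral time series
#'
#' Mean-subtracted, biased (divide-by-n) estimator of
#' \eqn{\langle x(t)x(t+\tau)\rangle}. The biased normalization guarantees
#' the estimated sequence is positive semi-definite, which downstream kernel
#' inversion relies on. Sample counts per lag are recorded.
#'
#' @param ts A [behav_ts()].
#' @param max_lag Largest lag, in samples; must be below `length/4` for
#'   usable estimates.
#' @return A tibble of class `behav_corr_est` with columns `lag` (time
#'   units), `value`, and `n_obs` (pairs per lag); carries attribute `dt`.
#' @export
estimate_corr <- function(ts, max_lag) {
  if (!inherits(ts, "behav_ts")) {
    stop_behavdim("`ts` must be a behav_ts.", class = "behavdim_parameter_error")
  }
  n <- nrow(ts)
  max_lag <- check_count(max_lag, "max_lag", min = 0L)
  if (max_lag >= n / 4) {
    stop_behavdim(
      sprintf("max_lag (%d) must be below length/4 (= %g) for usable estimates.",
              max_lag, n / 4),
      class = "behavdim_size_error"
    )
  }
  dt <- attr(ts, "dt")
  a <- acf(ts$value, lag.max = max_lag, type = "covariance",
           demean = TRUE, plot = FALSE)
  out <- tibble(
    lag = (0:max_lag) * dt,
    value = drop(a$acf),
    n_obs = n - (0:max_lag)
  )
  attr(out, "dt") <- dt
  class(out) <- c("behav_corr_est", class(out))
  out
}
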