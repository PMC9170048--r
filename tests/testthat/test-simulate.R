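test_that("OU simulation is stationary with the requested variance", {
  # T = 5e4 * tau_c makes a +-5% band a > 4-sigma check on the sample variance
  x <- simulate_ou(tau_c = 1, variance = 1, dt = 0.05, n = 1e6, seed = 101)
  expect_equal(var(x$value), 1, tolerance = 0.05)
  expect_equal(nrow(x), 1e6)
  expect_equal(attr(x, "seed"), 101L)
})

test_that("OU discretization is exact: lag-1 autocorrelation equals exp(-dt/tau_c)", {
  for (ratio in c(0.01, 0.1, 1)) {
    x <- simulate_ou(tau_c = 1, variance = 1, dt = ratio, n = 1e6,
                     seed = 7 + round(100 * ratio))
    rho <- exp(-ratio)
    r1 <- drop(acf(x$value, lag.max = 1, plot = FALSE)$acf)[2]
    se <- sqrt((1 - rho^2) / 1e6)
    expect_lt(abs(r1 - rho), 4 * se)
  }
})

test_that("OU estimated correlation matches the exponential form at lag tau_c", {
  x <- simulate_ou(tau_c = 1, variance = 1, dt = 0.1, n = 1e6, seed = 11)
  est <- estimate_corr(x, max_lag = 30)
  cm <- corr_ou_analytic(1, 1)
  for (tau in c(0, 1, 2)) {
    se <- bartlett_corr_se(cm, tau, 1e6, 0.1)
    expect_lt(abs(corr_value(est, tau) - corr_value(cm, tau)), 4 * se)
  }
})

test_that("two-variable simulation has unit variance and the two-exponential correlation", {
  x <- simulate_2d(tau_c = 1, a = 0.75, variance = 1, dt = 0.05, n = 1e6,
                   seed = 23)
  expect_equal(var(x$value), 1, tolerance = 0.05)
  est <- estimate_corr(x, max_lag = 100)
  cm <- corr_2d_analytic(1, 0.75, 1)
  for (tau in c(0.5, 2)) {
    se <- bartlett_corr_se(cm, tau, 1e6, 0.05)
    expect_lt(abs(corr_value(est, tau) - corr_value(cm, tau)), 4 * se)
  }
  expect_error(simulate_2d(1, 1.5, 1, 0.1, 100),
               class = "behavdim_stability_error")
})

test_that("decoupled two-variable model reproduces the one-dimensional statistics", {
  x <- simulate_2d(tau_c = 1, a = 0, variance = 1, dt = 0.1, n = 5e5, seed = 31)
  est <- estimate_corr(x, max_lag = 30)
  cm <- corr_ou_analytic(1, 1)
  for (tau in c(0, 1)) {
    se <- bartlett_corr_se(cm, tau, 5e5, 0.1)
    expect_lt(abs(corr_value(est, tau) - corr_value(cm, tau)), 4 * se)
  }
})

test_that("hidden-variable rescaling leaves the observable's statistics unchanged", {
  # z = (x, y) vs z' = (x, s*y): similarity-transformed drift, rescaled noise.
  # Compare the analytic stationary lagged covariance of x: expm(-B tau) C.
  a <- 0.6; tau_c <- 1; s <- 3.7
  B1 <- matrix(c(1, a, a, 1), 2, 2) / tau_c
  c1 <- sqrt(2 * (1 - a^2) / tau_c)
  S <- diag(c(1, s))
  B2 <- S %*% B1 %*% solve(S)
  xcorr <- function(B, amps) {
    C <- behavdim:::lyapunov_stationary_cov(B, amps)
    vapply(c(0, 0.5, 1, 2), function(tau) {
      (as.matrix(Matrix::expm(-B * tau)) %*% C)[1, 1]
    }, numeric(1))
  }
  expect_equal(xcorr(B2, c(c1, s * c1)), xcorr(B1, c(c1, c1)),
               tolerance = 1e-10)
})

test_that("three-variable diagonal model observed as an equal-weight sum gives a three-exponential mixture", {
  # rotate three independent relaxation modes (rates 1/4, 1/32, 1/256 per
  # step) so the first coordinate is their equal-weight sum; equal noise
  # amplitudes keep the rotated noise white and independent.
  rates <- c(1 / 4, 1 / 32, 1 / 256)
  Qc <- qr.Q(qr(cbind(rep(1, 3), diag(3)[, 1:2])))
  Q <- t(Qc * sign(Qc[1, 1]))  # orthogonal, first row = (1,1,1)/sqrt(3)
  B <- Q %*% diag(rates) %*% t(Q)
  camp <- sqrt(2 * min(rates))
  model <- linear_gaussian_model(B, rep(camp, 3), observed_index = 1L)
  # oracle: stationary Lyapunov solution mapped to a correlation mixture,
  # C_xx(tau) = sum_i Q[1,i]^2 * (camp^2 / (2 rate_i)) * exp(-rate_i tau)
  amps <- Q[1, ]^2 * camp^2 / (2 * rates)
  cm <- exp_mixture_corr(amps, 1 / rates)
  x <- simulate_linear(model, dt = 1, n = 5e5, seed = 41)
  est <- estimate_corr(x, max_lag = 120)
  for (tau in c(0, 4, 32, 100)) {
    se <- bartlett_corr_se(cm, tau, 5e5, 1, k_max = 5000L)
    expect_lt(abs(corr_value(est, tau) - corr_value(cm, tau)), 4 * se)
  }
})

test_that("one-variable linear model is the OU simulator", {
  m <- linear_gaussian_model(matrix(1 / 3), sqrt(2 / 3))
  x1 <- simulate_linear(m, dt = 0.5, n = 1000, seed = 5)
  # same stationary law: variance 1, correlation time 3
  est <- estimate_corr(simulate_linear(m, dt = 0.5, n = 5e5, seed = 6),
                       max_lag = 20)
  cm <- corr_ou_analytic(3, 1)
  se0 <- bartlett_corr_se(cm, 0, 5e5, 0.5)
  expect_lt(abs(corr_value(est, 0) - 1), 4 * se0)
  se3 <- bartlett_corr_se(cm, 3, 5e5, 0.5)
  expect_lt(abs(corr_value(est, 3) - exp(-1)), 4 * se3)
  expect_error(linear_gaussian_model(matrix(-1), 1),
               class = "behavdim_stability_error")
})

test_that("power-law draws reproduce the target covariance across draws", {
  corr <- powerlaw_corr(1, 1, 0.5)
  n <- 64L
  ndraw <- 10000L
  X <- vapply(seq_len(ndraw), function(i) {
    simulate_powerlaw(corr, dt = 1, n = n, seed = 40000L + i)$value
  }, numeric(n))
  Chat <- tcrossprod(X) / ndraw
  Ctrue <- toeplitz(corr_value(corr, 0:(n - 1L)))
  # entrywise Monte-Carlo error ~ sqrt((Cii Cjj + Cij^2)/ndraw)
  se <- sqrt((diag(Ctrue) %o% diag(Ctrue) + Ctrue^2) / ndraw)
  expect_lt(max(abs(Chat - Ctrue) / se), 6)
  expect_equal(mean(diag(Chat)), 1, tolerance = 0.05)
  expect_error(simulate_powerlaw(corr, 1, 5000),
               class = "behavdim_size_error")
})

test_that("correlation estimator behaves on degenerate and white inputs", {
  const <- behav_ts(rep(3, 1000), dt = 1)
  est <- estimate_corr(const, 10)
  expect_true(all(est$value == 0))
  expect_equal(est$n_obs, 1000L - 0:10)

  wn <- withr::with_seed(99, behav_ts(rnorm(1e5), dt = 1))
  est <- estimate_corr(wn, 20)
  expect_lt(max(abs(est$value[-1])), 4 / sqrt(1e5))
  expect_equal(est$value[1], 1, tolerance = 0.02)

  expect_error(estimate_corr(wn, 1e5), class = "behavdim_size_error")
})

test_that("time-series container validates its invariants", {
  expect_error(behav_ts(1, dt = 1), class = "behavdim_size_error")
  expect_error(behav_ts(c(1, NA), dt = 1), class = "behavdim_parameter_error")
  expect_error(behav_ts(c(1, 2), dt = 0), class = "behavdim_parameter_error")
  expect_error(simulate_ou(-1, 1, 1, 10), class = "behavdim_parameter_error")
  expect_error(simulate_ou(1, 1, 1, 1), class = "behavdim_size_error")
})

test_that("seeds isolate and reproduce trajectories", {
  a <- simulate_ou(1, 1, 0.1, 100, seed = 1)
  b <- simulate_ou(1, 1, 0.1, 100, seed = 1)
  c <- simulate_ou(1, 1, 0.1, 100, seed = 2)
  expect_identical(a$value, b$value)
  expect_false(identical(a$value, c$value))
})
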