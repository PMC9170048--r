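# Independent oracles shared across tests.

# Bartlett-type standard error of the lag-tau autocovariance estimate of a
# Gaussian process with analytic correlation model `corr`, record length n:
#   Var(C_hat(tau)) ~ (1/n) * sum_k [ C(k)^2 + C(k+tau) C(k-tau) ]
bartlett_corr_se <- function(corr, tau, n, dt, k_max = 2000L) {
  k <- (-k_max):k_max
  ck <- corr_value(corr, k * dt)
  ckp <- corr_value(corr, (k + tau / dt) * dt)
  ckm <- corr_value(corr, (k - tau / dt) * dt)
  sqrt(sum(ck^2 + ckp * ckm) / n)
}

# Brute-force moments of the stationary infinite Ising chain marginalized to
# n consecutive spins: enumerate all 2^n sequences, weigh each by
#   u(first block) * prod(step weights) * v(last block) / (lambda^(n-R) u.v),
# and sum mean / two-point moments directly. Shares only the transfer-matrix
# *construction* with the package; the correlation computation path
# (P-propagation) is not used.
ising_bruteforce_moments <- function(model, n, max_lag) {
  sys <- behavdim:::ising_leading_system(model)
  R <- model$range
  stopifnot(n > R)
  S <- sys$n_states
  h <- model$h
  J <- model$couplings
  grid <- as.matrix(expand.grid(rep(list(c(-1L, 1L)), n)))  # 2^n rows
  # columns are sigma_1 .. sigma_n
  state_of <- function(spins_block) {
    # block (oldest..newest) -> index, newest spin in lowest bit
    sum((spins_block > 0) * 2L^((length(spins_block) - 1L):0L)) + 1L
  }
  logw <- numeric(nrow(grid))
  for (t in (R + 1L):n) {
    loc <- h
    for (r in seq_len(R)) loc <- loc + J[r] * grid[, t - r]
    logw <- logw + grid[, t] * loc
  }
  s_first <- apply(grid[, 1:R, drop = FALSE], 1L, state_of)
  s_last <- apply(grid[, (n - R + 1L):n, drop = FALSE], 1L, state_of)
  w <- sys$u[s_first] * exp(logw) * sys$v[s_last]
  w <- w / sum(w)
  mid <- ceiling(n / 2)
  mean_mid <- sum(w * grid[, mid])
  raw <- vapply(0:max_lag, function(tau) {
    i <- max(1L, mid - floor(tau / 2))
    sum(w * grid[, i] * grid[, i + tau])
  }, numeric(1))
  list(mean = mean_mid, raw = raw)
}

# small grid of clearly k-dimensional exponential-mixture models (timescales
# in sample steps, resolvable within modest windows)
mixture_test_grid <- function() {
  list(
    exp_mixture_corr(1, 3),
    exp_mixture_corr(2.5, 6),
    exp_mixture_corr(c(0.5, 0.5), c(2, 7)),
    exp_mixture_corr(c(0.3, 0.7), c(3, 11)),
    exp_mixture_corr(c(1, 2), c(1.5, 9)),
    exp_mixture_corr(c(0.4, 0.3, 0.3), c(2, 5, 12)),
    exp_mixture_corr(c(1, 1, 1) / 3, c(1.5, 4, 10)),
    exp_mixture_corr(c(0.2, 0.5, 0.3), c(2.5, 6, 14)),
    exp_mixture_corr(c(0.3, 0.3, 0.2, 0.2), c(1.5, 5, 16, 50)),
    exp_mixture_corr(c(0.25, 0.25, 0.25, 0.25), c(2, 6, 18, 54))
  )
}

# spectrum straight from an analytic model
spectrum_of <- function(corr, window, dt = 1) {
  kpf_spectrum(invert_to_kernel(build_covariance(corr, window, dt), dt))
}
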