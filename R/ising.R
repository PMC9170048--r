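#' Two-state behavioral sequence models (Ising chains)
#'
#' A binary behavioral sequence \eqn{\sigma_t = \pm 1} (e.g. "moving" vs
#' "resting" at each clock tick) with stationary distribution
#' \deqn{P(\{\sigma\}) \propto \exp\Big[h\sum_t \sigma_t +
#'   \sum_{t} \sum_{r=1}^{R} J(r)\, \sigma_t \sigma_{t-r}\Big],}
#' the pairwise maximum-entropy (maximum-caliber) model matching a mean and
#' a correlation function out to lag \eqn{R}. With `range = 1` this is the
#' nearest-neighbor Ising chain: the sequence is Markov and its correlations
#' decay as a single exponential.
#'
#' All exact computations (moments, correlation times, sampling) use the
#' stationary infinite-chain limit via the leading eigensystem of the
#' \eqn{2^R}-state transfer matrix; `range` is capped at 12 to keep that
#' matrix tractable.
#'
#' @param h Field (bias toward +1).
#' @param couplings Couplings `J(1), ..., J(R)` at lags 1..R.
#' @return An `ising_chain` object with fields `h`, `couplings`, `range`.
#' @export
ising_chain <- function(h, couplings) {
  if (!is.numeric(h) || length(h) != 1L || !is.finite(h)) {
    stop_behavdim("`h` must be a single finite number.",
                  class = "behavdim_parameter_error")
  }
  if (length(couplings) < 1L || any(!is.finite(couplings))) {
    stop_behavdim("`couplings` must be a non-empty finite vector J(1..R).",
                  class = "behavdim_parameter_error")
  }
  structure(
    list(h = h, couplings = as.numeric(couplings),
         range = length(couplings)),
    class = "ising_chain"
  )
}

#' @export
print.ising_chain <- function(x, ...) {
  cat(sprintf("<Ising chain: h = %g, range R = %d>\n", x$h, x$range))
  cat("  J(1..R):", signif(x$couplings, 6), "\n")
  invisible(x)
}

check_ising_range <- function(model) {
  if (model$range > 12L) {
    stop_behavdim(
      sprintf("exact transfer-matrix computation is limited to range <= 12 (got %d); use sampling-based estimates for longer ranges.",
              model$range),
      class = "behavdim_capacity_error"
    )
  }
  invisible(model)
}

# Block-state encoding: state s in 0..2^R-1 holds (sigma_{t-R+1},...,sigma_t)
# with the newest spin in the lowest bit; bit 1 = +1, bit 0 = -1.
# Appending sigma_new carries weight exp(sigma_new * (h + sum_r J(r) sigma_{t+1-r})).
# Each state has exactly two successors (append -1 / +1), so applying the
# transfer matrix is O(2^R) with precomputed index/weight arrays.
ising_step_ops <- function(model) {
  check_ising_range(model)
  R <- model$range
  S <- 2L^R
  states <- 0:(S - 1L)
  mask <- S - 1L
  bit_spin <- function(s, k) ifelse(bitwAnd(s, bitwShiftL(1L, k)) > 0L, 1, -1)
  loc <- model$h + Reduce(`+`, lapply(seq_len(R), function(r) {
    model$couplings[r] * bit_spin(states, r - 1L)  # sigma_{t+1-r} is bit r-1
  }))
  succ_dn <- bitwAnd(bitwShiftL(states, 1L), mask)       # append -1
  succ_up <- bitwOr(succ_dn, 1L)                         # append +1
  w_dn <- exp(-loc)
  w_up <- exp(loc)
  # predecessors of s': drop the lowest bit, prepend either top bit
  drop_new <- bitwShiftR(states, 1L)
  top <- bitwShiftL(1L, R - 1L)
  pred1 <- drop_new                                      # old top bit 0
  pred2 <- bitwOr(drop_new, top)                         # old top bit 1
  new_spin <- ifelse(bitwAnd(states, 1L) > 0L, 1, -1)
  wp1 <- exp(new_spin * loc[pred1 + 1L])
  wp2 <- exp(new_spin * loc[pred2 + 1L])
  list(
    R = R, S = S,
    succ_dn = succ_dn + 1L, succ_up = succ_up + 1L, w_dn = w_dn, w_up = w_up,
    pred1 = pred1 + 1L, pred2 = pred2 + 1L, wp1 = wp1, wp2 = wp2,
    last_spin = new_spin
  )
}

apply_T <- function(ops, v) ops$w_dn * v[ops$succ_dn] + ops$w_up * v[ops$succ_up]
apply_Tt <- function(ops, u) ops$wp1 * u[ops$pred1] + ops$wp2 * u[ops$pred2]

# leading eigensystem (lambda1, right v, left u, stationary pi, up-step
# probabilities) by power iteration; convergence is geometric at |l2|/l1.
ising_leading_system <- function(model, tol = 1e-15, max_iter = 200000L) {
  ops <- ising_step_ops(model)
  S <- ops$S
  v <- rep(1, S)
  u <- rep(1, S)
  lam <- NA_real_
  for (i in seq_len(max_iter)) {
    v_new <- apply_T(ops, v)
    lam_new <- sum(v_new) / sum(v)
    v_new <- v_new / max(v_new)
    delta <- max(abs(v_new - v))
    v <- v_new
    lam <- lam_new
    if (delta < tol) break
  }
  for (i in seq_len(max_iter)) {
    u_new <- apply_Tt(ops, u)
    u_new <- u_new / max(u_new)
    if (max(abs(u_new - u)) < tol) { u <- u_new; break }
    u <- u_new
  }
  lam <- sum(u * apply_T(ops, v)) / sum(u * v)  # Rayleigh polish
  pi_s <- u * v / sum(u * v)
  p_up <- ops$w_up * v[ops$succ_up] / (lam * v)
  list(ops = ops, lambda1 = lam, v = v, u = u, pi = pi_s, p_up = p_up,
       last_spin = ops$last_spin, n_states = S)
}

# dense transfer matrix; used where subleading eigenvalues are needed
ising_transfer_dense <- function(model) {
  ops <- ising_step_ops(model)
  S <- ops$S
  Tm <- matrix(0, S, S)
  Tm[cbind(seq_len(S), ops$succ_dn)] <- ops$w_dn
  Tm[cbind(seq_len(S), ops$succ_up)] <- ops$w_up
  Tm
}

# exact stationary moments: mean and raw two-point <sigma_0 sigma_tau>.
# Propagates w' P with P(s,s') = T(s,s') v(s') / (lambda v(s)).
ising_moments <- function(model, max_lag) {
  sys <- ising_leading_system(model)
  sig <- sys$last_spin
  mu <- sum(sys$pi * sig)
  raw <- numeric(max_lag + 1L)
  raw[1] <- 1  # sigma^2 = 1
  if (max_lag >= 1L) {
    w <- sys$pi * sig / sys$v
    for (tau in 1:max_lag) {
      w <- apply_Tt(sys$ops, w) / sys$lambda1
      raw[tau + 1L] <- sum(w * sys$v * sig)
    }
  }
  list(mean = mu, raw = raw)
}

#' Exact correlation function of an Ising chain
#'
#' Connected correlation \eqn{C(\tau) = \langle(\sigma_t - \langle\sigma\rangle)
#' (\sigma_{t+\tau} - \langle\sigma\rangle)\rangle} of the stationary
#' infinite chain, computed exactly from the transfer-matrix eigensystem.
#' For the nearest-neighbor model at zero field this reduces to
#' \eqn{C(\tau) = (\tanh J)^{\tau}}.
#'
#' @param model An [ising_chain()] with `range <= 12`.
#' @param max_lag Largest lag (clock ticks).
#' @return A tibble of class `behav_corr_est` (columns `lag`, `value`) with
#'   `dt = 1` tick and the stationary mean in attribute `mean`, usable
#'   wherever an estimated correlation is.
#' @export
ising_corr <- function(model, max_lag) {
  stopifnot(inherits(model, "ising_chain"))
  max_lag <- check_count(max_lag, "max_lag", min = 0L)
  mom <- ising_moments(model, max_lag)
  out <- tibble(
    lag = as.numeric(0:max_lag),
    value = mom$raw - mom$mean^2,
    n_obs = rep(NA_integer_, max_lag + 1L)
  )
  attr(out, "dt") <- 1
  attr(out, "mean") <- mom$mean
  class(out) <- c("behav_corr_est", class(out))
  out
}

#' Correlation time of an Ising chain
#'
#' \eqn{\tau_c = 1/\log(\lambda_1/|\lambda_2|)} in clock ticks, from the two
#' leading transfer-matrix eigenvalues; the rate at which connected
#' correlations decay. For the nearest-neighbor chain at zero field this is
#' the closed form \eqn{-1/\log\tanh J}. A memoryless chain
#' (\eqn{\lambda_2 = 0}, e.g. `J = 0`) returns 0.
#'
#' @param model An [ising_chain()] with `range <= 12`.
#' @return Correlation time in ticks (0 for a memoryless chain).
#' @export
ising_tau_c <- function(model) {
  stopifnot(inherits(model, "ising_chain"))
  lam <- sort(Mod(eigen(ising_transfer_dense(model), only.values = TRUE)$values),
              decreasing = TRUE)
  if (lam[2] <= 1e-14 * lam[1]) return(0)
  1 / log(lam[1] / lam[2])
}

#' Exact sampling of Ising behavioral sequences
#'
#' Draws a stationary sequence without MCMC or burn-in: the first block of
#' `range` spins comes from the exact stationary block distribution, and
#' each subsequent spin from the exact conditional induced by the transfer
#' matrix.
#'
#' @param model An [ising_chain()] with `range <= 12`.
#' @param n Sequence length, at least 2.
#' @param seed Optional integer seed.
#' @return An integer vector of n spins in \{-1, +1\} with attribute `seed`.
#' @export
sample_ising_general <- function(model, n, seed = NULL) {
  stopifnot(inherits(model, "ising_chain"))
  n <- check_count(n, "n", min = 2L)
  sys <- ising_leading_system(model)
  R <- model$range
  S <- sys$n_states
  mask <- S - 1L
  p_up <- sys$p_up
  with_seed_maybe(seed, {
    s <- sample.int(S, 1L, prob = sys$pi) - 1L
    first <- ifelse(bitwAnd(s, bitwShiftL(1L, (R - 1L):0L)) > 0L, 1L, -1L)
    spins <- integer(n)
    take <- min(R, n)
    spins[seq_len(take)] <- first[seq_len(take)]
    if (n > R) {
      un <- stats::runif(n - R)
      for (t in (R + 1L):n) {
        up <- un[t - R] < p_up[s + 1L]
        spins[t] <- if (up) 1L else -1L
        s <- bitwOr(bitwAnd(bitwShiftL(s, 1L), mask), if (up) 1L else 0L)
      }
    }
    structure(spins, seed = if (is.null(seed)) NULL else as.integer(seed))
  })
}

#' @rdname sample_ising_general
#' @param h Field of the nearest-neighbor chain.
#' @param J Nearest-neighbor coupling.
#' @export
sample_ising_nn <- function(h, J, n, seed = NULL) {
  sample_ising_general(ising_chain(h, J), n = n, seed = seed)
}

#' Fit the pairwise maximum-entropy model to a mean and correlations
#'
#' Finds the field `h` and couplings `J(1..R)` of the least-structured
#' (maximum-entropy) two-state sequence model whose stationary mean and
#' connected correlations at lags 1..R match the targets. The fit minimizes
#' the convex dual (log of the leading transfer-matrix eigenvalue minus the
#' linear moment terms) by BFGS — its gradient is exactly the moment
#' mismatch — then polishes with damped Newton steps on the
#' moment-matching conditions using a numerical Jacobian. Convexity makes
#' the solution unique; the starting point only affects the path.
#'
#' @param mean Target mean \eqn{\langle\sigma\rangle}, strictly inside
#'   (-1, 1).
#' @param corr Target connected correlations: either a numeric vector
#'   `C(1..R)` (at least `range` values), or a correlation tibble with
#'   columns `lag` and `value` at integer lags (lag 0 is then \eqn{1 -
#'   \langle\sigma\rangle^2} and not a fitting target).
#' @param range Coupling range R (<= 12).
#' @param tol Sup-norm tolerance on the moment residuals (default 1e-10).
#' @param init Optional starting parameters `c(h, J(1..R))` (default all 0).
#' @return An [ising_chain()] carrying attributes `residual` (final sup-norm
#'   mismatch), `iterations`, and `trace` (residual per Newton iteration).
#' @export
fit_maxent_pairwise <- function(mean, corr, range, tol = 1e-10, init = NULL) {
  range <- check_count(range, "range")
  if (range > 12L) {
    stop_behavdim("exact fitting is limited to range <= 12.",
                  class = "behavdim_capacity_error")
  }
  if (!is.numeric(mean) || length(mean) != 1L || abs(mean) >= 1) {
    stop_behavdim("`mean` must lie strictly inside (-1, 1).",
                  class = "behavdim_parameter_error")
  }
  cvals <- if (is.data.frame(corr)) {
    idx <- match(1:range, round(corr$lag))
    if (any(is.na(idx))) {
      stop_behavdim("`corr` must contain values at integer lags 1..range.",
                    class = "behavdim_coverage_error")
    }
    corr$value[idx]
  } else {
    if (length(corr) < range) {
      stop_behavdim("`corr` must supply at least `range` values C(1..R).",
                    class = "behavdim_coverage_error")
    }
    as.numeric(corr[1:range])
  }
  c0 <- 1 - mean^2
  if (any(abs(cvals) > c0 + 1e-12)) {
    stop_behavdim("target correlations violate |C(tau)| <= C(0) = 1 - mean^2.",
                  class = "behavdim_parameter_error")
  }
  targets <- c(mean, cvals + mean^2)  # raw moments <s>, <s_0 s_r>

  model_moments <- function(theta) {
    mom <- ising_moments(ising_chain(theta[1], theta[-1]), range)
    c(mom$mean, mom$raw[-1])
  }
  # convex dual: log lambda1(h, J) - h*<s>* - sum_r J(r) <s0 sr>*
  dual <- function(theta) {
    sys <- ising_leading_system(ising_chain(theta[1], theta[-1]))
    log(sys$lambda1) - sum(theta * targets)
  }
  grad <- function(theta) model_moments(theta) - targets

  theta <- if (is.null(init)) numeric(range + 1L) else as.numeric(init)
  if (length(theta) != range + 1L) {
    stop_behavdim("`init` must have length range + 1 (h then J).",
                  class = "behavdim_parameter_error")
  }
  opt <- optim(theta, fn = dual, gr = grad, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-14))
  theta <- opt$par
  res <- grad(theta)
  trace <- max(abs(res))
  iter <- 0L
  damp <- 1
  while (max(abs(res)) > tol && iter < 60L) {
    iter <- iter + 1L
    Jac <- numeric_jacobian(grad, theta)
    step <- tryCatch(solve(Jac, res), error = function(e) NULL)
    if (is.null(step)) break
    cand <- theta - damp * step
    res_cand <- grad(cand)
    if (max(abs(res_cand)) < max(abs(res))) {
      theta <- cand
      res <- res_cand
      damp <- min(1, damp * 2)
    } else {
      damp <- damp / 2
      if (damp < 1e-6) break
    }
    trace <- c(trace, max(abs(res)))
  }
  if (max(abs(res)) > tol) {
    stop_behavdim(
      sprintf("maximum-entropy fit did not reach tol = %g; residuals: %s. Targets may not be realizable by a range-%d model.",
              tol, paste(signif(res, 3), collapse = ", "), range),
      class = "behavdim_fit_error"
    )
  }
  out <- ising_chain(theta[1], theta[-1])
  attr(out, "residual") <- max(abs(res))
  attr(out, "iterations") <- iter
  attr(out, "trace") <- trace
  out
}

numeric_jacobian <- function(f, x, eps = 1e-6) {
  f0 <- f(x)
  J <- matrix(0, length(f0), length(x))
  for (j in seq_along(x)) {
    xp <- x; xp[j] <- xp[j] + eps
    xm <- x; xm[j] <- xm[j] - eps
    J[, j] <- (f(xp) - f(xm)) / (2 * eps)
  }
  J
}
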