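#' Windowed covariance matrix of a stationary process
#'
#' Discretizes \eqn{\langle x(t)x(t')\rangle} on a window of `window_len`
#' uniformly spaced samples: a symmetric Toeplitz matrix with entry
#' \eqn{(i,j) = C(|i-j|\,\Delta t)}. This is the starting point for kernel
#' inversion, spectra, and predictive information; the window is later split
#' at its midpoint into equal past and future halves, so `window_len` must be
#' even.
#'
#' @param corr A correlation model or a `behav_corr_est` from
#'   [estimate_corr()]; estimated inputs must cover lags up to
#'   `(window_len - 1) * dt` and be positive definite on the window.
#' @param window_len Even number of samples in the window (past + future).
#' @param dt Sampling step.
#' @return A `window_len` x `window_len` covariance matrix.
#' @export
build_covariance <- function(corr, window_len, dt) {
  window_len <- check_count(window_len, "window_len", min = 2L)
  if (window_len %% 2L != 0L) {
    stop_behavdim("`window_len` must be even (equal past and future halves).",
                  class = "behavdim_size_error")
  }
  check_scalar_positive(dt, "dt")
  vals <- corr_value(corr, (0:(window_len - 1L)) * dt)
  C <- toeplitz(vals)
  if (inherits(corr, "behav_corr_est")) {
    ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0) {
      stop_behavdim(
        sprintf("estimated correlation gives a non-positive-definite window covariance (smallest eigenvalue %g).",
                min(ev)),
        class = "behavdim_conditioning_error"
      )
    }
    attr(C, "estimated") <- TRUE
  }
  C
}

#' Invert a windowed covariance to the kernel and its past-future blocks
#'
#' For a Gaussian process the log-probability of a trajectory is a quadratic
#' form \eqn{\tfrac12 x^\top K x} whose kernel \eqn{K} is inverse to the
#' correlation function. On a finite window the discrete kernel is the plain
#' matrix inverse of the window covariance (Kronecker-delta normalization;
#' no \eqn{1/\Delta t} continuum factor is applied — the rank of the
#' past-future block is scale invariant). The window splits at its midpoint:
#' past \eqn{= } first half (\eqn{t \le 0}), future \eqn{=} second half
#' (\eqn{t > 0}).
#'
#' @param cov Symmetric positive-definite covariance from
#'   [build_covariance()].
#' @param dt Sampling step (carried for downstream grids).
#' @return A `windowed_kernel` object with elements `kernel`, `window_len`,
#'   `m` (half-window), `dt`, and block accessors via [kernel_blocks()].
#' @export
invert_to_kernel <- function(cov, dt) {
  cov <- as.matrix(cov)
  n <- nrow(cov)
  if (ncol(cov) != n || max(abs(cov - t(cov))) > 1e-8 * max(abs(cov))) {
    stop_behavdim("`cov` must be symmetric.", class = "behavdim_parameter_error")
  }
  check_scalar_positive(dt, "dt")
  R <- tryCatch(chol(cov), error = function(e) NULL)
  if (is.null(R)) {
    stop_behavdim("covariance is not positive definite.",
                  class = "behavdim_conditioning_error")
  }
  cond <- kappa(R)^2  # kappa(cov) ~ kappa(chol)^2, cheap triangular estimate
  if (cond > 1e12) {
    stop_behavdim(
      sprintf("covariance condition number ~%g exceeds 1e12; regularize the correlation (shrinkage or shorter window) before inverting.",
              cond),
      class = "behavdim_conditioning_error"
    )
  }
  K <- chol2inv(R)
  # contract check on random probes: K %*% (cov %*% v) == v
  probes <- matrix(sin(seq_len(3L * n)), n, 3L)
  err <- max(abs(K %*% (cov %*% probes) - probes))
  if (err > 1e-6) {
    stop_behavdim(
      sprintf("kernel-covariance product deviates from identity by %g; input is too ill-conditioned.", err),
      class = "behavdim_conditioning_error"
    )
  }
  structure(
    list(kernel = K, window_len = n, m = n %/% 2L, dt = dt,
         estimated = isTRUE(attr(cov, "estimated"))),
    class = "windowed_kernel"
  )
}

#' @rdname invert_to_kernel
#' @param kern A `windowed_kernel`.
#' @return `kernel_blocks()`: list with `K_pp`, `K_ff`, `K_pf`.
#' @export
kernel_blocks <- function(kern) {
  stopifnot(inherits(kern, "windowed_kernel"))
  m <- kern$m
  ip <- seq_len(m)
  iff <- (m + 1L):kern$window_len
  list(
    K_pp = kern$kernel[ip, ip, drop = FALSE],
    K_ff = kern$kernel[iff, iff, drop = FALSE],
    K_pf = kern$kernel[ip, iff, drop = FALSE]
  )
}

#' @export
print.windowed_kernel <- function(x, ...) {
  cat(sprintf("<windowed kernel: %d samples (%d past + %d future), dt = %g>\n",
              x$window_len, x$m, x$m, x$dt))
  invisible(x)
}

#' Spectrum of the past-future kernel block
#'
#' The block of the kernel coupling past to future depends only on the sum
#' \eqn{t + t'} of the distance into the past and into the future. Reversing
#' the past axis therefore turns it into a symmetric (Hankel) matrix whose
#' eigenvalues \eqn{a_\mu} are the coefficients of the expansion
#' \eqn{K(t + t') = \sum_\mu a_\mu \phi_\mu(t)\phi_\mu(t')}, and whose
#' eigenvectors \eqn{\phi_\mu} are the predictive filters. The number of
#' coefficients distinguishable from zero is the dimensionality of the
#' underlying dynamics.
#'
#' @param kern A `windowed_kernel` from [invert_to_kernel()].
#' @return A `kpf_spectrum` object: coefficients sorted by decreasing
#'   magnitude (ties broken positive-first), the filter matrix (row `i` =
#'   distance `(i-1)*dt` into the past), `window_len`, and `dt`.
#' @export
kpf_spectrum <- function(kern) {
  stopifnot(inherits(kern, "windowed_kernel"))
  m <- kern$m
  Kpf <- kernel_blocks(kern)$K_pf
  M <- Kpf[m:1, , drop = FALSE]  # reverse past axis: entry depends on t + t'
  scale <- max(abs(M))
  if (scale > 0 && max(abs(M - t(M))) > 1e-8 * scale) {
    stop_behavdim(
      "re-indexed past-future block is not symmetric; the window covariance is not stationary-Toeplitz.",
      class = "behavdim_internal_error"
    )
  }
  eg <- eigen((M + t(M)) / 2, symmetric = TRUE)
  ord <- order(-abs(eg$values), -eg$values)
  out <- structure(
    list(coeffs = eg$values[ord],
         filters = eg$vectors[, ord, drop = FALSE],
         window_len = kern$window_len,
         dt = kern$dt,
         estimated = isTRUE(kern$estimated)),
    class = "kpf_spectrum"
  )
  if (out$estimated) {
    warn(paste(
      "spectrum computed from an estimated correlation: finite samples replace",
      "zero eigenvalues by a continuous bulk, so small coefficients need a",
      "looser rank threshold (default 1e-2) and are not individually meaningful."
    ))
  }
  out
}

#' @export
print.kpf_spectrum <- function(x, ...) {
  cat(sprintf("<past-future kernel spectrum: window %d, %d coefficients>\n",
              x$window_len, length(x$coeffs)))
  cat("  leading |a|:", signif(abs(x$coeffs[seq_len(min(5, length(x$coeffs)))]), 4), "\n")
  invisible(x)
}

#' Effective rank of a past-future spectrum
#'
#' Counts coefficients whose magnitude exceeds `rel_threshold` times the
#' leading magnitude. With analytic input correlations the default
#' `1e-6` cleanly separates true rank from the double-precision noise floor
#' (~1e-13 relative); for spectra estimated from data use a looser
#' threshold such as `1e-2` to stand clear of sampling noise.
#'
#' @param spec A `kpf_spectrum`.
#' @param rel_threshold Relative magnitude threshold in (0, 1).
#' @return Integer rank; 0 for an identically zero spectrum.
#' @export
effective_rank <- function(spec, rel_threshold = 1e-6) {
  stopifnot(inherits(spec, "kpf_spectrum"))
  if (!is.numeric(rel_threshold) || length(rel_threshold) != 1L ||
      rel_threshold <= 0 || rel_threshold >= 1) {
    stop_behavdim("`rel_threshold` must lie in (0, 1).",
                  class = "behavdim_parameter_error")
  }
  a1 <- abs(spec$coeffs[1])
  if (a1 == 0) return(0L)
  sum(abs(spec$coeffs) > rel_threshold * a1)
}

#' Top predictive filters
#'
#' Returns the first `d` eigenvectors of the symmetrized past-future block:
#' orthonormal filters \eqn{\phi_\mu} on the past grid. Applying them to a
#' past segment (most recent sample first) yields the features
#' \eqn{F_\mu = \sum_t \phi_\mu(t)\, x(-t)} that are sufficient statistics
#' for prediction.
#'
#' @param spec A `kpf_spectrum`.
#' @param d Number of filters, between 1 and the half-window size.
#' @return An m x d matrix; row `i` is the filter weight at distance
#'   `(i-1)*dt` into the past.
#' @export
predictive_filters <- function(spec, d) {
  stopifnot(inherits(spec, "kpf_spectrum"))
  d <- check_count(d, "d")
  if (d > length(spec$coeffs)) {
    stop_behavdim(
      sprintf("d = %d exceeds the number of available filters (%d).",
              d, length(spec$coeffs)),
      class = "behavdim_parameter_error"
    )
  }
  spec$filters[, seq_len(d), drop = FALSE]
}

#' Rank of the past-future kernel as a function of window size
#'
#' Recomputes the spectrum at each window and reports the effective rank.
#' Finite-dimensional (exponential-mixture) correlations keep a constant
#' rank once the window resolves all timescales; power-law correlations grow
#' rank without bound — the behavior is then effectively
#' infinite-dimensional.
#'
#' @param corr A correlation model (or estimate covering the largest window).
#' @param windows Increasing even window lengths (samples).
#' @param rel_threshold Passed to [effective_rank()].
#' @param dt Sampling step (default 1: lags in units of the sample step).
#' @return A `rank_report` tibble with columns `window`, `rank`; attributes
#'   `threshold` and `verdict` (`"finite"`, `"growing"`, or
#'   `"indeterminate"`).
#' @export
rank_vs_window <- function(corr, windows, rel_threshold = 1e-6, dt = 1) {
  if (length(windows) < 1L || is.unsorted(windows, strictly = TRUE)) {
    stop_behavdim("`windows` must be strictly increasing.",
                  class = "behavdim_parameter_error")
  }
  ranks <- purrr::map_int(windows, function(w) {
    spec <- kpf_spectrum(invert_to_kernel(build_covariance(corr, w, dt), dt))
    effective_rank(spec, rel_threshold)
  })
  verdict <- if (length(unique(ranks)) == 1L) {
    "finite"
  } else if (all(diff(ranks) > 0)) {
    "growing"
  } else {
    "indeterminate"
  }
  out <- tibble(window = as.integer(windows), rank = ranks)
  attr(out, "threshold") <- rel_threshold
  attr(out, "verdict") <- verdict
  class(out) <- c("rank_report", class(out))
  out
}

#' @export
print.rank_report <- function(x, ...) {
  cat(sprintf("<rank vs window: verdict '%s' at relative threshold %g>\n",
              attr(x, "verdict"), attr(x, "threshold")))
  NextMethod()
}
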