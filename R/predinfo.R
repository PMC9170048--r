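#' Gaussian predictive information of a windowed process
#'
#' Mutual information (in bits) between the past half and future half of a
#' stationary Gaussian process observed in a window of `window_len` samples:
#' \deqn{I_{\mathrm{pred}} = \tfrac12 \log_2 \frac{\det C_{pp}\,\det C_{ff}}
#' {\det C},} computed from triangular-factorization log-determinants (never
#' raw determinant products, which overflow at window 1000). For a Markov
#' (single-exponential) process only the boundary pair carries information,
#' so the value is window independent and equals
#' \eqn{-\tfrac12\log_2(1 - c^2)} with \eqn{c = e^{-\Delta t/\tau_c}}.
#'
#' @inheritParams build_covariance
#' @param shrinkage Diagonal shrinkage intensity applied to estimated
#'   (`behav_corr_est`) inputs before factorization: the window covariance
#'   is replaced by `(1 - shrinkage) * C + shrinkage * diag(C)`. Ignored for
#'   analytic models. Default 1e-3.
#' @return Predictive information in bits (non-negative scalar).
#' @export
gaussian_pred_info <- function(corr, window_len, dt, shrinkage = 1e-3) {
  C <- shrunk_covariance(corr, window_len, dt, shrinkage)
  m <- window_len %/% 2L
  ip <- seq_len(m)
  iff <- (m + 1L):window_len
  ld <- function(M) 2 * sum(log(diag(chol_or_conderr(M))))
  bits <- (ld(C[ip, ip]) + ld(C[iff, iff]) - ld(C)) / (2 * log(2))
  max(bits, 0)
}

shrunk_covariance <- function(corr, window_len, dt, shrinkage) {
  C <- build_covariance(corr, window_len, dt)
  if (isTRUE(attr(C, "estimated")) && shrinkage > 0) {
    C <- (1 - shrinkage) * C + shrinkage * diag(diag(C))
    attr(C, "estimated") <- TRUE
  }
  C
}

chol_or_conderr <- function(M) {
  out <- tryCatch(chol(M), error = function(e) NULL)
  if (is.null(out)) {
    stop_behavdim(
      "covariance block is not positive definite; regularize (shrinkage) or shorten the window.",
      class = "behavdim_conditioning_error"
    )
  }
  out
}

# canonical correlations between past and future halves of the window
past_future_canonical <- function(corr, window_len, dt, shrinkage = 1e-3) {
  C <- shrunk_covariance(corr, window_len, dt, shrinkage)
  m <- window_len %/% 2L
  ip <- seq_len(m)
  iff <- (m + 1L):window_len
  Rp <- chol_or_conderr(C[ip, ip])
  Rf <- chol_or_conderr(C[iff, iff])
  W <- backsolve(Rp, C[ip, iff, drop = FALSE], transpose = TRUE)
  W <- t(backsolve(Rf, t(W), transpose = TRUE))
  rho <- svd(W, nu = 0, nv = 0)$d
  pmin(rho, 1 - 1e-15)  # guard round-off at perfect correlation
}

#' Predictive information captured by the best d features
#'
#' For jointly Gaussian past and future, the optimal `d`-feature summary of
#' the past is the top `d` canonical correlates, and the information they
#' capture is \eqn{I(d) = -\tfrac12 \sum_{\mu \le d} \log_2(1 - \rho_\mu^2)}
#' with \eqn{\rho_\mu} the canonical correlations of the past/future
#' covariance blocks. Linear features are provably optimal in the Gaussian
#' case, so this realizes the maximization over feature mappings exactly.
#'
#' @inheritParams gaussian_pred_info
#' @param d_max Largest feature count to report (at most the half-window).
#' @return A tibble with columns `d` (0..`d_max`) and `bits`, monotone
#'   non-decreasing in `d`.
#' @export
ipred_vs_d <- function(corr, window_len, d_max, dt, shrinkage = 1e-3) {
  window_len <- check_count(window_len, "window_len", min = 2L)
  d_max <- check_count(d_max, "d_max", min = 1L)
  m <- window_len %/% 2L
  if (d_max > m) {
    stop_behavdim(sprintf("d_max (%d) exceeds the past-block size (%d).",
                          d_max, m),
                  class = "behavdim_parameter_error")
  }
  rho <- past_future_canonical(corr, window_len, dt, shrinkage)
  per_mode <- -0.5 * log2(1 - rho^2)
  bits <- c(0, cumsum(per_mode))[seq_len(d_max + 1L)]
  tibble(d = 0:d_max, bits = bits)
}

#' Predictive information vs window size, with divergence classification
#'
#' Computes \eqn{I_{\mathrm{pred}}(T)} across windows and classifies its
#' growth: `"saturating"` when the last increment falls below `1e-3` bits
#' (finite correlation time: finite predictive information),
#' `"log_divergent"` when the curve is affine in \eqn{\log T} over the top
#' decade of windows with positive slope and relative residual below 5%
#' (the signature of power-law correlations), otherwise `"indeterminate"`.
#'
#' @inheritParams gaussian_pred_info
#' @param windows Increasing even window lengths (samples).
#' @return A `predinfo_curve` tibble with columns `window`, `bits`;
#'   attributes `classification`, `log_slope` (bits per e-fold of T, NA when
#'   not log-divergent), and `units` (`"bits"`).
#' @export
pred_info_scaling <- function(corr, windows, dt, shrinkage = 1e-3) {
  if (length(windows) < 2L || is.unsorted(windows, strictly = TRUE)) {
    stop_behavdim("`windows` must be strictly increasing, length >= 2.",
                  class = "behavdim_parameter_error")
  }
  bits <- purrr::map_dbl(windows, gaussian_pred_info, corr = corr,
                         dt = dt, shrinkage = shrinkage)
  increments <- diff(bits)
  classification <- "indeterminate"
  slope <- NA_real_
  if (abs(increments[length(increments)]) < 1e-3) {
    classification <- "saturating"
  } else {
    top <- windows >= max(windows) / 10
    if (sum(top) >= 3L) {
      fit <- lm(bits[top] ~ log(windows[top]))
      rel_resid <- max(abs(resid(fit))) / mean(bits[top])
      if (coef(fit)[2] > 0 && rel_resid < 0.05) {
        classification <- "log_divergent"
        slope <- unname(coef(fit)[2])
      }
    }
  }
  out <- tibble(window = as.integer(windows), bits = bits)
  attr(out, "classification") <- classification
  attr(out, "log_slope") <- slope
  attr(out, "units") <- "bits"
  class(out) <- c("predinfo_curve", class(out))
  out
}

#' @export
print.predinfo_curve <- function(x, ...) {
  cat(sprintf("<predictive information curve: %s%s>\n",
              attr(x, "classification"),
              if (is.na(attr(x, "log_slope"))) "" else
                sprintf(", slope %.3g bits per e-fold", attr(x, "log_slope"))))
  NextMethod()
}

#' Dimensionality from saturation of the per-feature information curve
#'
#' The dimensionality of behavior is the smallest number of past features
#' whose captured information reaches the full predictive information:
#' smallest `d` with \eqn{I(d)/I_{\mathrm{full}} \ge 1 - } `tol`. When no
#' `d` in the curve qualifies the process is unsaturated at this window —
#' effectively infinite-dimensional — and `Inf` is returned.
#'
#' @param curve Per-feature curve from [ipred_vs_d()] (columns `d`, `bits`).
#' @param full_info Full predictive information at the same window, from
#'   [gaussian_pred_info()]; must be positive.
#' @param tol Saturation tolerance on the information ratio (default 1e-6).
#' @return Integer dimensionality, or `Inf` if unsaturated.
#' @export
dimension_from_saturation <- function(curve, full_info, tol = 1e-6) {
  if (!is.numeric(full_info) || length(full_info) != 1L || full_info <= 0) {
    stop_behavdim(
      "`full_info` must be positive: a process with no predictive structure has undefined dimensionality.",
      class = "behavdim_undefined_dimension_error"
    )
  }
  ok <- curve$bits / full_info >= 1 - tol
  if (!any(ok)) return(Inf)
  as.integer(min(curve$d[ok]))
}

#' Information captured by explicit past filters
#'
#' Evaluates \eqn{I(\{F_\mu\}; x_{\mathrm{fut}})} for linear features
#' \eqn{F_\mu} defined by a filter matrix on the past grid (rows = distance
#' into the past, as returned by [predictive_filters()]). Used to verify
#' that the top-D predictive filters preserve the full Gaussian predictive
#' information.
#'
#' @inheritParams gaussian_pred_info
#' @param filters m x d filter matrix; row `i` weights the sample at
#'   distance `(i-1)*dt` into the past.
#' @return Information in bits.
#' @export
feature_pred_info <- function(corr, window_len, dt, filters,
                              shrinkage = 1e-3) {
  C <- shrunk_covariance(corr, window_len, dt, shrinkage)
  m <- window_len %/% 2L
  if (nrow(filters) != m) {
    stop_behavdim("`filters` must have one row per past sample (half window).",
                  class = "behavdim_parameter_error")
  }
  ip <- seq_len(m)
  iff <- (m + 1L):window_len
  # past rows are ordered by time (oldest first); filters by distance into
  # the past (most recent first) -- reverse to align.
  Phi <- filters[m:1, , drop = FALSE]
  Cff <- C[iff, iff, drop = FALSE]
  CF <- t(Phi) %*% C[ip, ip, drop = FALSE] %*% Phi
  Cxf <- t(Phi) %*% C[ip, iff, drop = FALSE]
  joint <- rbind(cbind(CF, Cxf), cbind(t(Cxf), Cff))
  ld <- function(M) 2 * sum(log(diag(chol_or_conderr(M))))
  bits <- (ld(CF) + ld(Cff) - ld(joint)) / (2 * log(2))
  max(bits, 0)
}
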