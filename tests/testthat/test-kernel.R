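test_that("windowed covariance is the Toeplitz discretization of the correlation", {
  # white noise: diagonal
  Cw <- build_covariance(white_noise_corr(2), 4, 1)
  expect_equal(Cw, diag(2, 4))

  # single exponential, window 2, dt = tau_c
  C2 <- build_covariance(corr_ou_analytic(1, 1), 2, 1)
  expect_equal(C2, matrix(c(1, exp(-1), exp(-1), 1), 2, 2))

  # power law, window 4: first row 1, 1/2, 1/(1+sqrt 2), 1/(1+sqrt 3)
  Cp <- build_covariance(powerlaw_corr(1, 1, 0.5), 4, 1)
  expect_equal(Cp[1, ], c(1, 1 / 2, 1 / (1 + sqrt(2)), 1 / (1 + sqrt(3))))

  expect_error(build_covariance(white_noise_corr(1), 5, 1),
               class = "behavdim_size_error")
})

test_that("estimated-correlation inputs need lag coverage", {
  x <- simulate_ou(10, 1, 1, 5000, seed = 3)
  est <- estimate_corr(x, max_lag = 20)
  expect_error(build_covariance(est, 60, 1),
               class = "behavdim_coverage_error")
  C <- build_covariance(est, 20, 1)
  expect_true(isTRUE(attr(C, "estimated")))
})

test_that("kernel inversion satisfies the delta contract and closed forms", {
  # identity covariance -> identity kernel, no past-future coupling
  kern <- invert_to_kernel(diag(1, 6), 1)
  expect_equal(kern$kernel, diag(1, 6))
  expect_equal(kernel_blocks(kern)$K_pf, matrix(0, 3, 3))

  # 2x2 closed form: inverse of [[1,c],[c,1]] is [[1,-c],[-c,1]]/(1-c^2)
  cc <- exp(-1)
  kern2 <- invert_to_kernel(build_covariance(corr_ou_analytic(1, 1), 2, 1), 1)
  expect_equal(kern2$kernel,
               matrix(c(1, -cc, -cc, 1), 2, 2) / (1 - cc^2))
})

test_that("the single-exponential kernel is tridiagonal (Markov property)", {
  C <- build_covariance(corr_ou_analytic(10, 1), 100, 1)
  K <- invert_to_kernel(C, 1)$kernel
  off <- abs(row(K) - col(K)) > 1
  expect_lt(max(abs(K[off])), 1e-10 * max(abs(K)))
})

test_that("ill-conditioned covariances are refused with advice", {
  cm <- exp_mixture_corr(1, 1e12)  # correlation ~1 across the whole window
  C <- build_covariance(cm, 10, 1)
  expect_error(invert_to_kernel(C, 1), class = "behavdim_conditioning_error")
})

test_that("past-future spectra count the underlying dynamical variables", {
  # white noise: identically zero block
  sp <- spectrum_of(white_noise_corr(1), 8)
  expect_equal(max(abs(sp$coeffs)), 0)
  expect_equal(effective_rank(sp), 0L)

  # one-dimensional: exactly one coefficient at any window
  for (w in c(4, 20, 100)) {
    sp <- spectrum_of(corr_ou_analytic(5, 1), w)
    expect_equal(effective_rank(sp, 1e-6), 1L)
  }

  # two-dimensional at a = 0.75
  sp2 <- spectrum_of(corr_2d_analytic(8, 0.75, 1), 400)
  expect_equal(effective_rank(sp2, 1e-6), 2L)

  # three-timescale mixture: exactly 3, with a hard 1e-10 floor below
  mix <- exp_mixture_corr(rep(1 / 3, 3), c(4, 32, 256))
  for (w in c(100, 1000)) {
    sp3 <- spectrum_of(mix, w)
    expect_equal(effective_rank(sp3, 1e-6), 3L)
    expect_lt(abs(sp3$coeffs[4]), 1e-10)
  }
})

test_that("effective rank thresholding behaves at the edges", {
  sp <- spectrum_of(corr_2d_analytic(8, 0.75, 1), 200)
  expect_equal(effective_rank(sp, 1 - 1e-12), 1L)  # only the largest survives
  expect_error(effective_rank(sp, 0), class = "behavdim_parameter_error")
  expect_error(effective_rank(sp, 1), class = "behavdim_parameter_error")
})

test_that("finite mixtures have rank equal to their number of exponentials", {
  # windows at least 16x the longest timescale
  for (cm in mixture_test_grid()) {
    k <- length(cm$timescales)
    w <- 2L * ceiling(16 * max(cm$timescales) / 2)
    expect_equal(effective_rank(spectrum_of(cm, w), 1e-6), k,
                 info = sprintf("k = %d, window = %d", k, w))
  }
})

test_that("spectra are window-stable once the window covers the slowest mode", {
  cm <- exp_mixture_corr(c(0.4, 0.6), c(2, 9))
  a100 <- spectrum_of(cm, 100)$coeffs[1:2]
  a1000 <- spectrum_of(cm, 1000)$coeffs[1:2]
  expect_equal(a100, a1000, tolerance = 0.01)

  # the three-timescale reference mixture keeps its rank and leading
  # coefficient across windows even when the slow mode outlives the window
  mix <- exp_mixture_corr(rep(1 / 3, 3), c(4, 32, 256))
  s100 <- spectrum_of(mix, 100)
  s1000 <- spectrum_of(mix, 1000)
  expect_equal(effective_rank(s100), effective_rank(s1000))
  expect_equal(s100$coeffs[1], s1000$coeffs[1], tolerance = 0.01)
})

test_that("rank growth with window separates finite from power-law correlations", {
  mix <- exp_mixture_corr(rep(1 / 3, 3), c(4, 32, 256))
  rep_mix <- rank_vs_window(mix, c(100, 1000))
  expect_equal(rep_mix$rank, c(3L, 3L))
  expect_equal(attr(rep_mix, "verdict"), "finite")

  rep_pl <- rank_vs_window(powerlaw_corr(1, 1, 0.5), c(100, 1000))
  expect_true(all(diff(rep_pl$rank) > 0))
  expect_equal(attr(rep_pl, "verdict"), "growing")

  rep_wn <- rank_vs_window(white_noise_corr(1), c(8, 16))
  expect_equal(rep_wn$rank, c(0L, 0L))
})

test_that("predictive filters are orthonormal and capture the full information", {
  mix <- exp_mixture_corr(rep(1 / 3, 3), c(4, 32, 256))
  sp <- spectrum_of(mix, 200)
  phi <- predictive_filters(sp, 3)
  expect_equal(crossprod(phi), diag(1, 3), tolerance = 1e-10)

  full <- gaussian_pred_info(mix, 200, 1)
  kept <- feature_pred_info(mix, 200, 1, phi)
  expect_equal(kept / full, 1, tolerance = 1e-6)

  expect_error(predictive_filters(sp, 101), class = "behavdim_parameter_error")
})

test_that("the one-dimensional filter is concentrated on the most recent past", {
  sp <- spectrum_of(corr_ou_analytic(5, 1), 60)
  phi <- predictive_filters(sp, 1)
  # Markov: only the boundary sample couples past to future
  expect_gt(abs(phi[1, 1]), 0.999)
  expect_lt(max(abs(phi[-1, 1])), 1e-3)
})

test_that("spectra from estimated correlations recover rank at a loosened threshold", {
  x <- simulate_ou(10, 1, 1, 1e6, seed = 77)
  est <- estimate_corr(x, max_lag = 16)
  C <- build_covariance(est, 16, 1)
  expect_warning(
    sp <- kpf_spectrum(invert_to_kernel(C, 1)),
    "estimated correlation"
  )
  expect_equal(effective_rank(sp, 1e-2), 1L)
})

test_that("spectrum tie-break and ordering are deterministic", {
  sp <- spectrum_of(exp_mixture_corr(c(0.5, 0.5), c(3, 10)), 160)
  expect_true(all(diff(abs(sp$coeffs)) <= 1e-12))
  expect_identical(tidy(sp)$mode, seq_along(sp$coeffs))
  g <- glance(sp)
  expect_equal(g$effective_rank, 2L)
})
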