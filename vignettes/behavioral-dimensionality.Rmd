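---
title: "Measuring the dimensionality of behavior"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring the dimensionality of behavior}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(behavdim)
```

## The question

Modern behavioral recordings reduce video to a handful of scalar time
series. `behavdim` attaches a precise number to such a series: the
dimensionality of the dynamics that generated it, defined operationally as
the minimum number of features of the past needed to capture **all**
predictive information about the future. This vignette explains the models,
the estimators, the numerical choices, and what the package's tests do and
do not establish.

## Continuous behavior: Gaussian processes

A stationary Gaussian process is fully described by its autocorrelation
$C(\tau) = \langle x(t)x(t+\tau)\rangle$. The package works with three
families:

* **Exponential mixtures** $C(\tau) = \sum_{k=1}^{D} A_k e^{-|\tau|/\tau_k}$
  — the signature of a linear stochastic system with $D$ degrees of
  freedom. The canonical $D=1$ member is the Ornstein–Uhlenbeck (OU)
  relaxation $\tau_c \dot x = -x + \eta$ with white noise $\eta$. The
  whiteness matters: colored noise is equivalent to hidden variables, which
  is exactly what the dimensionality is meant to count. The $D=2$ member
  couples the observable to one hidden variable with strength $a$, giving
  timescales $\tau_c/(1\pm a)$ and amplitudes
  $A_\pm = \tfrac12\langle x^2\rangle(1-a^2)/(1\pm a)$.
* **Power laws** $C(\tau) = \langle x^2\rangle\, t_0^\alpha/(t_0^\alpha +
  |\tau|^\alpha)$, $\alpha \in (0,2)$ — no characteristic timescale.
* **White noise** — the memoryless limit, useful as a null.

### Exact simulation

All simulators draw from the exact finite-dimensional distributions rather
than integrating stochastic differential equations:

* `simulate_ou()` uses the AR(1) recursion with coefficient
  $e^{-\Delta t/\tau_c}$ and matched stationary innovation variance.
* `simulate_linear()` (and `simulate_2d()`, a two-variable convenience
  wrapper) propagates with the matrix exponential $e^{-B\Delta t}$ and a
  one-step noise covariance $Q = C - \Phi C \Phi^\top$ derived from the
  stationary Lyapunov solution $C$.
* `simulate_powerlaw()` factorizes the dense window covariance (Cholesky)
  and applies it to standard normal draws.

The initial state always comes from the stationary distribution, so there is
no burn-in and no discretization bias: sample statistics can be compared to
the continuous-time formulas at face value, which is what the test suite
does. The cost of exactness for the power-law generator is a dense $n \times
n$ covariance, so its length is capped at 4096 samples; analyses beyond that
run through the analytic correlation model instead of simulated records.

## From correlation to kernel to spectrum

`build_covariance()` discretizes $C$ on a window of $2m$ samples (a
symmetric Toeplitz matrix), `invert_to_kernel()` inverts it, and
`kpf_spectrum()` extracts the past–future block and eigendecomposes it. The
package's conventions, chosen where more than one faithful construction
exists:

* **Window split.** A "window of $T$ samples" holds $m = T/2$ past and $m$
  future samples, split at the midpoint. The symmetric split makes the
  re-indexed past–future block square and symmetric.
* **Delta normalization.** The discrete kernel is the plain matrix inverse
  (Kronecker-delta convention); no $1/\Delta t$ continuum factor is
  applied. Rank and relative thresholds are invariant to this scale.
* **Symmetrization.** The block entry depends only on the summed distance
  into past and future, so reversing the past axis yields a Hankel matrix
  that is symmetric up to round-off; asymmetry beyond $10^{-8}$ relative
  aborts (it indicates a non-Toeplitz input). Eigenvalues are reported
  sorted by decreasing magnitude, ties broken positive-first, so spectra
  are deterministic.
* **Rank thresholds.** For analytic inputs, coefficients below
  $10^{-6}|a_1|$ are noise: the true zero modes land at $10^{-13}$ relative
  in double precision, five orders below the threshold. For spectra built
  from *estimated* correlations the appropriate threshold is $\sim
  10^{-2}$: finite samples replace zero eigenvalues by a continuous bulk
  (at $10^6$ samples the bulk sits just below 1% of the leading
  coefficient), and `kpf_spectrum()` warns accordingly. Distinguishing a
  true small eigenvalue from that bulk is a random-matrix problem the
  package deliberately does not attempt; absence of resolved eigenvalues
  is not evidence of low dimensionality.
* **Conditioning.** Inversion refuses covariance matrices with condition
  number above $10^{12}$ and verifies the kernel–covariance product on
  probe vectors to $10^{-6}$; estimated covariances that fail positive
  definiteness are reported with the offending eigenvalue.

A window-size sweep (`rank_vs_window()`) distinguishes the two regimes: for
exponential mixtures the rank is constant in the window, while for power-law
correlations it grows without bound ("growing" verdict). One subtlety the
package surfaces deliberately: individual *small* coefficients of a mixture
are only window-stable once the window covers the corresponding timescale.
For the reference three-timescale model (4/32/256 steps) the third
coefficient changes by a factor of a few between windows of 100 and 1000
samples, while the rank and the leading coefficient are stable; tests assert
percent-level coefficient stability only where the smaller window already
covers the slowest mode.

## Predictive information

For jointly Gaussian past and future,

$$I_{\text{pred}} = \frac12 \log_2 \frac{\det C_{pp}\,\det C_{ff}}{\det C}
\quad\text{bits},$$

computed from Cholesky log-determinants (never raw determinants, which
over/underflow far below window 1000). Information is reported in bits
throughout. The per-feature curve uses canonical correlations $\rho_\mu$ of
the past and future blocks — for Gaussian variables linear features are
provably optimal, so the maximization over feature mappings is exact —
giving $I(d) = -\tfrac12\sum_{\mu\le d}\log_2(1-\rho_\mu^2)$.
`dimension_from_saturation()` reports the smallest $d$ with $I(d) \ge
(1-10^{-6})\, I_{\text{pred}}$, or `Inf` when no budget saturates
(effectively infinite dimensionality at that window).

Growth classification in `pred_info_scaling()`: *saturating* when the last
window-to-window increment is below $10^{-3}$ bits; *log-divergent* when the
curve is affine in $\log T$ over the top decade of windows with positive
slope and maximum residual below 5% of the mean information there;
*indeterminate* otherwise (a valid verdict, not an error). The $T\to\infty$
limit in the saturation fraction is approximated by the largest computed
window; for the models in the test grid the value changes by far less than
1% over the last doubling.

The two definitions — spectral rank and saturation dimensionality — agree on
every exponential mixture in the package's 10-model reference grid. One
caveat found while building that grid: the two routes threshold on
*different scales* (eigenvalue magnitude vs. information fraction), so for
mixtures with closely spaced timescales a weak mode can clear the
$10^{-6}$ eigenvalue threshold while contributing less than $10^{-6}$ of
the information. The equivalence is exact for exactly-zero modes; at any
finite tolerance it requires modes that are not marginal. The grid therefore
uses well-separated timescales (ratios $\gtrsim 3$), which is also the
regime where calling a behavior "$k$-dimensional" is meaningful at all.

## Discrete behavior: Ising chains and maximum entropy

Two-state behavior $\sigma_t = \pm 1$ with observed mean and correlations up
to lag $R$ is modeled by the least-structured (maximum-entropy) distribution
consistent with them: an Ising chain with field $h$ and couplings
$J(1..R)$. All exact computations run on the $2^R$-state transfer matrix in
the stationary infinite-chain limit (leading eigenvector boundary
conditions), not on periodic or open finite chains:

* `ising_corr()` propagates the induced Markov chain exactly; for $R=1$,
  $h=0$ it reproduces $C(\tau) = (\tanh J)^\tau$ to machine precision.
  Useful relative precision degrades once $C(\tau)$ decays within
  $\sim 10^{-7}$ of zero, where the $\sim 10^{-13}$ propagation floor
  shows; tail-based rate estimates should use lags where $C$ is still
  above that.
* `ising_tau_c()` generalizes the correlation time to
  $1/\log(\lambda_1/|\lambda_2|)$, which reduces to $-1/\log\tanh J$ at
  $h=0$, $R=1$, and returns 0 for memoryless chains rather than erroring.
* `sample_ising_general()` draws exactly: first block from the stationary
  block distribution, then exact conditionals. No MCMC, no burn-in.
* `fit_maxent_pairwise()` minimizes the convex dual
  $\log\lambda_1(h,J) - h\langle\sigma\rangle^* - \sum_r J(r)\langle
  \sigma_0\sigma_r\rangle^*$ (BFGS with the exact moment-mismatch
  gradient), then polishes with damped Newton steps to a sup-norm moment
  tolerance of $10^{-10}$ by default. Convexity makes the optimum unique;
  tests confirm agreement from random initializations. Non-realizable
  targets fail with the residuals reported.

The leading eigensystem is computed by power iteration on the two-nonzeros-
per-row transfer structure, which keeps the $R = 10$ power-law-coupling
round-trip (a 1024-state chain) well under a second; the dense matrix is
only built where subleading eigenvalues are needed ($\tau_c$). The range cap
$R \le 12$ keeps everything exact; sampling-based fitting for longer ranges
is out of scope.

## What the generators emulate — and what they don't

The simulators produce exactly the stationary, Gaussian (or binary-Markov
with range $R$) processes the theory addresses, at reference study
conditions fixed once: unit variance, hidden-variable coupling $a = 0.75$,
correlation times 4/32/256 sample steps with equal amplitudes (the
amplitudes of the three-timescale reference model are a package choice —
the rank and the $10^{-10}$ noise floor are insensitive to them), power-law
exponent $\alpha = 1/2$ with $t_0$ one sample step, and analysis windows of
100 and 1000 samples. Real behavioral records are none of these things
exactly: they are nonstationary over a session, non-Gaussian, observed
through measurement noise, and of finite length. Passing tests therefore
establish the *estimators'* correctness on their stated model classes, not
that any particular animal's behavior is low-dimensional. The finite-sample
bulk discussed above is the main practical hazard; the package flags it but
does not correct for it.

## Problem sizes and tolerances used in testing

Simulation-based checks use $10^5$–$10^6$-step records, where a ±5% variance
band is a $>4\sigma$ test and correlation estimates are compared to analytic
values within 4 Bartlett standard errors. Spectral checks invert windows up
to 1000 samples (seconds). Enumeration oracles for the discrete module sum
over all $2^{12}$ spin sequences and agree with the transfer matrix to
$10^{-10}$. The power-law generator is validated entrywise against its
target covariance over $10^4$ draws of 64 samples.

## Known limitations

* Single scalar observable only; the multivariate case is reserved in the
  API but not implemented.
* No nonlinear feature search: optimality of linear features is a Gaussian
  theorem, and the discrete module interfaces through fitted models rather
  than plug-in information estimates.
* No random-matrix denoising of estimated spectra, and no state discovery
  for the discrete module (states must be given as ±1).
* The coupling range $R$ for maximum-entropy fitting is an explicit input;
  the package does not choose it from data.
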