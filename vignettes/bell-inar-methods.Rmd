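---
title: "Methods: the BL-INAR(1) model in blinar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the BL-INAR(1) model in blinar}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(blinar)
```

## The model and its assumptions

Count time series are often analysed with the INAR(1) recursion
$X_t = \alpha \circ X_{t-1} + \epsilon_t$, where the binomial thinning
operator $\alpha \circ X = \sum_{i=1}^{X} \xi_i$ (iid Bernoulli($\alpha$)
counting variables, independent of everything else) plays the role of
scalar multiplication: each unit present at time $t-1$ survives to time
$t$ independently with probability $\alpha$, and $\epsilon_t$ new units
arrive. The classical choice of Poisson innovations forces equidispersion,
which real incident-count series frequently violate.

`blinar` takes the innovations to be Bell distributed,
$$P(\epsilon = z) = \frac{\theta^z e^{-(e^\theta-1)} B_z}{z!},$$
with $B_z$ the Bell numbers. The Bell law is a compound Poisson: a
Poisson($e^\theta-1$) number of clusters, each of zero-truncated
Poisson($\theta$) size. That makes it infinitely divisible — a requirement
for a coherent thinning-based INAR construction — and intrinsically
overdispersed, $\mathrm{Var}/\mathrm{E} = 1+\theta$, while still having a
single parameter and closed-form moments
($\mu_\epsilon = \theta e^\theta$,
$\sigma_\epsilon^2 = \theta(1+\theta)e^\theta$). As $\theta \to 0$ it
collapses to the Poisson, so the model nests near-equidispersed behaviour
continuously even though the Poisson is not a formal member of the family.

The process assumptions are: stationarity ($0 < \alpha < 1$), iid
innovations independent of the past, and a correctly specified innovation
family. Under them the chain is ergodic with

* mean $\mu = \theta e^\theta/(1-\alpha)$,
* variance $\sigma^2 = \theta e^\theta(1+\alpha+\theta)/(1-\alpha^2)$,
* autocorrelation $\rho_k = \alpha^k$,
* dispersion index $I_x = \sigma^2/\mu = 1 + \theta/(1+\alpha) > 1$.

Note the last identity: $I_x$ is $1 + \theta/(1+\alpha)$, i.e.
$(1+\alpha+\theta)/(1+\alpha)$, which is exactly $\sigma^2/\mu$ from the
displayed moments. `blinar_moments()` keeps the two representations
consistent by construction, and the test suite asserts
`dispersion == variance/mean`.

The $k$-step conditional moments are closed-form
(`blinar_kstep_moments()`):
$$E[X_{t+k}\mid X_t] = \alpha^k X_t +
  \mu_\epsilon\frac{1-\alpha^k}{1-\alpha},\qquad
\mathrm{Var}[X_{t+k}\mid X_t] = \alpha^k(1-\alpha^k)X_t +
  \mu_\epsilon\frac{(\alpha-\alpha^k)(1-\alpha^k)}{1-\alpha^2} +
  \sigma^2_\epsilon\frac{1-\alpha^{2k}}{1-\alpha^2},$$
and converge to the stationary moments as $k\to\infty$; the tests check
$k=2$ against brute-force Chapman–Kolmogorov composition of truncated
transition matrices.

## Numerical design

**Bell numbers.** $B_z$ exceeds $2^{53}$ at $z = 23$ and double range near
$z \approx 250$, while observed counts can be large, so nothing in the
probability path ever forms $B_z/z!$ directly. Exact values come from the
addition-only Peirce triangle in small-limb big-integer arithmetic
(`bell_number()`, `bell_number_string()`); the production path for
probabilities is `log_bell_number()`, a log-sum-exp form of the binomial
recurrence $B_{n+1} = \sum_k \binom{n}{k} B_k$ whose terms are all
positive, hence cancellation-free. The two routes agree to $10^{-12}$
relative over the first 150 orders, and both are checked against
Dobinski's series $B_n = e^{-1}\sum_k k^n/k!$ evaluated independently in
log space.

**Transition probabilities and likelihood.** The one-step transition is a
binomial–Bell convolution
$P_{ij} = \sum_{m=0}^{\min(i,j)} \binom{j}{m}\alpha^m(1-\alpha)^{j-m}
P(\epsilon = i-m)$, accumulated with log-sum-exp. For likelihood
evaluation all $T-1$ transitions are laid out as $(T-1)\times(M+1)$
matrices over the thinning count $m$; the parameter-free parts
($\log\binom{x_t}{m}$, index matrices) are precomputed once per series, so
one evaluation reduces to vectorised matrix arithmetic plus a row-wise
log-sum-exp. This is what makes 1000-replicate Monte Carlo cells at
$T = 1000$ affordable (roughly 0.02–0.15 s per CML fit depending on the
count scale).

**Mean inversion.** The moment estimators recover $\theta$ from
$\theta e^\theta = \hat\mu(1-\hat\alpha)$ via the principal Lambert W
branch (from `pracma`) with one Newton polish step, giving round-trip
error below $10^{-10}\max(1,m)$.

**Truncations.** Infinite sums over the count support stop when a
geometric majorant on successive pmf ratios bounds the remaining tail mass
below $10^{-14}$; the stationary pmf (needed only for the optional
marginal term of `blinar_joint_loglik`) is a fixed-point iteration of the
truncated transition operator to sup-norm $10^{-12}$, on a state space
covering the mean plus twelve standard deviations.

## Estimation

**CLS** minimises $\sum_{t=2}^{T}(X_t - E[X_t\mid X_{t-1}])^2$ and has the
closed forms implemented verbatim (sums over $t = 2..T$, prefactor
$T-1$). **YW** equates the lag-1 sample autocorrelation (denominator
summed over all $T$ deviations) to $\alpha$ and the sample mean to $\mu$.
The two are asymptotically equivalent; the suite checks that
$\sqrt{T}\,|\hat\alpha_{CLS}-\hat\alpha_{YW}|$ shrinks along nested paths.

**CML** maximises the likelihood conditional on $X_1$,
$L(\alpha,\theta)=\sum_{t=1}^{T-1}\log P(X_{t+1}\mid X_t)$, by BFGS with
numerical derivatives on the unconstrained scale
$(\mathrm{logit}\,\alpha, \log\theta)$, initialised at the YW estimates
clipped to $[0.001, 0.999]$. Convergence uses a relative tolerance of
$10^{-10}$ with at most 200 iterations; non-convergence is a flag on the
returned fit, not an exception, so large replicate studies can account for
failures rather than die on them. Standard errors come from the observed
information (numerical Hessian) mapped back to the natural scale.

**Boundary policy.** On short series the moment estimators can produce
$\hat\alpha \notin (0,1)$; the raw value is reported with flag
`alpha_outside_unit` (clipping happens only when the value seeds the CML
optimiser), and $\hat\theta$ is `NA` with flag `theta_undefined` whenever
$\hat\mu(1-\hat\alpha) \le 0$, where $\theta e^\theta = m$ has no positive
solution.

**Asymptotics.** `cls_asymptotic_cov()` evaluates the limiting covariance
$\Sigma$ of $\sqrt{T}(\hat\alpha_{CLS}-\alpha, \hat\mu_{CLS}-\mu)$ from
estimating-equation theory: with $V = E[\nabla g\,\nabla g']$ and
$W = E[v\,\nabla g\,\nabla g']$ (where $g$ and $v$ are the conditional
mean and variance), $\Sigma_{(\alpha,\mu_\epsilon)} = V^{-1}WV^{-1}$,
then a Jacobian transform to $(\alpha,\mu)$. The third raw moment
$E[X^3]$ required by $W$ follows from the stationary moment recursion
with the Bell third cumulant $\kappa_3 = \theta(1+3\theta+\theta^2)
e^\theta$. We derived the whole matrix from first principles rather than
transcribing a printed display because the available rendering of the
published covariance conflates the third raw moment with the cube of the
mean; the derivation is validated in the suite against the sampling
covariance of 2000 replicate CLS fits at $T = 2000$, entrywise within
15%. `delta_theta_se()` then propagates to $\hat\theta = W(\mu(1-\alpha))$
by the delta method with $W'(x) = W/(x(1+W))$; simulated 95% intervals
cover the truth at the nominal rate.

## Diagnostics and model comparison

Pearson residuals standardise one-step prediction errors by the
conditional standard deviation; under the true model they are
approximately white with unit variance, which `ljung_box()` (a wrapper
around the standard portmanteau test, with a `fitdf` option for estimated
parameters) checks. Information criteria use $n = T-1$, the number of
conditional terms in $L$ — the conditional likelihood never sees the
first observation, so $T-1$ is the defensible sample size; since the
choice is isolated in `information_criteria()`, users preferring $n = T$
can recompute trivially. The sample variance everywhere uses the
$T-1$ denominator, the standard unbiased default.

The overdispersion screen is a **parametric bootstrap**: fit the
equidispersed Poisson-innovation INAR(1) null by CML, simulate $B$ null
paths of the observed length, and take the empirical $(1-\mathrm{level})$
quantile of their dispersion indices as the critical value. A closed-form
asymptotic critical value exists in the literature for this test, but a
formula-free bootstrap is exact under the fitted null up to Monte Carlo
error and slots behind the same interface; the default $B = 499$ keeps the
quantile stable at the 5% level.

Innovation families are pluggable (`inar_family()`): a family contributes
its log-pmf, moments, sampler, moment-based initialiser and an
unconstrained transform, and the shared CML engine does the rest. Bell,
Poisson and geometric (success-probability parameterisation on
$\{0,1,\dots\}$, pmf $\pi(1-\pi)^k$) ship with the package; families whose
pmfs involve further structure can be user-supplied. `compare_models()`
reports, per family, the CML estimates, AIC/BIC/CAIC/HQIC, the fitted
stationary mean $\mu_\epsilon/(1-\alpha)$ and variance
$(\sigma_\epsilon^2+\alpha\mu_\epsilon)/(1-\alpha^2)$ from each family's
own formulas, and the holdout RMSE. Forecasts are conditional means —
real-valued, not integer-coherent, which is the convention the RMSE
evaluation implies.

## The Monte Carlo harness and the synthetic generator

`run_sim_study()` crosses $(\alpha, \theta, T)$, simulates `reps`
stationary paths per cell, applies the requested estimators and tabulates
empirical means and MSEs. Design choices:

* **Initialisation:** each path starts from a Bell($\theta$) draw and
  discards a 500-step burn-in; ergodicity makes the retained path
  effectively stationary. A fixed-$x_0$, zero-burn-in mode supports exact
  conditional-law tests.
* **Seeding:** each cell derives its own seed from the master seed by a
  fixed integer recurrence, so cells are independent and any one cell can
  be recomputed alone with identical output (asserted in the tests).
* **Failures:** CML non-convergence and undefined $\hat\theta$ are
  dropped from that cell's summaries and counted per parameter; moment
  estimates of $\alpha$ are retained even when flagged out-of-unit, since
  the estimator itself is always defined.
* **Scale:** the study grid of interest is
  $\alpha \in \{0.25, 0.5, 0.75\}$, $\theta \in \{0.5, 1.5\}$,
  $T \in \{100, 250, 500, 1000\}$ at 1000 replicates per cell; the
  vectorised likelihood makes full-size cells run in minutes, and the
  bundled tests use 1000 replicates for the table-cell checks and smaller
  counts (60–500) for purely qualitative properties.

`qq_data()` standardises a vector of replicate estimates and pairs order
statistics with normal quantiles at plotting positions $(i-0.5)/n$ — data
export only; plotting is left to the user.

`make_fixture()` generates seeded demonstration series whose
$(\alpha,\theta)$ are solved by `uniroot` from target (mean, dispersion
index) pairs chosen to mimic published low-count monthly series: mean 1.6
with $I_x = 1.5$, and mean 4.9 with $I_x = 1.59$. These are synthetic
stand-ins — the generator reproduces the first two stationary moments and
the AR(1) dependence structure, but real series also carry seasonality,
covariate effects and non-stationarity that the model family does not
represent. Passing tests on generated data therefore demonstrate
correctness of the implementation under the model's own assumptions, not
adequacy of the model for any particular real dataset.

## Known limitations

* Estimation assumes a stationary path; trends or seasonal structure must
  be handled upstream.
* The CML engine's per-evaluation cost grows with the count scale
  (through the thinning-sum width $M$); series with counts in the
  hundreds are feasible but noticeably slower than low-count series.
* Only first-order autoregression is implemented; higher-order INAR(p)
  and alternative thinning operators are out of scope.
* The delta-method SE for $\theta$ relies on the CLS/YW asymptotic
  covariance and degrades near boundary estimates, where it is flagged
  rather than reported.
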