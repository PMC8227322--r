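# blinar — integer-valued autoregression with Bell innovations

`blinar` models **overdispersed count time series** — monthly incident
counts, case numbers, strike tallies — with the BL-INAR(1) process: a
first-order integer-valued autoregression built from the binomial thinning
operator with Bell-distributed innovations,

```
X_t = α ∘ X_{t-1} + ε_t,      ε_t ~ iid Bell(θ),   0 < α < 1, θ > 0,
```

where `α ∘ X = Σ_{i=1}^{X} ξ_i` with iid Bernoulli(α) counting variables
ξ_i. The Bell distribution has pmf

```
P(Z = z) = θ^z e^{-(e^θ - 1)} B_z / z!,     z = 0, 1, 2, ...
```

with `B_z` the Bell numbers. It has a single parameter, is infinitely
divisible (so the INAR construction is coherent), and is always
overdispersed: `Var/E = 1 + θ`. The stationary process has mean
`μ = θe^θ/(1-α)`, variance `σ² = θe^θ(1+α+θ)/(1-α²)`, autocorrelation
`ρ_k = α^k`, and dispersion index `I_x = 1 + θ/(1+α) > 1` — a Poisson-style
count model that accommodates extra-Poisson variability without adding a
second innovation parameter.

The package is aimed at analysts of low-count epidemiological and social
time series who need: simulation, exact transition/likelihood computations,
estimation (conditional least squares, Yule–Walker, conditional maximum
likelihood) with asymptotic standard errors, forecasting, adequacy
diagnostics, and model comparison against alternative innovation families.

## Worked example

A synthetic monthly series on the scale of low-count misconduct data
(T = 132, mean ≈ 1.5, overdispersed):

```r
library(blinar)
set.seed(2021)
x <- rblinar(132, alpha = 0.26, theta = 0.63)
c(mean = mean(x), var = var(x), I = dispersion_index(x))
#>     mean      var        I
#> 1.500000 2.358779 1.572519

fit <- fit_blinar(x, method = "cml", se = TRUE)
fit
#> INAR(1) fit [BL-INAR, CML]
#>   alpha = 0.192206  theta = 0.639858
#>   conditional loglik = -213.6637 on 131 transitions
#>   se: 0.07385 0.05171
```

The sample dispersion index 1.57 exceeds the parametric-bootstrap critical
value under an equidispersed Poisson-INAR(1) null (1.21 at the 5% level),
so a Poisson innovation model is rejected:

```r
overdispersion_test(x, B = 499, seed = 1)[c("index", "critical_value", "reject")]
#> $index          1.572519
#> $critical_value 1.206087
#> $reject         TRUE
```

Comparing innovation families by conditional maximum likelihood: the Bell
model attains the smallest AIC/BIC and its fitted stationary variance
(2.31) tracks the sample variance (2.36) far better than the equidispersed
Poisson fit (1.50):

```r
compare_models(x, list(bell_family(), poisson_family(), geometric_family()), h = 6)
#>     model        params alpha_hat   AIC   BIC fitted_mean fitted_variance  rmse
#> 1 BL-INAR  theta=0.6399    0.1922 431.3 437.1       1.502           2.308 1.096
#> 2  G-INAR     pi=0.4674    0.2411 433.8 439.5       1.501           2.880 1.089
#> 3  P-INAR lambda=1.2463    0.1704 441.6 447.3       1.502           1.502 1.098
```

Forecasts are the closed-form k-step conditional moments anchored at the
last observation; they relax toward the stationary mean as the horizon
grows:

```r
blinar_forecast(x, fit$alpha_hat, fit$theta_hat, h = 3)
#>   h     mean variance
#> 1 1 1.213305 1.989647
#> 2 2 1.446509 2.251532
#> 3 3 1.491332 2.297415
```

A command-line interface with `simulate`, `fit`, `forecast`, `compare`,
`simstudy` and `fixture` subcommands is installed at

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/blinar.R", package = "blinar"))')" fit --input series.txt --method cml --se
```

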