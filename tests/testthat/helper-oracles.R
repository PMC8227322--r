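# Independent oracles used across the suite.  Each deliberately takes a
# different computational route from the production code it checks.

# Dobinski's series in log space: ln B_n = ln( sum_k k^n / k! ) - 1.
# All terms positive, so log-sum-exp is cancellation-free; slow but simple.
dobinski_log_bell <- function(n, k_max = 5000) {
  vapply(n, function(nn) {
    k <- if (nn == 0) 0:k_max else 1:k_max
    terms <- nn * log(pmax(k, 1)) * (k > 0) - lgamma(k + 1)
    mx <- max(terms)
    mx + log(sum(exp(terms - mx))) - 1
  }, numeric(1))
}

# Bell pmf straight from Definition: theta^z e^{1 - e^theta} B_z / z!,
# on the probability scale with exact Bell numbers (valid for modest z).
bell_pmf_direct <- function(z, theta) {
  theta^z * exp(1 - exp(theta)) * bell_number(z) / factorial(z)
}

# One-step transition probability by direct probability-scale summation.
transition_direct <- function(i, j, alpha, theta) {
  m <- 0:min(i, j)
  sum(choose(j, m) * alpha^m * (1 - alpha)^(j - m) *
        bell_pmf_direct(i - m, theta))
}

# Truncated transition matrix P[i+1, j+1] = P(j -> i), for
# Chapman-Kolmogorov brute force.
transition_matrix_direct <- function(alpha, theta, M) {
  outer(0:M, 0:M, Vectorize(function(i, j) transition_direct(i, j, alpha, theta)))
}

# Grid + golden-refinement minimiser of the conditional least squares
# objective S(a) = sum_t (X_t - a X_{t-1} - c(a))^2 with the intercept
# profiled out, independent of the closed forms.
cls_grid_oracle <- function(x, lower = -2, upper = 2) {
  xt <- x[-1]; xl <- x[-length(x)]
  obj <- function(a) {
    cc <- mean(xt - a * xl)
    sum((xt - a * xl - cc)^2)
  }
  grid <- seq(lower, upper, length.out = 4001)
  a0 <- grid[which.min(vapply(grid, obj, numeric(1)))]
  stats::optimize(obj, c(a0 - 0.01, a0 + 0.01), tol = 1e-10)$minimum
}
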