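# The BL-INAR(1) process
#   X_t = alpha o X_{t-1} + eps_t,   eps_t ~ iid Bell(theta),
# where "o" is binomial thinning: alpha o X = sum of X iid Bernoulli(alpha).
# An ergodic stationary Markov chain on the non-negative integers whenever
# 0 < alpha < 1 and theta > 0.

.check_alpha <- function(alpha, open = TRUE) {
  if (!is.numeric(alpha) || length(alpha) != 1 || is.na(alpha))
    stop("'alpha' must be a single number", call. = FALSE)
  lo <- if (open) alpha <= 0 || alpha >= 1 else alpha < 0 || alpha > 1
  if (lo) stop("'alpha' must lie in ", if (open) "(0, 1)" else "[0, 1]",
               call. = FALSE)
  alpha
}

.check_counts <- function(x, min_len = 1) {
  if (!is.numeric(x) || length(x) < min_len)
    stop("count series must be numeric with at least ", min_len,
         " observations", call. = FALSE)
  if (any(is.na(x)) || any(x < 0) || any(x != floor(x)))
    stop("count series must contain non-negative integers", call. = FALSE)
  as.integer(x)
}

#' Binomial thinning operator
#'
#' Draws \eqn{\alpha \circ x = \sum_{i=1}^{x} \xi_i} with iid
#' \eqn{\xi_i \sim} Bernoulli\eqn{(\alpha)}, i.e. a Binomial\eqn{(x, \alpha)}
#' variate — the integer-valued counterpart of scalar multiplication in AR
#' models.  Vectorised over `x`; the boundary values \eqn{\alpha = 0, 1} are
#' accepted here (degenerate thinning).
#'
#' @param x vector of non-negative integer counts.
#' @param alpha retention probability in \eqn{[0, 1]}.
#' @return integer vector, elementwise \eqn{\le x}.
#' @examples
#' set.seed(1); rthin(c(0, 10, 50), 0.25)
#' @export
rthin <- function(x, alpha) {
  .check_alpha(alpha, open = FALSE)
  x <- .check_counts(x)
  stats::rbinom(length(x), x, alpha)
}

# innovation-generic INAR(1) path generator shared by rblinar and the
# bootstrap/diagnostic machinery
.sim_inar <- function(n, alpha, rinnov, burnin = 500, x0 = NULL) {
  if (n < 1) stop("'n' must be at least 1", call. = FALSE)
  total <- n + burnin
  eps <- rinnov(total)
  x <- integer(total)
  prev <- if (is.null(x0)) rinnov(1) else as.integer(x0)
  for (t in seq_len(total)) {
    prev <- stats::rbinom(1, prev, alpha) + eps[t]
    x[t] <- prev
  }
  x[(burnin + 1):total]
}

#' Simulate a BL-INAR(1) path
#'
#' Generates \eqn{X_t = \alpha \circ X_{t-1} + \epsilon_t} with iid
#' Bell\eqn{(\theta)} innovations.  By default the chain starts from a single
#' Bell draw and `burnin` initial steps are discarded so the retained path is
#' approximately stationary (the chain is ergodic); supplying `x0` with
#' `burnin = 0` gives the exact conditional law given \eqn{X_0 = x_0}.
#'
#' @param n length of the returned series.
#' @param alpha thinning probability in (0, 1).
#' @param theta Bell innovation parameter, positive.
#' @param burnin number of initial steps to discard (default 500).
#' @param x0 optional fixed initial count.
#' @return integer vector of length `n`.
#' @examples
#' set.seed(42)
#' x <- rblinar(500, alpha = 0.5, theta = 1.5)
#' mean(x)   # near theta * exp(theta) / (1 - alpha)
#' @export
rblinar <- function(n, alpha, theta, burnin = 500, x0 = NULL) {
  .check_alpha(alpha); .check_theta(theta)
  if (burnin < 0) stop("'burnin' must be non-negative", call. = FALSE)
  .sim_inar(n, alpha, function(m) rbell(m, theta), burnin = burnin, x0 = x0)
}

#' One-step transition probabilities
#'
#' \eqn{P(X_t = i \mid X_{t-1} = j) = \sum_{m=0}^{\min(i,j)} \binom{j}{m}
#' \alpha^m (1-\alpha)^{j-m}\, P(\epsilon = i - m)}, the convolution of the
#' binomial survivor count with the Bell innovation.  Accumulation is done in
#' log space with log-sum-exp.  Vectorised over `i` (with `j` recycled).
#'
#' @param i next state(s), non-negative integers.
#' @param j current state(s), non-negative integers.
#' @inheritParams rblinar
#' @param log logical; return log probability?
#' @return numeric vector of transition probabilities.
#' @examples
#' sum(blinar_transition(0:60, j = 5, alpha = 0.5, theta = 0.5))  # 1
#' @export
blinar_transition <- function(i, j, alpha, theta, log = FALSE) {
  .check_alpha(alpha); .check_theta(theta)
  i <- .check_counts(i); j <- .check_counts(j)
  n <- max(length(i), length(j))
  i <- rep_len(i, n); j <- rep_len(j, n)
  out <- vapply(seq_len(n), function(t) {
    m <- 0:min(i[t], j[t])
    terms <- stats::dbinom(m, j[t], alpha, log = TRUE) +
      dbell(i[t] - m, theta, log = TRUE)
    mx <- max(terms)
    mx + log(sum(exp(terms - mx)))
  }, numeric(1))
  if (log) out else exp(out)
}

#' Joint log probability of an observed path
#'
#' With `initial = "conditional"` (the default, and the form the conditional
#' maximum likelihood estimator maximises) returns
#' \eqn{\sum_{t=1}^{T-1} \ln P(X_{t+1} \mid X_t)}.  With
#' `initial = "stationary"` the marginal \eqn{\ln P(X_1)} is added, where the
#' stationary pmf — which has no closed form — is obtained by fixed-point
#' iteration of the truncated transition operator to within \eqn{10^{-12}}.
#'
#' @param x observed count series, length at least 2.
#' @inheritParams rblinar
#' @param initial `"conditional"` or `"stationary"`.
#' @return a single finite negative number.
#' @export
blinar_joint_loglik <- function(x, alpha, theta,
                                initial = c("conditional", "stationary")) {
  initial <- match.arg(initial)
  x <- .check_counts(x, min_len = 2)
  ll <- conditional_loglik(x, alpha, theta)
  if (initial == "stationary") {
    pmf <- blinar_stationary_pmf(alpha, theta)
    p1 <- if (x[1] < length(pmf)) pmf[x[1] + 1] else 0
    ll <- ll + log(max(p1, .Machine$double.xmin))
  }
  ll
}

#' Stationary pmf by fixed-point iteration
#'
#' Iterates the transition operator on a truncated state space until
#' successive distributions differ by less than `tol` in sup norm.  The
#' truncation point covers the stationary mean plus twelve standard
#' deviations.
#'
#' @inheritParams rblinar
#' @param tol sup-norm convergence tolerance.
#' @return numeric vector, the stationary pmf over `0:(length - 1)`.
#' @export
blinar_stationary_pmf <- function(alpha, theta, tol = 1e-12) {
  mo <- blinar_moments(alpha, theta)
  M <- ceiling(mo$mean + 12 * sqrt(mo$variance)) + 20
  P <- vapply(0:M, function(j) blinar_transition(0:M, j, alpha, theta),
              numeric(M + 1))           # P[i+1, j+1] = P(j -> i)
  p <- dbell(0:M, theta)
  p <- p / sum(p)
  for (iter in 1:5000) {
    p_new <- as.vector(P %*% p)
    p_new <- p_new / sum(p_new)
    if (max(abs(p_new - p)) < tol) return(p_new)
    p <- p_new
  }
  warning("stationary pmf iteration did not fully converge")
  p
}

#' Stationary moments of the BL-INAR(1) process
#'
#' Closed-form mean \eqn{\mu = \theta e^\theta/(1-\alpha)}, variance
#' \eqn{\sigma^2 = \theta e^\theta (1+\alpha+\theta)/(1-\alpha^2)},
#' autocovariances \eqn{\gamma_k = \alpha^k \sigma^2}, autocorrelations
#' \eqn{\rho_k = \alpha^k} and dispersion index
#' \eqn{I_x = \sigma^2/\mu = 1 + \theta/(1+\alpha) > 1}: the process is
#' always overdispersed.
#'
#' @inheritParams rblinar
#' @param max_lag largest autocovariance lag to report.
#' @return object of class `blinar_moments`: list with `mean`, `variance`,
#'   `autocov`, `autocorr` (named by lag), `dispersion`.
#' @examples
#' blinar_moments(0.25, 0.5)$dispersion   # 1.75/1.25 = 1.4
#' @export
blinar_moments <- function(alpha, theta, max_lag = 5) {
  .check_alpha(alpha); .check_theta(theta)
  mu_eps <- theta * exp(theta)
  mu <- mu_eps / (1 - alpha)
  sig2 <- mu_eps * (1 + alpha + theta) / (1 - alpha^2)
  k <- seq_len(max_lag)
  structure(list(mean = mu, variance = sig2,
                 autocov = stats::setNames(alpha^k * sig2, k),
                 autocorr = stats::setNames(alpha^k, k),
                 dispersion = 1 + theta / (1 + alpha)),
            class = "blinar_moments")
}

#' @export
print.blinar_moments <- function(x, ...) {
  cat("BL-INAR(1) stationary moments\n")
  cat(sprintf("  mean %.6g  variance %.6g  dispersion index %.6g\n",
              x$mean, x$variance, x$dispersion))
  cat("  autocorrelation:", sprintf("%.4g", x$autocorr), "\n")
  invisible(x)
}

#' Conditional and multi-step conditional moments
#'
#' `blinar_cond_moments()` gives the one-step conditional mean
#' \eqn{\alpha x + \theta e^\theta} and variance
#' \eqn{\alpha(1-\alpha)x + \theta(1+\theta)e^\theta} given
#' \eqn{X_{t-1} = x}.  `blinar_kstep_moments()` gives the \eqn{k}-step-ahead
#' versions
#' \deqn{E[X_{t+k} \mid X_t] = \alpha^k X_t + \mu_\epsilon
#'   \frac{1-\alpha^k}{1-\alpha},}
#' \deqn{Var[X_{t+k} \mid X_t] = \alpha^k(1-\alpha^k) X_t + \mu_\epsilon
#'   \frac{(\alpha-\alpha^k)(1-\alpha^k)}{1-\alpha^2} + \sigma^2_\epsilon
#'   \frac{1-\alpha^{2k}}{1-\alpha^2},}
#' which converge to the stationary mean and variance as
#' \eqn{k \to \infty}.
#'
#' @param x_prev,x_t conditioning count(s).
#' @param k forecast horizon(s), positive integers.
#' @inheritParams rblinar
#' @return list with numeric components `mean` and `variance` (vectorised
#'   over the conditioning value and `k`).
#' @export
blinar_cond_moments <- function(x_prev, alpha, theta) {
  blinar_kstep_moments(x_prev, 1, alpha, theta)
}

#' @rdname blinar_cond_moments
#' @export
blinar_kstep_moments <- function(x_t, k, alpha, theta) {
  .check_alpha(alpha); .check_theta(theta)
  x_t <- .check_counts(x_t)
  if (any(k < 1) || any(k != floor(k))) stop("'k' must be a positive integer")
  mu_eps <- theta * exp(theta)
  sig2_eps <- theta * (1 + theta) * exp(theta)
  ak <- alpha^k
  list(mean = ak * x_t + mu_eps * (1 - ak) / (1 - alpha),
       variance = ak * (1 - ak) * x_t +
         mu_eps * (alpha - ak) * (1 - ak) / (1 - alpha^2) +
         sig2_eps * (1 - alpha^(2 * k)) / (1 - alpha^2))
}

#' Read or write a count series
#'
#' Plain-text interchange: one non-negative integer per line (single-column
#' CSV or whitespace-delimited); a single leading non-numeric line is treated
#' as a header and skipped.
#'
#' @param path file path.
#' @param x count series to write.
#' @return `read_counts()`: integer vector; `write_counts()`: `path`,
#'   invisibly.
#' @export
read_counts <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) stop("no data in ", path, call. = FALSE)
  vals <- suppressWarnings(as.numeric(lines))
  if (is.na(vals[1]) && length(lines) > 1) {   # header line
    lines <- lines[-1]
    vals <- suppressWarnings(as.numeric(lines))
  }
  if (any(is.na(vals)))
    stop("non-numeric entries in ", path, call. = FALSE)
  .check_counts(vals)
}

#' @rdname read_counts
#' @export
write_counts <- function(x, path) {
  x <- .check_counts(x)
  writeLines(as.character(x), path)
  invisible(path)
}
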