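# Parameter estimation for the BL-INAR(1) model: conditional least squares
# (closed form), Yule-Walker (moment matching on rho_1 and the mean), and
# conditional maximum likelihood (BFGS on the conditional likelihood).
# Asymptotic theory: the CLS sandwich covariance and delta-method standard
# errors for theta.

#' Fit a BL-INAR(1) model
#'
#' Estimates \eqn{(\alpha, \theta)} from an observed count series.
#'
#' * **CLS** minimises \eqn{\sum_{t=2}^{T} (X_t - E[X_t \mid X_{t-1}])^2};
#'   \eqn{\hat\alpha} and the process-mean estimate \eqn{\hat\mu} have closed
#'   forms, and \eqn{\hat\theta} solves
#'   \eqn{\theta e^\theta = \hat\mu(1-\hat\alpha)} by Lambert W.
#' * **YW** sets \eqn{\hat\alpha} to the lag-1 sample autocorrelation and
#'   \eqn{\hat\mu} to the sample mean; \eqn{\hat\theta} as above.  CLS and
#'   YW are asymptotically equivalent for this process.
#' * **CML** maximises the likelihood conditional on \eqn{X_1} by BFGS with
#'   numerical derivatives on \eqn{(logit\,\alpha, \ln\theta)}, initialised
#'   at the YW estimates clipped to \eqn{[0.001, 0.999]}.
#'
#' Moment estimates of \eqn{\alpha} can fall outside \eqn{(0,1)} on short
#' series; the raw value is reported and flagged (`alpha_outside_unit`), and
#' \eqn{\hat\theta} is left `NA` with flag `theta_undefined` whenever
#' \eqn{\hat\mu(1-\hat\alpha) \le 0}.
#'
#' @param x count series (non-negative integers), length at least 3.
#' @param method `"cml"` (default), `"cls"` or `"yw"`.
#' @param se logical; attach asymptotic standard errors (sandwich covariance
#'   for CLS/YW, observed information for CML)?
#' @param init optional starting values for CML, a list with `alpha`, `theta`.
#' @return object of class `blinar_fit` with components `method`,
#'   `alpha_hat`, `theta_hat`, `mu_hat`, `loglik` (CML), `cov`/`se` (if
#'   requested), `converged`, `n_used`, `flags`.
#' @examples
#' set.seed(11)
#' x <- rblinar(500, alpha = 0.5, theta = 0.5)
#' fit_blinar(x, "cls")
#' fit_blinar(x, "cml")
#' @export
fit_blinar <- function(x, method = c("cml", "cls", "yw"), se = FALSE,
                       init = NULL) {
  method <- match.arg(method)
  x <- .check_counts(x, min_len = 3)
  if (stats::var(x) == 0)
    stop("degenerate (constant) series: estimators are undefined",
         call. = FALSE)
  switch(method,
         cls = .fit_cls(x, se = se),
         yw = .fit_yw(x, se = se),
         cml = .fit_cml(x, se = se, init = init))
}

.moment_fit_result <- function(method, x, alpha_hat, mu_hat, se = FALSE) {
  flags <- character(0)
  if (alpha_hat <= 0 || alpha_hat >= 1) flags <- c(flags, "alpha_outside_unit")
  prod <- mu_hat * (1 - alpha_hat)
  if (prod > 0) theta_hat <- theta_from_mean(prod)
  else { theta_hat <- NA_real_; flags <- c(flags, "theta_undefined") }
  fit <- structure(list(method = method, family = "BL-INAR",
                        alpha_hat = alpha_hat, theta_hat = theta_hat,
                        mu_hat = mu_hat, loglik = NA_real_, converged = TRUE,
                        n_used = length(x) - 1L, flags = flags),
                   class = "blinar_fit")
  if (se && !is.na(theta_hat) && alpha_hat > 0 && alpha_hat < 1) {
    ac <- cls_asymptotic_cov(alpha_hat, theta_hat)
    fit$cov <- ac$sigma / length(x)
    fit$se <- c(alpha = sqrt(fit$cov[1, 1]),
                theta = delta_theta_se(fit, ac, n = length(x)))
  }
  fit
}

.fit_cls <- function(x, se = FALSE) {
  T_ <- length(x)
  xt <- x[-1]; xl <- x[-T_]                        # t = 2..T and lagged
  n <- T_ - 1
  denom <- n * sum(xl^2) - sum(xl)^2
  if (denom == 0)
    stop("degenerate series: CLS denominator is zero", call. = FALSE)
  alpha_hat <- (n * sum(xt * xl) - sum(xt) * sum(xl)) / denom
  mu_hat <- (sum(xt) - alpha_hat * sum(xl)) / (n * (1 - alpha_hat))
  .moment_fit_result("CLS", x, alpha_hat, mu_hat, se = se)
}

.fit_yw <- function(x, se = FALSE) {
  xbar <- mean(x)
  d <- x - xbar
  denom <- sum(d^2)
  alpha_hat <- sum(d[-length(x)] * d[-1]) / denom
  .moment_fit_result("YW", x, alpha_hat, xbar, se = se)
}

.fit_cml <- function(x, se = FALSE, init = NULL) {
  init2 <- if (!is.null(init)) list(alpha = init$alpha, par = init$theta)
  fit <- fit_inar(x, bell_family(), init = init2, se = se)
  fit$theta_hat <- unname(fit$par[["theta"]])
  if (!is.null(fit$se)) names(fit$se) <- c("alpha", "theta")
  fit
}

#' Asymptotic covariance of the CLS estimator
#'
#' Sampling covariance \eqn{\Sigma} in
#' \eqn{\sqrt{T}(\hat\alpha_{CLS}-\alpha, \hat\mu_{CLS}-\mu)' \to N(0, \Sigma)},
#' from estimating-equation (Klimko–Nelson/Tjøstheim) theory: with
#' conditional mean \eqn{g = \alpha X_{t-1} + \mu_\epsilon} and conditional
#' variance \eqn{v = \alpha(1-\alpha)X_{t-1} + \sigma^2_\epsilon}, the
#' \eqn{(\alpha, \mu_\epsilon)} covariance is
#' \eqn{V^{-1} W V^{-1}} with \eqn{V = E[\nabla g \nabla g']} and
#' \eqn{W = E[v\, \nabla g \nabla g']}, then transformed to
#' \eqn{(\alpha, \mu)} through \eqn{\mu = \mu_\epsilon/(1-\alpha)}.  The
#' third raw moment \eqn{\mu_3 = E[X_t^3]} enters \eqn{W} and is computed
#' from the exact stationary moment recursion using the Bell cumulant
#' \eqn{\kappa_3 = \theta(1+3\theta+\theta^2)e^\theta}.
#'
#' @inheritParams rblinar
#' @return list of class `blinar_asymcov` with `sigma` (symmetric 2x2,
#'   rows/cols `alpha`, `mu`) and `mu3` (third raw moment of \eqn{X_t}).
#' @examples
#' cls_asymptotic_cov(0.25, 0.5)
#' @export
cls_asymptotic_cov <- function(alpha, theta) {
  .check_alpha(alpha); .check_theta(theta)
  kap <- .bell_cumulants(theta)
  mu_eps <- kap[["k1"]]; sig2_eps <- kap[["k2"]]
  me2 <- sig2_eps + mu_eps^2
  me3 <- kap[["k3"]] + 3 * mu_eps * sig2_eps + mu_eps^3
  mo <- blinar_moments(alpha, theta)
  mu <- mo$mean; sig2 <- mo$variance
  m2 <- sig2 + mu^2
  # E[X^3] from X = alpha o Y + eps, Y stationary:
  # E[(a o Y)^p] via binomial raw moments with random trial count Y
  mu3 <- (alpha * (1 - alpha) * (1 - 2 * alpha) * mu +
            3 * alpha^2 * (1 - alpha) * m2 +
            3 * (alpha * (1 - alpha) * mu + alpha^2 * m2) * mu_eps +
            3 * alpha * mu * me2 + me3) / (1 - alpha^3)
  V <- matrix(c(m2, mu, mu, 1), 2)
  W <- matrix(c(alpha * (1 - alpha) * mu3 + sig2_eps * m2,
                alpha * (1 - alpha) * m2 + sig2_eps * mu,
                alpha * (1 - alpha) * m2 + sig2_eps * mu,
                alpha * (1 - alpha) * mu + sig2_eps), 2)
  Vinv <- solve(V)
  S_ame <- Vinv %*% W %*% Vinv                     # (alpha, mu_eps) scale
  J <- matrix(c(1, mu / (1 - alpha), 0, 1 / (1 - alpha)), 2)
  sigma <- J %*% S_ame %*% t(J)
  dimnames(sigma) <- list(c("alpha", "mu"), c("alpha", "mu"))
  structure(list(sigma = (sigma + t(sigma)) / 2, mu3 = mu3),
            class = "blinar_asymcov")
}

#' @export
print.blinar_asymcov <- function(x, ...) {
  cat("CLS asymptotic covariance (per sqrt(T) scaling)\n")
  print(round(x$sigma, 6))
  cat(sprintf("third raw moment E[X^3] = %.6g\n", x$mu3))
  invisible(x)
}

#' Delta-method standard error for theta
#'
#' Propagates the CLS/YW asymptotic covariance of
#' \eqn{(\hat\alpha, \hat\mu)} to \eqn{\hat\theta = W(\hat\mu(1-\hat\alpha))}
#' (Lambert W), using \eqn{W'(x) = W(x)/(x(1+W(x)))}: the gradient is
#' \eqn{(-\hat\mu W', (1-\hat\alpha) W')}.
#'
#' @param fit a `blinar_fit` from a moment method, with `alpha_hat`,
#'   `mu_hat`.
#' @param asymcov a [cls_asymptotic_cov()] result (evaluated at the
#'   estimates if omitted).
#' @param n series length used for the \eqn{1/\sqrt{T}} scaling.
#' @return standard error of \eqn{\hat\theta}, a single number (`NA` with a
#'   warning at boundary estimates).
#' @export
delta_theta_se <- function(fit, asymcov = NULL, n = fit$n_used + 1L) {
  a <- fit$alpha_hat; mu <- fit$mu_hat
  xw <- mu * (1 - a)
  if (is.na(fit$theta_hat) || xw <= 0 || a <= 0 || a >= 1) {
    warning("boundary estimates: delta-method SE undefined")
    return(NA_real_)
  }
  if (is.null(asymcov)) asymcov <- cls_asymptotic_cov(a, fit$theta_hat)
  w <- fit$theta_hat                      # W(xw) by definition of theta_hat
  wprime <- w / (xw * (1 + w))
  grad <- c(-mu * wprime, (1 - a) * wprime)
  sqrt(drop(t(grad) %*% asymcov$sigma %*% grad) / n)
}
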