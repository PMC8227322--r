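# Model adequacy and model comparison: information criteria, Pearson
# residuals, Ljung-Box whiteness, dispersion-index screening with a
# parametric-bootstrap overdispersion test, multi-step forecasting, holdout
# RMSE, and a comparison table across innovation families.

#' Information criteria from a conditional log-likelihood
#'
#' AIC \eqn{= -2L + 2k}, BIC \eqn{= -2L + k\ln n}, CAIC
#' \eqn{= -2L + k(\ln n + 1)}, HQIC \eqn{= -2L + 2k\ln\ln n}.  For INAR(1)
#' conditional likelihoods the natural sample size is the number of
#' transitions, \eqn{n = T - 1}.
#'
#' @param loglik maximised log-likelihood \eqn{L}.
#' @param n_params number of free parameters \eqn{k}.
#' @param n_obs effective sample size \eqn{n} (at least 2).
#' @return named numeric vector `c(AIC, BIC, CAIC, HQIC)`.
#' @examples
#' information_criteria(-100, 2, 100)   # AIC 204, ...
#' @export
information_criteria <- function(loglik, n_params, n_obs) {
  if (n_obs < 2) stop("'n_obs' must be at least 2", call. = FALSE)
  if (n_params < 1) stop("'n_params' must be at least 1", call. = FALSE)
  m2l <- -2 * loglik
  c(AIC = m2l + 2 * n_params,
    BIC = m2l + n_params * log(n_obs),
    CAIC = m2l + n_params * (log(n_obs) + 1),
    HQIC = m2l + 2 * n_params * log(log(n_obs)))
}

#' Pearson residuals of a fitted BL-INAR(1) model
#'
#' One-step prediction errors standardised by the conditional standard
#' deviation, \eqn{r_t = (X_t - \hat E[X_t \mid X_{t-1}]) /
#' \sqrt{\widehat{Var}[X_t \mid X_{t-1}]}} for \eqn{t = 2, \dots, T}.  Under
#' a correctly specified model they are approximately white with mean 0 and
#' variance 1.
#'
#' @inheritParams blinar_joint_loglik
#' @return numeric vector of length \eqn{T - 1}.
#' @export
pearson_residuals <- function(x, alpha, theta) {
  x <- .check_counts(x, min_len = 2)
  cm <- blinar_cond_moments(x[-length(x)], alpha, theta)
  (x[-1] - cm$mean) / sqrt(cm$variance)
}

#' Ljung-Box test for residual autocorrelation
#'
#' Portmanteau statistic \eqn{Q = n(n+2)\sum_{k=1}^{lags}
#' \hat\rho_k^2/(n-k)} with a \eqn{\chi^2} reference on `lags - fitdf`
#' degrees of freedom (set `fitdf` to the number of estimated parameters
#' when testing residuals of a fitted model).
#'
#' @param x numeric vector (a residual or count series).
#' @param lags number of autocorrelation lags pooled into the statistic.
#' @param fitdf degrees-of-freedom correction, default 0.
#' @return list with `statistic`, `p_value`, `lags`, `fitdf`.
#' @export
ljung_box <- function(x, lags = 10, fitdf = 0) {
  if (lags < 1 || length(x) <= lags)
    stop("need 'lags' >= 1 and more observations than lags", call. = FALSE)
  if (stats::sd(x) == 0) stop("degenerate input", call. = FALSE)
  bt <- stats::Box.test(x, lag = lags, type = "Ljung-Box", fitdf = fitdf)
  list(statistic = unname(bt$statistic), p_value = unname(bt$p.value),
       lags = lags, fitdf = fitdf)
}

#' Sample dispersion index
#'
#' \eqn{\hat I_x = S_X^2/\bar X} with the \eqn{T-1}-denominator sample
#' variance.  Values above 1 indicate overdispersion relative to Poisson;
#' the BL-INAR(1) stationary value is \eqn{1 + \theta/(1+\alpha)}.
#'
#' @param x count series with positive mean.
#' @return a single number.
#' @examples
#' dispersion_index(c(0, 2, 0, 2))   # 4/3
#' @export
dispersion_index <- function(x) {
  x <- .check_counts(x, min_len = 2)
  if (mean(x) == 0) stop("zero-mean series: dispersion index undefined",
                         call. = FALSE)
  stats::var(x) / mean(x)
}

#' Parametric-bootstrap overdispersion test
#'
#' Screens for overdispersion beyond an equidispersed Poisson-innovation
#' INAR(1): the null model is fitted by conditional maximum likelihood, `B`
#' paths of the observed length are simulated from it, and the
#' \eqn{(1-level)} empirical quantile of their dispersion indices is the
#' critical value against which the observed index is compared.
#'
#' @param x observed count series, length at least 30.
#' @param B number of bootstrap replicates (at least 199).
#' @param level nominal test size.
#' @param seed optional integer seed for the bootstrap.
#' @return list with `index`, `critical_value`, `reject`, `level`, `B`, and
#'   the fitted null parameters `alpha_hat`, `lambda_hat`.
#' @export
overdispersion_test <- function(x, B = 499, level = 0.05, seed = NULL) {
  x <- .check_counts(x, min_len = 30)
  if (B < 199) stop("'B' must be at least 199", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  null_fit <- fit_inar(x, poisson_family())
  a <- null_fit$alpha_hat; lam <- unname(null_fit$par[["lambda"]])
  idx <- vapply(seq_len(B), function(b) {
    dispersion_index(.sim_inar(length(x), a, function(m) stats::rpois(m, lam),
                               burnin = 200))
  }, numeric(1))
  crit <- unname(stats::quantile(idx, 1 - level, type = 7))
  obs <- dispersion_index(x)
  list(index = obs, critical_value = crit, reject = obs > crit,
       level = level, B = B, alpha_hat = a, lambda_hat = lam)
}

#' h-step-ahead forecasts
#'
#' Conditional mean and variance of \eqn{X_{T+k}} given the last
#' observation, for \eqn{k = 1, \dots, h}, from the closed-form multi-step
#' conditional moments.  The point forecast is the (real-valued) conditional
#' mean; as \eqn{h} grows both moments approach their stationary values.
#'
#' @param x observed count series (forecasts are anchored at its last value).
#' @inheritParams rblinar
#' @param h forecast horizon.
#' @return data frame with columns `h`, `mean`, `variance`.
#' @export
blinar_forecast <- function(x, alpha, theta, h = 6) {
  x <- .check_counts(x, min_len = 1)
  if (h < 1) stop("'h' must be at least 1", call. = FALSE)
  k <- seq_len(h)
  km <- blinar_kstep_moments(x[length(x)], k, alpha, theta)
  data.frame(h = k, mean = km$mean, variance = km$variance)
}

# forecast means for a general innovation family (used by rmse_holdout):
# E[X_{t+k} | X_t] = a^k X_t + mu_eps (1 - a^k)/(1 - a) holds for any INAR(1)
.inar_forecast_mean <- function(x_last, k, alpha, mu_eps) {
  alpha^k * x_last + mu_eps * (1 - alpha^k) / (1 - alpha)
}

#' Holdout forecast RMSE
#'
#' Fits the INAR(1) model with innovations from `family` by conditional
#' maximum likelihood on the first \eqn{T-h} observations, forecasts the
#' last \eqn{h} by the conditional mean anchored at observation \eqn{T-h},
#' and returns \eqn{\sqrt{\frac{1}{h}\sum_{k=1}^{h}(X_{T-h+k} -
#' \hat X_{T-h+k})^2}}.
#'
#' @param x count series with \eqn{T > h}.
#' @param family an [inar_family()]; default Bell.
#' @param h holdout length, default 6.
#' @return list with `rmse`, `fit`, `forecasts`, `actuals`.
#' @export
rmse_holdout <- function(x, family = bell_family(), h = 6) {
  x <- .check_counts(x, min_len = 2)
  if (h < 1 || h >= length(x)) stop("need T > h >= 1", call. = FALSE)
  train <- x[seq_len(length(x) - h)]
  fit <- fit_inar(train, family)
  mu_eps <- family$mean(fit$par)
  fc <- .inar_forecast_mean(train[length(train)], seq_len(h),
                            fit$alpha_hat, mu_eps)
  actual <- x[(length(x) - h + 1):length(x)]
  list(rmse = sqrt(mean((actual - fc)^2)), fit = fit,
       forecasts = fc, actuals = actual)
}

#' Compare INAR(1) innovation families on one series
#'
#' Fits each family by conditional maximum likelihood and tabulates the
#' four information criteria (on \eqn{n = T - 1} transitions), the fitted
#' stationary mean \eqn{\mu_\epsilon/(1-\alpha)} and variance
#' \eqn{(\sigma^2_\epsilon + \alpha\mu_\epsilon)/(1-\alpha^2)} from each
#' family's own formulas, and the holdout forecast RMSE.  Rows are ranked by
#' AIC; per-family failures are recorded in the row and the comparison
#' continues.
#'
#' @param x count series.
#' @param families list of [inar_family()] objects.
#' @param h holdout length for the RMSE column (`NA` to skip).
#' @return data frame of class `inar_comparison`, one row per family with
#'   columns `model`, `params`, `alpha_hat`, `loglik`, `AIC`, `BIC`, `CAIC`,
#'   `HQIC`, `fitted_mean`, `fitted_variance`, `rmse`, `converged`.
#' @examples
#' set.seed(3)
#' x <- rblinar(200, 0.5, 1.5)
#' compare_models(x, list(bell_family(), poisson_family()))
#' @export
compare_models <- function(x, families = list(bell_family(), poisson_family(),
                                              geometric_family()),
                           h = 6) {
  x <- .check_counts(x, min_len = 3)
  stopifnot(length(families) >= 1)
  rows <- lapply(families, function(fam) {
    out <- tryCatch({
      fit <- fit_inar(x, fam)
      ic <- information_criteria(fit$loglik, fam$n_params + 1, fit$n_used)
      mu_eps <- fam$mean(fit$par); v_eps <- fam$variance(fit$par)
      rmse <- if (!is.na(h))
        tryCatch(rmse_holdout(x, fam, h)$rmse, error = function(e) NA_real_)
      else NA_real_
      data.frame(model = fam$name,
                 params = paste(sprintf("%s=%.4f", names(fit$par), fit$par),
                                collapse = ", "),
                 alpha_hat = fit$alpha_hat, loglik = fit$loglik,
                 AIC = ic[["AIC"]], BIC = ic[["BIC"]], CAIC = ic[["CAIC"]],
                 HQIC = ic[["HQIC"]],
                 fitted_mean = mu_eps / (1 - fit$alpha_hat),
                 fitted_variance = (v_eps + fit$alpha_hat * mu_eps) /
                   (1 - fit$alpha_hat^2),
                 rmse = rmse, converged = fit$converged,
                 stringsAsFactors = FALSE)
    }, error = function(e)
      data.frame(model = fam$name, params = NA_character_,
                 alpha_hat = NA_real_, loglik = NA_real_, AIC = NA_real_,
                 BIC = NA_real_, CAIC = NA_real_, HQIC = NA_real_,
                 fitted_mean = NA_real_, fitted_variance = NA_real_,
                 rmse = NA_real_, converged = FALSE,
                 stringsAsFactors = FALSE))
    out
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$AIC), ]
  rownames(tab) <- NULL
  class(tab) <- c("inar_comparison", "data.frame")
  tab
}
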