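# CLS, Yule-Walker and CML estimation, asymptotic covariance, delta-method
# standard errors.

test_that("closed-form CLS equals the profiled grid-search minimiser", {
  toy <- c(1, 2, 1, 2, 1, 2)
  expect_equal(fit_blinar(toy, "cls")$alpha_hat, cls_grid_oracle(toy),
               tolerance = 1e-6)
  set.seed(5)
  for (i in 1:5) {
    x <- rblinar(40, 0.5, 0.8)
    if (stats::var(x) == 0 || stats::var(x[-length(x)]) == 0) next
    expect_equal(fit_blinar(x, "cls")$alpha_hat, cls_grid_oracle(x),
                 tolerance = 1e-6)
  }
  expect_error(fit_blinar(rep(2L, 10), "cls"), "degenerate")
})

test_that("Yule-Walker reproduces the hand-computed lag-1 autocorrelation", {
  # x = (0,1,0,1,0): numerator 4 * (-0.24), denominator 1.2
  fit <- fit_blinar(c(0, 1, 0, 1, 0), "yw")
  expect_equal(fit$alpha_hat, -0.8, tolerance = 1e-12)
  expect_true("alpha_outside_unit" %in% fit$flags)
  expect_equal(fit$mu_hat, 0.4, tolerance = 1e-12)
  # mu_hat (1 - alpha_hat) = 0.72 > 0, so theta is still recoverable here
  expect_equal(fit$theta_hat, theta_from_mean(0.72), tolerance = 1e-12)
  # but theta is undefined (and flagged) when mu_hat (1 - alpha_hat) <= 0
  fit2 <- blinar:::.moment_fit_result("CLS", 0:9, alpha_hat = 1.2,
                                      mu_hat = 2)
  expect_true(is.na(fit2$theta_hat))
  expect_true(all(c("alpha_outside_unit", "theta_undefined") %in% fit2$flags))
})

test_that("moment estimators are consistent on long single paths", {
  set.seed(21)
  x <- rblinar(5000, 0.5, 0.5)
  f <- fit_blinar(x, "cls")
  expect_lt(abs(f$alpha_hat - 0.5), 0.05)
  expect_lt(abs(f$theta_hat - 0.5), 0.05)
  set.seed(22)
  y <- rblinar(5000, 0.75, 1.5)
  g <- fit_blinar(y, "yw")
  expect_lt(abs(g$alpha_hat - 0.75), 0.05)
  expect_lt(abs(g$theta_hat - 1.5), 0.1)
})

test_that("CLS and YW coincide asymptotically on nested paths", {
  set.seed(31)
  x <- rblinar(10000, 0.5, 0.5)
  gap <- vapply(c(100, 1000, 10000), function(T_) {
    d <- abs(fit_blinar(x[1:T_], "cls")$alpha_hat -
               fit_blinar(x[1:T_], "yw")$alpha_hat)
    d * sqrt(T_)
  }, numeric(1))
  expect_true(all(diff(gap) < 0))
  expect_lt(gap[3], gap[1] / 3)
})

test_that("conditional log-likelihood is the sum of transition log terms", {
  set.seed(41)
  x <- rblinar(20, 0.4, 0.9)
  direct <- sum(blinar_transition(x[-1], x[-20], 0.4, 0.9, log = TRUE))
  expect_equal(conditional_loglik(x, 0.4, 0.9), direct, tolerance = 1e-12)
  expect_equal(blinar_joint_loglik(x, 0.4, 0.9),
               conditional_loglik(x, 0.4, 0.9), tolerance = 1e-12)
})

test_that("CML ascends from its initialisation and recovers the truth", {
  set.seed(51)
  x <- rblinar(2000, 0.5, 1.5)
  yw <- fit_blinar(x, "yw")
  fit <- fit_blinar(x, "cml")
  expect_true(fit$converged)
  expect_gte(fit$loglik,
             conditional_loglik(x, min(max(yw$alpha_hat, 0.001), 0.999),
                                yw$theta_hat))
  expect_lt(abs(fit$alpha_hat - 0.5), 0.05)
  expect_lt(abs(fit$theta_hat - 1.5), 0.08)
  # likelihood surface: optimum beats a coarse grid around the truth
  grid <- expand.grid(a = seq(0.35, 0.65, by = 0.05),
                      th = seq(1.2, 1.8, by = 0.1))
  lls <- mapply(function(a, th) conditional_loglik(x, a, th), grid$a, grid$th)
  expect_gte(fit$loglik, max(lls) - 1e-6)
})

test_that("CML with explicit init matches the default optimum", {
  set.seed(52)
  x <- rblinar(500, 0.25, 0.5)
  f1 <- fit_blinar(x, "cml")
  f2 <- fit_blinar(x, "cml", init = list(alpha = 0.6, theta = 1.2))
  expect_equal(f1$alpha_hat, f2$alpha_hat, tolerance = 1e-4)
  expect_equal(f1$theta_hat, f2$theta_hat, tolerance = 1e-4)
})

test_that("asymptotic covariance is symmetric PSD with a verified mu3", {
  for (a in c(0.25, 0.5, 0.75)) for (th in c(0.5, 1.5)) {
    S <- cls_asymptotic_cov(a, th)
    expect_identical(S$sigma, t(S$sigma))
    expect_true(all(diag(S$sigma) >= 0))
    expect_gt(S$mu3, 0)
  }
  # third raw moment against a long simulated path
  a <- 0.25; th <- 0.5
  set.seed(61)
  x <- rblinar(2e5, a, th)
  S <- cls_asymptotic_cov(a, th)
  se <- stats::sd(x^3) / sqrt(2e5) * sqrt((1 + a) / (1 - a))
  expect_lt(abs(mean(x^3) - S$mu3), 3 * se)
})

test_that("delta-method SE behaves linearly and covers the truth", {
  fit <- structure(list(method = "CLS", alpha_hat = 0.25, mu_hat = 0.8244,
                        theta_hat = theta_from_mean(0.8244 * 0.75),
                        n_used = 999), class = "blinar_fit")
  zero <- structure(list(sigma = matrix(0, 2, 2), mu3 = 1),
                    class = "blinar_asymcov")
  expect_equal(delta_theta_se(fit, zero, n = 1000), 0)
  S <- cls_asymptotic_cov(0.25, fit$theta_hat)
  se1 <- delta_theta_se(fit, S, n = 1000)
  se2 <- delta_theta_se(fit, S, n = 4000)
  expect_equal(se1 / se2, 2, tolerance = 1e-12)

  # coverage of nominal 95% intervals for theta from CLS fits
  set.seed(71)
  covered <- replicate(500, {
    x <- rblinar(2000, 0.25, 0.5)
    f <- fit_blinar(x, "cls")
    if (is.na(f$theta_hat) || length(f$flags)) return(NA)
    se <- delta_theta_se(f, n = 2000)
    abs(f$theta_hat - 0.5) <= 1.96 * se
  })
  rate <- mean(covered, na.rm = TRUE)
  expect_gt(rate, 0.92)
  expect_lt(rate, 0.98)

  bad <- structure(list(alpha_hat = 1.2, mu_hat = 1, theta_hat = NA_real_,
                        n_used = 99), class = "blinar_fit")
  expect_warning(out <- delta_theta_se(bad, zero, n = 100), "boundary")
  expect_true(is.na(out))
})

test_that("all three estimators shrink their bias as T grows", {
  set.seed(81)
  lens <- c(100, 1000)
  for (est in c("cls", "yw", "cml")) {
    bias <- vapply(lens, function(T_) {
      a <- replicate(60, {
        x <- rblinar(T_, 0.5, 0.5)
        tryCatch(fit_blinar(x, est)$alpha_hat, error = function(e) NA)
      })
      abs(mean(a, na.rm = TRUE) - 0.5)
    }, numeric(1))
    expect_lt(bias[2], max(bias[1], 0.02), label = est)
  }
})
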