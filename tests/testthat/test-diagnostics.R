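# Innovation families, information criteria, residual diagnostics, the
# overdispersion bootstrap, forecasting and model comparison.

test_that("built-in families have coherent pmf, moments and samplers", {
  cases <- list(list(fam = bell_family(), par = 1.2),
                list(fam = poisson_family(), par = 2),
                list(fam = geometric_family(), par = 0.4))
  for (cs in cases) {
    fam <- cs$fam; par <- cs$par
    k <- 0:400
    p <- exp(fam$logpmf(k, par))
    expect_lt(abs(sum(p) - 1), 1e-10, label = fam$name)
    expect_equal(sum(k * p), fam$mean(par), tolerance = 1e-8,
                 label = fam$name)
    expect_equal(sum(k^2 * p) - sum(k * p)^2, fam$variance(par),
                 tolerance = 1e-7, label = fam$name)
    set.seed(1)
    x <- fam$sample(2e4, par)
    expect_lt(abs(mean(x) - fam$mean(par)),
              3 * sqrt(fam$variance(par) / 2e4))
  }
})

test_that("generic CML with the Bell family is the BL-INAR(1) CML", {
  set.seed(2)
  x <- rblinar(300, 0.5, 1)
  f1 <- fit_blinar(x, "cml")
  f2 <- fit_inar(x, bell_family())
  expect_equal(f1$alpha_hat, f2$alpha_hat, tolerance = 1e-8)
  expect_equal(f1$theta_hat, unname(f2$par[["theta"]]), tolerance = 1e-8)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-8)
})

test_that("generic CML recovers Poisson and geometric innovations", {
  set.seed(3)
  x <- blinar:::.sim_inar(5000, 0.5, function(m) stats::rpois(m, 2))
  f <- fit_inar(x, poisson_family())
  expect_lt(abs(f$alpha_hat - 0.5), 0.05)
  expect_lt(abs(f$par[["lambda"]] - 2), 0.1)

  set.seed(4)
  y <- blinar:::.sim_inar(5000, 0.4, function(m) stats::rgeom(m, 0.45))
  g <- fit_inar(y, geometric_family())
  expect_lt(abs(g$alpha_hat - 0.4), 0.05)
  expect_lt(abs(g$par[["pi"]] - 0.45), 0.05)
})

test_that("information criteria follow their defining arithmetic", {
  ic <- information_criteria(-100, 2, 100)
  expect_equal(unname(ic["AIC"]), 204)
  expect_equal(unname(ic["BIC"]), 200 + 2 * log(100))
  expect_equal(unname(ic["CAIC"] - ic["BIC"]), 2)
  expect_equal(unname(ic["HQIC"]), 200 + 4 * log(log(100)))
  ic2 <- information_criteria(-50.5, 3, 40)
  expect_equal(unname(ic2["CAIC"] - ic2["BIC"]), 3)
  expect_gt(unname(ic2["BIC"]), unname(ic2["AIC"]))   # ln 40 > 2
  expect_error(information_criteria(-10, 2, 1), "n_obs")
})

test_that("Pearson residuals standardise correctly", {
  x <- c(2L, 3L, 1L)
  r <- pearson_residuals(x, 0.5, 0.8)
  cm <- blinar_cond_moments(c(2L, 3L), 0.5, 0.8)
  expect_equal(r, (c(3, 1) - cm$mean) / sqrt(cm$variance), tolerance = 1e-12)
  expect_length(r, 2)

  set.seed(5)
  y <- rblinar(20000, 0.5, 1)
  r <- pearson_residuals(y, 0.5, 1)
  expect_lt(abs(mean(r)), 3 / sqrt(length(r)))
  expect_lt(abs(stats::var(r) - 1), 3 * sqrt(2 / length(r)) * 2)
})

test_that("Ljung-Box holds its size on white noise and detects AR", {
  set.seed(6)
  rej <- mean(replicate(500, ljung_box(stats::rnorm(200), 10)$p_value < 0.05))
  expect_gt(rej, 0.02); expect_lt(rej, 0.09)
  set.seed(7)
  ar <- as.numeric(stats::arima.sim(list(ar = 0.7), 300))
  lb <- ljung_box(ar, 10)
  expect_gt(lb$statistic, 0)
  expect_lt(lb$p_value, 0.01)
  expect_error(ljung_box(rep(1, 50), 10), "degenerate")
})

test_that("dispersion index matches hand values and the stationary limit", {
  expect_equal(dispersion_index(c(3, 3, 3, 3)), 0)
  expect_equal(dispersion_index(c(0, 2, 0, 2)), 4 / 3, tolerance = 1e-12)
  set.seed(8)
  x <- rblinar(50000, 0.5, 1.5)
  expect_lt(abs(dispersion_index(x) - 2), 0.08)   # I_x = 1 + 1.5/1.5
  expect_error(dispersion_index(c(0L, 0L, 0L)), "zero-mean")
})

test_that("overdispersion bootstrap separates Bell from Poisson dynamics", {
  set.seed(9)
  x <- rblinar(300, 0.5, 1.5)          # strongly overdispersed
  ot <- overdispersion_test(x, B = 199, seed = 10)
  expect_true(ot$reject)
  expect_gt(ot$critical_value, 1)

  # size control under the Poisson-INAR null (small outer loop)
  set.seed(11)
  rejections <- replicate(25, {
    y <- blinar:::.sim_inar(150, 0.4, function(m) stats::rpois(m, 1.2))
    tryCatch(overdispersion_test(y, B = 199)$reject, error = function(e) NA)
  })
  expect_lte(mean(rejections, na.rm = TRUE), 0.25)
  expect_error(overdispersion_test(rblinar(20, 0.5, 1), B = 199), "30")
})

test_that("forecasts follow the multi-step conditional moments", {
  set.seed(12)
  x <- rblinar(100, 0.5, 1)
  fc <- blinar_forecast(x, 0.5, 1, h = 8)
  expect_identical(fc$h, 1:8)
  c1 <- blinar_cond_moments(x[100], 0.5, 1)
  expect_equal(fc$mean[1], c1$mean)
  expect_equal(fc$variance[1], c1$variance)
  km <- blinar_kstep_moments(x[100], 1:8, 0.5, 1)
  expect_equal(fc$mean, km$mean)
  expect_equal(fc$variance, km$variance)
  far <- blinar_forecast(x, 0.5, 1, h = 300)
  mo <- blinar_moments(0.5, 1)
  expect_equal(far$mean[300], mo$mean, tolerance = 1e-8)
  expect_equal(far$variance[300], mo$variance, tolerance = 1e-8)
})

test_that("holdout RMSE fits on the training slice only", {
  set.seed(13)
  x <- rblinar(160, 0.5, 1)
  out <- rmse_holdout(x, bell_family(), h = 6)
  expect_length(out$forecasts, 6)
  expect_identical(out$actuals, x[155:160])
  expect_identical(out$fit$n_used, 153L)    # T - h - 1 transitions
  expect_gte(out$rmse, 0)
  # hand arithmetic of the RMSE definition
  expect_equal(out$rmse, sqrt(mean((out$actuals - out$forecasts)^2)),
               tolerance = 1e-12)
  expect_error(rmse_holdout(x, h = 200), "T > h")
})

test_that("model comparison ranks families coherently", {
  set.seed(14)
  x <- rblinar(400, 0.5, 1.5)
  tab <- compare_models(x, list(bell_family(), poisson_family(),
                                geometric_family()), h = 6)
  expect_s3_class(tab, "data.frame")
  expect_identical(nrow(tab), 3L)
  expect_true(all(is.finite(tab$AIC)))
  expect_true(!is.unsorted(tab$AIC))
  # equal parameter counts: all four criteria agree on the ordering
  expect_identical(order(tab$AIC), order(tab$BIC))
  expect_identical(order(tab$AIC), order(tab$CAIC))
  expect_identical(order(tab$AIC), order(tab$HQIC))
  # fitted stationary mean should sit near the sample mean for the Bell row
  bell_row <- tab[tab$model == "BL-INAR", ]
  expect_lt(abs(bell_row$fitted_mean - mean(x)) / mean(x), 0.15)
})

test_that("Bell fitted variance tracks the sample variance better than
          Poisson on overdispersed data", {
  set.seed(15)
  wins <- replicate(30, {
    x <- rblinar(500, 0.5, 1.5)
    tab <- compare_models(x, list(bell_family(), poisson_family()), h = NA)
    sv <- stats::var(x)
    d <- abs(tab$fitted_variance - sv)
    d[tab$model == "BL-INAR"] < d[tab$model == "P-INAR"]
  })
  expect_gt(mean(wins), 0.8)
})

test_that("Pearson residuals of the true model pass Ljung-Box mostly", {
  set.seed(16)
  pass <- replicate(60, {
    x <- rblinar(400, 0.5, 1)
    ljung_box(pearson_residuals(x, 0.5, 1), 10)$p_value > 0.05
  })
  expect_gt(mean(pass), 0.85)
})
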