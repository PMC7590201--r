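test_that("noise-free self-generated data recovers every family's parameters", {
  for (fam in c("exponential", "logistic", "power", "gompertz")) {
    for (grp in c("L", "XL")) {
      truth <- reference_curve(fam, grp)
      fit <- fit_growth(model_series(truth), fam)
      expect_true(fit$converged)
      expect_lt(fit$rmse, 1e-8)
      expect_equal(fit$model$a, truth$a, tolerance = 1e-4)
      if (!is.null(truth$b))
        expect_equal(fit$model$b, truth$b, tolerance = 1e-4)
    }
  }
})

test_that("exponential NLLS on noise-free data matches log-linear OLS oracle", {
  truth <- growth_model("exponential", a = 0.81, b = 0.21)
  s <- model_series(truth)
  fit <- fit_growth(s, "exponential")
  # independent oracle: ordinary regression of log(y) on t
  ols <- lm(log(opacity) ~ day, data = s)
  expect_equal(fit$model$a, exp(unname(coef(ols)[1])), tolerance = 1e-6)
  expect_equal(fit$model$b, unname(coef(ols)[2]), tolerance = 1e-6)
})

test_that("goodness of fit follows its definitions", {
  m <- growth_model("exponential", a = 1, b = 0.2)
  s <- model_series(m)
  g <- goodness_of_fit(s, m)
  expect_equal(g$rmse, 0)
  expect_equal(g$r2, 1)

  # residuals (1, -1, 1, -1) -> rmse sqrt(4/4) = 1
  s2 <- data.frame(day = 1:4,
                   opacity = predict(m, 1:4) + c(1, -1, 1, -1))
  expect_equal(goodness_of_fit(s2, m)$rmse, 1)

  # a flat curve at the series mean has r2 = 0 by definition of SS_tot;
  # build it as the b -> 0 limit via a tiny-rate exponential
  y <- c(2, 4, 6, 8)
  flat <- growth_model("exponential", a = mean(y), b = 1e-12)
  expect_equal(goodness_of_fit(data.frame(day = c(0, 1, 2, 3), opacity = y),
                               flat)$r2, 0, tolerance = 1e-6)

  # zero-variance series: r2 undefined
  const <- data.frame(day = 1:4, opacity = rep(5, 4))
  expect_true(is.na(goodness_of_fit(const, m)$r2))
  expect_error(goodness_of_fit(data.frame(day = numeric(),
                                          opacity = numeric()), m),
               "empty")
})

test_that("constant series drives the exponential rate to zero", {
  s <- data.frame(day = 6:16, opacity = rep(7, 11))
  fit <- fit_growth(s, "exponential")
  expect_lt(abs(fit$model$b), 1e-4)
  expect_equal(predict(fit$model, 6:16), rep(7, 11), tolerance = 1e-4)
})

test_that("degenerate inputs are rejected", {
  expect_error(fit_growth(data.frame(day = c(6, 7), opacity = c(1, 2)),
                          "exponential"), ">= 3")
  expect_error(fit_growth(data.frame(day = c(6, 6, 6),
                                     opacity = c(1, 2, 3)),
                          "exponential"), "distinct days")
})

test_that("fit_all_growth compares families and the generating family wins", {
  truth <- reference_curve("power", "L")
  s <- model_series(truth)
  res <- fit_all_growth(s)
  expect_equal(nrow(res$comparison), 4L)
  # the generating family converges and attains the minimum rmse;
  # the logistic need not converge here (an exponential-like series is
  # its asymptote-to-infinity limit), and its flag records that
  expect_true(res$comparison$converged[res$comparison$family == "power"])
  expect_identical(res$comparison$family[1], "power")  # sorted by rmse
  expect_true(all(diff(res$comparison$rmse) >= 0))

  # determinism: identical data in, identical table out
  res2 <- fit_all_growth(s)
  expect_identical(res$comparison, res2$comparison)
})

test_that("fitted gompertz with fixed asymptote never exceeds 70", {
  set.seed(42)
  truth <- reference_curve("gompertz", "L")
  s <- model_series(truth)
  s$opacity <- s$opacity + rnorm(nrow(s), 0, 2)
  fit <- fit_growth(s, "gompertz")
  expect_equal(fit$model$asymptote, 70)
  expect_true(all(predict(fit$model, seq(0, 100, by = 0.5)) < 70))
})

test_that("fitted rmse tracks the injected noise level", {
  set.seed(1234)
  truth <- reference_curve("exponential", "L")
  y0 <- predict(truth, 6:16)
  sigma <- 1.5
  rmses <- replicate(200, {
    s <- data.frame(day = 6:16, opacity = y0 + rnorm(11, 0, sigma))
    fit_growth(s, "exponential")$rmse
  })
  expect_equal(mean(rmses), sigma, tolerance = 0.3)
})
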