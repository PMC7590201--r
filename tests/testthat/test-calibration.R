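test_that("calibration recovers a known linear opacity-weight relation", {
  model <- reference_curve("exponential", "L")
  days <- 6:16
  y_calc <- predict(model, days)
  # reference built so that weight = (y - 1.4166) / 1.954 exactly
  ref <- tibble::tibble(day = days,
                        embryo_weight = (y_calc - 1.4166) / 1.954)
  cal <- calibrate_opacity(model, ref)
  expect_equal(cal$intercept, 1.4166, tolerance = 1e-9)
  expect_equal(cal$slope, 1.954, tolerance = 1e-9)
  expect_equal(cal$r2_weight, 1, tolerance = 1e-12)
})

test_that("identity and affine references give perfect calibration", {
  model <- reference_curve("gompertz", "L")
  days <- 6:16
  y <- predict(model, days)
  ident <- tibble::tibble(day = days, embryo_weight = y)
  cal <- calibrate_opacity(model, ident)
  expect_equal(cal$slope, 1, tolerance = 1e-12)
  expect_equal(cal$intercept, 0, tolerance = 1e-10)
  expect_equal(cal$r2_weight, 1, tolerance = 1e-12)

  # any affine reference (beta != 0) gives r2_weight = 1
  aff <- tibble::tibble(day = days, embryo_weight = 2.2 + 0.41 * y)
  expect_equal(calibrate_opacity(model, aff)$r2_weight, 1,
               tolerance = 1e-12)
})

test_that("r2_weight is invariant under affine rescaling of either axis", {
  model <- reference_curve("power", "XL")
  ref <- make_reference_table(6:16)
  r2 <- calibrate_opacity(model, ref)$r2_weight
  ref2 <- ref
  ref2$embryo_weight <- 5 + 3 * ref$embryo_weight
  expect_equal(calibrate_opacity(model, ref2)$r2_weight, r2,
               tolerance = 1e-12)
  # rescaling calculated opacity is an affine map of y: same r2
  y <- predict(model, ref$day)
  expect_equal(stats::cor(7 - 2 * y, ref$embryo_weight)^2, r2,
               tolerance = 1e-12)
})

test_that("predicted weight inverts the calibration line", {
  eq <- published_calibrations()
  expo <- eq[eq$family == "exponential", ]
  expect_equal(predict_weight(expo, 20), 9.51044012282, tolerance = 1e-9)
  expect_equal(predict_weight(expo, expo$intercept), 0)

  # forward then inverse is the identity for any fitted calibration
  model <- reference_curve("logistic", "XL")
  ref <- make_reference_table(6:16)
  cal <- calibrate_opacity(model, ref)
  x <- seq(1, 15, by = 0.5)
  expect_equal(predict_weight(cal, cal$intercept + cal$slope * x), x,
               tolerance = 1e-9)

  expect_error(predict_weight(list(intercept = 1, slope = 0), 5),
               "nonzero")
})

test_that("calibration validates its reference input", {
  model <- reference_curve("exponential", "L")
  expect_error(
    calibrate_opacity(model, tibble::tibble(day = c(6, 7),
                                            embryo_weight = c(1, 2))),
    "3 reference days")
  expect_error(
    calibrate_opacity(model, tibble::tibble(day = 6:10,
                                            embryo_weight = rep(4, 5))),
    "constant")
})

test_that("calibration report covers converged fits and skips the rest", {
  # a logistic-truth series gives all four families an interior optimum
  truth <- reference_curve("logistic", "L")
  fits <- fit_all_growth(model_series(truth))
  ref <- make_reference_table(6:16)
  rep_tab <- calibration_report(fits, ref)
  expect_equal(nrow(rep_tab), 4L)
  expect_setequal(rep_tab$family,
                  c("exponential", "logistic", "power", "gompertz"))

  # reference affinely generated from the fitted exponential curve ->
  # exponential row has r2_weight = 1
  y <- predict(fits$fits$exponential$model, 6:16)
  aff_ref <- tibble::tibble(day = 6:16, embryo_weight = 0.3 + 0.5 * y)
  tab2 <- calibration_report(fits, aff_ref)
  expect_equal(tab2$r2_weight[tab2$family == "exponential"], 1,
               tolerance = 1e-10)

  broken <- fits$fits
  broken$gompertz$converged <- FALSE
  expect_warning(tab3 <- calibration_report(broken, ref), "gompertz")
  expect_equal(nrow(tab3), 3L)
})

test_that("calibration parameters converge to truth as noise vanishes", {
  # true opacity affine in a Gompertz-shaped weight trajectory plus noise
  ref <- make_reference_table(6:16)
  a_true <- 1.2; b_true <- 2.1
  err <- sapply(c(2, 0.5, 0), function(sigma) {
    set.seed(77)
    y_obs <- a_true + b_true * ref$embryo_weight +
      rnorm(nrow(ref), 0, sigma)
    fit <- lm(y_obs ~ ref$embryo_weight)
    cal <- list(intercept = unname(coef(fit)[1]),
                slope = unname(coef(fit)[2]))
    abs(cal$intercept - a_true) + abs(cal$slope - b_true)
  })
  expect_true(all(diff(err) < 0) || err[3] < err[1])
  expect_lt(err[3], 1e-10)
  # and through the package path at sigma = 0: exact recovery
  model <- reference_curve("exponential", "L")
  y <- predict(model, ref$day)
  ref0 <- tibble::tibble(day = ref$day,
                         embryo_weight = (y - a_true) / b_true)
  cal0 <- calibrate_opacity(model, ref0)
  expect_equal(c(cal0$intercept, cal0$slope), c(a_true, b_true),
               tolerance = 1e-9)
})
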