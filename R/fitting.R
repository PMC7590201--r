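#' Control settings for non-linear least-squares fitting
#'
#' Damped (Levenberg--Marquardt) least squares with tight relative
#' tolerances on both the parameters and the cost, matching the behavior
#' expected of growth-curve fitting on daily opacity series.
#'
#' @param ftol,ptol Relative tolerance on the sum of squares and on the
#'   parameter vector.
#' @param maxiter Maximum number of iterations.
#' @return A list passed to [minpack.lm::nls.lm.control()].
#' @export
growth_fit_control <- function(ftol = 1e-10, ptol = 1e-10, maxiter = 1000) {
  list(ftol = ftol, ptol = ptol, maxiter = maxiter)
}

n_free_params <- function(family, fix_asymptote) {
  switch(family,
    exponential = 2L,
    power       = 1L,
    gompertz    = if (fix_asymptote) 2L else 3L,
    logistic    = 3L)
}

#' Default starting values for each family
#'
#' Exponential and power start from a flat unit curve (a = 1, b = 0.1);
#' the logistic asymptote starts 20% above the largest observed opacity
#' with shape 10 and rate 0.3; the Gompertz shape/rate start at 13 and 0.2
#' with the asymptote held at 70 mA/V.
#'
#' @param family Model family.
#' @param y Observed opacity values (used for the logistic asymptote).
#' @param fix_asymptote Is the gompertz asymptote held fixed?
#' @return Named numeric vector of starting parameters.
#' @export
default_init <- function(family, y, fix_asymptote = TRUE) {
  switch(family,
    exponential = c(a = 1, b = 0.1),
    power       = c(a = 1),
    logistic    = c(A = 1.2 * max(y), a = 10, b = 0.3),
    gompertz    = if (fix_asymptote) c(a = 13, b = 0.2)
                  else c(A = 1.2 * max(y), a = 13, b = 0.2))
}

model_from_params <- function(family, p, asymptote_fixed = NULL) {
  growth_model(family,
    a = p[["a"]],
    b = if (family == "power") NULL else p[["b"]],
    asymptote = if (family %in% c("logistic", "gompertz")) {
      if ("A" %in% names(p)) p[["A"]] else asymptote_fixed
    } else NULL,
    validate = FALSE)
}

#' Fit a growth model to an opacity series
#'
#' Minimizes the sum of squared residuals between observed opacity and the
#' family's curve over incubation days using the Levenberg--Marquardt
#' algorithm. For the Gompertz family the upper asymptote is held fixed
#' (70 mA/V by default) unless `fix_asymptote = FALSE`.
#'
#' Non-convergence is reported through the `converged` field of the result,
#' not as an error; supplying fewer points than free parameters is an error.
#'
#' @param series Data frame with columns `day` and `opacity`, or a list
#'   with those elements. Flagged (out-of-range) measurements should be
#'   excluded before fitting; see [opacity_table()].
#' @param family One of `"exponential"`, `"logistic"`, `"power"`,
#'   `"gompertz"`.
#' @param init Optional named starting vector; defaults to
#'   [default_init()].
#' @param fix_asymptote Hold the Gompertz asymptote fixed at
#'   `asymptote` (default `TRUE`). Ignored by other families.
#' @param asymptote Fixed Gompertz asymptote value (mA/V).
#' @param control See [growth_fit_control()].
#'
#' @return An object of class `growth_fit`: list with `model`
#'   (a [growth_model()] carrying the fitted parameters), `family`,
#'   `rmse`, `r2`, `n_points`, `converged`, `n_iterations`, `residuals`.
#' @examples
#' truth <- reference_curve("exponential", "L")
#' series <- data.frame(day = 6:16, opacity = predict(truth, 6:16))
#' fit <- fit_growth(series, "exponential")
#' fit$model
#' @export
fit_growth <- function(series, family, init = NULL, fix_asymptote = TRUE,
                       asymptote = 70, control = growth_fit_control()) {
  family <- match.arg(family, GROWTH_FAMILIES)
  t <- as.numeric(series$day)
  y <- as.numeric(series$opacity)
  keep <- is.finite(t) & is.finite(y)
  t <- t[keep]; y <- y[keep]
  npar <- n_free_params(family, fix_asymptote)
  if (length(y) < npar)
    stop("need at least ", npar, " points to fit a ", family, " model",
         call. = FALSE)
  if (length(y) < 3L || length(unique(t)) < 3L)
    stop("need >= 3 points spanning >= 3 distinct days", call. = FALSE)
  if (is.null(init)) init <- default_init(family, y, fix_asymptote)

  resid_fn <- function(p) {
    m <- model_from_params(family, p,
                           asymptote_fixed = if (family == "gompertz" &&
                                                 fix_asymptote) asymptote)
    y - eval_growth(m, t)
  }
  res <- minpack.lm::nls.lm(
    par = init, fn = resid_fn,
    control = minpack.lm::nls.lm.control(
      ftol = control$ftol, ptol = control$ptol, maxiter = control$maxiter,
      maxfev = 100 * control$maxiter))

  fitted_model <- model_from_params(
    family, coef(res),
    asymptote_fixed = if (family == "gompertz" && fix_asymptote) asymptote)
  gof <- goodness_of_fit(list(day = t, opacity = y), fitted_model)

  structure(
    list(model = fitted_model,
         family = family,
         rmse = gof$rmse,
         r2 = gof$r2,
         n_points = length(y),
         converged = res$info %in% 1:4,
         n_iterations = res$niter,
         residuals = y - eval_growth(fitted_model, t)),
    class = "growth_fit")
}

#' @export
print.growth_fit <- function(x, ...) {
  cat("<growth_fit> ", x$family,
      sprintf(" | rmse = %.4g, R2 = %.4g, n = %d, converged = %s\n",
              x$rmse, x$r2, x$n_points, x$converged), sep = "")
  print(x$model)
  invisible(x)
}

#' Goodness of fit of a growth model against an opacity series
#'
#' @param series Data frame or list with `day` and `opacity`.
#' @param model A [growth_model()].
#' @return List with `rmse` (root mean squared residual, mA/V) and `r2`
#'   (`1 - SS_res / SS_tot` about the series mean; can be negative, and is
#'   `NA` for a zero-variance series where `SS_tot = 0`).
#' @export
goodness_of_fit <- function(series, model) {
  t <- as.numeric(series$day)
  y <- as.numeric(series$opacity)
  if (length(y) == 0L) stop("empty series", call. = FALSE)
  r <- y - eval_growth(model, t)
  ss_res <- sum(r^2)
  ss_tot <- sum((y - mean(y))^2)
  list(rmse = sqrt(ss_res / length(y)),
       r2 = if (ss_tot == 0) NA_real_ else 1 - ss_res / ss_tot)
}

#' Fit all four growth families and compare them
#'
#' Fits each family to the same opacity series using its default starting
#' values and returns the fits plus a comparison table sorted by RMSE,
#' mirroring the usual model-comparison summary (equation parameters, RMSE
#' of opacity, R-squared of the fitted curve).
#'
#' @inheritParams fit_growth
#' @param families Families to fit (all four by default).
#' @return A list of class `growth_fit_set`: `fits` (named list of
#'   [fit_growth()] results) and `comparison` (tibble with columns
#'   `family`, `a`, `b`, `asymptote`, `rmse`, `r2`, `n_points`,
#'   `converged`, ordered by increasing `rmse`).
#' @export
fit_all_growth <- function(series, families = GROWTH_FAMILIES,
                           fix_asymptote = TRUE, asymptote = 70,
                           control = growth_fit_control()) {
  families <- match.arg(families, GROWTH_FAMILIES, several.ok = TRUE)
  fits <- lapply(families, function(f)
    fit_growth(series, f, fix_asymptote = fix_asymptote,
               asymptote = asymptote, control = control))
  names(fits) <- families
  comparison <- tibble::tibble(
    family = families,
    a = vapply(fits, function(x) x$model$a, numeric(1)),
    b = vapply(fits, function(x)
      if (is.null(x$model$b)) NA_real_ else x$model$b, numeric(1)),
    asymptote = vapply(fits, function(x)
      if (is.null(x$model$asymptote)) NA_real_ else x$model$asymptote,
      numeric(1)),
    rmse = vapply(fits, function(x) x$rmse, numeric(1)),
    r2 = vapply(fits, function(x) x$r2, numeric(1)),
    n_points = vapply(fits, function(x) x$n_points, integer(1)),
    converged = vapply(fits, function(x) x$converged, logical(1)))
  comparison <- comparison[order(comparison$rmse), ]
  structure(list(fits = fits, comparison = comparison),
            class = "growth_fit_set")
}

#' @export
print.growth_fit_set <- function(x, ...) {
  cat("<growth_fit_set> ", length(x$fits), " families fitted\n", sep = "")
  print(x$comparison)
  invisible(x)
}
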