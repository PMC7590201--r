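#' Calibrate calculated opacity against reference embryo weight
#'
#' Evaluates the fitted growth curve at the reference table's days to get
#' the calculated opacity `y = f(t)` (a smooth curve, not the raw opacity
#' points), then fits the ordinary least-squares line of calculated
#' opacity on embryo weight:
#' \deqn{y_{calc} = a_c + b_c x}
#' so that embryo weight is recovered by the inverse map
#' \eqn{x = (y_{calc} - a_c) / b_c}. Regressing opacity on weight (rather
#' than the reverse) is what makes the inversion reproduce the printed
#' form of published opacity-to-weight equations exactly.
#'
#' @param model A fitted or reference [growth_model()].
#' @param reference Data frame with columns `day` and `embryo_weight`
#'   (grams); see [make_reference_table()]. At least 3 days,
#'   non-constant weights.
#' @return Object of class `opacity_calibration`: list with `family`,
#'   `intercept` (`a_c`, mA/V), `slope` (`b_c`, mA/V per gram),
#'   `r2_weight` (squared Pearson correlation between calculated opacity
#'   and embryo weight), `n_days`.
#' @examples
#' ref <- make_reference_table(6:16)
#' cal <- calibrate_opacity(reference_curve("exponential", "L"), ref)
#' predict_weight(cal, y_calc = 20)
#' @export
calibrate_opacity <- function(model, reference) {
  stopifnot(inherits(model, "growth_model"))
  day <- as.numeric(reference$day)
  x <- as.numeric(reference$embryo_weight)
  if (length(day) < 3L)
    stop("need at least 3 reference days", call. = FALSE)
  if (max(x) == min(x))
    stop("constant reference weights: calibration undefined", call. = FALSE)
  y <- eval_growth(model, day)
  fit <- lm(y ~ x)
  structure(
    list(family = model$family,
         intercept = unname(coef(fit)[1L]),
         slope = unname(coef(fit)[2L]),
         r2_weight = stats::cor(x, y)^2,
         n_days = length(day)),
    class = "opacity_calibration")
}

#' @export
print.opacity_calibration <- function(x, ...) {
  cat("<opacity_calibration> ", x$family,
      sprintf(": x = (y - %.4f) / %.4f, R2(weight) = %.4g, n = %d days\n",
              x$intercept, x$slope, x$r2_weight, x$n_days), sep = "")
  invisible(x)
}

#' Predict embryo weight from calculated opacity
#'
#' Inverts the calibration line: `x = (y_calc - a_c) / b_c`.
#'
#' @param cal An [calibrate_opacity()] result, or any list with
#'   `intercept` and `slope`.
#' @param y_calc Calculated opacity value(s), mA/V.
#' @return Embryo weight(s), grams.
#' @export
predict_weight <- function(cal, y_calc) {
  if (!is.finite(cal$slope) || cal$slope == 0)
    stop("calibration slope must be nonzero", call. = FALSE)
  (y_calc - cal$intercept) / cal$slope
}

#' Calibration report across fitted families
#'
#' One calibration row per converged fit, matching the shape of published
#' opacity-to-embryo-weight equation sets (intercept, slope, and the
#' squared correlation between calculated opacity and reference weight).
#' Non-converged fits are skipped with a warning.
#'
#' @param fits Named list of [fit_growth()] results (or a
#'   [fit_all_growth()] result).
#' @param reference Reference table as in [calibrate_opacity()].
#' @return Tibble with columns `family`, `intercept`, `slope`,
#'   `r2_weight`, `n_days`.
#' @export
calibration_report <- function(fits, reference) {
  if (inherits(fits, "growth_fit_set")) fits <- fits$fits
  rows <- lapply(fits, function(f) {
    if (!isTRUE(f$converged)) {
      warning("skipping non-converged ", f$family, " fit", call. = FALSE)
      return(NULL)
    }
    cal <- calibrate_opacity(f$model, reference)
    tibble::tibble(family = cal$family, intercept = cal$intercept,
                   slope = cal$slope, r2_weight = cal$r2_weight,
                   n_days = cal$n_days)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L)
    stop("no converged fits to calibrate", call. = FALSE)
  do.call(rbind, rows)
}

#' Published opacity-to-embryo-weight calibration coefficients
#'
#' Inverse-calibration coefficients `x = (y - intercept) / slope` reported
#' in the NIR opacity literature for graded broiler eggs over incubation
#' days 6--16, one row per growth-model family. Shipped for use with
#' [predict_weight()] on matching sensor data; they are not refit
#' estimates (reproducing them would require the original opacity dataset
#' and the measured embryo-weight reference, neither of which is
#' published).
#'
#' @return Tibble with columns `family`, `intercept` (mA/V), `slope`
#'   (mA/V per gram).
#' @export
published_calibrations <- function() {
  tibble::tibble(
    family = c("exponential", "logistic", "power", "gompertz"),
    intercept = c(1.4166, 1.5054, 3.3971, 1.1191),
    slope = c(1.954, 1.9444, 2.0095, 1.9111))
}
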