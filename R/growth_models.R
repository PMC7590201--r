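#' Growth model families
#'
#' The four curve families used to describe egg opacity (mA/V) as a function
#' of incubation day `t`:
#' \describe{
#'   \item{exponential}{`y = a * exp(b * t)`}
#'   \item{logistic}{`y = A / (1 + a * exp(-b * t))` (3-parameter sigmoid)}
#'   \item{power}{`y = a ^ t`}
#'   \item{gompertz}{`y = A * exp(-a * exp(-b * t))`, with upper asymptote
#'     `A` conventionally fixed at 70 mA/V for incubated-egg opacity}
#' }
#' All families are growth curves: `b > 0` (and `a > 1` for the power
#' family) so that opacity increases with incubation day.
#'
#' @name growth-families
#' @keywords internal
NULL

GROWTH_FAMILIES <- c("exponential", "logistic", "power", "gompertz")

#' Construct a growth model specification
#'
#' @param family One of `"exponential"`, `"logistic"`, `"power"`,
#'   `"gompertz"`.
#' @param a Shape coefficient (`> 0`; `> 1` for the power family, whose
#'   only parameter is the base `a`).
#' @param b Growth-rate parameter per day (`> 0`). Unused by the power
#'   family.
#' @param asymptote Upper asymptote `A` in mA/V for the logistic and
#'   Gompertz families (`> 0`); defaults to 70 for gompertz.
#' @param validate Check the growth-curve invariants (`TRUE` by default).
#'   Fitting routines may construct unvalidated specs for degenerate data.
#'
#' @return An object of class `growth_model`: a list with elements
#'   `family`, `a`, `b`, `asymptote`.
#' @examples
#' m <- growth_model("exponential", a = 0.5357, b = 0.2667)
#' predict(m, t = 6:16)
#' @export
growth_model <- function(family, a, b = NULL, asymptote = NULL,
                         validate = TRUE) {
  family <- match.arg(family, GROWTH_FAMILIES)
  if (family == "gompertz" && is.null(asymptote)) asymptote <- 70
  if (family == "power") b <- NULL
  m <- structure(
    list(family = family, a = as.numeric(a),
         b = if (!is.null(b)) as.numeric(b) else NULL,
         asymptote = if (!is.null(asymptote)) as.numeric(asymptote) else NULL),
    class = "growth_model"
  )
  if (validate) validate_growth_model(m)
  m
}

validate_growth_model <- function(m) {
  if (!is.finite(m$a) || m$a <= 0)
    stop("'a' must be a positive finite number", call. = FALSE)
  if (m$family == "power") {
    if (m$a <= 1)
      stop("power family requires base a > 1 for growth", call. = FALSE)
  } else {
    if (is.null(m$b) || !is.finite(m$b) || m$b <= 0)
      stop("'b' must be a positive finite growth rate", call. = FALSE)
  }
  if (m$family %in% c("logistic", "gompertz")) {
    if (is.null(m$asymptote) || !is.finite(m$asymptote) || m$asymptote <= 0)
      stop("'asymptote' must be a positive finite value (mA/V)",
           call. = FALSE)
  }
  invisible(m)
}

#' Evaluate a growth model at given incubation days
#'
#' @param object A [growth_model()].
#' @param t Numeric vector of incubation days.
#' @param ... Unused.
#' @return Numeric vector of opacity values (mA/V), same length as `t`.
#' @export
predict.growth_model <- function(object, t, ...) {
  eval_growth(object, t)
}

#' @rdname predict.growth_model
#' @export
eval_growth <- function(object, t) {
  stopifnot(inherits(object, "growth_model"))
  t <- as.numeric(t)
  switch(object$family,
    exponential = object$a * exp(object$b * t),
    logistic    = object$asymptote / (1 + object$a * exp(-object$b * t)),
    power       = object$a ^ t,
    gompertz    = object$asymptote * exp(-object$a * exp(-object$b * t)),
    stop("unknown growth family: ", object$family, call. = FALSE)
  )
}

#' @export
print.growth_model <- function(x, ...) {
  eq <- switch(x$family,
    exponential = sprintf("y = %.4g * exp(%.4g t)", x$a, x$b),
    logistic    = sprintf("y = %.4g / (1 + %.4g * exp(-%.4g t))",
                          x$asymptote, x$a, x$b),
    power       = sprintf("y = %.4g ^ t", x$a),
    gompertz    = sprintf("y = %.4g * exp(-%.4g * exp(-%.4g t))",
                          x$asymptote, x$a, x$b))
  cat("<growth_model> ", x$family, ": ", eq, "\n", sep = "")
  invisible(x)
}

#' Packaged reference opacity growth curves
#'
#' Fitted opacity-vs-day curves for graded broiler egg cohorts, one per
#' family and egg-size group (L = large, XL = extra large), shipped as a
#' plain-text fixtures file. They serve as simulation ground truth for
#' [simulate_cohort()] and as round-trip targets for parameter-recovery
#' tests. The logistic rows carry the 70 mA/V opacity asymptote shared
#' with the Gompertz rows.
#'
#' @param family Optional family filter.
#' @param group Optional group filter (`"L"` or `"XL"`).
#' @return `reference_curves()` returns a tibble with columns `family`,
#'   `group`, `a`, `b`, `asymptote`; `reference_curve()` returns the single
#'   matching [growth_model()].
#' @examples
#' reference_curves()
#' reference_curve("exponential", "L")
#' @export
reference_curves <- function(family = NULL, group = NULL) {
  path <- system.file("extdata", "reference_curves.csv",
                      package = "ovogrowth", mustWork = TRUE)
  tab <- tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE))
  if (!is.null(family)) {
    family <- match.arg(family, GROWTH_FAMILIES)
    tab <- tab[tab$family == family, , drop = FALSE]
  }
  if (!is.null(group)) {
    group <- match.arg(group, c("L", "XL"))
    tab <- tab[tab$group == group, , drop = FALSE]
  }
  tab
}

#' @rdname reference_curves
#' @export
reference_curve <- function(family, group = c("L", "XL")) {
  group <- match.arg(group)
  row <- reference_curves(family = family, group = group)
  if (nrow(row) != 1L)
    stop("no unique reference curve for ", family, "/", group, call. = FALSE)
  growth_model(row$family,
               a = row$a,
               b = if (is.na(row$b)) NULL else row$b,
               asymptote = if (is.na(row$asymptote)) NULL else row$asymptote)
}
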