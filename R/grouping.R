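#' Midpoint threshold between the smallest and largest value
#'
#' The grading rule splitting a cohort into a lower and an upper group at
#' `W_min + (W_max - W_min) / 2`, i.e. the midpoint of the observed range.
#'
#' @param weights Numeric vector with at least two distinct values.
#' @return The threshold, in the units of `weights` (grams for egg or
#'   chick weight).
#' @examples
#' midpoint_threshold(c(61.72, 65, 70, 72.48))  # 67.1
#' @export
midpoint_threshold <- function(weights) {
  weights <- weights[is.finite(weights)]
  if (length(weights) < 2L)
    stop("need at least two values", call. = FALSE)
  w_min <- min(weights)
  w_max <- max(weights)
  if (w_min == w_max)
    stop("degenerate range: all values identical", call. = FALSE)
  w_min + (w_max - w_min) / 2
}

#' Split a cohort into two groups at the midpoint threshold
#'
#' Records with attribute value below the threshold go to the lower group,
#' values above to the upper group. A value exactly at the threshold is
#' assigned to the upper group (the defining inequalities are strict in
#' opposite directions and leave equality open; this choice is
#' configurable via `ties`). The threshold is recomputed from the data by
#' default, or may be supplied as a fixed constant (e.g. 67.1 g for eggs,
#' 50.0 g for chicks) to reproduce a published grouping on new cohorts.
#'
#' @param records Data frame of cohort records (see [simulate_cohort()]).
#' @param attribute Column to split on: `"weight"`, `"chick_weight"`,
#'   `"major_axis"`, or any numeric column present.
#' @param labels Length-2 character vector, lower then upper group name.
#'   Defaults to `c("L", "XL")` for egg weight and `c("Small", "Large")`
#'   for chick weight.
#' @param threshold Optional fixed threshold; computed by
#'   [midpoint_threshold()] when `NULL`.
#' @param ties `"upper"` (default) or `"lower"`: group receiving values
#'   exactly at the threshold.
#' @return Object of class `grouping_result`: list with `threshold`,
#'   `labels` (tibble `egg_id`, `value`, `group`), `counts`, `w_min`,
#'   `w_max`, `attribute`.
#' @export
assign_groups <- function(records, attribute = "weight", labels = NULL,
                          threshold = NULL, ties = c("upper", "lower")) {
  ties <- match.arg(ties)
  if (!attribute %in% names(records))
    stop("attribute '", attribute, "' not present in records",
         call. = FALSE)
  value <- records[[attribute]]
  ids <- if ("egg_id" %in% names(records)) records$egg_id
         else sprintf("rec%03d", seq_along(value))
  missing <- ids[!is.finite(value)]
  if (length(missing) > 0L)
    stop("missing '", attribute, "' for: ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (is.null(labels))
    labels <- if (attribute == "chick_weight") c("Small", "Large")
              else c("L", "XL")
  stopifnot(length(labels) == 2L)
  if (is.null(threshold)) threshold <- midpoint_threshold(value)
  upper <- if (ties == "upper") value >= threshold else value > threshold
  group <- ifelse(upper, labels[2L], labels[1L])
  counts <- setNames(c(sum(!upper), sum(upper)), labels)
  structure(
    list(threshold = threshold,
         labels = tibble::tibble(egg_id = ids, value = value,
                                 group = group),
         counts = counts,
         w_min = min(value), w_max = max(value),
         attribute = attribute),
    class = "grouping_result")
}

#' @export
print.grouping_result <- function(x, ...) {
  cat("<grouping_result> split on '", x$attribute,
      sprintf("' at %.4g (range %.4g-%.4g)\n",
              x$threshold, x$w_min, x$w_max), sep = "")
  print(x$counts)
  invisible(x)
}

#' Chick conversion ratio
#'
#' Hatchling chick weight divided by the initial egg weight: an efficiency
#' measure of how the egg's internal resources were converted into chick
#' mass.
#'
#' @param chick_weight Chick weight at hatch, grams.
#' @param egg_weight Initial egg weight, grams (> 0).
#' @return Dimensionless ratio (vectorized).
#' @export
conversion_ratio <- function(chick_weight, egg_weight) {
  if (any(!is.finite(egg_weight) | egg_weight <= 0))
    stop("egg_weight must be positive", call. = FALSE)
  chick_weight / egg_weight
}
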