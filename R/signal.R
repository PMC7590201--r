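#' Average output voltage of a sensor trace
#'
#' The opacity statistic uses the arithmetic mean of samples 11 through
#' 300 of the 300-sample record (divisor 290). The first 10 samples are
#' the auto-ranging settling ramp, used only to adjust the LED series
#' resistance, and never contribute.
#'
#' @param trace A `sensor_trace` (see [simulate_trace()]) or any list with
#'   a 300-element `samples` vector.
#' @return Average output voltage, V.
#' @export
compute_vavg <- function(trace) {
  s <- trace$samples
  if (length(s) != 300L)
    stop("malformed trace: expected exactly 300 samples, got ",
         length(s), call. = FALSE)
  mean(s[11:300])
}

#' Opacity of one egg-day measurement
#'
#' Opacity (mA/V) is the LED input current divided by the average output
#' voltage, `I_LED / V_avg`. It rises as the egg transmits less
#' near-infrared light, i.e. as the embryo and extra-embryonic structures
#' grow.
#'
#' @param trace A `sensor_trace`.
#' @return One-row tibble (an opacity measurement): `egg_id`, `day`,
#'   `i_led` (mA), `v_avg` (V), `opacity` (mA/V), `flag` (`"ok"` or
#'   `"out_of_range"`, propagated from auto-ranging).
#' @examples
#' tr <- simulate_trace("egg001", 10, opacity_true = 10)
#' compute_opacity(tr)
#' @export
compute_opacity <- function(trace) {
  v_avg <- compute_vavg(trace)
  if (!is.finite(v_avg) || v_avg <= 0)
    stop("invalid signal: average output voltage must be positive",
         call. = FALSE)
  tibble::tibble(
    egg_id = trace$egg_id,
    day = as.integer(trace$day),
    i_led = trace$i_led,
    v_avg = v_avg,
    opacity = trace$i_led / v_avg,
    flag = if (is.null(trace$flag)) "ok" else trace$flag)
}

#' Opacity table for a set of traces
#'
#' One measurement per (egg, day), sorted by egg then day. Out-of-range
#' traces are kept with their flag so cohort tables stay rectangular;
#' exclude `flag != "ok"` rows before curve fitting.
#'
#' @param traces List of `sensor_trace` objects.
#' @return Tibble with the [compute_opacity()] columns, one row per trace.
#' @export
opacity_table <- function(traces) {
  if (length(traces) == 0L)
    return(tibble::tibble(egg_id = character(), day = integer(),
                          i_led = numeric(), v_avg = numeric(),
                          opacity = numeric(), flag = character()))
  tab <- do.call(rbind, lapply(traces, compute_opacity))
  key <- paste(tab$egg_id, tab$day, sep = "/")
  if (anyDuplicated(key)) {
    dups <- unique(key[duplicated(key)])
    stop("duplicate (egg, day) measurements: ",
         paste(dups, collapse = ", "), call. = FALSE)
  }
  tab[order(tab$egg_id, tab$day), ]
}

#' Per-day group mean opacity series
#'
#' Convenience reduction of an opacity table to a mean trajectory,
#' excluding flagged measurements.
#'
#' @param opacity Tibble from [opacity_table()].
#' @return Tibble with `day` and mean `opacity`.
#' @export
mean_opacity_series <- function(opacity) {
  ok <- opacity[opacity$flag == "ok", ]
  agg <- tapply(ok$opacity, ok$day, mean)
  tibble::tibble(day = as.integer(names(agg)),
                 opacity = as.numeric(agg))
}
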