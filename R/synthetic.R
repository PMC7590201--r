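#' Configuration for a simulated egg cohort
#'
#' Encodes the grading window of a commercial broiler (ROSS 308 type)
#' hatching-egg cohort: egg weight 68 +/- 5 g, major axis 59.5 +/- 3 mm,
#' minor axis 46 +/- 1 mm, machine-vision shell color r = 0.375 +/- 0.015,
#' measured daily on incubation days 6--16. Opacity trajectories are
#' generated from a ground-truth growth curve scaled per egg by relative
#' mass, with per-measurement multiplicative jitter and additive voltage
#' noise in the simulated sensor.
#'
#' @param n_eggs Number of eggs (>= 1).
#' @param weight_mean,weight_sd Egg weight distribution, grams.
#' @param major_axis_mean,major_axis_sd Major axis, mm.
#' @param minor_axis_mean,minor_axis_sd Minor axis, mm.
#' @param shell_color_mean,shell_color_sd Dimensionless shell color r.
#' @param days Strictly increasing integer incubation days.
#' @param additive_sd Additive Gaussian noise on each voltage sample, V.
#' @param multiplicative_cv Coefficient of variation of the multiplicative
#'   jitter applied to each egg-day true opacity (fraction).
#' @param truth_model [growth_model()] giving the population opacity
#'   trajectory; defaults to the packaged L-size exponential curve.
#' @param conversion_mean,conversion_sd Chick/egg weight conversion ratio
#'   distribution (normal, truncated to (0.5, 0.9)).
#' @param seed Integer seed; a fixed seed makes every downstream draw
#'   byte-identical.
#' @return A validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_eggs = 46,
                          weight_mean = 68, weight_sd = 5,
                          major_axis_mean = 59.5, major_axis_sd = 3,
                          minor_axis_mean = 46, minor_axis_sd = 1,
                          shell_color_mean = 0.375, shell_color_sd = 0.015,
                          days = 6:16,
                          additive_sd = 0.02,
                          multiplicative_cv = 0.05,
                          truth_model = NULL,
                          conversion_mean = 0.72, conversion_sd = 0.03,
                          seed = 1L) {
  if (is.null(truth_model)) truth_model <- reference_curve("exponential", "L")
  cfg <- structure(
    list(n_eggs = as.integer(n_eggs),
         weight_mean = weight_mean, weight_sd = weight_sd,
         major_axis_mean = major_axis_mean, major_axis_sd = major_axis_sd,
         minor_axis_mean = minor_axis_mean, minor_axis_sd = minor_axis_sd,
         shell_color_mean = shell_color_mean, shell_color_sd = shell_color_sd,
         days = as.integer(days),
         additive_sd = additive_sd,
         multiplicative_cv = multiplicative_cv,
         truth_model = truth_model,
         conversion_mean = conversion_mean, conversion_sd = conversion_sd,
         seed = as.integer(seed)),
    class = "cohort_config")
  validate_cohort_config(cfg)
  cfg
}

validate_cohort_config <- function(cfg) {
  if (is.na(cfg$n_eggs) || cfg$n_eggs < 1L)
    stop("n_eggs must be >= 1", call. = FALSE)
  sds <- c(cfg$weight_sd, cfg$major_axis_sd, cfg$minor_axis_sd,
           cfg$shell_color_sd, cfg$additive_sd, cfg$multiplicative_cv,
           cfg$conversion_sd)
  if (any(sds < 0)) stop("all sd/cv values must be >= 0", call. = FALSE)
  d <- cfg$days
  if (length(d) < 1L || any(diff(d) <= 0))
    stop("days must be strictly increasing integers", call. = FALSE)
  stopifnot(inherits(cfg$truth_model, "growth_model"))
  invisible(cfg)
}

rnorm_trunc <- function(n, mean, sd, lower, upper) {
  # rejection sampling; the (0.5, 0.9) window is ~7 sd wide at defaults
  out <- rnorm(n, mean, sd)
  bad <- which(out <= lower | out >= upper)
  while (length(bad) > 0L) {
    out[bad] <- rnorm(length(bad), mean, sd)
    bad <- which(out <= lower | out >= upper)
  }
  out
}

#' Simulate a graded egg cohort
#'
#' Draws per-egg physical attributes from the configured normal
#' distributions and derives `size_scale = weight / weight_mean`, the
#' multiplier applied to the population opacity curve (larger eggs contain
#' more internal matter and transmit less light, hence higher opacity).
#' Chick weight is `conversion_ratio * egg_weight` with the ratio drawn
#' from a truncated normal.
#'
#' @param config A [cohort_config()].
#' @return Tibble with one row per egg: `egg_id`, `weight`, `major_axis`,
#'   `minor_axis`, `shell_color`, `size_scale`, `chick_weight`.
#' @export
simulate_cohort <- function(config) {
  validate_cohort_config(config)
  set.seed(config$seed)
  n <- config$n_eggs
  weight <- rnorm(n, config$weight_mean, config$weight_sd)
  major <- rnorm(n, config$major_axis_mean, config$major_axis_sd)
  minor <- rnorm(n, config$minor_axis_mean, config$minor_axis_sd)
  # enforce physical invariants: positive mass, major axis > minor axis
  bad <- which(weight <= 0 | major <= minor)
  while (length(bad) > 0L) {
    weight[bad] <- rnorm(length(bad), config$weight_mean, config$weight_sd)
    major[bad] <- rnorm(length(bad), config$major_axis_mean,
                        config$major_axis_sd)
    minor[bad] <- rnorm(length(bad), config$minor_axis_mean,
                        config$minor_axis_sd)
    bad <- which(weight <= 0 | major <= minor)
  }
  color <- rnorm(n, config$shell_color_mean, config$shell_color_sd)
  ratio <- rnorm_trunc(n, config$conversion_mean, config$conversion_sd,
                       0.5, 0.9)
  tibble::tibble(
    egg_id = sprintf("egg%03d", seq_len(n)),
    weight = weight,
    major_axis = major,
    minor_axis = minor,
    shell_color = color,
    size_scale = weight / config$weight_mean,
    chick_weight = ratio * weight)
}

#' Ground-truth opacity of one egg on one day
#'
#' The egg's `size_scale` times the population growth curve: opacity scales
#' linearly with relative egg mass.
#'
#' @param egg A one-row cohort record (anything with a `size_scale`
#'   element), or a bare numeric `size_scale`.
#' @param day Incubation day(s).
#' @param truth A [growth_model()].
#' @return Opacity in mA/V.
#' @export
true_opacity <- function(egg, day, truth) {
  scale <- if (is.numeric(egg)) egg else as.numeric(egg$size_scale)
  scale * eval_growth(truth, day)
}

#' LED drive-current steps of the auto-ranging NIR sensor
#'
#' Sixteen geometrically spaced currents spanning 0.73--96.15 mA, emulating
#' a constant-ratio ladder of series resistances selecting the LED drive
#' level.
#'
#' @return Numeric vector of 16 currents, mA, increasing.
#' @export
led_current_steps <- function() {
  exp(seq(log(0.73), log(96.15), length.out = 16L))
}

#' Simulate one raw sensor voltage trace
#'
#' Emulates the auto-ranging acquisition: the smallest LED current step
#' whose steady-state output voltage `I_LED / opacity` falls inside the
#' 3--9.7 V detector window is selected; if no step lands in the window the
#' nearest feasible step is used and the trace is flagged `out_of_range`.
#' The record is 9 s at 33.3 Hz, stored as exactly 300 samples: samples
#' 1--10 hold the auto-ranging settling ramp (never used downstream) and
#' samples 11--300 hold the steady-state voltage plus additive Gaussian
#' noise.
#'
#' @param egg_id Identifier carried into the trace.
#' @param day Incubation day.
#' @param opacity_true True opacity, mA/V (> 0).
#' @param additive_sd Additive voltage noise sd, V (0 for a noiseless
#'   trace).
#' @return A list of class `sensor_trace`: `egg_id`, `day`, `i_led` (mA),
#'   `samples` (300 voltages, V), `sample_rate` (Hz), `flag`
#'   (`"ok"` or `"out_of_range"`).
#' @export
simulate_trace <- function(egg_id, day, opacity_true, additive_sd = 0) {
  if (!is.finite(opacity_true) || opacity_true <= 0)
    stop("opacity_true must be positive", call. = FALSE)
  steps <- led_current_steps()
  v <- steps / opacity_true
  in_window <- v >= 3 & v <= 9.7
  if (any(in_window)) {
    i_led <- steps[which(in_window)[1L]]
    flag <- "ok"
  } else {
    # nearest feasible step: voltage closest to the window
    dist <- pmax(3 - v, v - 9.7, 0)
    i_led <- steps[which.min(dist)]
    flag <- "out_of_range"
  }
  v_steady <- i_led / opacity_true
  samples <- numeric(300L)
  samples[1:10] <- v_steady * seq(0.1, 1, length.out = 10L)  # settling ramp
  samples[11:300] <- v_steady
  if (additive_sd > 0)
    samples <- samples + rnorm(300L, 0, additive_sd)
  structure(
    list(egg_id = egg_id, day = as.integer(day), i_led = i_led,
         samples = samples, sample_rate = 33.3, flag = flag),
    class = "sensor_trace")
}

#' Simulate raw traces for a whole cohort
#'
#' For every egg and configured day, perturbs the egg's true opacity by
#' the multiplicative jitter and acquires one [simulate_trace()] with the
#' configured additive voltage noise.
#'
#' @param cohort Tibble from [simulate_cohort()].
#' @param config The same [cohort_config()].
#' @return List of `sensor_trace` objects, one per egg-day, ordered by egg
#'   then day.
#' @export
simulate_cohort_traces <- function(cohort, config) {
  validate_cohort_config(config)
  set.seed(config$seed + 1L)
  traces <- vector("list", nrow(cohort) * length(config$days))
  k <- 0L
  for (i in seq_len(nrow(cohort))) {
    for (d in config$days) {
      k <- k + 1L
      o_true <- true_opacity(cohort$size_scale[i], d, config$truth_model)
      jitter <- 1 + rnorm(1L, 0, config$multiplicative_cv)
      o_obs <- max(o_true * jitter, 1e-6)
      traces[[k]] <- simulate_trace(cohort$egg_id[i], d, o_obs,
                                    additive_sd = config$additive_sd)
    }
  }
  traces
}

#' Synthetic reference embryo-weight table
#'
#' A stand-in day-by-day embryo-weight trajectory for calibration work.
#' Chicken embryo mass over days 6--16 follows a Gompertz-shaped course;
#' the default synthetic curve `W(t) = 30 * exp(-13 * exp(-0.18 t))` grams
#' rises from about 0.36 g at day 6 to about 14.5 g at day 16, a realistic
#' range for broiler embryos. This table is synthetic: substitute a real
#' reference CSV (columns `day`, `embryo_weight`) to calibrate against
#' measured embryo weights.
#'
#' @param days Integer days (no duplicates).
#' @param curve Optional [growth_model()] evaluated in grams; defaults to
#'   the Gompertz stand-in above.
#' @return Tibble with columns `day`, `embryo_weight` (grams), strictly
#'   increasing in `day`.
#' @export
make_reference_table <- function(days = 6:16, curve = NULL) {
  days <- as.integer(days)
  if (length(days) == 0L) stop("days must be nonempty", call. = FALSE)
  if (anyDuplicated(days)) stop("duplicate days requested", call. = FALSE)
  days <- sort(days)
  if (is.null(curve))
    curve <- growth_model("gompertz", a = 13, b = 0.18, asymptote = 30)
  w <- eval_growth(curve, days)
  if (any(diff(w) <= 0))
    stop("reference weights must increase strictly with day", call. = FALSE)
  tibble::tibble(day = days, embryo_weight = w)
}
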