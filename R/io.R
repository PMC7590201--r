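#' Read and write pipeline tables
#'
#' Plain-CSV interchange for the pipeline's tables: cohorts, long-form raw
#' traces, opacity measurements, and reference embryo-weight tables.
#'
#' Column conventions:
#' \itemize{
#'   \item cohort: `egg_id, weight_g, major_axis_mm, minor_axis_mm,
#'     shell_color_r, chick_weight_g`
#'   \item traces (long form): `egg_id, day, i_led_mA, sample_index,
#'     v_out_V`
#'   \item opacity: `egg_id, day, i_led_mA, v_avg_V, opacity_mA_per_V,
#'     flag`
#'   \item reference: `day, embryo_weight_g`
#' }
#' @name ovogrowth-io
NULL

#' @param cohort Tibble from [simulate_cohort()].
#' @param path File path.
#' @rdname ovogrowth-io
#' @export
write_cohort_csv <- function(cohort, path) {
  out <- data.frame(egg_id = cohort$egg_id,
                    weight_g = cohort$weight,
                    major_axis_mm = cohort$major_axis,
                    minor_axis_mm = cohort$minor_axis,
                    shell_color_r = cohort$shell_color,
                    chick_weight_g = cohort$chick_weight)
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname ovogrowth-io
#' @export
read_cohort_csv <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  tibble::tibble(egg_id = tab$egg_id,
                 weight = tab$weight_g,
                 major_axis = tab$major_axis_mm,
                 minor_axis = tab$minor_axis_mm,
                 shell_color = tab$shell_color_r,
                 size_scale = tab$weight_g / 68,
                 chick_weight = tab$chick_weight_g)
}

#' @param traces List of `sensor_trace` objects.
#' @rdname ovogrowth-io
#' @export
write_traces_csv <- function(traces, path) {
  rows <- lapply(traces, function(tr)
    data.frame(egg_id = tr$egg_id, day = tr$day, i_led_mA = tr$i_led,
               sample_index = seq_along(tr$samples),
               v_out_V = tr$samples, flag = tr$flag))
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname ovogrowth-io
#' @export
read_traces_csv <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  keys <- unique(tab[, c("egg_id", "day")])
  lapply(seq_len(nrow(keys)), function(i) {
    sub <- tab[tab$egg_id == keys$egg_id[i] & tab$day == keys$day[i], ]
    sub <- sub[order(sub$sample_index), ]
    structure(
      list(egg_id = keys$egg_id[i], day = as.integer(keys$day[i]),
           i_led = sub$i_led_mA[1L], samples = sub$v_out_V,
           sample_rate = 33.3,
           flag = if ("flag" %in% names(sub)) sub$flag[1L] else "ok"),
      class = "sensor_trace")
  })
}

#' @param opacity Tibble from [opacity_table()].
#' @rdname ovogrowth-io
#' @export
write_opacity_csv <- function(opacity, path) {
  out <- data.frame(egg_id = opacity$egg_id, day = opacity$day,
                    i_led_mA = opacity$i_led, v_avg_V = opacity$v_avg,
                    opacity_mA_per_V = opacity$opacity,
                    flag = opacity$flag)
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname ovogrowth-io
#' @export
read_opacity_csv <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  tibble::tibble(egg_id = tab$egg_id, day = as.integer(tab$day),
                 i_led = tab$i_led_mA, v_avg = tab$v_avg_V,
                 opacity = tab$opacity_mA_per_V, flag = tab$flag)
}

#' @param reference Tibble from [make_reference_table()].
#' @rdname ovogrowth-io
#' @export
write_reference_csv <- function(reference, path) {
  out <- data.frame(day = reference$day,
                    embryo_weight_g = reference$embryo_weight)
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname ovogrowth-io
#' @export
read_reference_csv <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  tibble::tibble(day = as.integer(tab$day),
                 embryo_weight = tab$embryo_weight_g)
}

#' Read a cohort configuration from YAML
#'
#' The YAML keys mirror the [cohort_config()] arguments; `truth_model` may
#' be given as a mapping with `family`, `a`, `b`, `asymptote`, or as
#' `{reference: {family: ..., group: ...}}` to use a packaged curve.
#'
#' @param path YAML file path.
#' @return A [cohort_config()].
#' @export
read_cohort_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$truth_model)) {
    tm <- y$truth_model
    y$truth_model <- if (!is.null(tm$reference))
      reference_curve(tm$reference$family, tm$reference$group)
    else
      growth_model(tm$family, a = tm$a, b = tm$b, asymptote = tm$asymptote)
  }
  do.call(cohort_config, y)
}

#' Write a set of growth fits to JSON
#'
#' @param fit_set A [fit_all_growth()] result, or named list of fits.
#' @param path Output JSON path.
#' @export
write_fits_json <- function(fit_set, path) {
  fits <- if (inherits(fit_set, "growth_fit_set")) fit_set$fits else fit_set
  out <- lapply(fits, function(f) list(
    family = f$family,
    params = list(a = f$model$a, b = f$model$b,
                  asymptote = f$model$asymptote),
    rmse = f$rmse, r2 = f$r2, n_points = f$n_points,
    converged = f$converged))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
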