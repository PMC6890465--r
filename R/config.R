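#' Run configuration for rhythm analysis
#'
#' Bundles the tunable parameters of the periodogram / phase pipeline.
#' Defaults follow the screening conventions of FaasX-style analysis:
#' trial periods 18-30 h on a 0.1 h grid (the resolution at which screen
#' period histograms are binned), chi-squared significance level 0.05, and
#' the rhythmicity thresholds power > 20 and width > 1.5 h.
#'
#' @param period_min,period_max,period_step trial-period grid in hours.
#' @param alpha significance level of the chi-squared line (0 < alpha < 1).
#' @param power_min rhythmicity threshold on peak power (strict).
#' @param width_min rhythmicity threshold on peak width, hours (strict).
#' @param bin_hours analysis bin length in hours; raw counts are aggregated
#'   to this resolution before the periodogram so every trial period is an
#'   integer number of bins (0.1 h makes the default grid exact).
#' @param smoothing_hours width of the moving average used for peak-phase
#'   extraction, hours.
#' @param morning_window,morning_subwindow,evening_window,evening_subwindow
#'   ZT intervals (hours) for the anticipation phase scores: the score is
#'   the percent of window activity falling in the subwindow.
#' @param seed optional integer seed recorded with the configuration.
#' @return a list of class `rhythm_config`.
#' @export
#' @examples
#' cfg <- rhythm_config(alpha = 0.01)
#' cfg$alpha
rhythm_config <- function(period_min = 18, period_max = 30, period_step = 0.1,
                          alpha = 0.05, power_min = 20, width_min = 1.5,
                          bin_hours = 0.1, smoothing_hours = 4,
                          morning_window = c(17.5, 23.5),
                          morning_subwindow = c(20.5, 23.5),
                          evening_window = c(5.5, 11.5),
                          evening_subwindow = c(8.5, 11.5),
                          seed = NULL) {
  check_that(period_step > 0, "period_step must be positive")
  check_that(period_min < period_max, "period_min must be below period_max")
  check_that(alpha > 0 && alpha < 1, "alpha must lie in (0, 1)")
  check_that(bin_hours > 0, "bin_hours must be positive")
  structure(list(period_min = period_min, period_max = period_max,
                 period_step = period_step, alpha = alpha,
                 power_min = power_min, width_min = width_min,
                 bin_hours = bin_hours, smoothing_hours = smoothing_hours,
                 morning_window = morning_window,
                 morning_subwindow = morning_subwindow,
                 evening_window = evening_window,
                 evening_subwindow = evening_subwindow,
                 seed = seed),
            class = "rhythm_config")
}

#' Read a run configuration from a YAML file
#'
#' Any field of [rhythm_config()] may appear in the file; unspecified
#' fields keep their defaults.  Unknown fields are an error, so typos do
#' not silently fall back to defaults.
#'
#' @param path path to a YAML file.
#' @return a `rhythm_config` list.
#' @export
read_run_config <- function(path) {
  check_that(file.exists(path), paste0("config file not found: ", path))
  vals <- yaml::read_yaml(path)
  known <- names(formals(rhythm_config))
  unknown <- setdiff(names(vals), known)
  check_that(length(unknown) == 0,
             paste0("unknown config field(s): ", paste(unknown, collapse = ", ")))
  do.call(rhythm_config, vals)
}
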