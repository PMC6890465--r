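# Internal helpers shared across modules.

#' Circular difference mapped to (-cycle/2, +cycle/2]
#'
#' Difference `a - b` on a circle of circumference `cycle`, mapped to the
#' half-open interval (-cycle/2, cycle/2].  A difference of exactly half a
#' cycle is reported as +cycle/2.
#'
#' @param a,b times in hours.
#' @param cycle cycle length in hours (default 24).
#' @return numeric vector of signed differences in hours.
#' @export
#' @examples
#' circular_diff(2, 23)        # +3
#' circular_diff(12, 0)        # +12 (half-cycle convention)
circular_diff <- function(a, b, cycle = 24) {
  d <- (a - b) %% cycle
  ifelse(d > cycle / 2, d - cycle, d)
}

# stopifnot-style check with a readable message
check_that <- function(ok, msg) {
  if (!isTRUE(ok)) abort(msg)
  invisible(TRUE)
}

# infer the bin length (hours) of an activity tibble from its time column
infer_bin_hours <- function(activity) {
  tt <- sort(unique(activity$time))
  check_that(length(tt) >= 2, "activity data must contain at least two time bins")
  dt <- diff(tt)
  bin <- min(dt)
  check_that(bin > 0, "time values must be strictly increasing within a fly")
  bin
}

# columns every activity tibble must carry
activity_columns <- c("fly_id", "genotype", "time", "counts",
                      "light", "temperature", "protocol", "day")

#' Validate a tidy activity tibble
#'
#' Checks the per-fly-bin activity layout used throughout the package:
#' one row per fly and time bin with columns `fly_id`, `genotype`, `time`
#' (hours from experiment start, bin start), `counts` (non-negative integer
#' beam breaks, `NA` = missing bin), `light` (`"ON"`/`"OFF"`),
#' `temperature` (degrees C), `protocol` (`"LD"`, `"DD"` or `"TC"`) and
#' `day` (1-based protocol day index, non-decreasing in time).
#'
#' @param activity a data frame in the tidy activity layout.
#' @return the input, invisibly, as a tibble.
#' @export
validate_activity <- function(activity) {
  activity <- tibble::as_tibble(activity)
  missing_cols <- setdiff(activity_columns, names(activity))
  check_that(length(missing_cols) == 0,
             paste0("activity data lacks column(s): ",
                    paste(missing_cols, collapse = ", ")))
  cnt <- activity$counts
  check_that(all(is.na(cnt) | cnt >= 0), "counts must be non-negative")
  check_that(all(activity$light %in% c("ON", "OFF")),
             'light must be "ON" or "OFF"')
  check_that(all(activity$protocol %in% c("LD", "DD", "TC")),
             'protocol must be one of "LD", "DD", "TC"')
  ord <- order(activity$fly_id, activity$time)
  day_ok <- all(unlist(tapply(activity$day[ord], activity$fly_id[ord],
                              function(d) all(diff(d) >= 0))))
  check_that(day_ok, "day index must be non-decreasing in time within a fly")
  invisible(activity)
}
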