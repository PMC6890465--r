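# Chi-squared (Sokolove-Bushell) periodogram and rhythmicity calling.

# Core statistic for one series x (analysis bins, NA = missing) at one
# trial period of p_bins bins.  Uses the first K = floor(n/p) complete
# cycles; missing bins drop out of the column means and of N.  The
# statistic is the ANOVA-normalized form
#   Qp = N * sum_c K_c (M_c - Mbar)^2 / sum_i (x_i - Mbar)^2,
# which is ~ chi-squared with P - 1 df under the null.
qp_single <- function(x, p_bins) {
  k <- length(x) %/% p_bins
  if (k < 2) return(NA_real_)
  m <- matrix(x[seq_len(k * p_bins)], nrow = p_bins)
  kc <- rowSums(!is.na(m))
  mc <- rowMeans(m, na.rm = TRUE)
  use <- kc > 0
  n <- sum(kc)
  gm <- sum(m, na.rm = TRUE) / n
  sst <- sum((m - gm)^2, na.rm = TRUE)
  if (sst == 0) return(NA_real_)
  n * sum(kc[use] * (mc[use] - gm)^2) / sst
}

# peak power / width bookkeeping on a computed spectrum
peak_stats <- function(period, qp, sig, step) {
  excess <- qp - sig
  if (all(is.na(excess))) {
    return(list(peak_period = NA_real_, power = NA_real_, width = 0))
  }
  i <- which.max(excess)
  above <- !is.na(excess) & excess > 0
  if (!above[i]) {
    return(list(peak_period = period[i], power = excess[i], width = 0))
  }
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  j <- which(starts <= i & ends >= i & r$values)
  list(peak_period = period[i], power = excess[i],
       width = r$lengths[j] * step)
}

#' Chi-squared periodogram of locomotor activity
#'
#' Computes the Sokolove-Bushell chi-squared periodogram per fly over a
#' grid of trial periods, together with the FaasX-style peak summary:
#' `peak_period` (global maximum of Qp minus the significance line),
#' `power` (Qp at the peak minus the chi-squared `1 - alpha` quantile with
#' P - 1 df) and `width` (hours of the contiguous grid span containing the
#' peak where Qp exceeds the line).  Counts are first aggregated to
#' `config$bin_hours` so every trial period is an integer number of bins;
#' for each trial period only complete cycles are folded (the incomplete
#' final cycle is truncated) and missing bins are excluded pairwise.
#'
#' A fly whose analysis window has zero variance (all-missing or constant)
#' yields a non-rhythmic row with `undefined = TRUE` rather than an error.
#'
#' @param activity tidy activity tibble (any number of flies).
#' @param config a [rhythm_config()].
#' @param window protocol phase to analyze: `"DD"` (default), `"LD"`,
#'   `"TC"`, or `"all"`.
#' @param days optional day indices (within the whole experiment) to
#'   restrict the window further.
#' @return tibble with one row per fly: `fly_id`, `genotype`,
#'   `peak_period`, `power`, `width`, `rhythmic`, `undefined`,
#'   `n_bins_used`, `bin_hours`, and a `spectrum` list-column of tibbles
#'   (`period`, `qp`, `df`, `sig`).
#' @export
#' @examples
#' sim <- simulate_locomotor_cohort(n_flies = 2, days_ld = 0, days_dd = 3,
#'                                  tau = 24, seed = 1)
#' pg <- chi_squared_periodogram(sim$activity)
#' pg[, c("fly_id", "peak_period", "power", "rhythmic")]
chi_squared_periodogram <- function(activity, config = rhythm_config(),
                                    window = "DD", days = NULL) {
  validate_activity(activity)
  act <- aggregate_bins(activity, config$bin_hours)
  if (!identical(window, "all")) {
    act <- dplyr::filter(act, .data$protocol == window)
  }
  if (!is.null(days)) act <- dplyr::filter(act, .data$day %in% days)
  check_that(nrow(act) > 0, "selected window contains no data")

  step <- config$period_step
  periods <- seq(config$period_min, config$period_max, by = step)
  p_bins <- periods / config$bin_hours
  check_that(all(abs(p_bins - round(p_bins)) < 1e-8),
             "every trial period must be an integer number of analysis bins")
  p_bins <- as.integer(round(p_bins))
  dfs <- p_bins - 1L
  sig <- qchisq(1 - config$alpha, dfs)

  one_fly <- function(d) {
    d <- dplyr::arrange(d, .data$time)
    x <- as.numeric(d$counts)
    check_that(length(x) >= 2 * max(p_bins),
               paste0("window for fly ", d$fly_id[1], " is shorter than two",
                      " cycles of the longest trial period"))
    if (all(is.na(x)) || stats::var(x, na.rm = TRUE) == 0) {
      return(tibble::tibble(
        fly_id = d$fly_id[1], genotype = d$genotype[1],
        peak_period = NA_real_, power = NA_real_, width = NA_real_,
        rhythmic = FALSE, undefined = TRUE,
        n_bins_used = sum(!is.na(x)), bin_hours = config$bin_hours,
        spectrum = list(tibble::tibble(period = periods, qp = NA_real_,
                                       df = dfs, sig = sig))))
    }
    qp <- vapply(p_bins, function(p) qp_single(x, p), numeric(1))
    pk <- peak_stats(periods, qp, sig, step)
    tibble::tibble(
      fly_id = d$fly_id[1], genotype = d$genotype[1],
      peak_period = pk$peak_period, power = pk$power, width = pk$width,
      rhythmic = call_rhythmicity(power = pk$power, width = pk$width,
                                  power_min = config$power_min,
                                  width_min = config$width_min),
      undefined = FALSE, n_bins_used = sum(!is.na(x)),
      bin_hours = config$bin_hours,
      spectrum = list(tibble::tibble(period = periods, qp = qp, df = dfs,
                                     sig = sig)))
  }
  out <- act |>
    dplyr::group_by(.data$fly_id) |>
    dplyr::group_map(~ one_fly(.x |> dplyr::mutate(fly_id = .y$fly_id))) |>
    dplyr::bind_rows()
  class(out) <- c("periodogram_df", class(out))
  out
}

#' Call rhythmicity from periodogram power and width
#'
#' A fly is rhythmic iff `power > power_min` and `width > width_min`, both
#' strict inequalities (the FaasX-style screening criteria power > 20,
#' width > 1.5 h).  Undefined results (`NA` power) are non-rhythmic.
#'
#' @param result optional periodogram tibble (as returned by
#'   [chi_squared_periodogram()]); alternatively give `power` and `width`
#'   directly.
#' @param power,width numeric vectors of peak power and width (hours).
#' @param power_min,width_min thresholds.
#' @return logical vector.
#' @export
#' @examples
#' call_rhythmicity(power = c(25, 20, 50), width = c(2, 2, 1))
call_rhythmicity <- function(result = NULL, power = NULL, width = NULL,
                             power_min = 20, width_min = 1.5) {
  if (!is.null(result)) {
    power <- result$power
    width <- result$width
  }
  ok <- !is.na(power) & !is.na(width) & power > power_min & width > width_min
  unname(ok)
}

#' Per-genotype rhythm summary
#'
#' Summarizes a periodogram table the way screen tables report genotypes:
#' flies tested, percent rhythmic, mean period +/- SEM over rhythmic
#' flies, and mean power +/- SEM.
#'
#' @param result a tibble from [chi_squared_periodogram()].
#' @return tibble with one row per genotype.
#' @export
summarize_rhythms <- function(result) {
  sem <- function(x) if (length(x) > 1) sd(x) / sqrt(length(x)) else NA_real_
  result |>
    dplyr::group_by(.data$genotype) |>
    dplyr::summarise(
      n = dplyr::n(),
      pct_rhythmic = 100 * mean(.data$rhythmic),
      mean_period = mean(.data$peak_period[.data$rhythmic]),
      sem_period = sem(.data$peak_period[.data$rhythmic]),
      mean_power = mean(.data$power[.data$rhythmic]),
      sem_power = sem(.data$power[.data$rhythmic]),
      .groups = "drop")
}
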