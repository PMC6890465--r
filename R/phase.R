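# Eduction profiles and behavioral phase quantification.

#' Educe an average-day activity profile
#'
#' Folds multiday activity at `cycle_length` and averages: for each fly,
#' the per-phase-bin mean over the selected days; across flies, the mean
#' and SEM per phase bin.  All flies are included regardless of
#' rhythmicity (phase analyses deliberately use every fly), unless the
#' caller filters beforehand.
#'
#' @param activity tidy activity tibble.
#' @param days optional experiment day indices to include.
#' @param protocol optional protocol selector (`"LD"`, `"DD"`, `"TC"`).
#' @param cycle_length folding period, hours; must be an integer number
#'   of bins.
#' @return an `eduction_profile` tibble: `phase` (bin start, hours in
#'   [0, cycle)), `mean_activity`, `sem`, `n_flies`; attributes
#'   `cycle_length`, `bin_hours`, `days_included`.
#' @export
#' @examples
#' sim <- simulate_locomotor_cohort(n_flies = 4, days_ld = 2, days_dd = 0,
#'                                  seed = 1)
#' prof <- educe_profile(sim$activity, protocol = "LD")
#' head(prof)
educe_profile <- function(activity, days = NULL, protocol = NULL,
                          cycle_length = 24) {
  validate_activity(activity)
  act <- tibble::as_tibble(activity)
  if (!is.null(protocol)) act <- dplyr::filter(act, .data$protocol %in% !!protocol)
  if (!is.null(days)) act <- dplyr::filter(act, .data$day %in% !!days)
  check_that(nrow(act) > 0, "eduction selection is empty")
  bin <- infer_bin_hours(act)
  nb <- cycle_length / bin
  check_that(abs(nb - round(nb)) < 1e-8,
             "cycle_length must be an integer number of bins")
  nb <- as.integer(round(nb))

  per_fly <- act |>
    dplyr::mutate(phase_bin = as.integer(round((.data$time %% cycle_length) / bin)) %% nb) |>
    dplyr::group_by(.data$fly_id, .data$phase_bin) |>
    dplyr::summarise(fly_mean = mean(.data$counts, na.rm = TRUE),
                     .groups = "drop")
  sem <- function(x) if (length(x) > 1) sd(x) / sqrt(length(x)) else 0
  out <- per_fly |>
    dplyr::group_by(.data$phase_bin) |>
    dplyr::summarise(mean_activity = mean(.data$fly_mean, na.rm = TRUE),
                     sem = sem(.data$fly_mean[!is.na(.data$fly_mean)]),
                     n_flies = sum(!is.na(.data$fly_mean)),
                     .groups = "drop") |>
    dplyr::mutate(phase = .data$phase_bin * bin, .before = 1) |>
    dplyr::select(-"phase_bin") |>
    dplyr::arrange(.data$phase)
  attr(out, "cycle_length") <- cycle_length
  attr(out, "bin_hours") <- bin
  attr(out, "days_included") <- days %||% sort(unique(act$day))
  class(out) <- c("eduction_profile", class(out))
  out
}

# build an eduction_profile directly from a vector (used in tests and by
# callers that already have an averaged day)
#' Construct an eduction profile from per-bin values
#'
#' @param mean_activity per-bin mean activity over one cycle.
#' @param cycle_length cycle length, hours.
#' @param sem optional per-bin SEM (default 0).
#' @param n_flies number of flies the profile averages.
#' @return an `eduction_profile` tibble.
#' @export
as_eduction_profile <- function(mean_activity, cycle_length = 24, sem = 0,
                                n_flies = 1) {
  nb <- length(mean_activity)
  out <- tibble::tibble(phase = (seq_len(nb) - 1) * cycle_length / nb,
                        mean_activity = as.numeric(mean_activity),
                        sem = rep_len(sem, nb),
                        n_flies = n_flies)
  attr(out, "cycle_length") <- cycle_length
  attr(out, "bin_hours") <- cycle_length / nb
  class(out) <- c("eduction_profile", class(out))
  out
}

# centered circular moving average; window rounded to an odd number of bins
circular_ma <- function(x, window_bins) {
  n <- length(x)
  w <- max(1L, as.integer(round(window_bins)))
  if (w %% 2 == 0) w <- w + 1L
  if (w == 1L) return(x)
  h <- (w - 1L) %/% 2L
  idx <- outer(seq_len(n), -h:h, function(i, k) ((i - 1 + k) %% n) + 1)
  rowMeans(matrix(x[idx], nrow = n))
}

#' Peak phase of an eduction profile
#'
#' Smooths the profile with a centered circular moving average (default
#' 4 h, the standard treatment before reading activity peaks) and returns
#' the argmax within a search window.  Ties are broken by the earliest
#' time and flagged; an all-equal smoothed profile yields an undefined
#' phase.
#'
#' After smoothing, the grid argmax is refined by the vertex of a local
#' quadratic fit over +/- 1 h (the standard sub-bin refinement of a peak
#' on a sampled curve; the moving average flattens the peak top, so the
#' raw argmax alone is noisier than the data warrant).  The refinement
#' never moves the peak by more than one smoothing half-width and is
#' exact for symmetric peaks; set `refine = FALSE` for the plain argmax.
#'
#' @param profile an `eduction_profile`.
#' @param smoothing_hours moving-average width, hours (must be less than
#'   half the cycle).
#' @param search_window optional `c(from, to)` in cycle hours; may wrap
#'   (e.g. `c(20, 4)`).  Default: the full cycle.
#' @param refine apply the local quadratic vertex refinement.
#' @return one-row tibble: `peak_time`, `smoothing_hours`, `tie`,
#'   `undefined`.
#' @export
peak_phase <- function(profile, smoothing_hours = 4, search_window = NULL,
                       refine = TRUE) {
  check_that(inherits(profile, "eduction_profile"),
             "profile must come from educe_profile()/as_eduction_profile()")
  cycle <- attr(profile, "cycle_length")
  bin <- attr(profile, "bin_hours")
  check_that(smoothing_hours < cycle / 2,
             "smoothing window must be below half the cycle")
  sm <- circular_ma(profile$mean_activity, smoothing_hours / bin)
  phase <- profile$phase
  keep <- rep(TRUE, length(phase))
  if (!is.null(search_window)) {
    a <- search_window[1] %% cycle
    b <- search_window[2] %% cycle
    keep <- if (a <= b) phase >= a & phase < b else phase >= a | phase < b
    check_that(any(keep), "search window contains no bins")
  }
  vals <- sm[keep]
  ph <- phase[keep]
  if (diff(range(vals)) == 0) {
    return(tibble::tibble(peak_time = NA_real_,
                          smoothing_hours = smoothing_hours,
                          tie = FALSE, undefined = TRUE))
  }
  at_max <- which(vals == max(vals))
  peak <- ph[at_max[1]]
  tie <- length(at_max) > 1
  if (refine && !tie) {
    i0 <- which(phase == peak)
    n <- length(sm)
    h <- max(1L, as.integer(round(1 / bin)))
    idx <- ((i0 - 1 + (-h:h)) %% n) + 1
    xx <- (-h:h) * bin
    yy <- sm[idx]
    cf <- coef(lm(yy ~ xx + I(xx^2)))
    if (is.finite(cf[3]) && cf[3] < 0) {
      v <- -cf[2] / (2 * cf[3])
      v <- max(min(v, h * bin), -h * bin)
      peak <- (peak + v) %% cycle
    }
  }
  tibble::tibble(peak_time = peak,
                 smoothing_hours = smoothing_hours,
                 tie = tie, undefined = FALSE)
}

#' Light-pulse phase shift between two cohorts
#'
#' Educes the pulsed and unpulsed groups over the same post-pulse days,
#' reads each group's smoothed activity peak, and returns
#' `peak(unpulsed) - peak(pulsed)` as a circular difference in
#' (-cycle/2, +cycle/2].  Positive values are phase advances, negative
#' values delays.
#'
#' @param pulsed,unpulsed tidy activity tibbles for the two groups.
#' @param days post-pulse day indices analyzed in both groups.
#' @param protocol protocol window (default `"DD"`).
#' @param cycle_length folding period, hours.
#' @param smoothing_hours moving-average width for peak reading.
#' @param search_window peak search window (default the subjective
#'   evening half-cycle, `c(6, 18)`).
#' @return one-row tibble: `shift` (hours), the two peak times, and the
#'   settings used.
#' @export
phase_shift <- function(pulsed, unpulsed, days = NULL, protocol = "DD",
                        cycle_length = 24, smoothing_hours = 4,
                        search_window = c(6, 18)) {
  pp <- educe_profile(pulsed, days = days, protocol = protocol,
                      cycle_length = cycle_length)
  up <- educe_profile(unpulsed, days = days, protocol = protocol,
                      cycle_length = cycle_length)
  pk_p <- peak_phase(pp, smoothing_hours, search_window)
  pk_u <- peak_phase(up, smoothing_hours, search_window)
  check_that(!pk_p$undefined && !pk_u$undefined,
             "peak phase undefined in one of the groups")
  tibble::tibble(shift = circular_diff(pk_u$peak_time, pk_p$peak_time,
                                       cycle_length),
                 peak_unpulsed = pk_u$peak_time,
                 peak_pulsed = pk_p$peak_time,
                 cycle_length = cycle_length,
                 smoothing_hours = smoothing_hours)
}

#' Evening peak phase relative to an internal control
#'
#' Circular difference (test minus control) of the smoothed evening
#' activity peaks of two eduction profiles from the same run, mapped to
#' (-cycle/2, +cycle/2].  Negative values mean the test genotype's
#' evening peak is advanced relative to the control.
#'
#' @param test,internal_control `eduction_profile` objects sharing the
#'   same cycle structure.
#' @param search_window evening-peak search window, cycle hours (default
#'   `c(6, 18)`, the thermophase half of a temperature cycle whose
#'   cold-to-warm transition defines time 0).
#' @param smoothing_hours moving-average width.
#' @return one-row tibble: `relative_phase` (hours), both peak times.
#' @export
relative_evening_phase <- function(test, internal_control,
                                   search_window = c(6, 18),
                                   smoothing_hours = 4) {
  cyc_t <- attr(test, "cycle_length")
  cyc_c <- attr(internal_control, "cycle_length")
  check_that(identical(cyc_t, cyc_c), "profiles must share a cycle length")
  pk_t <- peak_phase(test, smoothing_hours, search_window)
  pk_c <- peak_phase(internal_control, smoothing_hours, search_window)
  check_that(!pk_t$undefined && !pk_c$undefined,
             "evening peak undefined in test or control profile")
  tibble::tibble(relative_phase = circular_diff(pk_t$peak_time,
                                                pk_c$peak_time, cyc_t),
                 peak_test = pk_t$peak_time,
                 peak_control = pk_c$peak_time)
}

#' Morning and evening anticipation phase scores
#'
#' Morning score: percent of the activity between ZT 17.5-23.5 that falls
#' in ZT 20.5-23.5.  Evening score: percent of the activity between
#' ZT 5.5-11.5 that falls in ZT 8.5-11.5.  Lower scores mean activity
#' rises earlier (an advanced phase).  Window edges are snapped to the
#' nearest bin edge; a zero denominator gives an `NA` score with the
#' `undefined` flag set.
#'
#' @param profile an `eduction_profile` indexed in ZT.
#' @param config a [rhythm_config()] carrying the window definitions.
#' @return one-row tibble: `morning_score`, `evening_score`,
#'   `morning_undefined`, `evening_undefined` (scores in percent).
#' @export
#' @examples
#' flat <- as_eduction_profile(rep(5, 240))
#' anticipation_scores(flat)   # both scores 50
anticipation_scores <- function(profile, config = rhythm_config()) {
  check_that(inherits(profile, "eduction_profile"),
             "profile must be an eduction_profile")
  bin <- attr(profile, "bin_hours")
  cycle <- attr(profile, "cycle_length")
  win_sum <- function(w) {
    a <- (round(w[1] / bin) * bin) %% cycle
    b <- (round(w[2] / bin) * bin) %% cycle
    keep <- if (a <= b) profile$phase >= a & profile$phase < b
            else profile$phase >= a | profile$phase < b
    sum(profile$mean_activity[keep])
  }
  score <- function(window, subwindow) {
    den <- win_sum(window)
    if (den <= 0) return(c(NA_real_, TRUE))
    c(100 * win_sum(subwindow) / den, FALSE)
  }
  m <- score(config$morning_window, config$morning_subwindow)
  e <- score(config$evening_window, config$evening_subwindow)
  tibble::tibble(morning_score = m[1], evening_score = e[1],
                 morning_undefined = as.logical(m[2]),
                 evening_undefined = as.logical(e[2]))
}

#' Day-to-day peak drift across entrained days
#'
#' Reads the smoothed evening peak separately for each selected day and
#' reports the maximum pairwise circular drift.  Drift above
#' `tolerance_hours` (default 0.5 h) warns that the cohort may not have
#' reached a stable phase relationship with the entraining cycle; it is
#' a warning, not an error.
#'
#' @param activity tidy activity tibble.
#' @param days day indices to compare.
#' @param protocol protocol selector (default `"TC"`).
#' @param cycle_length cycle, hours.
#' @param search_window,smoothing_hours passed to [peak_phase()].
#' @param tolerance_hours drift that triggers the warning.
#' @return tibble with one row per day (`day`, `peak_time`) plus
#'   attribute `max_drift`.
#' @export
entrainment_stability <- function(activity, days, protocol = "TC",
                                  cycle_length = 24,
                                  search_window = c(6, 18),
                                  smoothing_hours = 4,
                                  tolerance_hours = 0.5) {
  peaks <- purrr::map_dfr(days, function(d) {
    prof <- educe_profile(activity, days = d, protocol = protocol,
                          cycle_length = cycle_length)
    pk <- peak_phase(prof, smoothing_hours, search_window)
    tibble::tibble(day = d, peak_time = pk$peak_time)
  })
  drift <- max(abs(circular_diff(rep(peaks$peak_time, each = nrow(peaks)),
                                 rep(peaks$peak_time, nrow(peaks)),
                                 cycle_length)), na.rm = TRUE)
  if (is.finite(drift) && drift > tolerance_hours) {
    warn(sprintf("day-to-day peak drift %.2f h exceeds %.2f h: phase may not be stable",
                 drift, tolerance_hours))
  }
  attr(peaks, "max_drift") <- drift
  peaks
}
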