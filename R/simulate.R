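# Synthetic-data generators.  Each generator stores its ground truth so the
# matching analysis module has a parameter-recovery test surface.

# bimodal circadian activity template on [0, 24), peak-normalized to 1.
# Sum of two wrapped-Gaussian bumps (morning, evening); sd = width / 2.
circadian_template <- function(phase, morning_phase = 0, evening_phase = 12,
                               peak_width = 2) {
  s <- peak_width / 2
  bump <- function(mu) {
    d <- circular_diff(phase, mu, 24)
    exp(-0.5 * (d / s)^2)
  }
  b <- bump(morning_phase) + bump(evening_phase)
  ref <- seq(0, 24, by = 0.01)
  bmax <- max(exp(-0.5 * (circular_diff(ref, morning_phase, 24) / s)^2) +
                exp(-0.5 * (circular_diff(ref, evening_phase, 24) / s)^2))
  b / bmax
}

#' Simulate a cohort of fly activity recordings
#'
#' Per-fly beam-break counts are drawn from an inhomogeneous Poisson
#' process with rate `baseline_rate * (1 + amplitude * template(phase))`,
#' where the template is a bimodal (morning/evening) wrapped-Gaussian
#' profile on the circadian day.  During LD days the phase runs at the
#' 24 h entraining cycle and masking is applied (multiplicative night
#' suppression plus an additive startle bump in the 2 bins after each
#' light transition); during temperature-cycle (TC) days the same applies
#' with the thermophase (warm half, hours 0-12 of the cycle) playing the
#' role of day; in DD the phase free-runs at `tau`.  A fraction of flies
#' is arrhythmic (amplitude forced to 0; they are alive and active).
#'
#' Protocol order is `days_ld` LD days, then `days_tc` TC days, then
#' `days_dd` DD days.  Time 0 is lights-on of the first LD day, so ZT0 =
#' lights-on; in DD, circadian time continues from the projected
#' lights-on of the last entrained day.
#'
#' @param n_flies number of flies.
#' @param tau free-running period in hours (18-32).
#' @param amplitude modulation depth in `[0, 1]`.
#' @param morning_phase,evening_phase peak centers, circadian hours.
#' @param peak_width bump width (2 x Gaussian sd), hours.
#' @param baseline_rate baseline activity, counts per hour.
#' @param arrhythmic_fraction fraction of flies with amplitude 0.
#' @param masking additive startle amplitude, multiples of the baseline.
#' @param night_suppression multiplicative activity factor during the
#'   dark (LD) or cold (TC) half-cycle.
#' @param days_ld,days_tc,days_dd protocol segment lengths in days.
#' @param ld_period entraining cycle length, hours.
#' @param warm,cold TC temperatures, degrees C.
#' @param constant_temperature temperature outside TC days, degrees C.
#' @param dd_phase_shift phase shift applied at DD onset, circadian hours
#'   (positive = advance; used to emulate light-pulse resetting).
#' @param bin_minutes recording bin length, minutes.
#' @param genotype genotype label.
#' @param seed integer seed; identical seeds give bit-identical output.
#' @return a list with `activity` (tidy activity tibble) and `truth`
#'   (one row per fly: `fly_id`, `rhythmic`, `tau`, peak phases,
#'   `dd_phase_shift`).
#' @export
#' @examples
#' sim <- simulate_locomotor_cohort(n_flies = 2, days_ld = 1, days_dd = 1,
#'                                  seed = 1)
#' head(sim$activity)
#' sim$truth
simulate_locomotor_cohort <- function(n_flies = 16, tau = 24.1,
                                      amplitude = 0.8,
                                      morning_phase = 0, evening_phase = 12,
                                      peak_width = 2, baseline_rate = 40,
                                      arrhythmic_fraction = 0, masking = 2,
                                      night_suppression = 0.4,
                                      days_ld = 3, days_tc = 0, days_dd = 5,
                                      ld_period = 24, warm = 29, cold = 20,
                                      constant_temperature = 25,
                                      dd_phase_shift = 0, bin_minutes = 6,
                                      genotype = "sim", seed = NULL) {
  check_that(amplitude >= 0 && amplitude <= 1, "amplitude must be in [0, 1]")
  check_that(arrhythmic_fraction >= 0 && arrhythmic_fraction <= 1,
             "arrhythmic_fraction must be in [0, 1]")
  check_that(tau >= 18 && tau <= 32, "tau must lie in [18, 32] hours")
  check_that(days_ld + days_tc + days_dd >= 1, "protocol must contain days")
  if (!is.null(seed)) set.seed(seed)

  bin <- bin_minutes / 60
  n_ent_days <- days_ld + days_tc
  total_h <- 24 * (n_ent_days + days_dd)
  t0 <- seq(0, total_h - bin, by = bin)      # bin starts
  tc <- t0 + bin / 2                         # bin centers
  day <- as.integer(floor(t0 / 24) + 1)
  protocol <- rep("DD", length(t0))
  protocol[day <= days_ld] <- "LD"
  protocol[day > days_ld & day <= n_ent_days] <- "TC"

  zt <- tc %% ld_period
  light <- ifelse(protocol == "LD" & zt < ld_period / 2, "ON", "OFF")
  temperature <- rep(constant_temperature, length(t0))
  temperature[protocol == "TC"] <-
    ifelse(zt[protocol == "TC"] < ld_period / 2, warm, cold)

  t_ent_end <- 24 * n_ent_days
  phase <- ifelse(tc < t_ent_end, tc %% 24,
                  ((t_ent_end %% 24) + (tc - t_ent_end) * 24 / tau +
                     dd_phase_shift) %% 24)

  entrained <- protocol %in% c("LD", "TC")
  is_dark <- (protocol == "LD" & light == "OFF") |
    (protocol == "TC" & temperature == cold)
  transition <- entrained & c(FALSE, diff(is_dark) != 0)
  startle <- transition | c(FALSE, head(transition, -1))  # 2 bins

  n_arr <- round(arrhythmic_fraction * n_flies)
  arrhythmic <- rep(FALSE, n_flies)
  if (n_arr > 0) arrhythmic[sample.int(n_flies, n_arr)] <- TRUE

  template <- circadian_template(phase, morning_phase, evening_phase,
                                 peak_width)
  fly_ids <- sprintf("%s_f%03d", genotype, seq_len(n_flies))
  base <- tibble::tibble(time = t0, light = light,
                         temperature = temperature,
                         protocol = protocol, day = day)
  activity <- purrr::map_dfr(seq_len(n_flies), function(i) {
    amp_i <- if (arrhythmic[i]) 0 else amplitude
    rate <- baseline_rate * (1 + amp_i * template)
    rate[is_dark] <- rate[is_dark] * night_suppression
    rate[startle] <- rate[startle] + masking * baseline_rate
    dplyr::mutate(base, fly_id = fly_ids[i], genotype = genotype,
                  counts = rpois(length(rate), rate * bin), .before = 1)
  })
  activity <- activity[, activity_columns]
  truth <- tibble::tibble(fly_id = fly_ids, genotype = genotype,
                          rhythmic = !arrhythmic, tau = tau,
                          morning_phase = morning_phase,
                          evening_phase = evening_phase,
                          dd_phase_shift = dd_phase_shift)
  list(activity = activity, truth = truth)
}

#' Simulate a luciferase reporter time series
#'
#' `y(t) = mesor + amplitude * exp(-damping * t) * cos(2*pi*(t - phase)/tau)`
#' plus Gaussian noise, sampled on a regular grid.
#'
#' @param tau period, hours (> 0).
#' @param damping exponential damping rate, per hour (>= 0).
#' @param mesor,amplitude midline and cosine amplitude, counts.
#' @param phase acrophase, hours.
#' @param noise_sd Gaussian noise sd, counts.
#' @param sampling_minutes sampling interval, minutes.
#' @param duration_hours total duration, hours (>= 2 * tau).
#' @param seed integer seed.
#' @return tibble with `time` (hours) and `signal` (counts); the generating
#'   parameters are attached as attribute `"truth"`.
#' @export
simulate_luciferase_series <- function(tau = 24, damping = 0.02,
                                       mesor = 100, amplitude = 30,
                                       phase = 6, noise_sd = 0,
                                       sampling_minutes = 30,
                                       duration_hours = 48, seed = NULL) {
  check_that(tau > 0, "tau must be positive")
  check_that(damping >= 0, "damping must be non-negative")
  check_that(duration_hours >= 2 * tau,
             "duration must cover at least two periods")
  if (!is.null(seed)) set.seed(seed)
  t <- seq(0, duration_hours, by = sampling_minutes / 60)
  y <- mesor + amplitude * exp(-damping * t) * cos(2 * pi * (t - phase) / tau)
  if (noise_sd > 0) y <- y + rnorm(length(t), 0, noise_sd)
  out <- tibble::tibble(time = t, signal = y)
  attr(out, "truth") <- list(tau = tau, damping = damping, mesor = mesor,
                             amplitude = amplitude, phase = phase,
                             noise_sd = noise_sd)
  out
}

#' Simulate an RNAi screen dataset
#'
#' Per-fly free-running periods are
#' `base_period + collection offset + driver offset (+ 40D offset where
#' applicable) + injected hit effect + N(0, fly_sd)`.
#' Defaults mirror the batch structure of a fly RNAi period screen:
#' TRiP-collection backgrounds run 0.3 h shorter than VDRC; the GAL4
#' drivers add a dominant ~0.8 h lengthening; KK lines with a 40D-locus
#' insertion add ~0.6 h with the PDF-neuron driver (a smaller effect with
#' the tim driver).
#'
#' @param n_lines named counts of lines per collection; names from
#'   `c("TRiP", "VDRC-GD", "VDRC-KK", "VDRC-KK-40D")`.
#' @param drivers drivers each line is crossed to.
#' @param base_period wild-type background period, hours.
#' @param trip_offset TRiP-vs-VDRC background offset, hours.
#' @param driver_offset named per-driver lengthening, hours.
#' @param offset_40d named per-driver extra lengthening of 40D-KK lines.
#' @param hits optional tibble (`line_id`, `delta`) of injected period
#'   effects in hours, applied in every cross of that line.
#' @param fly_sd per-fly period SD, hours (> 0).
#' @param flies_per_cross flies tested per line x driver cross (>= 1).
#' @param rhythmic_prob probability a tested fly is rhythmic (only
#'   rhythmic flies contribute periods).
#' @param power_mean,power_sd distribution of per-fly periodogram power.
#' @param seed integer seed.
#' @return list with `flies` (one row per rhythmic-or-not fly), `lines`
#'   (line x driver summaries via [summarize_screen()]) and `truth`
#'   (injected hits).
#' @export
simulate_screen_dataset <- function(n_lines = c("TRiP" = 60, "VDRC-GD" = 60,
                                                "VDRC-KK" = 60,
                                                "VDRC-KK-40D" = 20),
                                    drivers = c("TD2", "PD2"),
                                    base_period = 24.1, trip_offset = -0.3,
                                    driver_offset = c(TD2 = 0.8, PD2 = 0.8,
                                                      none = 0),
                                    offset_40d = c(TD2 = 0.2, PD2 = 0.6,
                                                   none = 0),
                                    hits = NULL, fly_sd = 0.5,
                                    flies_per_cross = 6,
                                    rhythmic_prob = 0.85,
                                    power_mean = 50, power_sd = 12,
                                    seed = NULL) {
  check_that(flies_per_cross >= 1, "flies_per_cross must be >= 1")
  check_that(fly_sd > 0, "fly_sd must be positive")
  valid <- c("TRiP", "VDRC-GD", "VDRC-KK", "VDRC-KK-40D")
  check_that(all(names(n_lines) %in% valid),
             paste0("collections must be among: ", paste(valid, collapse = ", ")))
  if (!is.null(seed)) set.seed(seed)

  line_tbl <- purrr::map_dfr(names(n_lines), function(col) {
    k <- n_lines[[col]]
    if (k == 0) return(NULL)
    tibble::tibble(
      line_id = sprintf("%s-%04d", gsub("VDRC-", "", col), seq_len(k)),
      gene = sprintf("gene_%s_%03d", gsub("[^A-Za-z0-9]", "", col), seq_len(k)),
      collection = col)
  })
  if (!is.null(hits)) {
    check_that(all(hits$line_id %in% line_tbl$line_id),
               "hits reference unknown line_id values")
  }
  delta <- setNames(rep(0, nrow(line_tbl)), line_tbl$line_id)
  if (!is.null(hits)) delta[hits$line_id] <- hits$delta

  crosses <- tidyr::expand_grid(line_tbl, driver = drivers)
  flies <- crosses |>
    dplyr::mutate(
      mu = base_period +
        ifelse(.data$collection == "TRiP", trip_offset, 0) +
        driver_offset[.data$driver] +
        ifelse(.data$collection == "VDRC-KK-40D", offset_40d[.data$driver], 0) +
        delta[.data$line_id]) |>
    tidyr::uncount(flies_per_cross, .id = "fly") |>
    dplyr::mutate(
      fly_id = sprintf("%s_%s_f%02d", .data$line_id, .data$driver, .data$fly),
      rhythmic = stats::runif(dplyr::n()) < rhythmic_prob,
      period = ifelse(.data$rhythmic, rnorm(dplyr::n(), .data$mu, fly_sd), NA_real_),
      power = ifelse(.data$rhythmic, rnorm(dplyr::n(), power_mean, power_sd), NA_real_)) |>
    dplyr::select("line_id", "gene", "collection", "driver", "fly_id",
                  "rhythmic", "period", "power")
  truth <- tibble::tibble(line_id = names(delta)[delta != 0],
                          delta = unname(delta[delta != 0]))
  list(flies = flies, lines = summarize_screen(flies), truth = truth)
}

#' Simulate a qPCR Ct table
#'
#' For every sample the reference target amplifies at `reference_ct`; each
#' assayed target amplifies at `reference_ct + base_delta_ct - log2(ratio)`
#' so that the programmed `ratio` (fold change relative to a sample with
#' ratio 1) is exactly recoverable by [delta_delta_ct()] when noise is 0.
#' Technical replicates get independent Gaussian Ct noise.
#'
#' @param fold_changes tibble with columns `sample_id`, `target`, `ratio`
#'   (> 0) and optionally `timepoint` (CT hours).
#' @param ct_noise_sd per-replicate Ct noise sd, cycles.
#' @param reference_target reference gene name.
#' @param reference_ct reference-gene Ct, cycles.
#' @param base_delta_ct target-minus-reference Ct at ratio 1; scalar or a
#'   vector named by target.
#' @param n_replicates technical replicates per sample x target.
#' @param seed integer seed.
#' @return tibble (`sample_id`, `timepoint`, `target`, `replicate`, `ct`)
#'   with the programmed fold changes attached as attribute `"truth"`.
#' @export
simulate_qpcr_plate <- function(fold_changes, ct_noise_sd = 0,
                                reference_target = "RpL32",
                                reference_ct = 15, base_delta_ct = 5,
                                n_replicates = 3, seed = NULL) {
  fold_changes <- tibble::as_tibble(fold_changes)
  check_that(all(c("sample_id", "target", "ratio") %in% names(fold_changes)),
             "fold_changes needs columns sample_id, target, ratio")
  check_that(all(fold_changes$ratio > 0), "ratios must be positive")
  if (!is.null(seed)) set.seed(seed)
  if (!"timepoint" %in% names(fold_changes)) fold_changes$timepoint <- NA_real_

  bdc <- function(target) {
    if (length(base_delta_ct) == 1 && is.null(names(base_delta_ct))) {
      rep(base_delta_ct, length(target))
    } else {
      unname(base_delta_ct[target])
    }
  }
  samples <- dplyr::distinct(fold_changes, .data$sample_id, .data$timepoint)
  ref <- dplyr::mutate(samples, target = reference_target, mean_ct = reference_ct)
  tgt <- dplyr::mutate(fold_changes,
                       mean_ct = reference_ct + bdc(.data$target) -
                         log2(.data$ratio)) |>
    dplyr::select("sample_id", "timepoint", "target", "mean_ct")
  out <- dplyr::bind_rows(ref, tgt) |>
    tidyr::uncount(n_replicates, .id = "replicate") |>
    dplyr::mutate(ct = .data$mean_ct +
                    if (ct_noise_sd > 0) rnorm(dplyr::n(), 0, ct_noise_sd) else 0) |>
    dplyr::select("sample_id", "timepoint", "target", "replicate", "ct")
  attr(out, "truth") <- fold_changes
  out
}
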