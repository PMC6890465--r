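# 2^-ddCt relative quantification and standard-curve efficiency QC.

#' Relative expression by the 2^-ddCt method
#'
#' Technical replicates are averaged on the Ct scale; per sample and
#' target, `dCt = mean(target Ct) - mean(reference Ct)`;
#' `ddCt = dCt - dCt(calibrator)`; `rel_expr = 2^(-ddCt)`.  When several
#' calibrator samples are given their dCt values are averaged per target.
#' An optional `rescale` group divides all `rel_expr` of a target by that
#' group's mean, so that, e.g., a whole knockdown time course averages to
#' 1 and control and knockdown series share one scale.
#'
#' Replicate dispersion (SD of the Ct triplicates) is reported per
#' sample x target and flagged when above `dispersion_max` cycles.
#'
#' @param measurements tibble with columns `sample_id`, `target`,
#'   `replicate`, `ct` and optionally `timepoint`.
#' @param reference reference (housekeeping) target name, default
#'   `"RpL32"`.
#' @param calibrator character vector of calibrator `sample_id`(s).
#' @param rescale optional character vector of `sample_id`s whose mean
#'   relative expression is divided out per target (`NULL` = none).
#' @param dispersion_max replicate-SD flag threshold, cycles.
#' @return tibble with one row per sample x target (reference excluded):
#'   `sample_id`, `timepoint`, `target`, `n_replicates`, `ct_sd`,
#'   `high_dispersion`, `delta_ct`, `delta_delta_ct`, `rel_expr`, plus
#'   attributes `calibrator` and `rescale` describing the normalization.
#' @export
#' @examples
#' plate <- simulate_qpcr_plate(tibble::tibble(
#'   sample_id = c("ctl", "kd"), target = "tim-cold", ratio = c(1, 2)))
#' delta_delta_ct(plate, calibrator = "ctl")
delta_delta_ct <- function(measurements, reference = "RpL32",
                           calibrator, rescale = NULL,
                           dispersion_max = 0.5) {
  m <- tibble::as_tibble(measurements)
  check_that(all(c("sample_id", "target", "ct") %in% names(m)),
             "measurements needs columns sample_id, target, ct")
  check_that(all(is.finite(m$ct) & m$ct > 0), "Ct values must be finite and > 0")
  if (!"timepoint" %in% names(m)) m$timepoint <- NA_real_
  check_that(reference %in% m$target,
             paste0("reference target not present: ", reference))

  by_st <- m |>
    dplyr::group_by(.data$sample_id, .data$timepoint, .data$target) |>
    dplyr::summarise(mean_ct = mean(.data$ct),
                     ct_sd = if (dplyr::n() > 1) sd(.data$ct) else 0,
                     n_replicates = dplyr::n(), .groups = "drop")
  check_that(all(by_st$n_replicates >= 1), "zero replicates for a sample")

  refs <- by_st |>
    dplyr::filter(.data$target == reference) |>
    dplyr::select("sample_id", ref_ct = "mean_ct")
  tgts <- dplyr::filter(by_st, .data$target != reference)
  no_ref <- setdiff(unique(tgts$sample_id), refs$sample_id)
  check_that(length(no_ref) == 0,
             paste0("sample(s) lack the reference target: ",
                    paste(no_ref, collapse = ", ")))

  dct <- tgts |>
    dplyr::left_join(refs, by = "sample_id") |>
    dplyr::mutate(delta_ct = .data$mean_ct - .data$ref_ct)
  check_that(all(calibrator %in% dct$sample_id),
             paste0("calibrator sample(s) not found: ",
                    paste(setdiff(calibrator, dct$sample_id), collapse = ", ")))
  cal <- dct |>
    dplyr::filter(.data$sample_id %in% calibrator) |>
    dplyr::group_by(.data$target) |>
    dplyr::summarise(cal_dct = mean(.data$delta_ct), .groups = "drop")
  no_cal <- setdiff(unique(dct$target), cal$target)
  check_that(length(no_cal) == 0,
             paste0("calibrator has no measurement for target(s): ",
                    paste(no_cal, collapse = ", ")))

  out <- dct |>
    dplyr::left_join(cal, by = "target") |>
    dplyr::mutate(delta_delta_ct = .data$delta_ct - .data$cal_dct,
                  rel_expr = 2^(-.data$delta_delta_ct),
                  high_dispersion = .data$ct_sd > dispersion_max)
  if (!is.null(rescale)) {
    check_that(all(rescale %in% out$sample_id),
               "rescale group contains unknown sample_id values")
    out <- out |>
      dplyr::group_by(.data$target) |>
      dplyr::mutate(rel_expr = .data$rel_expr /
                      mean(.data$rel_expr[.data$sample_id %in% rescale])) |>
      dplyr::ungroup()
  }
  out <- out |>
    dplyr::select("sample_id", "timepoint", "target", "n_replicates",
                  "ct_sd", "high_dispersion", "delta_ct", "delta_delta_ct",
                  "rel_expr")
  attr(out, "calibrator") <- calibrator
  attr(out, "rescale") <- rescale %||% "none"
  out
}

#' Amplification efficiency from a standard curve
#'
#' Least-squares line of mean Ct against log10 input amount over a
#' dilution series; efficiency `E = 10^(-1/slope) - 1` (1 = perfect
#' doubling per cycle, slope -3.3219).  Reports R-squared and a pass
#' flag for `E` within `[0.9, 1.1]` -- a QC report, not a correction.
#'
#' @param dilution_series data frame with columns `log10_amount` and
#'   `ct` (mean Ct per dilution point).
#' @return one-row tibble: `slope`, `intercept`, `efficiency`,
#'   `r_squared`, `n_points`, `passes`.
#' @export
#' @examples
#' std <- tibble::tibble(log10_amount = c(0, -1, -2),
#'                       ct = 20 + 3.3219 * c(0, 1, 2))
#' standard_curve_efficiency(std)
standard_curve_efficiency <- function(dilution_series) {
  d <- tibble::as_tibble(dilution_series)
  check_that(all(c("log10_amount", "ct") %in% names(d)),
             "dilution_series needs columns log10_amount, ct")
  check_that(nrow(d) >= 3, "need at least 3 dilution points")
  check_that(length(unique(d$log10_amount)) >= 2,
             "dilution points must have at least 2 distinct amounts")
  check_that(diff(range(d$log10_amount)) >= 2,
             "dilution series must span at least 2 log10 units")
  fit <- lm(ct ~ log10_amount, data = d)
  slope <- unname(coef(fit)[2])
  eff <- 10^(-1 / slope) - 1
  r2 <- suppressWarnings(summary(fit)$r.squared)  # noiseless series fit exactly
  tibble::tibble(slope = slope, intercept = unname(coef(fit)[1]),
                 efficiency = eff, r_squared = r2, n_points = nrow(d),
                 passes = eff >= 0.9 & eff <= 1.1)
}
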