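# ggplot2 views of the pipeline's result objects.

#' Plot chi-squared periodograms
#'
#' Spectrum per fly with the chi-squared significance line dashed.
#'
#' @param object a tibble from [chi_squared_periodogram()].
#' @param flies optional subset of `fly_id`s to draw.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.periodogram_df <- function(object, flies = NULL, ...) {
  if (!is.null(flies)) object <- dplyr::filter(object, .data$fly_id %in% flies)
  spec <- object |>
    dplyr::select("fly_id", "spectrum") |>
    tidyr::unnest("spectrum")
  ggplot2::ggplot(spec, ggplot2::aes(x = .data$period)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$qp), linewidth = 0.4) +
    ggplot2::geom_line(ggplot2::aes(y = .data$sig), linetype = "dashed",
                       colour = "red3", linewidth = 0.3) +
    ggplot2::facet_wrap(~fly_id) +
    ggplot2::labs(x = "trial period (h)", y = expression(Q[p]),
                  title = "Chi-squared periodogram") +
    ggplot2::theme_minimal()
}

#' Plot an eduction profile
#'
#' Average-day activity with a SEM ribbon; the light/temperature phase
#' structure of the cycle is not drawn (profiles carry no environment).
#'
#' @param object an `eduction_profile`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.eduction_profile <- function(object, ...) {
  cycle <- attr(object, "cycle_length")
  ggplot2::ggplot(object, ggplot2::aes(x = .data$phase,
                                       y = .data$mean_activity)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean_activity - .data$sem,
                                      ymax = .data$mean_activity + .data$sem),
                         alpha = 0.25) +
    ggplot2::geom_line() +
    ggplot2::scale_x_continuous(breaks = seq(0, cycle, by = 6)) +
    ggplot2::labs(x = "phase (h)", y = "mean activity (counts/bin)",
                  title = "Eduction profile") +
    ggplot2::theme_minimal()
}

#' Plot a damped cosinor fit
#'
#' @param object a `cosinor_fit`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.cosinor_fit <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$time)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$signal), size = 0.6,
                        alpha = 0.6) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "blue3") +
    ggplot2::labs(x = "time (h)", y = "luminescence (counts)",
                  title = sprintf("Damped cosinor: tau = %.2f h",
                                  object$coefficients["tau"])) +
    ggplot2::theme_minimal()
}

#' Screen period histogram with 2-SD cutoffs
#'
#' Line mean periods at 0.1 h bins, faceted by stratum panel, coloured by
#' driver, with the stratum cutoffs dashed -- the standard view of a
#' stratified period screen.
#'
#' @param records line-level screen tibble.
#' @param cutoffs output of [compute_cutoffs()].
#' @param binwidth histogram bin width, hours.
#' @return a ggplot.
#' @export
plot_screen_histogram <- function(records, cutoffs, binwidth = 0.1) {
  recs <- records |>
    dplyr::mutate(stratum = screen_stratum(.data$collection, .data$driver)) |>
    dplyr::filter(!is.na(.data$mean_period))
  cuts <- tidyr::pivot_longer(cutoffs, c("low_cut", "high_cut"),
                              names_to = "side", values_to = "cut")
  ggplot2::ggplot(recs, ggplot2::aes(x = .data$mean_period,
                                     fill = .data$driver)) +
    ggplot2::geom_histogram(binwidth = binwidth, position = "identity",
                            alpha = 0.6) +
    ggplot2::geom_vline(data = cuts,
                        ggplot2::aes(xintercept = .data$cut),
                        linetype = "dashed", na.rm = TRUE) +
    ggplot2::facet_wrap(~stratum, scales = "free_y") +
    ggplot2::labs(x = "line mean period (h)", y = "lines per bin",
                  title = "Screen period distribution with 2-SD cutoffs") +
    ggplot2::theme_minimal()
}

#' Plot relative expression time courses
#'
#' @param rel output of [delta_delta_ct()].
#' @param group optional column name used to colour/group lines
#'   (e.g. a genotype column joined onto the result).
#' @return a ggplot.
#' @export
plot_relative_expression <- function(rel, group = NULL) {
  aes <- if (is.null(group)) {
    ggplot2::aes(x = .data$timepoint, y = .data$rel_expr)
  } else {
    ggplot2::aes(x = .data$timepoint, y = .data$rel_expr,
                 colour = .data[[group]], group = .data[[group]])
  }
  ggplot2::ggplot(rel, aes) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~target, scales = "free_y") +
    ggplot2::labs(x = "circadian time (h)",
                  y = expression(2^{-Delta * Delta * C[t]}),
                  title = "Relative expression") +
    ggplot2::theme_minimal()
}
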