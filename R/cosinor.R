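# Exponentially damped cosinor fitting for luciferase reporter rhythms.

# linear sub-fit of (M, a, b) at fixed (tau, gamma):
# y ~ M + exp(-g t) (a cos wt + b sin wt)
cosinor_linear <- function(t, y, tau, gamma) {
  w <- 2 * pi / tau
  X <- cbind(1, exp(-gamma * t) * cos(w * t), exp(-gamma * t) * sin(w * t))
  fit <- stats::lm.fit(X, y)
  rss <- sum(fit$residuals^2)
  list(coef = c(M = unname(fit$coefficients[1]),
                a = unname(fit$coefficients[2]),
                b = unname(fit$coefficients[3]),
                g = gamma, tau = tau),
       rss = rss)
}

#' Fit an exponentially damped cosinor
#'
#' Least-squares fit of
#' `y(t) = M + A * exp(-gamma * t) * cos(2*pi*(t - phi)/tau)`
#' to a luminescence trace, by multi-start nonlinear least squares:
#' `tau` is initialized on a coarse grid over `tau_bounds` (step
#' `tau_step`) crossed with a small set of damping starts; `(M, A, phi)`
#' come from an exact linear sub-fit at each start; the best starts are
#' refined with bounded Levenberg-Marquardt and the lowest-RSS local
#' optimum is returned.  The internal parameterization
#' `a*cos + b*sin` makes the returned amplitude non-negative and the
#' acrophase unique in `[0, tau)` by construction.
#'
#' The default window is the first 48 h (the first two days of constant
#' darkness, where reporter oscillations are still strong before they
#' damp out).
#'
#' @param data data frame with time and signal columns, or `NULL` when
#'   `time`/`signal` vectors are given directly.
#' @param time,signal column names (tidy-select, defaults `time`,
#'   `signal`) or, with `data = NULL`, numeric vectors.
#' @param window `c(from, to)` hours of data used for the fit.
#' @param tau_bounds allowed period range, hours.
#' @param tau_step coarse grid step for period starts, hours.
#' @param gamma_starts damping starts, per hour.
#' @param fix_gamma optional fixed damping (0 gives the classical
#'   undamped cosinor).
#' @param detrend remove a linear trend before fitting (off by default).
#' @param n_refine number of best starts refined with the full nonlinear
#'   optimizer.
#' @return an object of class `cosinor_fit`: coefficients `mesor`,
#'   `amplitude`, `damping`, `tau`, `acrophase`, plus `rss`, `converged`,
#'   `n`, the window, and fitted values.  `converged` is `FALSE` when the
#'   optimizer hit the period/damping bounds or the iteration cap, or the
#'   series was flat.
#' @export
#' @examples
#' lux <- simulate_luciferase_series(tau = 24, damping = 0.02, seed = 1)
#' fit <- fit_damped_cosinor(lux)
#' tidy(fit)
fit_damped_cosinor <- function(data = NULL, time = NULL, signal = NULL,
                               window = c(0, 48), tau_bounds = c(18, 30),
                               tau_step = 0.5,
                               gamma_starts = c(0, 0.02, 0.05),
                               fix_gamma = NULL, detrend = FALSE,
                               n_refine = 5) {
  if (!is.null(data)) {
    check_that(is.data.frame(data), "data must be a data frame")
    tcol <- if (is.null(time)) "time" else time
    ycol <- if (is.null(signal)) "signal" else signal
    t <- data[[tcol]]
    y <- data[[ycol]]
  } else {
    t <- time
    y <- signal
  }
  check_that(is.numeric(t) && is.numeric(y) && length(t) == length(y),
             "time and signal must be numeric vectors of equal length")
  keep <- !is.na(t) & !is.na(y) & t >= window[1] & t <= window[2]
  t <- t[keep]
  y <- y[keep]
  span <- diff(range(t))
  check_that(span >= 1.5 * tau_bounds[1],
             "window must contain at least 1.5 cycles of the shortest trial period")
  check_that(median(diff(sort(t))) <= 2,
             "sampling interval must be at most 2 h")
  t0 <- t - min(t)   # fit on a local clock; acrophase reported on input clock
  toff <- min(t)

  flat_result <- function() {
    structure(list(coefficients = c(mesor = mean(y), amplitude = NA_real_,
                                    damping = NA_real_, tau = NA_real_,
                                    acrophase = NA_real_),
                   rss = 0, converged = FALSE, n = length(y),
                   window = window, tau_bounds = tau_bounds,
                   data = tibble::tibble(time = t, signal = y,
                                         fitted = mean(y))),
              class = "cosinor_fit")
  }
  if (length(unique(y)) == 1) return(flat_result())

  gammas <- if (is.null(fix_gamma)) gamma_starts else fix_gamma
  taus <- seq(tau_bounds[1], tau_bounds[2], by = tau_step)
  starts <- tidyr::expand_grid(tau = taus, gamma = gammas)
  lin <- purrr::pmap(starts, function(tau, gamma) cosinor_linear(t0, y, tau, gamma))
  start_rss <- vapply(lin, function(f) f$rss, numeric(1))
  best <- order(start_rss)[seq_len(min(n_refine, length(lin)))]

  refine <- function(st) {
    df <- data.frame(t = t0, y = y)
    if (is.null(fix_gamma)) {
      fit <- try(minpack.lm::nlsLM(
        y ~ M + exp(-g * t) * (a * cos(2 * pi * t / tau) +
                                 b * sin(2 * pi * t / tau)),
        data = df, start = as.list(st$coef),
        lower = c(M = -Inf, a = -Inf, b = -Inf, g = 0, tau = tau_bounds[1]),
        upper = c(M = Inf, a = Inf, b = Inf, g = 2, tau = tau_bounds[2]),
        control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
    } else {
      g0 <- fix_gamma
      fit <- try(minpack.lm::nlsLM(
        y ~ M + exp(-g0 * t) * (a * cos(2 * pi * t / tau) +
                                  b * sin(2 * pi * t / tau)),
        data = df, start = as.list(st$coef[c("M", "a", "b", "tau")]),
        lower = c(M = -Inf, a = -Inf, b = -Inf, tau = tau_bounds[1]),
        upper = c(M = Inf, a = Inf, b = Inf, tau = tau_bounds[2]),
        control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
    }
    if (inherits(fit, "try-error")) return(NULL)
    cf <- coef(fit)
    if (!is.null(fix_gamma)) cf <- c(cf[c("M", "a", "b")], g = fix_gamma,
                                     tau = unname(cf["tau"]))
    list(coef = cf, rss = sum(stats::residuals(fit)^2),
         finished = fit$convInfo$isConv %||% TRUE)
  }
  cands <- purrr::compact(purrr::map(best, function(i) refine(lin[[i]])))
  # fall back to the best linear sub-fit if every refinement failed
  if (length(cands) == 0) {
    i <- which.min(start_rss)
    cands <- list(list(coef = lin[[i]]$coef, rss = lin[[i]]$rss,
                       finished = FALSE))
  }
  rss <- vapply(cands, function(f) f$rss, numeric(1))
  bestfit <- cands[[which.min(rss)]]
  cf <- bestfit$coef
  A <- sqrt(cf[["a"]]^2 + cf[["b"]]^2)
  tau_hat <- cf[["tau"]]
  # acrophase on the original time axis
  phi_local <- (atan2(cf[["b"]], cf[["a"]]) * tau_hat / (2 * pi)) %% tau_hat
  phi <- (phi_local + toff) %% tau_hat
  eps <- 1e-6
  at_bounds <- tau_hat <= tau_bounds[1] + eps || tau_hat >= tau_bounds[2] - eps ||
    (is.null(fix_gamma) && cf[["g"]] >= 2 - eps)
  w <- 2 * pi / tau_hat
  fitted <- cf[["M"]] + exp(-cf[["g"]] * t0) *
    (cf[["a"]] * cos(w * t0) + cf[["b"]] * sin(w * t0))
  structure(list(
    coefficients = c(mesor = cf[["M"]], amplitude = A, damping = cf[["g"]],
                     tau = tau_hat, acrophase = phi),
    rss = min(rss), converged = isTRUE(bestfit$finished) && !at_bounds,
    n = length(y), window = window, tau_bounds = tau_bounds,
    start_rss = start_rss,
    data = tibble::tibble(time = t, signal = y, fitted = fitted)),
    class = "cosinor_fit")
}

#' @export
print.cosinor_fit <- function(x, ...) {
  cf <- x$coefficients
  cat("Damped cosinor fit (", x$n, " points, window ",
      x$window[1], "-", x$window[2], " h)\n", sep = "")
  cat(sprintf("  period  %.3f h   damping %.4f /h   amplitude %.2f\n",
              cf["tau"], cf["damping"], cf["amplitude"]))
  cat(sprintf("  mesor   %.2f     acrophase %.2f h   RSS %.3g   converged: %s\n",
              cf["mesor"], cf["acrophase"], x$rss, x$converged))
  invisible(x)
}

#' Tidy a damped cosinor fit
#'
#' @param x a `cosinor_fit`.
#' @param ... unused.
#' @return `tidy()`: tibble of `term`/`estimate`; `glance()`: one-row
#'   model summary.
#' @export
tidy.cosinor_fit <- function(x, ...) {
  tibble::tibble(term = names(x$coefficients),
                 estimate = unname(x$coefficients))
}

#' @rdname tidy.cosinor_fit
#' @export
glance.cosinor_fit <- function(x, ...) {
  tibble::tibble(tau = unname(x$coefficients["tau"]),
                 damping = unname(x$coefficients["damping"]),
                 rss = x$rss,
                 sigma = sqrt(x$rss / max(1, x$n - 5)),
                 n = x$n, converged = x$converged)
}

#' Fit damped cosinors to a plate of wells
#'
#' Per-well fits (one well = one trace, typically a few flies pooled),
#' returning a tibble of coefficients per well.
#'
#' @param data long tibble with columns `well`, `time`, `signal` and
#'   optionally `genotype`.
#' @param ... passed to [fit_damped_cosinor()].
#' @return tibble with one row per well: coefficients plus `rss`,
#'   `converged`, `n`.
#' @export
fit_cosinor_wells <- function(data, ...) {
  check_that(all(c("well", "time", "signal") %in% names(data)),
             "data needs columns well, time, signal")
  data |>
    dplyr::group_by(.data$well) |>
    dplyr::group_map(function(d, key) {
      fit <- fit_damped_cosinor(d, ...)
      cf <- fit$coefficients
      tibble::tibble(well = key$well,
                     genotype = if ("genotype" %in% names(d)) d$genotype[1] else NA_character_,
                     mesor = cf[["mesor"]], amplitude = cf[["amplitude"]],
                     damping = cf[["damping"]], tau = cf[["tau"]],
                     acrophase = cf[["acrophase"]], rss = fit$rss,
                     converged = fit$converged, n = fit$n)
    }) |>
    dplyr::bind_rows()
}

#' Per-genotype luciferase period summary
#'
#' Genotype period = mean over converged wells, with SEM and well counts.
#'
#' @param fits output of [fit_cosinor_wells()].
#' @return tibble with one row per genotype.
#' @export
summarize_luciferase <- function(fits) {
  sem <- function(x) if (length(x) > 1) sd(x) / sqrt(length(x)) else NA_real_
  fits |>
    dplyr::group_by(.data$genotype) |>
    dplyr::summarise(n_wells = dplyr::n(),
                     n_converged = sum(.data$converged),
                     mean_tau = mean(.data$tau[.data$converged]),
                     sem_tau = sem(.data$tau[.data$converged]),
                     mean_damping = mean(.data$damping[.data$converged]),
                     .groups = "drop")
}

#' Read a plate-reader CSV export
#'
#' Expects a `time` column (hours) followed by one column per well;
#' returns the long tidy layout used by [fit_cosinor_wells()].
#'
#' @param path CSV file path.
#' @return tibble with `well`, `time`, `signal`.
#' @export
read_plate_csv <- function(path) {
  check_that(file.exists(path), paste0("file not found: ", path))
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  check_that("time" %in% names(df),
             "plate CSV must have a 'time' column (hours)")
  tidyr::pivot_longer(df, -"time", names_to = "well",
                      values_to = "signal") |>
    dplyr::arrange(.data$well, .data$time)
}
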