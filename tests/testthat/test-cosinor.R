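test_that("noiseless damped cosine is recovered to high precision", {
  lux <- simulate_luciferase_series(tau = 24, damping = 0.02, mesor = 100,
                                    amplitude = 30, phase = 6, noise_sd = 0,
                                    sampling_minutes = 30)
  fit <- fit_damped_cosinor(lux)
  cf <- fit$coefficients
  expect_equal(unname(cf["tau"]), 24, tolerance = 1e-4)
  expect_equal(unname(cf["damping"]), 0.02, tolerance = 1e-4)
  expect_equal(unname(cf["mesor"]), 100, tolerance = 1e-3)
  expect_equal(unname(cf["amplitude"]), 30, tolerance = 1e-3)
  expect_equal(unname(cf["acrophase"]), 6, tolerance = 1e-3)
  expect_true(fit$converged)
})

test_that("gamma fixed to zero reduces to the classical cosinor", {
  lux <- simulate_luciferase_series(tau = 25.3, damping = 0, mesor = 40,
                                    amplitude = 12, phase = 2, noise_sd = 0,
                                    sampling_minutes = 20, duration_hours = 52)
  fit <- fit_damped_cosinor(lux, window = c(0, 52), fix_gamma = 0)
  expect_equal(unname(fit$coefficients["tau"]), 25.3, tolerance = 1e-6)
  expect_equal(unname(fit$coefficients["damping"]), 0)
})

test_that("amplitude is canonically non-negative with a unique acrophase", {
  # a trough-first signal (equivalent to negative amplitude at phase 0)
  t <- seq(0, 48, by = 0.5)
  y <- 10 - 5 * cos(2 * pi * t / 24)
  fit <- fit_damped_cosinor(tibble::tibble(time = t, signal = y))
  expect_gte(fit$coefficients["amplitude"], 0)
  expect_equal(unname(fit$coefficients["acrophase"]), 12, tolerance = 1e-3)
  expect_true(fit$coefficients["acrophase"] >= 0 &&
                fit$coefficients["acrophase"] < fit$coefficients["tau"])
})

test_that("shifting the time origin shifts only the acrophase", {
  lux <- simulate_luciferase_series(tau = 24, damping = 0.01, mesor = 80,
                                    amplitude = 20, phase = 5, noise_sd = 1,
                                    sampling_minutes = 30, seed = 8)
  f0 <- fit_damped_cosinor(lux)
  shifted <- dplyr::mutate(lux, time = time + 7)
  f1 <- fit_damped_cosinor(shifted, window = c(7, 55))
  expect_equal(unname(f1$coefficients["tau"]),
               unname(f0$coefficients["tau"]), tolerance = 0.02)
  dphi <- (f1$coefficients["acrophase"] - f0$coefficients["acrophase"]) %%
    f0$coefficients["tau"]
  expect_equal(unname(dphi), 7, tolerance = 0.05)
})

test_that("the returned fit never sits above its own multi-start initializations", {
  lux <- simulate_luciferase_series(tau = 22.5, damping = 0.04, mesor = 60,
                                    amplitude = 15, noise_sd = 3,
                                    sampling_minutes = 30, seed = 13)
  fit <- fit_damped_cosinor(lux)
  expect_true(all(fit$rss <= fit$start_rss + 1e-8))
})

test_that("degenerate inputs are flagged, not fatal", {
  flat <- tibble::tibble(time = seq(0, 48, 0.5), signal = 5)
  fit <- fit_damped_cosinor(flat)
  expect_false(fit$converged)
  expect_true(is.na(fit$coefficients["tau"]))
  short <- tibble::tibble(time = seq(0, 10, 0.5), signal = rnorm(21))
  expect_error(fit_damped_cosinor(short), "1.5 cycles")
})

test_that("tidy and glance expose the fit in broom form", {
  lux <- simulate_luciferase_series(seed = 2)
  fit <- fit_damped_cosinor(lux)
  td <- tidy(fit)
  expect_equal(td$term,
               c("mesor", "amplitude", "damping", "tau", "acrophase"))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_true(all(c("tau", "rss", "converged", "n") %in% names(gl)))
})

test_that("well-level fits aggregate to genotype period summaries", {
  wells <- purrr::map_dfr(1:4, function(w) {
    lux <- simulate_luciferase_series(tau = 23.5, damping = 0.02,
                                      noise_sd = 2, seed = 100 + w)
    dplyr::mutate(lux, well = paste0("W", w),
                  genotype = ifelse(w <= 2, "ctrl", "kd"))
  })
  fits <- fit_cosinor_wells(wells)
  expect_equal(nrow(fits), 4)
  summ <- summarize_luciferase(fits)
  expect_equal(sort(summ$genotype), c("ctrl", "kd"))
  expect_true(all(abs(summ$mean_tau - 23.5) < 0.3))
})

test_that("plate CSV reader produces the long well layout", {
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(time = c(0, 0.5, 1), A1 = 1:3, A2 = 4:6),
                   path)
  long <- read_plate_csv(path)
  expect_equal(nrow(long), 6)
  expect_equal(sort(unique(long$well)), c("A1", "A2"))
  expect_equal(long$signal[long$well == "A2"], c(4, 5, 6))
})
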