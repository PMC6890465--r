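test_that("cutoffs match hand arithmetic and tolerate outlier inflation", {
  lines <- tibble::tibble(line_id = sprintf("L%d", 1:5), collection = "TRiP",
                          driver = "TD2",
                          mean_period = c(24, 24, 24, 24, 29))
  co <- compute_cutoffs(lines, min_lines = 5)
  expect_equal(co$stratum_mean, 25)
  expect_equal(co$stratum_sd, sqrt(5), tolerance = 1e-12)
  expect_equal(co$high_cut, 25 + 2 * sqrt(5), tolerance = 1e-12)
  hits <- call_hits(lines, co)
  # the 29 h line inflates its own cutoff and does not pass
  expect_false(hits$passes[hits$mean_period == 29])
})

test_that("a line exactly at a cutoff does not pass (strict inequality)", {
  lines <- tibble::tibble(line_id = sprintf("L%02d", 1:12),
                          collection = "VDRC-GD", driver = "PD2",
                          mean_period = c(rep(24, 11), 25))
  co <- compute_cutoffs(lines)
  at_cut <- tibble::tibble(line_id = "X", collection = "VDRC-GD",
                           driver = "PD2", mean_period = co$high_cut)
  h <- call_hits(at_cut, co)
  expect_false(h$passes)
  expect_equal(h$direction, "none")
  just_over <- dplyr::mutate(at_cut, mean_period = co$high_cut + 1e-9)
  expect_true(call_hits(just_over, co)$passes)
  expect_equal(call_hits(just_over, co)$direction, "long")
})

test_that("degenerate and undersized strata are flagged, never classified", {
  same <- tibble::tibble(line_id = sprintf("L%02d", 1:12),
                         collection = "TRiP", driver = "TD2",
                         mean_period = 24.5)
  expect_warning(co <- compute_cutoffs(same), "degenerate")
  expect_true(is.na(co$high_cut))
  small <- tibble::tibble(line_id = c("A", "B"), collection = "TRiP",
                          driver = "PD2", mean_period = c(24, 25))
  expect_warning(co2 <- compute_cutoffs(small), "below minimum size")
  h <- call_hits(small, co2)
  expect_true(all(h$category == "unclassified"))
})

test_that("40D-KK lines form their own stratum; GD and KK pool as VDRC", {
  lines <- tibble::tibble(
    line_id = sprintf("L%02d", 1:30),
    collection = rep(c("VDRC-GD", "VDRC-KK", "VDRC-KK-40D"), each = 10),
    driver = "TD2",
    mean_period = rep(c(24.9, 24.9, 25.5), each = 10) + (1:30) * 1e-3)
  co <- compute_cutoffs(lines)
  expect_setequal(co$stratum, c("VDRC:TD2", "VDRC-KK-40D:TD2"))
  expect_equal(co$n_lines[co$stratum == "VDRC:TD2"], 20)
})

test_that("hit calls in one stratum are unaffected by shifts in another", {
  set.seed(77)
  lines <- tibble::tibble(
    line_id = sprintf("L%03d", 1:60),
    collection = rep(c("TRiP", "VDRC-GD"), each = 30),
    driver = "TD2",
    mean_period = c(rnorm(30, 24.6, 0.2), rnorm(30, 24.9, 0.2)))
  h1 <- call_hits(lines, compute_cutoffs(lines))
  shifted <- dplyr::mutate(lines,
                           mean_period = mean_period +
                             ifelse(collection == "TRiP", 3, 0))
  h2 <- call_hits(shifted, compute_cutoffs(shifted))
  keep <- lines$collection == "VDRC-GD"
  expect_identical(h1$passes[keep], h2$passes[keep])
})

test_that("arrhythmic lines are routed to rhythmicity candidates", {
  flies <- tibble::tibble(
    line_id = rep(c("L1", "L2"), each = 4), gene = "g",
    collection = "TRiP", driver = "TD2",
    fly_id = sprintf("f%d", 1:8),
    rhythmic = c(rep(TRUE, 4), rep(FALSE, 4)),
    period = c(rnorm(4, 24.5, 0.1), rep(NA, 4)),
    power = c(rnorm(4, 50, 5), rep(NA, 4)))
  recs <- summarize_screen(flies)
  expect_true(is.na(recs$mean_period[recs$line_id == "L2"]))
  filler <- tibble::tibble(line_id = sprintf("F%02d", 1:12),
                           collection = "TRiP", driver = "TD2",
                           mean_period = rnorm(12, 24.5, 0.2))
  co <- compute_cutoffs(dplyr::bind_rows(recs, filler))
  h <- call_hits(recs, co)
  expect_equal(h$category[h$line_id == "L2"], "rhythmicity_candidate")
})

test_that("injected hits are recovered with the right direction", {
  ht <- tibble::tibble(line_id = c("GD-0001", "GD-0002"), delta = c(2, -2))
  sim <- simulate_screen_dataset(n_lines = c("VDRC-GD" = 80),
                                 drivers = "TD2", hits = ht, seed = 15)
  h <- call_hits(sim$lines, compute_cutoffs(sim$lines))
  calls <- h[match(ht$line_id, h$line_id), ]
  expect_true(all(calls$passes))
  expect_equal(calls$direction, c("long", "short"))
  counts <- screen_panel_counts(h)
  expect_gte(sum(counts$n), 2)
})

test_that("external screen tables load through a column mapping", {
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(RNAi_line = c("GD1", "KK2"),
                                  Library = c("GD", "KK"),
                                  GAL4 = c("TD2", "TD2"),
                                  Period = c(24.7, 25.1)), path)
  tbl <- read_screen_table(
    path,
    mapping = c(line_id = "RNAi_line", collection = "Library",
                driver = "GAL4", mean_period = "Period"),
    collection_map = c(GD = "VDRC-GD", KK = "VDRC-KK"))
  expect_equal(tbl$collection, c("VDRC-GD", "VDRC-KK"))
  expect_error(
    read_screen_table(path,
                      mapping = c(line_id = "RNAi_line",
                                  collection = "Library", driver = "GAL4",
                                  mean_period = "nope")),
    "lacks column")
})
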