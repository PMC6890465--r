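# Independent brute-force oracle for the chi-squared periodogram.
# Deliberately written with explicit loops and no shared code with the
# package internals: fold the first K complete cycles at the trial period,
# take column means over the P circadian phases, and form the
# ANOVA-normalized ratio N * sum_c K_c (M_c - Mbar)^2 / sum_i (x_i - Mbar)^2.
oracle_qp <- function(x, p) {
  k <- floor(length(x) / p)
  if (k < 2) return(NA_real_)
  x <- x[1:(k * p)]
  cols <- vector("list", p)
  for (i in seq_along(x)) {
    c_idx <- ((i - 1) %% p) + 1
    cols[[c_idx]] <- c(cols[[c_idx]], x[i])
  }
  all_obs <- unlist(lapply(cols, function(v) v[!is.na(v)]))
  n <- length(all_obs)
  if (n == 0) return(NA_real_)
  gm <- sum(all_obs) / n
  ssb <- 0
  for (v in cols) {
    v <- v[!is.na(v)]
    if (length(v) > 0) ssb <- ssb + length(v) * (mean(v) - gm)^2
  }
  sst <- 0
  for (xi in all_obs) sst <- sst + (xi - gm)^2
  if (sst == 0) return(NA_real_)
  n * ssb / sst
}

# square-wave activity with an exact period (hours) on a bin grid
square_wave_activity <- function(period_h = 24, days = 5, bin_hours = 0.1,
                                 high = 20, low = 0, fly_id = "sq1") {
  n <- as.integer(round(days * 24 / bin_hours))
  t <- (seq_len(n) - 1) * bin_hours
  phase <- t %% period_h
  counts <- ifelse(phase < period_h / 2, high, low)
  tibble::tibble(fly_id = fly_id, genotype = "square", time = t,
                 counts = as.integer(counts), light = "OFF",
                 temperature = 25, protocol = "DD",
                 day = as.integer(floor(t / 24) + 1))
}

# small DAM-format fixture written on the fly
write_dam_fixture <- function(path, n_rows = 60, bad_row = NULL,
                              n_fields = 42) {
  t0 <- as.POSIXct("2019-01-07 08:00:00", tz = "UTC")
  lines <- vapply(seq_len(n_rows), function(i) {
    tt <- t0 + (i - 1) * 60
    status <- if (!is.null(bad_row) && i == bad_row) "51" else "1"
    light <- if ((i - 1) %% 40 < 20) "1" else "0"
    counts <- ((i + seq_len(32)) %% 7)
    fields <- c(i, format(tt, "%d %b %y"), format(tt, "%H:%M:%S"), status,
                rep("0", 5), light, counts)  # 42 fields when complete
    paste(fields[seq_len(n_fields)], collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  path
}
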