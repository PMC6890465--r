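#' Read a Trikinetics DAM monitor file
#'
#' Parses the DAMSystem3 tab-delimited monitor layout: one row per reading
#' with columns (1) reading index, (2) date `dd mmm yy`, (3) time
#' `HH:MM:SS`, (4) monitor status, (5-9) device fields (ignored), (10)
#' light sensor (0/1), and (11-42) beam-break counts for the 32 channels.
#' Each channel becomes one fly.  Rows whose status differs from `1` (OK)
#' are kept but their counts are flagged missing (`NA`), never zeroed.
#'
#' Protocol annotation is derived per day: days on which the light sensor
#' was ever on are labeled `"LD"`, all later days `"DD"` (temperature-cycle
#' labeling is not encoded in DAM files; relabel downstream if needed).
#'
#' @param path path to a DAM text file.
#' @param bin_minutes length of the recording bin in minutes (the DAM
#'   acquisition interval; it must match the file's timestamps).
#' @param genotype genotype label attached to every channel.
#' @param temperature constant temperature annotation, degrees C.
#' @param tz timezone used to parse timestamps (experiment-local clock).
#' @return a tidy activity tibble (see [validate_activity()]) with
#'   one row per channel and bin; `fly_id` is `<file>#ch<k>`.
#' @export
read_dam_file <- function(path, bin_minutes = 1, genotype = NA_character_,
                          temperature = 25, tz = "UTC") {
  check_that(file.exists(path), paste0("file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  check_that(length(lines) > 0, paste0("empty DAM file: ", path))

  fields <- strsplit(lines, "\t", fixed = TRUE)
  nfld <- lengths(fields)
  bad <- which(nfld != 42L)
  if (length(bad) > 0) {
    abort(paste0("malformed DAM row: line ", bad[1], " has ", nfld[bad[1]],
                 " fields (expected 42) in ", path))
  }
  mat <- do.call(rbind, fields)

  stamp <- strptime(paste(mat[, 2], mat[, 3]), format = "%d %b %y %H:%M:%S",
                    tz = tz)
  if (anyNA(stamp)) {
    abort(paste0("unparseable timestamp at line ",
                 which(is.na(stamp))[1], " in ", path))
  }
  tsec <- as.numeric(stamp)
  if (any(diff(tsec) <= 0)) {
    abort(paste0("non-monotone timestamps at line ",
                 which(diff(tsec) <= 0)[1] + 1L, " in ", path))
  }

  status_ok <- mat[, 4] == "1"
  light_on <- suppressWarnings(as.numeric(mat[, 10])) > 0
  light_on[is.na(light_on)] <- FALSE
  counts <- matrix(suppressWarnings(as.integer(mat[, 11:42])),
                   nrow = nrow(mat))
  if (anyNA(counts[status_ok, ])) {
    abort(paste0("non-numeric count field in ", path))
  }
  counts[!status_ok, ] <- NA_integer_

  hours <- (tsec - tsec[1]) / 3600
  day <- floor(hours / 24) + 1L
  ld_day <- vapply(split(light_on, day), any, logical(1))
  protocol <- ifelse(ld_day[as.character(day)], "LD", "DD")

  base <- tibble::tibble(
    time = hours, light = ifelse(light_on, "ON", "OFF"),
    temperature = temperature, protocol = protocol, day = as.integer(day))
  out <- purrr::map_dfr(seq_len(32), function(ch) {
    dplyr::mutate(base,
                  fly_id = sprintf("%s#ch%02d", basename(path), ch),
                  genotype = genotype, counts = counts[, ch],
                  .before = 1)
  })
  validate_activity(out[, activity_columns])
  out[, activity_columns]
}

#' Read and write tidy activity CSV
#'
#' The package's escape-hatch dialect: a CSV with exactly the columns of
#' the tidy activity layout (`fly_id, genotype, time, counts, light,
#' temperature, protocol, day`), one row per fly-bin.  Missing bins are
#' empty `counts` fields.
#'
#' @param path file path.
#' @return `read_activity_csv()` returns a validated activity tibble.
#' @export
read_activity_csv <- function(path) {
  check_that(file.exists(path), paste0("file not found: ", path))
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  extra <- setdiff(names(df), activity_columns)
  check_that(length(extra) == 0,
             paste0("unknown column(s) in activity CSV: ",
                    paste(extra, collapse = ", "),
                    " (not the documented tidy dialect)"))
  validate_activity(df)
  df[, activity_columns]
}

#' @rdname read_activity_csv
#' @param activity a tidy activity tibble.
#' @export
write_activity_csv <- function(activity, path) {
  validate_activity(activity)
  readr::write_csv(activity[, activity_columns], path, progress = FALSE)
  invisible(path)
}

#' Write / read a results table
#'
#' Thin CSV writer for the tibbles the pipeline produces (periodogram
#' summaries, hit calls, relative expression ...).  The column order of the
#' input is preserved and is the documented, stable order; numbers are
#' written with full precision so the matching reader round-trips
#' losslessly.  List-columns (e.g. embedded spectra) are dropped with a
#' warning since CSV cannot carry them.
#'
#' @param records a data frame of results.
#' @param path destination file.
#' @param allow_empty write a header-only file when `records` has no rows.
#' @return `path`, invisibly.
#' @export
write_results_table <- function(records, path, allow_empty = FALSE) {
  check_that(is.data.frame(records), "records must be a data frame")
  if (nrow(records) == 0 && !allow_empty) {
    abort("refusing to write an empty results table (set allow_empty = TRUE)")
  }
  is_list <- vapply(records, is.list, logical(1))
  if (any(is_list)) {
    warn(paste0("dropping list-column(s): ",
                paste(names(records)[is_list], collapse = ", ")))
    records <- records[, !is_list, drop = FALSE]
  }
  readr::write_csv(tibble::as_tibble(records), path, progress = FALSE)
  invisible(path)
}

#' @rdname write_results_table
#' @export
read_results_table <- function(path) {
  check_that(file.exists(path), paste0("file not found: ", path))
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' Aggregate activity counts to a coarser bin
#'
#' Sums counts into analysis bins of `bin_hours` (default 0.1 h so that
#' every trial period on the 0.1 h periodogram grid is an integer number of
#' bins).  The target bin must be an integer multiple of the recording bin.
#' An aggregated bin is missing when any constituent bin is missing.
#'
#' @param activity tidy activity tibble.
#' @param bin_hours target bin length in hours.
#' @return activity tibble at the new bin length; `time` is the bin start.
#' @export
aggregate_bins <- function(activity, bin_hours = 0.1) {
  validate_activity(activity)
  raw <- infer_bin_hours(activity)
  ratio <- bin_hours / raw
  check_that(abs(ratio - round(ratio)) < 1e-8 && round(ratio) >= 1,
             "bin_hours must be an integer multiple of the recording bin")
  if (round(ratio) == 1) return(tibble::as_tibble(activity))
  activity |>
    dplyr::group_by(.data$fly_id) |>
    dplyr::mutate(.bin = floor((.data$time - min(.data$time)) / bin_hours + 1e-9)) |>
    dplyr::group_by(.data$fly_id, .data$.bin) |>
    dplyr::summarise(
      genotype = .data$genotype[1],
      time = min(.data$time),
      counts = if (anyNA(.data$counts)) NA_integer_ else as.integer(sum(.data$counts)),
      light = if (any(.data$light == "ON")) "ON" else "OFF",
      temperature = mean(.data$temperature),
      protocol = .data$protocol[1],
      day = .data$day[1],
      .groups = "drop") |>
    dplyr::select(dplyr::all_of(activity_columns)) |>
    dplyr::arrange(.data$fly_id, .data$time)
}
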