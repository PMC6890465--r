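# Batch-stratified 2-SD screen hit-calling.

# Panel (stratum) assignment: TRiP, pooled VDRC (GD + non-40D KK), and
# 40D-locus KK lines, each crossed with each driver.  40D-KK lines are
# never pooled with other VDRC lines because the 40D landing site itself
# lengthens period.
screen_stratum <- function(collection, driver) {
  panel <- dplyr::case_match(collection,
                             "TRiP" ~ "TRiP",
                             c("VDRC-GD", "VDRC-KK") ~ "VDRC",
                             "VDRC-KK-40D" ~ "VDRC-KK-40D",
                             .default = collection)
  paste(panel, driver, sep = ":")
}

#' Summarize per-fly screen data to line level
#'
#' Collapses per-fly periods to one row per line x driver cross: flies
#' tested, flies rhythmic, mean period and SEM over rhythmic flies, and
#' mean periodogram power.  Lines in which no fly was rhythmic get an
#' undefined (`NA`) mean period; they are later reported as rhythmicity
#' candidates, not period hits.
#'
#' @param flies tibble with columns `line_id`, `gene`, `collection`,
#'   `driver`, `fly_id`, `rhythmic`, `period`, `power`.
#' @return line-level tibble (one row per line x driver).
#' @export
summarize_screen <- function(flies) {
  check_that(all(c("line_id", "collection", "driver", "rhythmic", "period")
                 %in% names(flies)),
             "flies needs columns line_id, collection, driver, rhythmic, period")
  sem <- function(x) if (length(x) > 1) sd(x) / sqrt(length(x)) else NA_real_
  flies |>
    dplyr::group_by(.data$line_id, .data$collection, .data$driver) |>
    dplyr::summarise(
      gene = if ("gene" %in% names(flies)) .data$gene[1] else NA_character_,
      n_total = dplyr::n(),
      n_rhythmic = sum(.data$rhythmic),
      mean_period = ifelse(sum(.data$rhythmic) > 0,
                           mean(.data$period[.data$rhythmic]), NA_real_),
      sem_period = sem(.data$period[.data$rhythmic]),
      mean_power = if ("power" %in% names(flies))
        mean(.data$power[.data$rhythmic]) else NA_real_,
      .groups = "drop") |>
    dplyr::relocate("gene", .after = "line_id")
}

#' Per-stratum 2-SD period cutoffs
#'
#' Stratifies lines by RNAi collection panel (TRiP / pooled VDRC /
#' 40D-KK VDRC) crossed with driver, and computes the mean and SD of
#' line-level mean periods within each stratum; cutoffs are
#' `mean +/- 2 SD`.  Lines without a defined mean period (no rhythmic
#' flies) do not enter the distribution.  Strata with fewer than
#' `min_lines` usable lines get undefined cutoffs with a warning, as does
#' a stratum with zero SD.
#'
#' @param records line-level tibble from [summarize_screen()] or
#'   [read_screen_table()].
#' @param min_lines minimum usable lines per stratum.
#' @param k cutoff multiplier (2 = the screening convention).
#' @return tibble with one row per stratum: `stratum`, `n_lines`,
#'   `stratum_mean`, `stratum_sd`, `low_cut`, `high_cut`.
#' @export
#' @examples
#' lines <- tibble::tibble(line_id = sprintf("L%02d", 1:12),
#'                         collection = "TRiP", driver = "TD2",
#'                         mean_period = rnorm(12, 24.6, 0.3))
#' compute_cutoffs(lines)
compute_cutoffs <- function(records, min_lines = 10, k = 2) {
  check_that(all(c("collection", "driver", "mean_period") %in% names(records)),
             "records needs columns collection, driver, mean_period")
  out <- records |>
    dplyr::mutate(stratum = screen_stratum(.data$collection, .data$driver)) |>
    dplyr::filter(!is.na(.data$mean_period)) |>
    dplyr::group_by(.data$stratum) |>
    dplyr::summarise(n_lines = dplyr::n(),
                     stratum_mean = mean(.data$mean_period),
                     stratum_sd = sd(.data$mean_period),
                     .groups = "drop") |>
    dplyr::mutate(
      usable = .data$n_lines >= min_lines & !is.na(.data$stratum_sd) &
        .data$stratum_sd > 0,
      low_cut = ifelse(.data$usable,
                       .data$stratum_mean - k * .data$stratum_sd, NA_real_),
      high_cut = ifelse(.data$usable,
                        .data$stratum_mean + k * .data$stratum_sd, NA_real_))
  small <- out$stratum[out$n_lines < min_lines]
  if (length(small) > 0) {
    warn(paste0("stratum below minimum size, cutoffs undefined: ",
                paste(small, collapse = ", ")))
  }
  degen <- out$stratum[out$n_lines >= min_lines &
                         (is.na(out$stratum_sd) | out$stratum_sd == 0)]
  if (length(degen) > 0) {
    warn(paste0("degenerate (zero) SD, cutoffs undefined: ",
                paste(degen, collapse = ", ")))
  }
  dplyr::select(out, -"usable")
}

#' Classify screen lines against stratified cutoffs
#'
#' Strict-inequality classification: a line passes iff its mean period
#' lies strictly beyond `mean +/- 2 SD` of its stratum; a line exactly at
#' a cutoff does not pass.  Lines with no rhythmic flies are labeled
#' `rhythmicity_candidate` (the period screen cannot classify them);
#' lines in strata without cutoffs are `unclassified`.
#'
#' @param records line-level tibble (see [compute_cutoffs()]).
#' @param cutoffs output of [compute_cutoffs()] on the same
#'   stratification.
#' @return tibble of hit calls: inputs plus `stratum`, `stratum_mean`,
#'   `stratum_sd`, `z`, `direction` (`"long"`, `"short"`, `"none"`),
#'   `passes`, `category`.
#' @export
call_hits <- function(records, cutoffs) {
  calls <- records |>
    dplyr::mutate(stratum = screen_stratum(.data$collection, .data$driver)) |>
    dplyr::left_join(cutoffs, by = "stratum") |>
    dplyr::mutate(
      z = (.data$mean_period - .data$stratum_mean) / .data$stratum_sd,
      passes = !is.na(.data$mean_period) & !is.na(.data$low_cut) &
        (.data$mean_period < .data$low_cut | .data$mean_period > .data$high_cut),
      direction = dplyr::case_when(
        .data$passes & .data$mean_period > .data$high_cut ~ "long",
        .data$passes ~ "short",
        .default = "none"),
      category = dplyr::case_when(
        is.na(.data$mean_period) ~ "rhythmicity_candidate",
        is.na(.data$low_cut) ~ "unclassified",
        .data$passes ~ "period_hit",
        .default = "none"))
  dplyr::select(calls, -"n_lines")
}

#' Count passing lines per screen panel
#'
#' The per-panel tally of lines beyond the 2-SD cutoffs, by driver and
#' direction -- the numbers a screen's period-histogram legend reports.
#'
#' @param hits output of [call_hits()].
#' @return tibble: `stratum`, `driver`, `direction`, `n`.
#' @export
screen_panel_counts <- function(hits) {
  hits |>
    dplyr::filter(.data$category == "period_hit") |>
    dplyr::count(.data$stratum, .data$driver, .data$direction, name = "n") |>
    dplyr::arrange(.data$stratum, .data$driver, .data$direction)
}

#' Read a line-level screen table from CSV
#'
#' Reads an external screen summary (for example a published screen
#' dataset export) into the line-level layout used by
#' [compute_cutoffs()] / [call_hits()].  `mapping` renames the file's
#' columns onto the package schema: required are `line_id`, `collection`,
#' `driver`, `mean_period`; `gene`, `n_total`, `n_rhythmic`, `mean_power`
#' are carried through when mapped.  Collection labels are matched onto
#' `TRiP` / `VDRC-GD` / `VDRC-KK` / `VDRC-KK-40D` via `collection_map`.
#'
#' @param path CSV file path.
#' @param mapping named character vector `c(schema_name = file_column)`.
#' @param collection_map named character vector translating the file's
#'   collection labels to the package's.
#' @return line-level tibble.
#' @export
read_screen_table <- function(path,
                              mapping = c(line_id = "line_id",
                                          collection = "collection",
                                          driver = "driver",
                                          mean_period = "mean_period"),
                              collection_map = NULL) {
  check_that(file.exists(path), paste0("file not found: ", path))
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("line_id", "collection", "driver", "mean_period")
  check_that(all(required %in% names(mapping)),
             paste0("mapping must name: ", paste(required, collapse = ", ")))
  missing_cols <- setdiff(unname(mapping), names(df))
  check_that(length(missing_cols) == 0,
             paste0("screen table lacks column(s): ",
                    paste(missing_cols, collapse = ", ")))
  out <- df[, unname(mapping)]
  names(out) <- names(mapping)
  if (!is.null(collection_map)) {
    unknown <- setdiff(unique(out$collection), names(collection_map))
    check_that(length(unknown) == 0,
               paste0("unmapped collection label(s): ",
                      paste(unknown, collapse = ", ")))
    out$collection <- unname(collection_map[out$collection])
  }
  tibble::as_tibble(out)
}
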