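#' Read a plate-level multiplex readout table
#'
#' The plate table is a plain CSV with one row per (plate, well, analyte)
#' bead region: columns `plate`, `well`, `sample`, `analyte`, `mfi` (median
#' fluorescence intensity) and `bead_count`. `sample` holds the study sample
#' id, or the roles `STD1..STDk` / `BLANK` / bridge-sample ids for
#' non-study wells. Extra columns are tolerated and carried along; analyte
#' names are alias-resolved against `panel`; row order is preserved.
#'
#' @param path CSV path (or anything `readr::read_csv()` accepts).
#' @param panel An `ontokine_panel` used to canonicalize analyte names.
#' @return A tibble of plate wells with canonical analyte names.
#' @export
read_plate_table <- function(path, panel = default_panel()) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_plate_table(df, panel)
}

#' Validate (and canonicalize) an in-memory plate table
#'
#' @param df Data frame with the plate-table columns.
#' @inheritParams read_plate_table
#' @return The validated tibble.
#' @export
validate_plate_table <- function(df, panel = default_panel()) {
  need <- c("plate", "well", "sample", "analyte", "mfi", "bead_count")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    abort(paste0("Plate table missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  df <- as_tibble(df)
  df$analyte <- resolve_analytes(panel, df$analyte)
  if (any(df$mfi < 0, na.rm = TRUE)) abort("Negative `mfi` in plate table.")
  if (any(df$bead_count < 0, na.rm = TRUE)) abort("Negative `bead_count` in plate table.")
  if (any(df$bead_count != floor(df$bead_count), na.rm = TRUE)) {
    abort("`bead_count` must be a nonnegative integer.")
  }
  key <- paste(df$plate, df$well, df$analyte, sep = "\r")
  if (anyDuplicated(key)) {
    abort("Duplicate (plate, well, analyte) rows in plate table.")
  }
  df
}

#' Write a plate table to CSV
#' @param df Plate-well tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_plate_table <- function(df, path) {
  readr::write_csv(df, path, progress = FALSE)
  invisible(path)
}

#' Read a standards / dilution-series table
#'
#' One row per standards or blank well: columns `plate`, `analyte`, `sample`
#' (`STD1..STDk` or `BLANK`), `expected_conc` (pg/mL on the well scale, 0 for
#' blanks) and `mfi`.
#'
#' @inheritParams read_plate_table
#' @return A tibble with canonical analyte names.
#' @export
read_standards_table <- function(path, panel = default_panel()) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("plate", "analyte", "sample", "expected_conc", "mfi")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    abort(paste0("Standards table missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  df <- as_tibble(df)
  df$analyte <- resolve_analytes(panel, df$analyte)
  if (any(df$expected_conc < 0)) abort("Negative `expected_conc` in standards table.")
  if (any(df$expected_conc == 0 & df$sample != "BLANK")) {
    abort("Zero `expected_conc` allowed only for BLANK rows.")
  }
  df
}

#' Read and validate a participant metadata table
#'
#' One row per participant: columns `participant`, `sex` (`F`/`M`),
#' `visit2_dol` (1, 3 or 7 -- the single follow-up day of life), `gest_cat`,
#' `mat_age_band`, `ethnicity`, `bf_v1`, `bf_v2`. Every participant
#' contributes exactly two samples, one at day of life 0 and one at
#' `visit2_dol`; any other follow-up day is an error.
#'
#' @param path CSV path, or a data frame already in memory.
#' @param quiet Suppress the per-day accounting message.
#' @return A validated tibble, one row per participant.
#' @export
read_metadata <- function(path, quiet = FALSE) {
  df <- if (is.data.frame(path)) {
    as_tibble(path)
  } else {
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  }
  need <- c("participant", "sex", "visit2_dol")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    abort(paste0("Metadata missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(df$participant)) {
    abort("Duplicate participant row(s): each participant has one record carrying both visits.")
  }
  bad <- !df$visit2_dol %in% c(1, 3, 7)
  if (any(bad)) {
    abort(paste0(
      "Invalid follow-up day(s) (must be 1, 3 or 7): ",
      paste(unique(df$visit2_dol[bad]), collapse = ", ")
    ))
  }
  if ("sex" %in% names(df) && !all(df$sex %in% c("F", "M"))) {
    abort("`sex` must be F or M.")
  }
  if (!quiet) {
    tab <- table(factor(df$visit2_dol, levels = c(1, 3, 7)))
    inform(sprintf(
      "Metadata: %d participants; follow-ups DOL1 n=%d, DOL3 n=%d, DOL7 n=%d.",
      nrow(df), tab[["1"]], tab[["3"]], tab[["7"]]
    ))
  }
  df
}
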