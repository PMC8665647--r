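#' Fit standard curves for every (plate, analyte)
#'
#' Applies [fit_standard_curve()] to each plate/analyte dilution series and
#' [estimate_limits()] to its blanks, returning one row per (plate,
#' analyte). Non-convergent series are kept with `ok = FALSE` (and a
#' warning) so the caller can exclude them explicitly.
#'
#' @param standards Standards table (see [read_standards_table()]): columns
#'   `plate`, `analyte`, `sample`, `expected_conc`, `mfi`; blanks have
#'   `expected_conc == 0`.
#' @inheritParams fit_standard_curve
#' @param recovery Acceptable back-calculated recovery window for the
#'   quantification limits.
#' @return A tibble of class `ontokine_curves`: `plate`, `analyte`,
#'   `family`, `model` (list of `curve_model`), `fit_sse`, `lld`, `uld`,
#'   `lloq`, `uloq`, `ok`, `note`. Limits are on the well (diluted) scale.
#' @export
fit_standard_curves <- function(standards,
                                families = c("logistic4", "logistic5", "exponential"),
                                criterion = c("aic", "sse"),
                                recovery = c(0.7, 1.3),
                                seed = 1L) {
  criterion <- match.arg(criterion)
  groups <- standards |>
    group_by(.data$plate, .data$analyte) |>
    tidyr::nest() |>
    ungroup()
  res <- map(groups$data, function(d) {
    blanks <- d$mfi[d$expected_conc == 0]
    out <- tryCatch(
      {
        m <- fit_standard_curve(d,
          families = families, criterion = criterion, seed = seed
        )
        lim <- estimate_limits(m, blanks = blanks, standards = d, recovery = recovery)
        list(
          family = m$family, model = list(m), fit_sse = m$fit_sse,
          lld = lim$lld, uld = lim$uld, lloq = lim$lloq, uloq = lim$uloq,
          ok = TRUE, note = NA_character_
        )
      },
      error = function(e) {
        list(
          family = NA_character_, model = list(NULL), fit_sse = NA_real_,
          lld = NA_real_, uld = NA_real_, lloq = NA_real_, uloq = NA_real_,
          ok = FALSE, note = conditionMessage(e)
        )
      }
    )
    tibble(
      family = out$family, model = out$model, fit_sse = out$fit_sse,
      lld = out$lld, uld = out$uld, lloq = out$lloq, uloq = out$uloq,
      ok = out$ok, note = out$note
    )
  })
  fits <- bind_cols(groups[, c("plate", "analyte")], bind_rows(res))
  n_bad <- sum(!fits$ok)
  if (n_bad > 0) {
    warn(sprintf(
      "%d (plate, analyte) standard curve(s) failed and are flagged for exclusion.",
      n_bad
    ))
  }
  class(fits) <- c("ontokine_curves", class(fits))
  fits
}

#' @exportS3Method generics::glance
glance.ontokine_curves <- function(x, ...) {
  tibble(
    n_curves = nrow(x),
    n_failed = sum(!x$ok),
    n_logistic4 = sum(x$family == "logistic4", na.rm = TRUE),
    n_logistic5 = sum(x$family == "logistic5", na.rm = TRUE),
    n_exponential = sum(x$family == "exponential", na.rm = TRUE),
    median_sse = median(x$fit_sse, na.rm = TRUE)
  )
}

#' Quantify plate wells against fitted standard curves
#'
#' Applies the censoring rules to each well: wells with fewer than
#' `bead_min` beads are discarded (no value); otherwise the MFI is inverted
#' through the plate/analyte curve and multiplied by the dilution factor.
#' Back-calculated concentrations below the lower limit of detection are
#' flagged `below_lld`; values outside the quantification range are imputed
#' at the corresponding limit of quantification (times the dilution
#' factor).
#'
#' @param wells Plate table (see [read_plate_table()]).
#' @param fits `ontokine_curves` from [fit_standard_curves()].
#' @param dilution_factor Plasma dilution applied before assaying
#'   (default 2, i.e. 1:2).
#' @param bead_min Minimum bead count for a valid reading (default 30).
#' @return Tibble `sample`, `plate`, `well`, `analyte`, `conc` (pg/mL,
#'   neat plasma scale), `flag` in
#'   `quantified|imputed_low|imputed_high|below_lld|discarded_low_beads|no_curve`.
#' @export
quantify_wells <- function(wells, fits, dilution_factor = 2, bead_min = 30) {
  key_w <- paste(wells$plate, wells$analyte, sep = "\r")
  key_f <- paste(fits$plate, fits$analyte, sep = "\r")
  idx <- match(key_w, key_f)
  if (anyNA(idx)) {
    abort("Missing standard-curve fit for some (plate, analyte) wells.")
  }
  out <- tibble(
    sample = wells$sample, plate = wells$plate, well = wells$well,
    analyte = wells$analyte,
    conc = NA_real_, flag = NA_character_
  )
  fit_ok <- fits$ok[idx]
  out$flag[!fit_ok] <- "no_curve"
  discard <- fit_ok & wells$bead_count < bead_min
  out$flag[discard] <- "discarded_low_beads"
  todo <- which(fit_ok & !discard)
  # invert per (plate, analyte) group so each curve is evaluated vectorized
  for (g in split(todo, idx[todo])) {
    f <- idx[g[1]]
    model <- fits$model[[f]]
    x <- curve_inverse(model, wells$mfi[g])
    lld <- fits$lld[f]; lloq <- fits$lloq[f]; uloq <- fits$uloq[f]
    flag <- rep("quantified", length(g))
    val <- x * dilution_factor
    low <- x < lloq
    flag[low] <- "imputed_low"
    flag[x < lld] <- "below_lld"
    val[low | x < lld] <- lloq * dilution_factor
    high <- x > uloq
    flag[high] <- "imputed_high"
    val[high] <- uloq * dilution_factor
    out$conc[g] <- val
    out$flag[g] <- flag
  }
  out
}

#' Assemble the sample-by-analyte concentration table
#'
#' Averages replicate wells of the same sample/analyte on the concentration
#' scale (discarded wells do not contribute), errors if a sample appears on
#' more than one plate, and drops samples whose every non-discarded analyte
#' reading is below the lower limit of detection (logging how many).
#'
#' @param quantified Output of [quantify_wells()].
#' @param quiet Suppress the exclusion-accounting message.
#' @return A tibble of class `ontokine_conc`: `sample`, `plate`, `analyte`,
#'   `conc`, `flag`, one row per retained sample/analyte.
#' @export
assemble_table <- function(quantified, quiet = FALSE) {
  plate_per_sample <- quantified |>
    distinct(.data$sample, .data$plate)
  dup <- plate_per_sample$sample[duplicated(plate_per_sample$sample)]
  if (length(dup)) {
    abort(paste0(
      "Sample(s) present on more than one plate: ",
      paste(unique(dup), collapse = ", ")
    ))
  }
  flag_rank <- c(
    quantified = 1, imputed_low = 2, imputed_high = 2,
    below_lld = 3, no_curve = 4, discarded_low_beads = 5
  )
  key <- paste(quantified$sample, quantified$analyte, sep = "\r")
  if (anyDuplicated(key) == 0) {
    # no replicate wells: nothing to aggregate
    tab <- quantified |> select("sample", "plate", "analyte", "conc", "flag")
  } else {
    tab <- quantified |>
      group_by(.data$sample, .data$plate, .data$analyte) |>
      summarise(
        conc = if (all(is.na(.data$conc))) NA_real_ else mean(.data$conc, na.rm = TRUE),
        flag = .data$flag[which.min(flag_rank[.data$flag])],
        .groups = "drop"
      )
  }
  informative <- tab |>
    filter(!.data$flag %in% c("discarded_low_beads", "no_curve")) |>
    group_by(.data$sample) |>
    summarise(all_below = all(.data$flag == "below_lld"), .groups = "drop")
  drop_samples <- informative$sample[informative$all_below]
  # samples with no informative wells at all are dropped too
  empty <- setdiff(unique(tab$sample), informative$sample)
  drop_samples <- c(drop_samples, empty)
  if (!quiet && length(drop_samples)) {
    inform(sprintf(
      "Excluding %d sample(s) with all analytes below the lower limit of detection.",
      length(drop_samples)
    ))
  }
  out <- tab |> filter(!.data$sample %in% drop_samples)
  class(out) <- c("ontokine_conc", class(out))
  attr(out, "dropped_samples") <- drop_samples
  out
}

#' Expand participant metadata into a per-sample table
#'
#' Each participant contributes a DOL0 sample and one follow-up sample;
#' sample ids follow the `<participant>_D<dol>` convention used by the
#' synthetic generator.
#'
#' @param metadata Validated metadata tibble (see [read_metadata()]).
#' @return Tibble `sample`, `participant`, `dol`, `visit`.
#' @export
sample_table <- function(metadata) {
  tibble(
    participant = rep(metadata$participant, each = 2),
    dol = as.vector(rbind(0L, metadata$visit2_dol)),
    visit = rep(c(1L, 2L), times = nrow(metadata))
  ) |>
    mutate(sample = sprintf("%s_D%d", .data$participant, .data$dol)) |>
    select("sample", "participant", "dol", "visit")
}
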