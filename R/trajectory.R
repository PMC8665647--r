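#' Standardize normalized values per analyte
#'
#' Z-scores each analyte's log10 values over all study samples pooled
#' across visits (so the visit contrast the trajectories display is
#' preserved). Bridge and other non-study samples are excluded via the
#' `sample_info` join.
#'
#' @param norm An `ontokine_norm` or its `values` tibble.
#' @param sample_info Per-sample table from [sample_table()].
#' @return Tibble `sample`, `participant`, `dol`, `visit`, `analyte`,
#'   `value` (standardized).
#' @export
standardize_values <- function(norm, sample_info) {
  values <- if (inherits(norm, "ontokine_norm")) norm$values else norm
  values |>
    inner_join(sample_info, by = "sample") |>
    group_by(.data$analyte) |>
    mutate(value = (.data$value - mean(.data$value, na.rm = TRUE)) /
      sd(.data$value, na.rm = TRUE)) |>
    ungroup() |>
    select("sample", "participant", "dol", "visit", "analyte", "value")
}

#' Mean standardized trajectories
#'
#' Builds each analyte's 4-point mean time series over DOL {0, 1, 3, 7}:
#' values are standardized per analyte over all samples pooled, then
#' averaged per DOL. The DOL0 mean uses every participant; each follow-up
#' mean uses the subgroup sampled on that day.
#'
#' @inheritParams standardize_values
#' @param dols Days of life the series runs over.
#' @return Tibble of class `trajectory_set`: `analyte`, `dol`, `value`,
#'   `n`.
#' @export
build_trajectories <- function(norm, sample_info, dols = c(0, 1, 3, 7)) {
  std <- standardize_values(norm, sample_info)
  out <- std |>
    filter(.data$dol %in% dols) |>
    group_by(.data$analyte, .data$dol) |>
    summarise(
      value = mean(.data$value, na.rm = TRUE),
      n = sum(!is.na(.data$value)),
      .groups = "drop"
    ) |>
    arrange(.data$analyte, .data$dol)
  counts <- out |> distinct(.data$dol)
  missing <- setdiff(dols, counts$dol)
  if (length(missing)) {
    abort(paste0("No samples at DOL ", paste(missing, collapse = ", "), "."))
  }
  class(out) <- c("trajectory_set", class(out))
  out
}

#' Dynamic time warping distance
#'
#' Dynamic-programming global alignment cost between two series with
#' absolute-difference local cost and both endpoints matched. The default
#' step pattern uses unit weights for the three moves
#' `{(1,0), (0,1), (1,1)}`; `"symmetric2"` doubles the weight of the
#' diagonal move (the classic symmetric normalizable pattern). The full
#' window is used and series may differ in length.
#'
#' @param a,b Numeric series (finite, nonempty).
#' @param step `"unit"` (default) or `"symmetric2"`.
#' @return Nonnegative alignment cost.
#' @export
#' @examples
#' dtw_distance(c(0, 0), c(1, 1)) # 2
dtw_distance <- function(a, b, step = c("unit", "symmetric2")) {
  step <- match.arg(step)
  n <- length(a)
  m <- length(b)
  if (n == 0 || m == 0) abort("Empty series in dtw_distance().")
  if (any(!is.finite(a)) || any(!is.finite(b))) abort("Series must be finite.")
  w_diag <- if (step == "symmetric2") 2 else 1
  cost <- abs(outer(a, b, "-"))
  D <- matrix(NA_real_, n, m)
  D[1, 1] <- cost[1, 1]
  if (n > 1) for (i in 2:n) D[i, 1] <- D[i - 1, 1] + cost[i, 1]
  if (m > 1) for (j in 2:m) D[1, j] <- D[1, j - 1] + cost[1, j]
  if (n > 1 && m > 1) {
    for (i in 2:n) {
      for (j in 2:m) {
        D[i, j] <- min(
          D[i - 1, j] + cost[i, j],
          D[i, j - 1] + cost[i, j],
          D[i - 1, j - 1] + w_diag * cost[i, j]
        )
      }
    }
  }
  D[n, m]
}

#' Pairwise DTW distances between analyte trajectories
#'
#' @param traj A `trajectory_set` from [build_trajectories()].
#' @inheritParams dtw_distance
#' @return A symmetric analyte-by-analyte distance matrix (zero diagonal),
#'   rows/columns in lexicographic analyte order.
#' @export
trajectory_distances <- function(traj, step = c("unit", "symmetric2")) {
  step <- match.arg(step)
  wide <- traj |>
    select("analyte", "dol", "value") |>
    tidyr::pivot_wider(names_from = "dol", values_from = "value")
  wide <- wide[order(wide$analyte), , drop = FALSE]
  series <- as.matrix(wide[, -1, drop = FALSE])
  A <- nrow(series)
  D <- matrix(0, A, A, dimnames = list(wide$analyte, wide$analyte))
  for (i in seq_len(A - 1)) {
    for (j in (i + 1):A) {
      D[i, j] <- D[j, i] <- dtw_distance(series[i, ], series[j, ], step = step)
    }
  }
  D
}
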