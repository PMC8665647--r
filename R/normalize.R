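#' Log-transform a concentration table
#'
#' Elementwise log10 of the concentration values. Imputation upstream floors
#' every retained value at a positive limit of quantification, so a
#' nonpositive cell indicates corrupted input and is an error naming the
#' cell. Missing cells (discarded wells) propagate as `NA`.
#'
#' @param conc An `ontokine_conc` table from [assemble_table()] (or any
#'   tibble with `sample`, `plate`, `analyte`, `conc`).
#' @return Tibble `sample`, `plate`, `analyte`, `value` (log10 pg/mL).
#' @export
log_transform <- function(conc) {
  bad <- which(!is.na(conc$conc) & conc$conc <= 0)
  if (length(bad)) {
    b <- bad[1]
    abort(sprintf(
      "Nonpositive concentration for sample %s, analyte %s.",
      conc$sample[b], conc$analyte[b]
    ))
  }
  tibble(
    sample = conc$sample, plate = conc$plate, analyte = conc$analyte,
    value = log10(conc$conc)
  )
}

#' Batch design of a normalized table
#'
#' Records the sample-to-plate map and which samples are bridge aliquots
#' (the universal reference sample set run on every plate). By default
#' bridge samples are recognized by the `BRIDGE` prefix the synthetic
#' generator uses.
#'
#' @param df Tibble with `sample` and `plate` columns.
#' @param bridge_pattern Regular expression identifying bridge sample ids.
#' @param bridge_samples Explicit bridge sample ids (overrides the pattern).
#' @return A list of class `batch_design` with `samples` (tibble `sample`,
#'   `plate`, `is_bridge`) and `plates`.
#' @export
batch_design <- function(df, bridge_pattern = "^BRIDGE", bridge_samples = NULL) {
  samples <- df |> distinct(.data$sample, .data$plate)
  if (anyDuplicated(samples$sample)) {
    abort("A sample maps to more than one plate.")
  }
  samples$is_bridge <- if (is.null(bridge_samples)) {
    grepl(bridge_pattern, samples$sample)
  } else {
    samples$sample %in% bridge_samples
  }
  structure(
    list(samples = samples, plates = sort(unique(samples$plate))),
    class = "batch_design"
  )
}

#' Empirical-Bayes batch (plate) correction
#'
#' Parametric empirical-Bayes location/scale adjustment of plate effects:
#' per-analyte standardization, per-plate mean and variance estimates shrunk
#' toward pooled priors by the iterative parametric EB update, then removal
#' of the shrunken effects. No covariates enter the batch model. Missing
#' cells are tolerated (all moments are computed over observed cells) and
#' returned unchanged. A plate on which an analyte is constant gets its
#' scale estimate floored at `eps` with a warning. With a single plate the
#' transform is the identity.
#'
#' @param df Long tibble `sample`, `plate`, `analyte`, `value` (log10 scale).
#' @param design Optional [batch_design()]; derived from `df` if omitted.
#' @param mean_only Correct locations only, leaving scales untouched.
#' @param eps Variance floor for degenerate estimates.
#' @param conv Convergence tolerance of the EB iteration.
#' @return Tibble of the same shape with corrected `value`.
#' @export
combat_correct <- function(df, design = NULL, mean_only = FALSE,
                           eps = 1e-8, conv = 1e-6) {
  if (is.null(design)) design <- batch_design(df)
  M <- long_to_matrix(df)
  batch <- design$samples$plate[match(colnames(M), design$samples$sample)]
  if (anyNA(batch)) abort("Samples missing from the batch design.")
  if (length(unique(batch)) < 2) {
    return(df) # single batch: identity
  }
  adj <- combat_adjust(M, factor(batch), mean_only = mean_only, eps = eps, conv = conv)
  out <- df
  out$value <- adj[cbind(
    match(df$analyte, rownames(adj)),
    match(df$sample, colnames(adj))
  )]
  out
}

# core parametric-EB adjustment on an analytes x samples matrix
combat_adjust <- function(M, batch, mean_only = FALSE, eps = 1e-8, conv = 1e-6) {
  levs <- levels(batch)
  G <- nrow(M)
  obs <- !is.na(M)
  # per-batch per-analyte means and observation counts
  n_gb <- sapply(levs, function(b) rowSums(obs[, batch == b, drop = FALSE]))
  if (any(n_gb < 2)) {
    warn("Some plate has < 2 observed values for an analyte; its EB estimates are unstable.")
  }
  B_hat <- sapply(levs, function(b) {
    rowMeans(M[, batch == b, drop = FALSE], na.rm = TRUE)
  })
  B_hat[!is.finite(B_hat)] <- 0
  grand <- rowSums(B_hat * n_gb) / rowSums(n_gb)
  resid <- M - B_hat[, match(batch, levs), drop = FALSE]
  var_pooled <- rowSums(resid^2, na.rm = TRUE) / rowSums(obs)
  degenerate <- var_pooled < eps
  if (any(degenerate)) {
    warn(sprintf(
      "Variance floored at eps for %d analyte(s) with (near-)constant values.",
      sum(degenerate)
    ))
    var_pooled[degenerate] <- eps
  }
  Z <- (M - grand) / sqrt(var_pooled)

  gamma_hat <- sapply(levs, function(b) rowMeans(Z[, batch == b, drop = FALSE], na.rm = TRUE))
  delta_hat <- sapply(levs, function(b) {
    apply(Z[, batch == b, drop = FALSE], 1, var, na.rm = TRUE)
  })
  delta_hat[!is.finite(delta_hat) | delta_hat < eps] <- eps

  gamma_bar <- colMeans(gamma_hat)
  t2 <- apply(gamma_hat, 2, var)
  V <- colMeans(delta_hat)
  S <- apply(delta_hat, 2, var)
  a_prior <- (2 * S + V^2) / S
  b_prior <- (V * S + V^3) / S

  gamma_star <- gamma_hat
  delta_star <- delta_hat
  for (j in seq_along(levs)) {
    b <- levs[j]
    Zb <- Z[, batch == b, drop = FALSE]
    n <- n_gb[, j]
    g_old <- gamma_hat[, j]
    d_old <- delta_hat[, j]
    if (!is.finite(t2[j]) || t2[j] <= 0 || !is.finite(S[j]) || S[j] <= 0) {
      # degenerate priors (e.g. a single analyte): no shrinkage
      gamma_star[, j] <- g_old
      delta_star[, j] <- d_old
      next
    }
    change <- 1
    it <- 0
    while (change > conv && it < 200) {
      g_new <- (t2[j] * n * gamma_hat[, j] + d_old * gamma_bar[j]) /
        (t2[j] * n + d_old)
      sum2 <- rowSums((Zb - g_new)^2, na.rm = TRUE)
      d_new <- (0.5 * sum2 + b_prior[j]) / (n / 2 + a_prior[j] - 1)
      d_new[d_new < eps] <- eps
      change <- max(
        abs(g_new - g_old) / pmax(abs(g_old), eps),
        abs(d_new - d_old) / pmax(abs(d_old), eps)
      )
      g_old <- g_new
      d_old <- d_new
      it <- it + 1
    }
    gamma_star[, j] <- g_old
    delta_star[, j] <- if (mean_only) 1 else d_old
  }
  if (mean_only) delta_star[] <- 1

  idx <- match(batch, levs)
  adj <- (Z - gamma_star[, idx, drop = FALSE]) /
    sqrt(delta_star[, idx, drop = FALSE])
  adj * sqrt(var_pooled) + grand
}

#' Bridge-sample quality control
#'
#' Per analyte, the across-plate standard deviation of the plate-level
#' bridge-sample means, before and after batch correction. Analytes whose
#' post-correction bridge SD exceeds the pre-correction SD are flagged. If
#' some plate carries no bridge sample a warning is emitted and the QC is
#' computed over the remaining plates.
#'
#' @param before,after Long value tibbles (same shape) before and after
#'   [combat_correct()].
#' @param design A [batch_design()] identifying the bridge samples.
#' @return Tibble `analyte`, `sd_before`, `sd_after`, `flagged`.
#' @export
bridge_qc <- function(before, after, design = NULL) {
  if (is.null(design)) design <- batch_design(before)
  bridge_ids <- design$samples$sample[design$samples$is_bridge]
  if (!length(bridge_ids)) abort("No bridge samples in the design.")
  plates_with <- design$samples |>
    filter(.data$is_bridge) |>
    distinct(.data$plate)
  missing_plates <- setdiff(design$plates, plates_with$plate)
  if (length(missing_plates)) {
    warn(sprintf(
      "%d plate(s) carry no bridge sample; QC uses the remaining plates.",
      length(missing_plates)
    ))
  }
  plate_sd <- function(df) {
    df |>
      filter(.data$sample %in% bridge_ids) |>
      group_by(.data$analyte, .data$plate) |>
      summarise(m = mean(.data$value, na.rm = TRUE), .groups = "drop") |>
      group_by(.data$analyte) |>
      summarise(sd = sd(.data$m, na.rm = TRUE), .groups = "drop")
  }
  qc <- full_join(
    plate_sd(before) |> rename(sd_before = "sd"),
    plate_sd(after) |> rename(sd_after = "sd"),
    by = "analyte"
  ) |>
    mutate(flagged = .data$sd_after > .data$sd_before)
  qc
}

#' Near-zero-variance analyte filter
#'
#' An analyte is excluded when both (i) the ratio of the counts of its most
#' frequent to second most frequent value exceeds `freq_ratio_cut` and (ii)
#' its percentage of unique values is below `unique_pct_cut` — the standard
#' near-zero-variance rule, with the conventional defaults (95/5 and 10).
#' Analytes with a single unique value are always excluded. This catches
#' floor-censored analytes whose cells sit almost entirely at the imputed
#' limit of quantification.
#'
#' @param df Long tibble `sample`, `analyte`, `value`.
#' @param freq_ratio_cut Frequency-ratio threshold (default `95/5`).
#' @param unique_pct_cut Unique-percentage threshold (default `10`).
#' @return List with `retained`, `excluded` (character vectors) and
#'   `metrics` (per-analyte tibble).
#' @export
nzv_filter <- function(df, freq_ratio_cut = 95 / 5, unique_pct_cut = 10) {
  metrics <- df |>
    filter(!is.na(.data$value)) |>
    group_by(.data$analyte) |>
    summarise(
      freq_ratio = {
        tab <- sort(table(.data$value), decreasing = TRUE)
        if (length(tab) == 1) Inf else unname(tab[1] / tab[2])
      },
      unique_pct = 100 * length(unique(.data$value)) / dplyr::n(),
      .groups = "drop"
    ) |>
    mutate(excluded = .data$freq_ratio > freq_ratio_cut &
      .data$unique_pct < unique_pct_cut)
  excluded <- metrics$analyte[metrics$excluded]
  retained <- metrics$analyte[!metrics$excluded]
  if (!length(retained)) abort("Near-zero-variance filter excluded every analyte.")
  list(retained = retained, excluded = excluded, metrics = metrics)
}

#' Normalize a concentration table end to end
#'
#' Convenience wrapper chaining the normalization stages in the package's
#' default order: log10 transform, near-zero-variance analyte filtering,
#' empirical-Bayes plate correction, bridge QC. Filtering runs before the
#' batch correction by default because the filter's frequency-ratio
#' signature for floor-censored analytes (cells tied at the imputed limit)
#' is destroyed once the correction maps the tied values to plate-specific
#' ones; set `nzv_after_combat = TRUE` for the other order.
#'
#' @param conc An `ontokine_conc` table.
#' @param design Optional [batch_design()].
#' @param combat Apply the batch correction (default TRUE).
#' @param nzv_after_combat Filter after rather than before correction.
#' @inheritParams nzv_filter
#' @inheritParams combat_correct
#' @return List of class `ontokine_norm`: `values` (long corrected tibble,
#'   retained analytes only), `retained`, `excluded`, `nzv_metrics`,
#'   `bridge_qc`, `design`.
#' @export
normalize_table <- function(conc, design = NULL, combat = TRUE,
                            nzv_after_combat = FALSE,
                            freq_ratio_cut = 95 / 5, unique_pct_cut = 10,
                            mean_only = FALSE) {
  lg <- log_transform(conc)
  if (is.null(design)) design <- batch_design(lg)
  nzv <- NULL
  if (!nzv_after_combat) {
    nzv <- nzv_filter(lg, freq_ratio_cut, unique_pct_cut)
    lg <- lg |> filter(.data$analyte %in% nzv$retained)
  }
  corrected <- if (combat) combat_correct(lg, design, mean_only = mean_only) else lg
  qc <- if (combat) bridge_qc(lg, corrected, design) else NULL
  if (nzv_after_combat) {
    nzv <- nzv_filter(corrected, freq_ratio_cut, unique_pct_cut)
    corrected <- corrected |> filter(.data$analyte %in% nzv$retained)
  }
  structure(
    list(
      values = corrected, retained = nzv$retained, excluded = nzv$excluded,
      nzv_metrics = nzv$metrics, bridge_qc = qc, design = design
    ),
    class = "ontokine_norm"
  )
}

#' @export
print.ontokine_norm <- function(x, ...) {
  cat("<ontokine_norm> ", length(x$retained), " retained analytes (",
    length(x$excluded), " excluded), ",
    dplyr::n_distinct(x$values$sample), " samples\n",
    sep = ""
  )
  invisible(x)
}
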