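#' Per-participant fold changes versus birth
#'
#' Fold change is computed by indexing the untransformed concentration at
#' the follow-up visit to the participant's DOL0 concentration and taking
#' log10 (log2 is carried alongside for the volcano criterion). Pairs with
#' either visit missing are skipped.
#'
#' @param conc An `ontokine_conc` table (untransformed pg/mL).
#' @param sample_info Per-sample table from [sample_table()].
#' @return Tibble `participant`, `analyte`, `dol` (follow-up day),
#'   `log10_fc`, `log2_fc`.
#' @export
fold_change <- function(conc, sample_info) {
  df <- conc |>
    inner_join(sample_info, by = "sample") |>
    select("participant", "analyte", "dol", "conc") |>
    tidyr::pivot_wider(names_from = "dol", values_from = "conc", names_prefix = "d")
  fu_cols <- intersect(c("d1", "d3", "d7"), names(df))
  out <- map(fu_cols, function(cl) {
    ok <- !is.na(df$d0) & !is.na(df[[cl]])
    tibble(
      participant = df$participant[ok],
      analyte = df$analyte[ok],
      dol = as.integer(sub("^d", "", cl)),
      log10_fc = log10(df[[cl]][ok] / df$d0[ok])
    )
  }) |> bind_rows()
  out$log2_fc <- out$log10_fc / log10(2)
  out
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided signed-rank test on paired values. Zero differences are
#' dropped (Wilcoxon's rule). The exact null distribution is used for
#' `n <= exact_max` untied differences; otherwise the normal approximation
#' with tie and continuity corrections. If every difference is zero the
#' test is degenerate: `p = 1` with a warning.
#'
#' @param x,y Paired numeric vectors (e.g. DOL0 and follow-up values).
#' @param exact_max Largest n for the exact distribution (default 25).
#' @return List `statistic` (V, the positive-rank sum), `p_value`, `n`
#'   (nonzero pairs), `exact`.
#' @export
#' @examples
#' paired_wilcoxon(c(1, 2, 3, 4, 5), c(2, 4, 6, 8, 10))$p_value # 1/16
paired_wilcoxon <- function(x, y, exact_max = 25) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  d <- y - x
  d <- d[!is.na(d)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    warn("All paired differences are zero; signed-rank test is degenerate.")
    return(list(statistic = 0, p_value = 1, n = 0L, exact = TRUE))
  }
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  ties <- anyDuplicated(r) > 0
  if (n <= exact_max && !ties) {
    p_le <- psignrank(W, n)
    p_ge <- 1 - psignrank(W - 1, n)
    p <- min(1, 2 * min(p_le, p_ge))
    exact <- TRUE
  } else {
    mu <- n * (n + 1) / 4
    tie_counts <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_counts^3 - tie_counts) / 48
    z <- W - mu
    z <- (z - sign(z) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * pnorm(-abs(z)))
    exact <- FALSE
  }
  list(statistic = unname(W), p_value = p, n = n, exact = exact)
}

#' Holm step-down multiple-testing adjustment with a fixed family size
#'
#' Step-down Bonferroni: with the raw p-values sorted ascending, the i-th
#' smallest is multiplied by `m - i + 1`, running maxima are taken, results
#' are capped at 1 and restored to input order. `m` may exceed the number
#' of p-values supplied, matching an analysis that fixes the family size at
#' the full analyte roster even when a contrast list is shorter.
#'
#' @param p Numeric vector of raw p-values in `[0, 1]`.
#' @param m Family size (default `length(p)`, must be `>= length(p)`).
#' @return Adjusted p-values in input order.
#' @export
#' @examples
#' holm_adjust(c(0.01, 0.04, 0.03), m = 3)
holm_adjust <- function(p, m = length(p)) {
  if (any(!is.na(p) & (p < 0 | p > 1))) abort("p-values must lie in [0, 1].")
  if (m < length(p)) abort("Family size `m` must be >= length(p).")
  p.adjust(p, method = "holm", n = m)
}

#' Paired ontogeny contrasts for every analyte and follow-up day
#'
#' For each analyte and follow-up day: the number of complete pairs, the
#' median log10 (and log2) fold change versus DOL0 on untransformed
#' concentrations, the two-sided paired Wilcoxon signed-rank test on the
#' normalized log10 values, and Holm-adjusted p-values with the family size
#' fixed at the retained-analyte count for every follow-up day.
#'
#' @param norm An `ontokine_norm` (or its `values` tibble).
#' @param sample_info Per-sample table from [sample_table()].
#' @param conc Untransformed `ontokine_conc` table for the fold changes.
#' @param family_size Holm family size; defaults to the number of analytes
#'   tested.
#' @return Tibble of class `ontokine_contrasts`: `analyte`, `dol`,
#'   `n_pairs`, `median_log10_fc`, `median_log2_fc`, `statistic`, `p_raw`,
#'   `p_holm`.
#' @export
ontogeny_contrasts <- function(norm, sample_info, conc, family_size = NULL) {
  values <- if (inherits(norm, "ontokine_norm")) norm$values else norm
  if (is.null(family_size)) family_size <- dplyr::n_distinct(values$analyte)
  fc <- fold_change(conc, sample_info) |>
    filter(.data$analyte %in% unique(values$analyte)) |>
    group_by(.data$analyte, .data$dol) |>
    summarise(
      median_log10_fc = median(.data$log10_fc),
      median_log2_fc = median(.data$log2_fc),
      .groups = "drop"
    )
  pairs <- values |>
    inner_join(sample_info, by = "sample") |>
    select("participant", "analyte", "dol", "value") |>
    tidyr::pivot_wider(names_from = "dol", values_from = "value", names_prefix = "d")
  fu_cols <- intersect(c("d1", "d3", "d7"), names(pairs))
  tests <- map(fu_cols, function(cl) {
    pairs |>
      group_by(.data$analyte) |>
      summarise(
        dol = as.integer(sub("^d", "", cl)),
        n_pairs = sum(!is.na(.data$d0) & !is.na(.data[[cl]])),
        res = {
          ok <- !is.na(.data$d0) & !is.na(.data[[cl]])
          list(paired_wilcoxon(.data$d0[ok], .data[[cl]][ok]))
        },
        .groups = "drop"
      )
  }) |>
    bind_rows() |>
    mutate(
      statistic = map_dbl(.data$res, "statistic"),
      p_raw = map_dbl(.data$res, "p_value")
    ) |>
    select(-"res") |>
    group_by(.data$dol) |>
    mutate(p_holm = holm_adjust(.data$p_raw, m = family_size)) |>
    ungroup()
  out <- tests |>
    left_join(fc, by = c("analyte", "dol")) |>
    select(
      "analyte", "dol", "n_pairs", "median_log10_fc", "median_log2_fc",
      "statistic", "p_raw", "p_holm"
    )
  class(out) <- c("ontokine_contrasts", class(out))
  out
}

#' Volcano criterion
#'
#' Flags analyte/day contrasts jointly significant and of meaningful
#' magnitude: raw paired-test p below `p_cut` and absolute log2 fold change
#' versus DOL0 above `lfc_cut` (defaults 0.01 and 0.2).
#'
#' @param contrasts An `ontokine_contrasts` tibble.
#' @param p_cut P-value threshold (default 0.01).
#' @param lfc_cut Absolute log2 fold-change threshold (default 0.2).
#' @param use_adjusted Apply `p_cut` to the Holm-adjusted p instead.
#' @return The input with a logical `hit` column.
#' @export
volcano_filter <- function(contrasts, p_cut = 0.01, lfc_cut = 0.2,
                           use_adjusted = FALSE) {
  p <- if (use_adjusted) contrasts$p_holm else contrasts$p_raw
  contrasts$hit <- p < p_cut & abs(contrasts$median_log2_fc) > lfc_cut
  contrasts
}

#' PCA summary of a normalized matrix
#'
#' Principal component analysis of the sample-by-analyte matrix with every
#' analyte centered and scaled to unit variance. Samples with missing cells
#' (discarded wells) are dropped for this summary.
#'
#' @param norm An `ontokine_norm` or its `values` tibble.
#' @param sample_info Optional per-sample table to carry `dol`/`visit` onto
#'   the scores.
#' @return Object of class `ontokine_pca`: `explained` (per-component
#'   variance fractions), `loadings`, `scores` tibbles, `n_samples`,
#'   `n_dropped`.
#' @export
pca_summary <- function(norm, sample_info = NULL) {
  values <- if (inherits(norm, "ontokine_norm")) norm$values else norm
  M <- long_to_matrix(values) # analytes x samples
  keep <- colSums(is.na(M)) == 0
  M <- M[, keep, drop = FALSE]
  if (ncol(M) < 2 || nrow(M) < 2) abort("PCA needs at least 2 samples and 2 analytes.")
  if (any(apply(M, 1, sd) == 0)) {
    abort("Constant analyte encountered in PCA input; filter it upstream.")
  }
  pc <- prcomp(t(M), center = TRUE, scale. = TRUE)
  expl <- pc$sdev^2 / sum(pc$sdev^2)
  scores <- as_tibble(pc$x, .name_repair = "minimal") |>
    mutate(sample = colnames(M), .before = 1)
  if (!is.null(sample_info)) {
    scores <- left_join(scores, sample_info, by = "sample")
  }
  loadings <- as_tibble(pc$rotation, .name_repair = "minimal") |>
    mutate(analyte = rownames(pc$rotation), .before = 1)
  structure(
    list(
      explained = tibble(
        component = seq_along(expl),
        var_fraction = expl
      ),
      loadings = loadings, scores = scores,
      n_samples = ncol(M), n_dropped = sum(!keep)
    ),
    class = "ontokine_pca"
  )
}

#' @exportS3Method generics::glance
glance.ontokine_pca <- function(x, ...) {
  tibble(
    n_samples = x$n_samples,
    n_dropped = x$n_dropped,
    pc1_var = x$explained$var_fraction[1],
    pc2_var = x$explained$var_fraction[2],
    pc12_var = sum(x$explained$var_fraction[1:2])
  )
}

#' Covariate association models
#'
#' Fits, per analyte, an ordinary least-squares model of the normalized
#' value on the covariate, a visit term (1 = birth, 2 = follow-up) and
#' their interaction, and returns the coefficient table with Holm-adjusted
#' p-values per term across analytes. Rank-deficient designs (e.g. a
#' single-level covariate) are flagged and skipped.
#'
#' @param norm An `ontokine_norm` or its `values` tibble.
#' @param sample_info Per-sample table from [sample_table()].
#' @param metadata Participant metadata (see [read_metadata()]).
#' @param covariate Name of the metadata column to test
#'   (`sex`, `ethnicity`, `mat_age_band`, `gest_cat`, `bf_v1`, ...).
#' @param family_size Holm family size (default: analytes tested).
#' @return Tibble `analyte`, `term`, `estimate`, `std_error`, `p_raw`,
#'   `p_holm`, `flagged`.
#' @export
covariate_association <- function(norm, sample_info, metadata, covariate,
                                  family_size = NULL) {
  values <- if (inherits(norm, "ontokine_norm")) norm$values else norm
  if (!covariate %in% names(metadata)) {
    abort(paste0("Covariate `", covariate, "` not in metadata."))
  }
  df <- values |>
    inner_join(sample_info, by = "sample") |>
    inner_join(metadata[, c("participant", covariate)], by = "participant")
  df$visit_f <- factor(df$visit)
  df$cov_ <- df[[covariate]]
  if (dplyr::n_distinct(df$cov_[!is.na(df$cov_)]) < 2) {
    return(tibble(
      analyte = unique(df$analyte), term = NA_character_,
      estimate = NA_real_, std_error = NA_real_,
      p_raw = NA_real_, p_holm = NA_real_, flagged = TRUE
    ))
  }
  if (is.null(family_size)) family_size <- dplyr::n_distinct(df$analyte)
  per_analyte <- df |>
    group_by(.data$analyte) |>
    group_map(function(d, key) {
      fit <- lm(value ~ cov_ * visit_f, data = d)
      sm <- summary(fit)$coefficients
      aliased <- any(is.na(coef(fit)))
      tibble(
        analyte = key$analyte,
        term = rownames(sm),
        estimate = sm[, "Estimate"],
        std_error = sm[, "Std. Error"],
        p_raw = sm[, "Pr(>|t|)"],
        flagged = aliased
      )
    }) |>
    bind_rows() |>
    filter(.data$term != "(Intercept)") |>
    mutate(term = gsub("cov_", covariate, .data$term, fixed = TRUE)) |>
    group_by(.data$term) |>
    mutate(p_holm = holm_adjust(.data$p_raw, m = family_size)) |>
    ungroup()
  per_analyte
}

#' Cluster-level paired t-tests and confidence intervals
#'
#' For each trajectory cluster: the per-participant mean of the
#' standardized values over the cluster's analytes is formed at DOL0 and at
#' the follow-up visit, and a two-sided paired t-test compares the two,
#' separately for each follow-up day. The 95% confidence interval of the
#' cluster mean is reported per DOL. Clusters contributing fewer than 3
#' complete pairs get the interval only, no test.
#'
#' @param std Long tibble of standardized values (`sample`, `analyte`,
#'   `value`), e.g. from [standardize_values()].
#' @param labels Tibble `analyte`, `cluster`.
#' @param sample_info Per-sample table from [sample_table()].
#' @param conf_level Confidence level for the cluster-mean interval.
#' @return Tibble `cluster`, `dol`, `n_pairs`, `mean`, `ci_lo`, `ci_hi`,
#'   `t`, `p_value` (t/p `NA` for DOL0 rows and underpowered clusters).
#' @export
cluster_paired_ttest <- function(std, labels, sample_info, conf_level = 0.95) {
  df <- std |>
    select(dplyr::any_of(c("sample", "analyte", "value"))) |>
    inner_join(labels, by = "analyte") |>
    inner_join(sample_info, by = "sample") |>
    group_by(.data$cluster, .data$participant, .data$dol, .data$visit) |>
    summarise(value = mean(.data$value, na.rm = TRUE), .groups = "drop")
  # per-cluster, per-DOL mean and CI
  ci <- df |>
    group_by(.data$cluster, .data$dol) |>
    summarise(
      n = sum(!is.na(.data$value)),
      mean = mean(.data$value, na.rm = TRUE),
      se = sd(.data$value, na.rm = TRUE) / sqrt(.data$n),
      .groups = "drop"
    ) |>
    mutate(
      tcrit = ifelse(.data$n >= 2, qt((1 - conf_level) / 2, pmax(.data$n - 1, 1)), NA_real_),
      ci_lo = .data$mean + .data$tcrit * .data$se,
      ci_hi = .data$mean - .data$tcrit * .data$se
    ) |>
    select(-"tcrit")
  # paired tests DOL0 vs follow-up, within the follow-up-day subgroup
  wide <- df |>
    select("cluster", "participant", "visit", "value") |>
    tidyr::pivot_wider(names_from = "visit", values_from = "value", names_prefix = "v") |>
    inner_join(metadata_fu(sample_info), by = "participant")
  tests <- wide |>
    group_by(.data$cluster, .data$dol) |>
    summarise(
      n_pairs = sum(!is.na(.data$v1) & !is.na(.data$v2)),
      res = {
        ok <- !is.na(.data$v1) & !is.na(.data$v2)
        if (sum(ok) >= 3) {
          tt <- t.test(.data$v2[ok], .data$v1[ok], paired = TRUE)
          list(c(t = unname(tt$statistic), p = tt$p.value))
        } else {
          list(c(t = NA_real_, p = NA_real_))
        }
      },
      .groups = "drop"
    ) |>
    mutate(
      t = map_dbl(.data$res, "t"),
      p_value = map_dbl(.data$res, "p")
    ) |>
    select(-"res")
  ci |>
    left_join(tests, by = c("cluster", "dol")) |>
    select(
      "cluster", "dol", "n", "mean", "ci_lo", "ci_hi", "n_pairs", "t",
      "p_value"
    )
}

# follow-up day per participant, derived from the sample table
metadata_fu <- function(sample_info) {
  sample_info |>
    filter(.data$visit == 2L) |>
    distinct(.data$participant, dol = .data$dol)
}
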