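# two-plate fixture with a planted location shift (and optional scale) on
# plate 2, no real biology: what batch correction must remove
planted_batch_data <- function(n_per_plate = 60, n_analytes = 8, shift = 0.5,
                               scale = 1, seed = 11) {
  withr::with_seed(seed, {
    analytes <- sprintf("A%02d", seq_len(n_analytes))
    samples <- sprintf("S%03d", seq_len(2 * n_per_plate))
    plate <- rep(1:2, each = n_per_plate)
    base <- runif(n_analytes, 1, 3)
    rows <- lapply(seq_along(analytes), function(i) {
      x <- base[i] + rnorm(length(samples), 0, 0.2)
      x <- ifelse(plate == 2, base[i] + (x - base[i]) * scale + shift, x)
      tibble::tibble(sample = samples, plate = plate, analyte = analytes[i], value = x)
    })
    dplyr::bind_rows(rows)
  })
}

plate_means <- function(df) {
  df |>
    dplyr::group_by(analyte, plate) |>
    dplyr::summarise(m = mean(value, na.rm = TRUE), .groups = "drop") |>
    tidyr::pivot_wider(names_from = plate, values_from = m, names_prefix = "p")
}

test_that("log transform is elementwise log10 and names offending cells", {
  conc <- tibble::tibble(
    sample = c("S1", "S1", "S2"), plate = 1L,
    analyte = c("IL-6", "IL-10", "IL-6"), conc = c(100, 1, 0.001),
    flag = "quantified"
  )
  lg <- log_transform(conc)
  expect_equal(lg$value, c(2, 0, -3))
  conc$conc[2] <- 0
  expect_error(log_transform(conc), "S1.*IL-10")
})

test_that("a planted 0.5 log10 plate shift is removed to < 0.05", {
  df <- planted_batch_data(shift = 0.5)
  pm_before <- plate_means(df)
  expect_true(all(abs(pm_before$p2 - pm_before$p1 - 0.5) < 0.15))
  corrected <- suppressWarnings(combat_correct(df))
  pm <- plate_means(corrected)
  expect_true(all(abs(pm$p2 - pm$p1) < 0.05))
})

test_that("planted scale effects are equalized within 10% systematically", {
  df <- planted_batch_data(shift = 0.5, scale = 2, n_per_plate = 170)
  ratios <- function(d) {
    d |>
      dplyr::group_by(analyte, plate) |>
      dplyr::summarise(v = var(value), .groups = "drop") |>
      tidyr::pivot_wider(names_from = plate, values_from = v, names_prefix = "p") |>
      dplyr::mutate(r = p2 / p1) |>
      dplyr::pull(r)
  }
  expect_gt(mean(ratios(df)), 3) # planted 2x SD = 4x variance
  corrected <- suppressWarnings(combat_correct(df))
  r <- ratios(corrected)
  # the systematic scale effect is gone; per-analyte ratios keep only the
  # sampling noise of a variance estimate at this plate size
  expect_true(abs(mean(r) - 1) < 0.1)
  expect_true(all(r > 0.6 & r < 1.6))
})

test_that("single batch is an identity transform", {
  df <- planted_batch_data()
  df1 <- df[df$plate == 1, ]
  expect_equal(combat_correct(df1), df1)
})

test_that("the grand mean of each analyte is essentially preserved", {
  df <- planted_batch_data(shift = 0.3, scale = 1.5)
  corrected <- suppressWarnings(combat_correct(df))
  gm <- function(d) {
    d |>
      dplyr::group_by(analyte) |>
      dplyr::summarise(m = mean(value), .groups = "drop")
  }
  # the EB estimator preserves the pooled location up to shrinkage residue
  expect_equal(gm(corrected)$m, gm(df)$m, tolerance = 1e-2)
})

test_that("re-correcting corrected data is a much smaller perturbation", {
  # the EB estimator is not exactly idempotent (shrinkage leaves a residual
  # a second pass partially removes); the honest property is contraction
  df <- planted_batch_data(shift = 0.5)
  c1 <- suppressWarnings(combat_correct(df))
  c2 <- suppressWarnings(combat_correct(c1))
  first <- max(abs(c1$value - df$value))
  second <- max(abs(c2$value - c1$value))
  expect_lt(second, 0.1 * first)
  expect_lt(second, 0.02)
})

test_that("correction on batch-effect-free data barely perturbs cells", {
  # plates sized like the default cohort (about 170 samples each)
  q95 <- withr::with_seed(21, vapply(1:10, function(i) {
    df <- planted_batch_data(
      shift = 0, scale = 1, n_per_plate = 170, seed = 1000 + i
    )
    corrected <- suppressWarnings(combat_correct(df))
    quantile(abs(corrected$value - df$value), 0.95)
  }, numeric(1)))
  expect_true(all(q95 < 0.02))
})

test_that("the EB adjustment matches the reference ComBat implementation", {
  skip_if_not_installed("sva")
  df <- planted_batch_data(shift = 0.4, scale = 1.5, n_analytes = 10)
  M <- ontokine:::long_to_matrix(df)
  batch <- df$plate[match(colnames(M), df$sample)]
  mine <- ontokine:::combat_adjust(M, factor(batch))
  ref <- suppressMessages(sva::ComBat(M, batch = factor(batch)))
  expect_equal(mine, ref, tolerance = 1e-5)
})

test_that("constant-analyte plates are floored with a warning, not an error", {
  df <- planted_batch_data(n_analytes = 5)
  df$value[df$analyte == "A01"] <- 2 # constant everywhere
  expect_warning(combat_correct(df), "floored")
})

test_that("bridge QC reports the across-plate SD before and after", {
  cohort <- .small$cohort
  norm <- .small$norm
  qc <- norm$bridge_qc
  expect_setequal(names(qc), c("analyte", "sd_before", "sd_after", "flagged"))
  # correction must on the whole shrink bridge variability
  expect_lt(mean(qc$sd_after / qc$sd_before, na.rm = TRUE), 0.6)
  # an uncorrected matrix reports the planted plate spread: compare one
  # analyte against the planted location effects
  lg <- log_transform(.small$conc)
  qc0 <- bridge_qc(lg, lg)
  expect_equal(qc0$sd_before, qc0$sd_after)
  expect_true(all(qc0$sd_before[!is.na(qc0$sd_before)] >= 0))
})

test_that("bridge QC tolerates a plate without bridge samples", {
  lg <- log_transform(.small$conc)
  no_bridge_p1 <- lg[!(grepl("^BRIDGE", lg$sample) & lg$plate == 1), ]
  design <- batch_design(no_bridge_p1)
  expect_warning(bridge_qc(no_bridge_p1, no_bridge_p1, design), "no bridge")
})

test_that("near-zero-variance rule counts frequencies and unique values", {
  n <- 200
  vals <- withr::with_seed(3, {
    tibble::tibble(
      sample = rep(sprintf("S%03d", 1:n), 3),
      analyte = rep(c("floored", "spread", "binary"), each = n),
      value = c(
        c(rep(1.5, 191), runif(9)), # 95.5% at the floor, rest unique
        runif(n), # all unique
        rep(c(0, 1), each = n / 2) # two balanced values: ratio 1
      )
    )
  })
  res <- nzv_filter(vals)
  expect_equal(res$excluded, "floored")
  expect_setequal(res$retained, c("spread", "binary"))

  skip_if_not_installed("caret")
  M <- t(ontokine:::long_to_matrix(vals))
  ref <- caret::nearZeroVar(as.data.frame(M), saveMetrics = TRUE)
  expect_equal(res$metrics$excluded[match(rownames(ref), res$metrics$analyte)], ref$nzv)
})

test_that("a filter excluding everything is an error", {
  df <- tibble::tibble(
    sample = rep(sprintf("S%d", 1:100), 1),
    analyte = "only", value = rep(7, 100)
  )
  expect_error(nzv_filter(df), "every analyte")
})

test_that("the synthetic cohort retains 38 of 41 analytes", {
  norm <- .small$norm
  expect_length(norm$retained, 38)
  expect_setequal(norm$excluded, c("IL-2", "IL-3", "IL-17A"))
  # retained analytes have positive variance
  v <- norm$values |>
    dplyr::group_by(analyte) |>
    dplyr::summarise(v = var(value, na.rm = TRUE))
  expect_true(all(v$v > 0))
})
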