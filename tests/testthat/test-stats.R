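test_that("fold change is log10 of the follow-up / birth concentration ratio", {
  md <- read_metadata(
    tibble::tibble(participant = c("P1", "P2", "P3"), sex = "F", visit2_dol = c(1L, 3L, 7L)),
    quiet = TRUE
  )
  si <- sample_table(md)
  conc <- tibble::tibble(
    sample = c("P1_D0", "P1_D1", "P2_D0", "P2_D3", "P3_D0"),
    plate = 1L, analyte = "IL-6",
    conc = c(100, 1000, 200, 50, 10), flag = "quantified"
  )
  fc <- fold_change(conc, si)
  expect_equal(fc$log10_fc[fc$participant == "P1"], 1)
  expect_equal(fc$log10_fc[fc$participant == "P2"], log10(0.25), tolerance = 1e-12)
  expect_equal(fc$log2_fc[fc$participant == "P1"], log2(10), tolerance = 1e-12)
  # P3 has no follow-up value: the pair is skipped
  expect_false("P3" %in% fc$participant)
  # identical visits give exactly zero
  conc0 <- conc
  conc0$conc <- 100
  expect_equal(fold_change(conc0, si)$log10_fc, c(0, 0))
})

test_that("signed-rank exact p matches hand-enumerable cases", {
  # n = 5, all positive differences: one-sided 1/32, two-sided 1/16
  r5 <- paired_wilcoxon(c(1, 2, 3, 4, 5), c(2, 4, 6, 8, 10))
  expect_equal(r5$p_value, 1 / 16)
  expect_equal(r5$statistic, 15)
  # n = 8, all positive: two-sided 2/256
  r8 <- paired_wilcoxon(rep(0, 8), 1:8)
  expect_equal(r8$p_value, 2 / 256)
  # antisymmetric differences: p = 1
  expect_equal(paired_wilcoxon(c(0, 0), c(-1, 1))$p_value, 1)
  # all-zero differences: degenerate, p = 1 with a warning
  expect_warning(r0 <- paired_wilcoxon(1:4, 1:4), "degenerate")
  expect_equal(r0$p_value, 1)
})

test_that("signed-rank agrees with sign-flip enumeration for n <= 10", {
  withr::with_seed(42, {
    for (i in 1:100) {
      n <- sample(2:10, 1)
      d <- round(rnorm(n, mean = sample(c(-0.5, 0, 0.5), 1)), 6)
      d <- ifelse(d == 0, 0.1, d)
      res <- paired_wilcoxon(rep(0, n), d)
      expect_equal(res$p_value, enumerate_signrank(d), tolerance = 1e-12)
    }
  })
})

test_that("signed-rank agrees with the stats implementation where exact", {
  withr::with_seed(7, {
    for (i in 1:20) {
      n <- sample(6:20, 1)
      x <- rnorm(n)
      y <- x + rnorm(n, 0.3)
      res <- paired_wilcoxon(x, y)
      ref <- wilcox.test(y, x, paired = TRUE, exact = TRUE)
      expect_equal(res$p_value, ref$p.value, tolerance = 1e-12)
      expect_equal(res$statistic, unname(ref$statistic))
    }
  })
})

test_that("Holm adjustment matches the brute-force step-down oracle", {
  expect_equal(holm_adjust(c(0.01, 0.04, 0.03), m = 3), c(0.03, 0.06, 0.06))
  expect_equal(holm_adjust(0.2, m = 1), 0.2)
  withr::with_seed(13, {
    for (i in 1:100) {
      p <- runif(sample(1:12, 1))
      m <- length(p) + sample(0:30, 1) # fixed family sizes beyond the list
      adj <- holm_adjust(p, m = m)
      expect_equal(adj, holm_oracle(p, m))
      expect_true(all(adj >= p & adj <= 1))
      # monotone w.r.t. raw ranks
      expect_true(all(diff(adj[order(p)]) >= -1e-15))
    }
  })
  expect_error(holm_adjust(c(0.1, 1.2)), "0, 1")
  expect_error(holm_adjust(c(0.1, 0.2), m = 1), ">= length")
})

test_that("ontogeny contrasts flag the planted kinetic classes coherently", {
  norm <- .small$norm
  si <- .small$sample_info
  contrasts <- suppressWarnings(ontogeny_contrasts(norm, si, .small$conc))
  expect_equal(sort(unique(contrasts$dol)), c(1, 3, 7))
  expect_true(all(contrasts$p_raw <= contrasts$p_holm + 1e-15))
  expect_true(all(contrasts$n_pairs <= 40))
  # class-4 analytes (steady decrease) must show negative DOL7 fold changes
  truth <- .small$cohort$truth$analytes
  c4 <- truth$analyte[!truth$censored & truth$archetype == 4]
  d7 <- contrasts[contrasts$dol == 7 & contrasts$analyte %in% c4, ]
  expect_true(all(d7$median_log10_fc < 0))
  vol <- volcano_filter(contrasts)
  expect_true(all(vol$hit[vol$analyte %in% c4 & vol$dol == 7]))
})

test_that("PCA summary is orthonormal, ordered, and order-invariant", {
  norm <- .small$norm
  pca <- pca_summary(norm, .small$sample_info)
  expect_true(all(diff(pca$explained$var_fraction) <= 1e-12))
  expect_lte(sum(pca$explained$var_fraction), 1 + 1e-8)
  L <- as.matrix(pca$loadings[, -1])
  expect_equal(crossprod(L), diag(ncol(L)), tolerance = 1e-8, ignore_attr = TRUE)
  # permuting sample order leaves the spectrum unchanged
  shuffled <- norm$values[withr::with_seed(1, sample(nrow(norm$values))), ]
  pca2 <- pca_summary(shuffled)
  expect_equal(pca2$explained$var_fraction, pca$explained$var_fraction, tolerance = 1e-8)
})

test_that("a rank-1 planted factor loads PC1 with > 99% variance", {
  withr::with_seed(5, {
    f <- rnorm(100)
    vals <- tidyr::expand_grid(sample = sprintf("S%03d", 1:100), analyte = sprintf("A%d", 1:6))
    vals$value <- f[as.integer(sub("S", "", vals$sample))] *
      (1 + 0.2 * as.integer(sub("A", "", vals$analyte))) +
      rnorm(nrow(vals), 0, 1e-3)
    vals$plate <- 1L
    pca <- pca_summary(vals)
    expect_gt(pca$explained$var_fraction[1], 0.99)
  })
})

test_that("covariate models detect planted visit effects and respect nulls", {
  # the synthetic cohort plants no sex effect but strong visit kinetics
  res <- covariate_association(.small$norm, .small$sample_info,
    read_metadata(.small$cohort$metadata, quiet = TRUE),
    covariate = "sex"
  )
  expect_true(all(c("estimate", "p_raw", "p_holm") %in% names(res)))
  truth <- .small$cohort$truth$analytes
  moving <- truth$analyte[!truth$censored & truth$archetype %in% 3:5]
  visit_p <- res$p_holm[res$term == "visit_f2" & res$analyte %in% moving]
  sex_p <- res$p_holm[res$term == "sexM"]
  # classes with sustained kinetics move with visit; sex stays null
  expect_gt(mean(visit_p < 0.05), 0.5)
  expect_lt(mean(sex_p < 0.05), 0.2)

  # a planted sex effect is picked up
  cohort_sex <- generate_cohort(small_config(seed = 77, sex_effect = 0.15))
  fe <- run_front_end(cohort_sex, seed = 3)
  res2 <- covariate_association(fe$norm, fe$sample_info,
    read_metadata(cohort_sex$metadata, quiet = TRUE),
    covariate = "sex"
  )
  expect_gt(mean(res2$p_holm[res2$term == "sexM"] < 0.05), 0.5)

  # single-level covariate is flagged, not fitted
  md <- read_metadata(.small$cohort$metadata, quiet = TRUE)
  md$sex <- "F"
  res3 <- covariate_association(.small$norm, .small$sample_info, md, "sex")
  expect_true(all(res3$flagged))
})

test_that("cluster-level paired t-tests detect planted shifts with interval cover", {
  toy <- toy_norm_values(list(
    up = c(0, 0, 0.5, 1), flat = c(0, 0, 0, 0)
  ), n_each = 3, participants = 60)
  std <- standardize_values(toy$values, toy$sample_info)
  labels <- tibble::tibble(
    analyte = unique(toy$values$analyte),
    cluster = ifelse(grepl("^up", unique(toy$values$analyte)), 1L, 2L)
  )
  res <- cluster_paired_ttest(std, labels, toy$sample_info)
  up7 <- res[res$cluster == 1 & res$dol == 7, ]
  expect_lt(up7$p_value, 1e-4)
  expect_true(up7$ci_lo < up7$mean & up7$mean < up7$ci_hi)
  flat <- res[res$cluster == 2 & res$dol %in% c(1, 3, 7), ]
  expect_true(all(flat$p_value > 1e-4))
  # fewer than 3 pairs: interval only, no test
  tiny <- toy_norm_values(list(up = c(0, 0, 0.5, 1)), n_each = 2, participants = 3)
  std_t <- standardize_values(tiny$values, tiny$sample_info)
  lab_t <- tibble::tibble(analyte = unique(tiny$values$analyte), cluster = 1L)
  res_t <- cluster_paired_ttest(std_t, lab_t, tiny$sample_info)
  expect_true(all(is.na(res_t$t)))
})
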