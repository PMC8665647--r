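# shared fixtures, built in code once per test run

# a scaled-down cohort: full 41-analyte panel, 3 plates, 120 participants
small_config <- function(seed = 101, ...) {
  sim_config(
    n_participants = 120L,
    visit2_counts = c("1" = 40L, "3" = 40L, "7" = 40L),
    n_plates = 3L,
    seed = seed,
    ...
  )
}

# run the quantification + normalization front end of the pipeline
run_front_end <- function(cohort, seed = 1L) {
  curves <- suppressWarnings(
    fit_standard_curves(cohort$standards, seed = seed)
  )
  conc <- assemble_table(quantify_wells(cohort$plates, curves), quiet = TRUE)
  norm <- suppressWarnings(suppressMessages(normalize_table(conc)))
  si <- sample_table(read_metadata(cohort$metadata, quiet = TRUE))
  list(curves = curves, conc = conc, norm = norm, sample_info = si)
}

planted_labels <- function(cohort) {
  tr <- cohort$truth$analytes
  setNames(tr$archetype[!tr$censored], tr$analyte[!tr$censored])
}

# cached small cohort shared across test files
.small <- local({
  cohort <- generate_cohort(small_config())
  c(list(cohort = cohort), run_front_end(cohort, seed = 2))
})

# independent oracle: exhaustive sign-flip enumeration for the paired
# signed-rank test (two-sided), conditional on |d|
enumerate_signrank <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(FALSE, TRUE)), n))
  w_all <- apply(signs, 1, function(s) sum(r[unlist(s)]))
  p_le <- mean(w_all <= w_obs + 1e-9)
  p_ge <- mean(w_all >= w_obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

# independent oracle: brute-force Holm step-down at family size m
holm_oracle <- function(p, m = length(p)) {
  o <- order(p)
  adj <- numeric(length(p))
  running <- 0
  for (i in seq_along(o)) {
    running <- max(running, min(1, (m - i + 1) * p[o[i]]))
    adj[o[i]] <- running
  }
  adj
}

# independent oracle: exhaustive enumeration of all monotone warping paths
dtw_oracle <- function(a, b, w_diag = 1) {
  n <- length(a)
  m <- length(b)
  best <- Inf
  walk <- function(i, j, acc) {
    if (acc >= best) return(invisible())
    if (i == n && j == m) {
      best <<- min(best, acc)
      return(invisible())
    }
    if (i < n) walk(i + 1, j, acc + abs(a[i + 1] - b[j]))
    if (j < m) walk(i, j + 1, acc + abs(a[i] - b[j + 1]))
    if (i < n && j < m) {
      walk(i + 1, j + 1, acc + w_diag * abs(a[i + 1] - b[j + 1]))
    }
  }
  walk(1, 1, abs(a[1] - b[1]))
  best
}

# noiseless trajectory fixture: k well-separated archetype groups as a
# long normalized-value table with one sample per (participant, dol)
toy_norm_values <- function(series, n_each = 3, participants = 24, seed = 5) {
  # series: named list analyte_prefix -> 4-point archetype (dol 0,1,3,7)
  withr::with_seed(seed, {
    dols <- c(0, 1, 3, 7)
    v2 <- rep(c(1, 3, 7), length.out = participants)
    meta <- tibble::tibble(
      participant = sprintf("T%03d", seq_len(participants)),
      sex = "F", visit2_dol = v2
    )
    si <- sample_table(meta)
    rows <- list()
    for (g in names(series)) {
      for (j in seq_len(n_each)) {
        analyte <- sprintf("%s_%d", g, j)
        delta <- series[[g]]
        val <- delta[match(si$dol, dols)] + rnorm(nrow(si), 0, 1e-3)
        rows[[analyte]] <- tibble::tibble(
          sample = si$sample, plate = 1L, analyte = analyte, value = val
        )
      }
    }
    list(values = dplyr::bind_rows(rows), sample_info = si, metadata = meta)
  })
}
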