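test_that("default cohort reproduces the study bookkeeping", {
  md <- generate_cohort(sim_config(seed = 9))$metadata
  expect_equal(nrow(md), 608)
  counts <- table(md$visit2_dol)
  expect_equal(unname(counts[c("1", "3", "7")]), c(202, 206, 200), ignore_attr = TRUE)
})

test_that("the same seed reproduces the cohort exactly; seeds differ otherwise", {
  a <- generate_cohort(small_config(seed = 123))
  b <- generate_cohort(small_config(seed = 123))
  expect_identical(a$plates, b$plates)
  expect_identical(a$standards, b$standards)
  expect_identical(a$metadata, b$metadata)
  c2 <- generate_cohort(small_config(seed = 124))
  expect_false(identical(a$plates$mfi, c2$plates$mfi))
  # generation does not disturb the caller's RNG stream
  withr::with_seed(1, {
    before <- runif(1)
  })
  withr::with_seed(1, {
    invisible(generate_cohort(small_config(seed = 55)))
    after <- runif(1)
  })
  expect_identical(before, after)
})

test_that("archetype curves have the described kinetic shapes", {
  expect_equal(archetype_curves(1)[1], 0) # indexed to birth
  expect_lt(archetype_curves(1)[2], 0) # transient DOL1 trough
  expect_equal(archetype_curves(1)[c(3, 4)], c(0, 0))
  expect_gt(archetype_curves(2)[2], 0) # transient DOL1 peak
  expect_true(all(diff(archetype_curves(3)) > 0)) # slow rise
  expect_true(all(diff(archetype_curves(4)) < 0)) # steady decrease
  a5 <- archetype_curves(5)
  expect_equal(which.max(a5), 2) # sharp DOL1 peak
  expect_lt(a5[3], a5[2]) # reversal by DOL3
  expect_error(archetype_curves(6), "1..5")
  expect_equal(archetype_curves(4, dols = c(0, 7)), c(0, -1.1))
})

test_that("configs are validated", {
  expect_error(
    sim_config(n_participants = 10L, visit2_counts = c("1" = 2L, "3" = 2L, "7" = 2L)),
    "sum"
  )
  expect_error(sim_config(n_plates = 0L), "plate")
  expect_error(sim_config(banana = 1), "Unknown")
  expect_error(
    sim_config(
      n_participants = 3L, visit2_counts = c("1" = 1L, "3" = 1L, "7" = 1L),
      archetype_map = c("IL-6" = 1)
    ),
    "cover"
  )
})

test_that("plates carry every sample once, bridges on every plate, standards ladders complete", {
  cohort <- .small$cohort
  cfg <- cohort$config
  # each study sample: one well, all 41 analytes
  study <- cohort$plates[!grepl("^BRIDGE", cohort$plates$sample), ]
  expect_equal(nrow(study), 2 * cfg$n_participants * 41)
  expect_true(all(table(study$sample) == 41))
  # participant-level round-robin: plate sizes differ by at most one pair,
  # and a participant's two samples share a plate
  per_plate <- table(unique(study[, c("sample", "plate")])$plate)
  expect_lte(diff(range(per_plate)), 2)
  pair_plates <- unique(study[, c("sample", "plate")])
  pair_plates$participant <- sub("_D\\d+$", "", pair_plates$sample)
  expect_true(all(tapply(pair_plates$plate, pair_plates$participant,
    function(x) length(unique(x))) == 1))
  # visits are balanced within every plate
  v1 <- grepl("_D0$", pair_plates$sample)
  expect_true(all(abs(tapply(v1, pair_plates$plate, mean) - 0.5) < 1e-9))
  # bridge aliquots on every plate
  bridge <- cohort$plates[grepl("^BRIDGE", cohort$plates$sample), ]
  expect_setequal(unique(bridge$plate), seq_len(cfg$n_plates))
  expect_equal(nrow(bridge), cfg$n_plates * cfg$n_bridge * 41)
  # standards: full ladder + blanks per (plate, analyte)
  std <- cohort$standards
  per <- std |>
    dplyr::count(plate, analyte)
  expect_true(all(per$n == cfg$n_standards + cfg$n_blanks))
  expect_true(all(std$mfi > 0))
})

test_that("censored analytes sit at their floor; others span their curves", {
  cohort <- .small$cohort
  q <- quantify_wells(cohort$plates, .small$curves)
  cens <- q[q$analyte %in% c("IL-2", "IL-3", "IL-17A"), ]
  # nearly every censored well is pinned at the quantification floor
  # (mostly under the detection limit; measurement noise around the blank
  # level pushes the remainder into the imputed-low band)
  expect_gt(mean(cens$flag %in% c("below_lld", "imputed_low")), 0.95)
  expect_gt(mean(cens$flag == "below_lld"), 0.5)
  open <- q[!q$analyte %in% c("IL-2", "IL-3", "IL-17A"), ]
  expect_gt(mean(open$flag == "quantified"), 0.9)
})

test_that("cohorts write to plain-text files that read back", {
  dir <- tempfile()
  cohort <- generate_cohort(sim_config(
    n_participants = 6L, visit2_counts = c("1" = 2L, "3" = 2L, "7" = 2L),
    n_plates = 2L, seed = 77
  ))
  write_cohort(cohort, dir)
  expect_setequal(
    list.files(dir),
    c("plates.csv", "standards.csv", "meta.csv", "truth.json")
  )
  back <- read_plate_table(file.path(dir, "plates.csv"), cohort$config$panel)
  expect_equal(nrow(back), nrow(cohort$plates))
  expect_equal(back$mfi, cohort$plates$mfi, tolerance = 1e-12)
  md <- read_metadata(file.path(dir, "meta.csv"), quiet = TRUE)
  expect_equal(nrow(md), 6)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"), simplifyVector = TRUE)
  expect_equal(truth$seed, 77)
})
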