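test_that("standardization gives pooled mean 0 and SD 1 per analyte", {
  std <- standardize_values(.small$norm, .small$sample_info)
  mom <- std |>
    dplyr::group_by(analyte) |>
    dplyr::summarise(
      m = mean(value, na.rm = TRUE), s = sd(value, na.rm = TRUE)
    )
  expect_equal(mom$m, rep(0, nrow(mom)), tolerance = 1e-9)
  expect_equal(mom$s, rep(1, nrow(mom)), tolerance = 1e-9)
  # bridge samples are excluded by the sample_info join
  expect_false(any(grepl("^BRIDGE", std$sample)))
})

test_that("trajectories are 4-point series; planted monotone classes rise or fall", {
  traj <- build_trajectories(.small$norm, .small$sample_info)
  expect_true(all(table(traj$analyte) == 4))
  truth <- .small$cohort$truth$analytes
  c3 <- truth$analyte[!truth$censored & truth$archetype == 3][1]
  c4 <- truth$analyte[!truth$censored & truth$archetype == 4][1]
  expect_true(all(diff(traj$value[traj$analyte == c3]) > -0.15))
  expect_true(all(diff(traj$value[traj$analyte == c4]) < 0.05))
  # an empty DOL group is an error
  si17 <- .small$sample_info[.small$sample_info$dol != 3, ]
  v <- .small$norm$values[.small$norm$values$sample %in% si17$sample, ]
  expect_error(build_trajectories(v, si17), "No samples at DOL 3")
})

test_that("zero-noise planted cohort recovers the archetype deltas after standardization", {
  # archetype deltas are specified in units of the biological SD, so the
  # noise-free limit is taken by shrinking the SDs while scaling the delta
  # matrix up to hold the absolute planted effects fixed
  cfg <- sim_config(
    n_participants = 30L, visit2_counts = c("1" = 10L, "3" = 10L, "7" = 10L),
    n_plates = 2L, seed = 400,
    participant_sd = 1e-4, residual_sd = 1e-4, archetype_jitter_sd = 0,
    archetype_deltas = default_archetype_deltas() * (0.2 / sqrt(2) / 1e-4),
    baseline_log10_range = c(2.2, 2.6),
    plate_loc_sd = 0, plate_loc_analyte_sd = 0, plate_scale_sd = 0,
    assay_drift_sd = 0, mfi_noise_sd = 1e-5, standards_noise_sd = 1e-5,
    low_bead_prob = 0
  )
  cohort <- generate_cohort(cfg)
  fe <- run_front_end(cohort, seed = 5)
  traj <- build_trajectories(fe$norm, fe$sample_info)
  truth <- cohort$truth$analytes
  for (cls in 1:5) {
    an <- truth$analyte[!truth$censored & truth$archetype == cls][1]
    got <- traj$value[traj$analyte == an]
    # the deltas re-emerge up to the common standardization affine map:
    # correlation with the planted shape must be essentially perfect
    want <- archetype_curves(cls)
    expect_gt(cor(got, want), 0.999)
  }
})

test_that("dtw matches hand-computed and degenerate cases", {
  expect_equal(dtw_distance(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(dtw_distance(c(0, 1), c(0, 1, 1)), 0) # repeat matches free
  expect_equal(dtw_distance(c(0, 0), c(1, 1)), 2)
  expect_error(dtw_distance(numeric(0), 1), "Empty")
  expect_error(dtw_distance(c(1, NA), c(1, 2)), "finite")
  # symmetric2 weights the diagonal twice
  expect_equal(dtw_distance(c(0, 0), c(1, 1), step = "symmetric2"), 3)
})

test_that("dtw equals exhaustive path enumeration on 200 random pairs", {
  withr::with_seed(123, {
    for (i in 1:200) {
      a <- rnorm(sample(1:4, 1))
      b <- rnorm(sample(1:4, 1))
      expect_equal(dtw_distance(a, b), dtw_oracle(a, b), tolerance = 1e-12)
      expect_equal(
        dtw_distance(a, b, step = "symmetric2"),
        dtw_oracle(a, b, w_diag = 2),
        tolerance = 1e-12
      )
      expect_equal(dtw_distance(a, b), dtw_distance(b, a))
    }
  })
})

test_that("distance matrices are symmetric, nonnegative, zero-diagonal", {
  traj <- build_trajectories(.small$norm, .small$sample_info)
  D <- trajectory_distances(traj)
  expect_equal(D, t(D))
  expect_true(all(D >= 0))
  expect_equal(unname(diag(D)), rep(0, nrow(D)))
  expect_equal(rownames(D), sort(rownames(D)))
})

test_that("complete linkage recovers well-separated groups exactly", {
  toy <- toy_norm_values(
    list(a = c(0, 0, 0, 0), b = c(0, 2, 2, 2), c = c(0, -2, -2, -2)),
    n_each = 4
  )
  D <- trajectory_distances(build_trajectories(toy$values, toy$sample_info))
  cl <- cluster_trajectories(D, 3)
  want <- sub("_\\d+$", "", cl$labels$analyte)
  expect_equal(adjusted_rand(cl$labels, setNames(as.integer(factor(want)), cl$labels$analyte)), 1)
  # merge heights are nondecreasing
  expect_true(all(diff(cl$hclust$height) >= -1e-12))
  # k = n gives singletons
  singletons <- cluster_trajectories(D, nrow(D))
  expect_equal(sort(unique(singletons$labels$cluster)), seq_len(nrow(D)))
  expect_error(cluster_trajectories(D, 1), "at least 2")
  # input order does not change the partition (labels permute at most)
  perm <- withr::with_seed(9, sample(nrow(D)))
  cl2 <- cluster_trajectories(D[perm, perm], 3)
  expect_equal(adjusted_rand(cl$labels, cl2$labels), 1)
})

test_that("silhouette widths follow the definition on a toy matrix", {
  # two antipodal pairs: within distance 1, between distance 10
  D <- matrix(10, 4, 4) - diag(10, 4)
  D[1, 2] <- D[2, 1] <- 1
  D[3, 4] <- D[4, 3] <- 1
  rownames(D) <- colnames(D) <- c("a1", "a2", "b1", "b2")
  sw <- silhouette_width(D, c(1, 1, 2, 2))
  expect_equal(sw$widths$silhouette, rep((10 - 1) / 10, 4))
  expect_equal(sw$asw, 0.9)
  # all distances equal: a = b so silhouettes vanish
  De <- matrix(1, 4, 4) - diag(1, 4)
  expect_equal(silhouette_width(De, c(1, 1, 2, 2))$asw, 0)
  # singleton convention
  expect_equal(silhouette_width(D, c(1, 1, 2, 3))$widths$silhouette[3:4], c(0, 0))

  skip_if_not_installed("cluster")
  set.seed(31)
  Dr <- as.matrix(dist(matrix(rnorm(40), 10)))
  lab <- cutree(hclust(as.dist(Dr), "complete"), k = 3)
  ref <- cluster::silhouette(lab, dmatrix = Dr)
  expect_equal(silhouette_width(Dr, lab)$asw, mean(ref[, "sil_width"]))
})

test_that("silhouette selection finds the five planted archetypes", {
  toy <- toy_norm_values(
    setNames(
      lapply(1:5, archetype_curves),
      paste0("k", 1:5)
    ),
    n_each = 4, participants = 120
  )
  D <- trajectory_distances(build_trajectories(toy$values, toy$sample_info))
  sel <- select_k(D, 2:8)
  expect_equal(sel$k, 5)
  # two antipodal groups give ASW near 1 at k = 2
  toy2 <- toy_norm_values(list(u = c(0, 2, 2, 2), d = c(0, -2, -2, -2)), n_each = 5)
  D2 <- trajectory_distances(build_trajectories(toy2$values, toy2$sample_info))
  sel2 <- select_k(D2, 2:5)
  expect_equal(sel2$k, 2)
  expect_gt(max(sel2$asw$asw), 0.9)
  expect_error(select_k(D2, 1:3), "k_range")
})

test_that("planted recovery holds under both DTW step patterns", {
  toy <- toy_norm_values(
    setNames(lapply(1:5, archetype_curves), paste0("k", 1:5)),
    n_each = 4, participants = 120
  )
  want <- setNames(
    rep(1:5, each = 4),
    sprintf("k%d_%d", rep(1:5, each = 4), rep(1:4, 5))
  )
  for (step in c("unit", "symmetric2")) {
    D <- trajectory_distances(
      build_trajectories(toy$values, toy$sample_info),
      step = step
    )
    cl <- cluster_trajectories(D, 5)
    expect_equal(adjusted_rand(cl$labels, want), 1)
  }
})

test_that("merge trees export as valid single-root Newick", {
  traj <- build_trajectories(.small$norm, .small$sample_info)
  cl <- cluster_trajectories(trajectory_distances(traj), 5)
  nwk <- merge_tree_newick(cl)
  expect_match(nwk, ";$")
  expect_equal(
    lengths(regmatches(nwk, gregexpr("\\(", nwk))),
    lengths(regmatches(nwk, gregexpr("\\)", nwk)))
  )
  # every retained analyte appears exactly once
  leaves <- strsplit(gsub("[();]", ",", nwk), ",+")[[1]]
  expect_setequal(setdiff(leaves, ""), gsub("[(),;: ]", "_", cl$labels$analyte))
})
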