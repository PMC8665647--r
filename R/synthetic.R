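#' Kinetic archetype delta series
#'
#' The generator plants five kinetic classes of first-week trajectories,
#' expressed as standardized-unit offsets from the birth (day-of-life 0)
#' level at DOL 0, 1, 3 and 7:
#' class 1 -- flat with a transient trough at DOL1; class 2 -- flat with a
#' transient peak at DOL1; class 3 -- slow steady rise across the week;
#' class 4 -- steady decrease across the week; class 5 -- sharp rise to a
#' DOL1 peak that reverses course by DOL3. Magnitudes are generator
#' parameters chosen so the planted partition is recoverable but not
#' trivial; they are not estimates from any cohort.
#'
#' @param class_id Integer in 1..5.
#' @param dols Days of life at which to evaluate (default `c(0, 1, 3, 7)`).
#' @return Numeric delta series (standard-deviation units), one per DOL.
#' @export
#' @examples
#' archetype_curves(4) # strictly decreasing
archetype_curves <- function(class_id, dols = c(0, 1, 3, 7)) {
  deltas <- default_archetype_deltas()
  if (!(length(class_id) == 1 && class_id %in% seq_len(nrow(deltas)))) {
    abort("`class_id` must be a single integer in 1..5.")
  }
  full <- setNames(deltas[class_id, ], c(0, 1, 3, 7))
  bad <- setdiff(as.character(dols), colnames(deltas))
  if (length(bad)) abort(paste0("Unsupported DOL(s): ", paste(bad, collapse = ", ")))
  unname(full[as.character(dols)])
}

#' @rdname archetype_curves
#' @export
default_archetype_deltas <- function() {
  m <- rbind(
    c(0, -0.5, 0.0, 0.0),
    c(0, 0.5, 0.0, 0.0),
    c(0, 0.2, 0.5, 0.8),
    c(0, -0.4, -0.8, -1.1),
    c(0, 1.2, 0.8, 0.5)
  )
  dimnames(m) <- list(paste0("class", 1:5), c("0", "1", "3", "7"))
  m
}

#' Default analyte-to-archetype assignment
#'
#' For the default 41-analyte panel the assignment follows the biology the
#' classes emulate (inflammation-associated analytes decrease, the
#' interferon-gamma axis spikes early, and so on). For other panels the
#' non-censored analytes are assigned to the five classes round-robin.
#'
#' @param panel An `ontokine_panel`.
#' @param censored Analytes planted as floor-censored (near-always below the
#'   detection limit); they receive no archetype.
#' @return Named integer vector: analyte -> class in 1..5.
#' @export
default_archetype_map <- function(panel = default_panel(),
                                  censored = c("IL-2", "IL-3", "IL-17A")) {
  curated <- c(
    # class 1: flat, transient DOL1 trough
    "sCD40L" = 1, "EGF" = 1, "CX3CL1" = 1, "CXCL1" = 1, "IL-12p40" = 1,
    "PDGF-AB/BB" = 1, "CCL3" = 1, "VEGF" = 1,
    # class 2: flat, transient DOL1 peak
    "CCL2" = 2, "CCL5" = 2, "CCL7" = 2, "CCL11" = 2, "IL-15" = 2,
    "IL-4" = 2, "IL-7" = 2, "PDGF-AA" = 2, "TNF-b" = 2,
    # class 3: slow rise
    "FGF-2" = 3, "Flt-3L" = 3, "IFN-a2" = 3, "IL-1a" = 3, "IL-1b" = 3,
    "IL-9" = 3, "IL-12p70" = 3, "IL-13" = 3, "TNF-a" = 3, "CCL22" = 3,
    # class 4: steady decrease
    "CCL4" = 4, "CXCL8" = 4, "G-CSF" = 4, "IL-10" = 4, "IL-1RA" = 4,
    "IL-6" = 4, "TGF-a" = 4,
    # class 5: sharp DOL1 rise, reversal by DOL3
    "IFN-g" = 5, "CXCL10" = 5, "IL-5" = 5, "GM-CSF" = 5
  )
  active <- setdiff(panel$analytes, censored)
  if (all(active %in% names(curated))) {
    return(curated[active])
  }
  setNames(rep_len(1:5, length(active)), active)
}

#' Synthetic-cohort generator configuration
#'
#' Defaults emulate the study conditions the pipeline is built for: 608
#' participants each sampled at DOL0 plus one follow-up (202 at DOL1, 206 at
#' DOL3, 200 at DOL7), 41 analytes on 7 plates with plate-level
#' location/scale batch effects and shared bridge aliquots, per-analyte 4PL
#' standard curves with an 8-point 4-fold dilution ladder, bead-count
#' variation with a small low-bead probability, three analytes (IL-2, IL-3,
#' IL-17A) planted almost entirely below the detection limit, and the five
#' kinetic archetypes of [archetype_curves()].
#'
#' @param ... Named overrides of any default listed below.
#' @return A list of class `sim_config`.
#' @section Parameters:
#' \describe{
#'   \item{n_participants, visit2_counts}{Cohort size and follow-up-day
#'     allocation (must sum to `n_participants`).}
#'   \item{n_plates, n_bridge}{Plates and bridge aliquots per plate.}
#'   \item{participant_sd, residual_sd}{Biological random-effect and
#'     residual SDs on the log10 pg/mL scale; their quadrature sum is the
#'     "standard-deviation unit" the archetype deltas are expressed in.}
#'   \item{archetype_jitter_sd}{Per-analyte jitter (SD units) around its
#'     class delta at each follow-up DOL: within-class heterogeneity.}
#'   \item{plate_loc_sd, plate_loc_analyte_sd, plate_scale_sd}{Batch-effect
#'     location SDs (log10; a plate-wide component plus an analyte-specific
#'     one, since matrix effects differ by analyte) and log-scale SD,
#'     applied to sample/bridge wells (not standards).}
#'   \item{assay_drift_sd}{Plate-level log10-MFI drift applied to every
#'     well including standards (absorbed by the standard curves).}
#'   \item{mfi_noise_sd, standards_noise_sd}{Multiplicative (log-normal)
#'     MFI noise for sample and standards/blank wells.}
#'   \item{sex_effect}{Planted log10 main effect of male sex (0 by
#'     default, matching a null covariate structure; set nonzero for
#'     power tests).}
#' }
#' @export
sim_config <- function(...) {
  cfg <- list(
    n_participants = 608L,
    visit2_counts = c("1" = 202L, "3" = 206L, "7" = 200L),
    n_plates = 7L,
    panel = default_panel(),
    censored_analytes = c("IL-2", "IL-3", "IL-17A"),
    archetype_deltas = default_archetype_deltas(),
    archetype_map = NULL, # filled from panel below
    archetype_jitter_sd = 0.07,
    participant_sd = 0.15,
    residual_sd = 0.15,
    plate_loc_sd = 0.15,
    plate_loc_analyte_sd = 0.10,
    plate_scale_sd = 0.10,
    assay_drift_sd = 0.05,
    mfi_noise_sd = 0.05,
    standards_noise_sd = 0.02,
    n_standards = 8L,
    standards_top = 10000,
    standards_dilution = 4,
    n_blanks = 2L,
    n_bridge = 3L,
    bead_mean = 45,
    bead_size = 10,
    low_bead_prob = 0.002,
    baseline_log10_range = c(1.2, 2.8),
    censored_baseline_log10 = -3,
    bridge_offset_log10 = 0,
    dilution_factor = 2,
    sex_effect = 0,
    seed = 20210928L
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) {
    abort(paste0("Unknown sim_config field(s): ", paste(unknown, collapse = ", ")))
  }
  cfg <- modifyList(cfg, over)
  cfg$visit2_counts <- unlist(cfg$visit2_counts) # YAML configs give a list
  if (is.null(names(cfg$visit2_counts)) && length(cfg$visit2_counts) == 3) {
    names(cfg$visit2_counts) <- c("1", "3", "7") # follow-up days in order
  }
  if (sum(cfg$visit2_counts) != cfg$n_participants) {
    abort("`visit2_counts` must sum to `n_participants`.")
  }
  if (cfg$n_plates < 1) abort("Need at least one plate.")
  if (is.null(cfg$archetype_map)) {
    cfg$archetype_map <- default_archetype_map(cfg$panel, cfg$censored_analytes)
  }
  active <- setdiff(cfg$panel$analytes, cfg$censored_analytes)
  if (!all(active %in% names(cfg$archetype_map))) {
    abort("`archetype_map` must cover every non-censored analyte.")
  }
  structure(cfg, class = "sim_config")
}

#' Generate a synthetic longitudinal multiplex cohort
#'
#' Simulates, from the configured ground truth, everything the pipeline
#' consumes: per-plate readout tables (sample, bridge wells), per-plate
#' standards/blank dilution series, a participant metadata table, and the
#' ground truth needed to score recovery at every stage.
#'
#' The forward model for a study sample is
#' `log10 conc = baseline(analyte) + delta(archetype, DOL) + participant
#' effect + residual`, with plate location/scale batch effects applied to
#' sample and bridge wells on the log10-concentration scale, a 4PL curve
#' mapping the (1:2 diluted) well concentration to MFI, plate-level assay
#' drift applied to all wells including standards, and multiplicative MFI
#' noise. Participants are assigned to plates round-robin by enrollment
#' order with both of a participant's samples on the same plate (so neither
#' visit nor DOL is confounded with plate); follow-up day assignment is
#' block-randomized under the master seed.
#'
#' @param config A [sim_config()].
#' @return An object of class `ontokine_cohort`: list with tibbles
#'   `plates`, `standards`, `metadata`, plus `truth` (ground-truth lists)
#'   and `config`.
#' @export
#' @examples
#' cohort <- generate_cohort(sim_config(
#'   n_participants = 12, visit2_counts = c("1" = 4, "3" = 4, "7" = 4),
#'   n_plates = 2
#' ))
#' nrow(cohort$metadata)
generate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  with_preserved_seed(config$seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(cfg) {
  panel <- cfg$panel
  analytes <- panel$analytes
  A <- length(analytes)
  n <- cfg$n_participants
  dils <- cfg$dilution_factor

  ## ---- participants -------------------------------------------------
  ids <- sprintf("P%04d", seq_len(n))
  v2 <- sample(rep(
    as.integer(names(cfg$visit2_counts)),
    times = cfg$visit2_counts
  ))
  metadata <- tibble(
    participant = ids,
    sex = sample(c("F", "M"), n, replace = TRUE),
    visit2_dol = v2,
    gest_cat = sample(c("preterm", "early term", "full term", "late term"),
      n,
      replace = TRUE, prob = c(0.007, 0.247, 0.615, 0.131)
    ),
    mat_age_band = sample(
      c("18-19", "20-24", "25-29", "30-34", "35-39", "40-45"),
      n,
      replace = TRUE, prob = c(0.043, 0.222, 0.291, 0.207, 0.179, 0.058)
    ),
    ethnicity = sample(
      c("Mandinka", "Jola", "Fula", "Wollof", "Serahule", "Other"),
      n,
      replace = TRUE, prob = c(0.479, 0.158, 0.130, 0.112, 0.036, 0.085)
    ),
    bf_v1 = runif(n) < 0.885,
    bf_v2 = runif(n) < 0.988
  )

  ## ---- analyte-level truth ------------------------------------------
  censored <- analytes %in% cfg$censored_analytes
  baseline <- runif(A, cfg$baseline_log10_range[1], cfg$baseline_log10_range[2])
  baseline[censored] <- cfg$censored_baseline_log10
  sd_unit <- sqrt(cfg$participant_sd^2 + cfg$residual_sd^2)
  arch <- rep(NA_integer_, A)
  arch[!censored] <- unname(cfg$archetype_map[analytes[!censored]])
  # realized per-analyte deltas (log10 units) at DOL 0/1/3/7
  delta <- matrix(0, A, 4, dimnames = list(analytes, c("0", "1", "3", "7")))
  for (i in seq_len(A)) {
    if (censored[i]) next
    jit <- c(0, rnorm(3, 0, cfg$archetype_jitter_sd))
    delta[i, ] <- (cfg$archetype_deltas[arch[i], ] + jit) * sd_unit
  }
  # inflection near each analyte's typical well concentration (assays are
  # designed so samples fall mid-curve); censored analytes get an ordinary
  # curve so their signal sits at its floor
  infl <- 10^(baseline - log10(dils) + runif(A, -0.3, 0.7))
  infl[censored] <- 10^runif(sum(censored), 1.5, 2.5)
  curves <- tibble(
    analyte = analytes,
    a = runif(A, 25000, 35000),
    d = runif(A, 30, 80),
    c = infl,
    b = runif(A, 0.8, 1.4)
  )

  ## ---- plate-level truth --------------------------------------------
  P <- cfg$n_plates
  plate_effects <- tibble(
    plate = seq_len(P),
    batch_loc = rnorm(P, 0, cfg$plate_loc_sd),
    batch_scale = exp(rnorm(P, 0, cfg$plate_scale_sd)),
    assay_drift = rnorm(P, 0, cfg$assay_drift_sd)
  )
  # analyte-specific component of the plate batch effect (matrix effects
  # differ by analyte on real multiplex plates)
  W <- matrix(rnorm(P * A, 0, cfg$plate_loc_analyte_sd), P, A,
    dimnames = list(NULL, analytes)
  )

  ## ---- study samples ------------------------------------------------
  samples <- tibble(
    participant = rep(ids, each = 2),
    dol = as.vector(rbind(0L, v2))
  )
  samples$sample <- sprintf("%s_D%d", samples$participant, samples$dol)
  # round-robin over participants, both visits on the participant's plate:
  # keeps visit and DOL composition balanced across plates for any P
  samples$plate <- ((match(samples$participant, ids) - 1L) %% P) + 1L

  u <- matrix(rnorm(n * A, 0, cfg$participant_sd), n, A,
    dimnames = list(ids, analytes)
  )
  ns <- nrow(samples)
  p_idx <- match(samples$participant, ids)
  dol_col <- match(as.character(samples$dol), colnames(delta))
  # true log10 plasma concentration, samples x analytes
  X <- matrix(baseline, ns, A, byrow = TRUE) +
    delta[, dol_col, drop = FALSE] |> t()
  X <- X + u[p_idx, , drop = FALSE] +
    matrix(rnorm(ns * A, 0, cfg$residual_sd), ns, A)
  if (cfg$sex_effect != 0) {
    male <- metadata$sex[p_idx] == "M"
    X <- X + cfg$sex_effect * male
  }
  # plate batch effect on sample concentrations (location + scale on the
  # deviation from the analyte baseline)
  pe <- plate_effects[samples$plate, ]
  Xb <- matrix(baseline, ns, A, byrow = TRUE) +
    (X - matrix(baseline, ns, A, byrow = TRUE)) * pe$batch_scale +
    pe$batch_loc + W[samples$plate, , drop = FALSE]

  ## ---- bridge samples -----------------------------------------------
  bridge_true <- baseline + cfg$bridge_offset_log10
  bridge <- tidyr::expand_grid(plate = seq_len(P), rep = seq_len(cfg$n_bridge))
  bridge$sample <- sprintf("BRIDGE%d_PL%d", bridge$rep, bridge$plate)
  nb <- nrow(bridge)
  pb <- plate_effects[bridge$plate, ]
  Xbr <- matrix(baseline, nb, A, byrow = TRUE) +
    matrix(cfg$bridge_offset_log10, nb, A) * pb$batch_scale +
    pb$batch_loc + W[bridge$plate, , drop = FALSE]

  ## ---- wells: concentrations -> MFI ---------------------------------
  all_samples <- tibble(
    sample = c(samples$sample, bridge$sample),
    plate = c(samples$plate, bridge$plate)
  )
  Xall <- rbind(Xb, Xbr)
  nw <- nrow(all_samples)
  well_conc <- 10^Xall / dils
  mfi <- matrix(0, nw, A)
  for (i in seq_len(A)) {
    m <- curve_model("logistic4", c(
      a = curves$a[i], d = curves$d[i],
      c = curves$c[i], b = curves$b[i]
    ))
    mfi[, i] <- curve_forward(m, well_conc[, i])
  }
  drift <- plate_effects$assay_drift[all_samples$plate]
  mfi <- mfi * 10^drift * exp(matrix(rnorm(nw * A, 0, cfg$mfi_noise_sd), nw, A))

  beads <- 30L + rnbinom(nw * A, size = cfg$bead_size, mu = cfg$bead_mean)
  low <- runif(nw * A) < cfg$low_bead_prob
  beads[low] <- pmin(29L, 5L + rpois(sum(low), 8))

  well_of <- ave(all_samples$sample, all_samples$plate, FUN = seq_along)
  plates <- tibble(
    plate = rep(all_samples$plate, times = A),
    well = rep(sprintf("W%03d", as.integer(well_of)), times = A),
    sample = rep(all_samples$sample, times = A),
    analyte = rep(analytes, each = nw),
    mfi = as.vector(mfi),
    bead_count = as.integer(beads)
  )

  ## ---- standards & blanks -------------------------------------------
  ladder <- cfg$standards_top / cfg$standards_dilution^(seq_len(cfg$n_standards) - 1)
  std <- tidyr::expand_grid(
    plate = seq_len(P),
    analyte = analytes,
    std_idx = seq_len(cfg$n_standards)
  )
  std$sample <- sprintf("STD%d", std$std_idx)
  std$expected_conc <- ladder[std$std_idx]
  ai <- match(std$analyte, analytes)
  std_clean <- curves$d[ai] + (curves$a[ai] - curves$d[ai]) /
    (1 + (std$expected_conc / curves$c[ai])^(-curves$b[ai]))
  std$mfi <- std_clean * 10^plate_effects$assay_drift[std$plate] *
    exp(rnorm(nrow(std), 0, cfg$standards_noise_sd))
  std$std_idx <- NULL

  blank <- tidyr::expand_grid(
    plate = seq_len(P),
    analyte = analytes,
    rep = seq_len(cfg$n_blanks)
  )
  bi <- match(blank$analyte, analytes)
  blank$sample <- "BLANK"
  blank$expected_conc <- 0
  blank$mfi <- curves$d[bi] * 10^plate_effects$assay_drift[blank$plate] *
    exp(rnorm(nrow(blank), 0, cfg$standards_noise_sd))
  blank$rep <- NULL
  standards <- bind_rows(std, blank) |>
    arrange(.data$plate, .data$analyte, dplyr::desc(.data$expected_conc))

  truth <- list(
    analytes = tibble(
      analyte = analytes,
      archetype = arch,
      censored = censored,
      baseline_log10 = baseline
    ) |> bind_cols(as_tibble(delta, .name_repair = ~ paste0("delta_dol", c(0, 1, 3, 7)))),
    curves = curves,
    plate_effects = plate_effects,
    plate_analyte_loc = W,
    participant_effects = u,
    bridge_log10 = setNames(bridge_true, analytes),
    sd_unit = sd_unit
  )

  structure(
    list(
      plates = plates, standards = standards, metadata = metadata,
      truth = truth, config = cfg
    ),
    class = "ontokine_cohort"
  )
}

#' @export
print.ontokine_cohort <- function(x, ...) {
  cat("<ontokine_cohort> ", nrow(x$metadata), " participants, ",
    length(x$config$panel$analytes), " analytes, ",
    x$config$n_plates, " plates, ",
    nrow(x$plates), " plate-table rows\n",
    sep = ""
  )
  invisible(x)
}

#' Write a synthetic cohort to disk
#'
#' Emits `plates.csv`, `standards.csv`, `meta.csv` and `truth.json` (the
#' analyte- and plate-level ground truth; participant effects are omitted
#' from the JSON).
#'
#' @param cohort An `ontokine_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "ontokine_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_csv(cohort$plates, file.path(dir, "plates.csv"), progress = FALSE)
  readr::write_csv(cohort$standards, file.path(dir, "standards.csv"), progress = FALSE)
  readr::write_csv(cohort$metadata, file.path(dir, "meta.csv"), progress = FALSE)
  jsonlite::write_json(
    list(
      analytes = cohort$truth$analytes,
      curves = cohort$truth$curves,
      plate_effects = cohort$truth$plate_effects,
      sd_unit = cohort$truth$sd_unit,
      seed = cohort$config$seed
    ),
    file.path(dir, "truth.json"),
    dataframe = "columns", digits = NA, auto_unbox = TRUE
  )
  invisible(dir)
}
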