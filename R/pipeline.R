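#' Pipeline configuration
#'
#' Assembles the configuration for [run_pipeline()]. Every analysis choice
#' that is a tunable rather than a fact of the data surfaces here with its
#' documented default.
#'
#' @param seed Master seed; all stage-level randomness derives from it.
#' @param sim Named list of [sim_config()] overrides (ignored when `input`
#'   is given).
#' @param input Optional list with file paths `plates`, `standards`, `meta`
#'   to analyze an existing dataset instead of a simulated one.
#' @param curve_families,curve_criterion Standard-curve model selection.
#' @param combat,nzv_after_combat,freq_ratio_cut,unique_pct_cut
#'   Normalization-stage switches (see [normalize_table()]).
#' @param volcano_p,volcano_lfc Volcano criterion thresholds (raw paired
#'   p-value and absolute log2 fold change).
#' @param covariates Metadata columns to run through
#'   [covariate_association()].
#' @param B,subsample_frac,k,k_rule,k_range,step Consensus-clustering
#'   parameters (see [bootstrap_consensus()]); `k = NULL` selects by
#'   silhouette.
#' @param B_individual Resamples for the individual-level validation run
#'   (`0` skips it).
#' @param outdir Optional directory: when set, stage outputs are written as
#'   CSV and the manifest records their checksums.
#' @return List of class `ontokine_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            sim = list(),
                            input = NULL,
                            curve_families = c("logistic4", "logistic5", "exponential"),
                            curve_criterion = "aic",
                            combat = TRUE,
                            nzv_after_combat = FALSE,
                            freq_ratio_cut = 95 / 5,
                            unique_pct_cut = 10,
                            volcano_p = 0.01,
                            volcano_lfc = 0.2,
                            covariates = "sex",
                            B = 1000,
                            subsample_frac = 0.9,
                            k = NULL,
                            k_rule = "fixed",
                            k_range = 2:8,
                            step = "unit",
                            B_individual = B,
                            outdir = NULL) {
  cfg <- as.list(environment())
  class(cfg) <- "ontokine_config"
  cfg
}

#' Run the full ontogeny pipeline
#'
#' Chains simulate (or load) -> quantify -> normalize -> ontogeny statistics
#' -> trajectory consensus clustering -> report, with per-stage record
#' accounting collected into a machine-readable manifest. Any stage error
#' aborts naming the stage.
#'
#' @param config An [pipeline_config()], a named list of its arguments, or
#'   the path to a YAML file holding them.
#' @return Object of class `ontokine_run` with the stage outputs
#'   (`cohort`, `curves`, `conc`, `norm`, `contrasts`, `pca`, `covars`,
#'   `primary`, `individual`, `cluster_tests`), a `report` list of summary
#'   tables, and the `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!inherits(config, "ontokine_config")) {
    config <- do.call(pipeline_config, config)
  }
  counts <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("Pipeline stage `%s` failed: %s", name, conditionMessage(e)))
    })
  }

  ## simulate / load ---------------------------------------------------
  cohort <- NULL
  if (is.null(config$input)) {
    cohort <- stage("simulate", {
      sim_over <- config$sim
      sim_over$seed <- sim_over$seed %||% derive_seed(config$seed, 1L)
      generate_cohort(do.call(sim_config, sim_over))
    })
    plates <- cohort$plates
    standards <- cohort$standards
    metadata <- read_metadata(cohort$metadata, quiet = TRUE)
    panel <- cohort$config$panel
  } else {
    for (f in unlist(config$input)) {
      if (!file.exists(f)) abort(paste0("Missing input file: ", f))
    }
    panel <- default_panel()
    plates <- stage("load", read_plate_table(config$input$plates, panel))
    standards <- stage("load", read_standards_table(config$input$standards, panel))
    metadata <- stage("load", read_metadata(config$input$meta, quiet = TRUE))
  }
  counts$participants <- nrow(metadata)
  counts$plate_rows <- nrow(plates)

  ## quantify ----------------------------------------------------------
  curves <- stage("quantify", fit_standard_curves(
    standards,
    families = config$curve_families,
    criterion = config$curve_criterion,
    seed = derive_seed(config$seed, 2L)
  ))
  conc <- stage("quantify", {
    q <- quantify_wells(plates, curves)
    assemble_table(q, quiet = TRUE)
  })
  counts$samples_quantified <- dplyr::n_distinct(conc$sample)
  counts$samples_dropped_all_below_lld <- length(attr(conc, "dropped_samples"))

  ## normalize ---------------------------------------------------------
  norm <- stage("normalize", normalize_table(
    conc,
    combat = config$combat,
    nzv_after_combat = config$nzv_after_combat,
    freq_ratio_cut = config$freq_ratio_cut,
    unique_pct_cut = config$unique_pct_cut
  ))
  counts$analytes_in <- length(panel$analytes)
  counts$analytes_retained <- length(norm$retained)
  sample_info <- sample_table(metadata)

  ## ontogeny statistics -----------------------------------------------
  contrasts <- stage("stats", ontogeny_contrasts(norm, sample_info, conc))
  volcano <- volcano_filter(contrasts,
    p_cut = config$volcano_p,
    lfc_cut = config$volcano_lfc
  )
  pca <- stage("stats", pca_summary(norm, sample_info))
  covars <- stage("stats", {
    out <- map(config$covariates, function(cv) {
      covariate_association(norm, sample_info, metadata, cv)
    })
    setNames(out, config$covariates)
  })

  ## trajectory clustering ---------------------------------------------
  primary <- stage("cluster", bootstrap_consensus(
    norm, sample_info,
    B = config$B, subsample_frac = config$subsample_frac,
    k = config$k, k_rule = config$k_rule, k_range = config$k_range,
    step = config$step, seed = derive_seed(config$seed, 3L)
  ))
  individual <- NULL
  if (config$B_individual > 0) {
    individual <- stage("cluster", individual_consensus(
      norm, sample_info,
      B = config$B_individual, subsample_frac = config$subsample_frac,
      k = primary$k, seed = derive_seed(config$seed, 4L),
      reference = primary
    ))
  }
  std <- standardize_values(norm, sample_info)
  cluster_tests <- stage("report", cluster_paired_ttest(
    std, primary$labels, sample_info
  ))
  counts$clusters <- primary$k

  report <- list(
    volcano = volcano |> filter(.data$hit),
    pca_explained = head(pca$explained, 5),
    cluster_membership = tidy(primary),
    consensus = bind_rows(
      glance(primary),
      if (!is.null(individual)) glance(individual)
    ),
    cluster_tests = cluster_tests,
    silhouette = primary$full$asw
  )

  run <- structure(
    list(
      config = config, cohort = cohort, curves = curves, conc = conc,
      norm = norm, sample_info = sample_info, metadata = metadata,
      contrasts = contrasts, pca = pca, covars = covars,
      primary = primary, individual = individual,
      cluster_tests = cluster_tests, report = report,
      manifest = NULL
    ),
    class = "ontokine_run"
  )
  run$manifest <- build_manifest(run, counts)
  if (!is.null(config$outdir)) {
    write_run(run, config$outdir)
    run$manifest <- build_manifest(run, counts, config$outdir)
  }
  run
}

build_manifest <- function(run, counts, outdir = NULL) {
  cfg <- run$config
  cfg_file <- tempfile(fileext = ".rds")
  on.exit(unlink(cfg_file))
  saveRDS(cfg[setdiff(names(cfg), "outdir")], cfg_file)
  files <- NULL
  if (!is.null(outdir)) {
    paths <- list.files(outdir, full.names = TRUE, pattern = "\\.(csv|json|nwk)$")
    files <- tibble(
      file = basename(paths),
      md5 = unname(tools::md5sum(paths))
    )
  }
  list(
    package_version = as.character(utils::packageVersion("ontokine")),
    config_hash = unname(tools::md5sum(cfg_file)),
    seed = cfg$seed,
    counts = counts,
    files = files
  )
}

write_run <- function(run, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  w <- function(x, f) readr::write_csv(x, file.path(dir, f), progress = FALSE)
  w(run$curves |> select(-"model"), "qc_curves.csv")
  w(run$conc, "conc.csv")
  w(run$norm$values, "norm.csv")
  if (!is.null(run$norm$bridge_qc)) w(run$norm$bridge_qc, "bridge_qc.csv")
  w(run$contrasts, "contrasts.csv")
  w(run$pca$explained, "pca_explained.csv")
  w(tidy(run$primary), "clusters.csv")
  w(as_tibble(run$primary$M, rownames = "analyte"), "consensus.csv")
  w(run$cluster_tests, "cluster_tests.csv")
  writeLines(
    merge_tree_newick(run$primary$full$clustering),
    file.path(dir, "merge_tree.nwk")
  )
  jsonlite::write_json(run$manifest, file.path(dir, "manifest.json"),
    dataframe = "rows", auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(dir)
}

#' @export
print.ontokine_run <- function(x, ...) {
  cat("<ontokine_run>\n")
  cat("  participants: ", x$manifest$counts$participants, "\n", sep = "")
  cat("  analytes retained: ", x$manifest$counts$analytes_retained, "/",
    x$manifest$counts$analytes_in, "\n",
    sep = ""
  )
  cat("  clusters (k): ", x$primary$k,
    sprintf(" (ASW %.2f)", x$primary$full$clustering$asw), "\n",
    sep = ""
  )
  cat(sprintf(
    "  average consensus: %.1f%% (trajectory)%s\n",
    100 * x$primary$avg_consensus,
    if (!is.null(x$individual)) {
      sprintf(
        ", %.1f%% (individual-level), ARI %.2f",
        100 * x$individual$avg_consensus, x$individual$ari
      )
    } else {
      ""
    }
  ))
  cat("  PC1+PC2 variance: ",
    sprintf("%.1f%%", 100 * sum(x$pca$explained$var_fraction[1:2])), "\n",
    sep = ""
  )
  invisible(x)
}
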