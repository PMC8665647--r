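#' Bootstrap co-clustering consensus of analyte trajectories
#'
#' Repeats the trajectory clustering across `B` seeded resamples of a
#' fraction of the participants drawn without replacement. Each resample
#' rebuilds the standardized mean trajectories, recomputes DTW distances
#' and the complete-linkage cut, and the frequency with which every analyte
#' pair lands in the same cluster is accumulated into the consensus matrix
#' `M`. Final labels come from complete-linkage clustering of `1 - M` cut
#' at `k`; cluster stability is summarized as the mean of the
#' within-cluster off-diagonal consensus entries.
#'
#' By default `k` is selected once from the full data by average silhouette
#' width and held fixed across resamples, which keeps "co-clustering
#' frequency" well defined; set `k_rule = "per_resample"` to re-select
#' within every resample instead.
#'
#' @param norm An `ontokine_norm` or its `values` tibble.
#' @param sample_info Per-sample table from [sample_table()].
#' @param B Number of bootstrap resamples (the reference analysis uses
#'   1000).
#' @param subsample_frac Fraction of participants per resample (without
#'   replacement, `floor`ed; default 0.9).
#' @param k Number of clusters; `NULL` selects it from the full data over
#'   `k_range`.
#' @param k_rule `"fixed"` (default) or `"per_resample"`.
#' @param k_range Candidate `k` for silhouette selection.
#' @param step DTW step pattern (see [dtw_distance()]).
#' @param seed Master seed; every resample derives its own stream from it.
#' @return Object of class `ontokine_consensus`: consensus matrix `M`,
#'   `labels`, `k`, `per_cluster` consensus tibble, `avg_consensus`,
#'   `full` (full-data clustering and silhouette profile), `B`, `mode`.
#' @export
bootstrap_consensus <- function(norm, sample_info, B = 1000,
                                subsample_frac = 0.9, k = NULL,
                                k_rule = c("fixed", "per_resample"),
                                k_range = 2:8,
                                step = c("unit", "symmetric2"),
                                seed = 1L) {
  k_rule <- match.arg(k_rule)
  step <- match.arg(step)
  if (B < 1) abort("`B` must be at least 1.")
  values <- if (inherits(norm, "ontokine_norm")) norm$values else norm
  participants <- unique(sample_info$participant)
  n_sub <- floor(subsample_frac * length(participants))
  if (n_sub < 1 || n_sub > length(participants)) {
    abort("`subsample_frac` yields an empty or oversized resample.")
  }

  full_traj <- build_trajectories(values, sample_info)
  D_full <- trajectory_distances(full_traj, step = step)
  if (is.null(k) || k_rule == "per_resample") {
    k_range <- k_range[k_range >= 2 & k_range <= nrow(D_full) - 1]
    if (!length(k_range)) abort("`k_range` has no feasible values for this panel.")
    sel <- select_k(D_full, k_range = k_range)
    if (is.null(k)) k <- sel$k
  } else {
    sel <- list(k = k, asw = NULL) # k supplied: no selection needed
  }
  full_fit <- cluster_trajectories(D_full, k)

  label_runs <- run_resamples(
    B = B, seed = seed, stream = 1L,
    draw = function(rs) {
      sub <- with_preserved_seed(rs, sample(participants, n_sub))
      si <- sample_info[sample_info$participant %in% sub, , drop = FALSE]
      if (length(unique(si$dol)) < length(unique(sample_info$dol))) {
        return(NULL) # a DOL subgroup emptied out: redraw
      }
      v <- values[values$sample %in% si$sample, , drop = FALSE]
      traj <- build_trajectories(v, si)
      D <- trajectory_distances(traj, step = step)
      kk <- if (k_rule == "fixed") k else select_k(D, k_range = k_range)$k
      cutree(hclust(as.dist(D), method = "complete"), k = kk)
    }
  )
  finish_consensus(label_runs, k, B,
    mode = "trajectory",
    full = list(
      trajectories = full_traj, D = D_full, asw = sel$asw,
      selected_k = sel$k, clustering = full_fit
    )
  )
}

#' Individual-level consensus clustering (validation methodology)
#'
#' Validation counterpart of [bootstrap_consensus()] that preserves
#' individual-level information: instead of averaging into mean
#' trajectories, each resample clusters analytes on the distance obtained
#' by averaging, over the resampled participants, the DTW distance between
#' the two-point (DOL0, follow-up) standardized series of each analyte
#' pair. (For aligned two-point series the DTW cost reduces to the sum of
#' the per-visit absolute differences.) If a reference clustering is
#' supplied, agreement is reported as the adjusted Rand index.
#'
#' @inheritParams bootstrap_consensus
#' @param k Number of clusters (no in-resample selection here; pass the
#'   primary analysis' k).
#' @param reference Optional labels (tibble or `ontokine_consensus` /
#'   `ontokine_clust`) to compare against.
#' @return An `ontokine_consensus` (mode `"individual"`), with `ari` when a
#'   reference is given.
#' @export
individual_consensus <- function(norm, sample_info, B = 1000,
                                 subsample_frac = 0.9, k = 5,
                                 seed = 1L, reference = NULL) {
  if (B < 1) abort("`B` must be at least 1.")
  values <- if (inherits(norm, "ontokine_norm")) norm$values else norm
  std <- standardize_values(values, sample_info)
  analytes <- sort(unique(std$analyte))
  # analyte x sample matrix of standardized values (study samples only)
  Z <- long_to_matrix(std[, c("sample", "analyte", "value")])
  Z <- Z[analytes, , drop = FALSE]
  samp_part <- sample_info$participant[match(colnames(Z), sample_info$sample)]
  participants <- unique(sample_info$participant)
  n_sub <- floor(subsample_frac * length(participants))
  if (n_sub < 1 || n_sub > length(participants)) {
    abort("`subsample_frac` yields an empty or oversized resample.")
  }

  label_runs <- run_resamples(
    B = B, seed = seed, stream = 2L,
    draw = function(rs) {
      sub <- with_preserved_seed(rs, sample(participants, n_sub))
      cols <- which(samp_part %in% sub)
      if (!length(cols)) {
        return(NULL)
      }
      Zs <- Z[, cols, drop = FALSE]
      # re-standardize within the resample
      mu <- rowMeans(Zs, na.rm = TRUE)
      sg <- apply(Zs, 1, sd, na.rm = TRUE)
      sg[sg == 0 | !is.finite(sg)] <- 1
      Zs <- (Zs - mu) / sg
      D <- pairwise_mean_abs(Zs) * 2 # two visits per participant
      dimnames(D) <- list(analytes, analytes)
      cutree(hclust(as.dist(D), method = "complete"), k = k)
    }
  )
  out <- finish_consensus(label_runs, k, B, mode = "individual", full = NULL)
  if (!is.null(reference)) {
    ref <- if (inherits(reference, "ontokine_consensus")) {
      reference$labels
    } else if (inherits(reference, "ontokine_clust")) {
      reference$labels
    } else {
      reference
    }
    out$ari <- adjusted_rand(out$labels, ref)
  }
  out
}

# mean |x_i - x_j| across columns for every row pair (NA-tolerant)
pairwise_mean_abs <- function(Z) {
  A <- nrow(Z)
  D <- matrix(0, A, A)
  for (i in seq_len(A - 1)) {
    rest <- (i + 1):A
    d <- abs(Z[rest, , drop = FALSE] -
      matrix(Z[i, ], nrow = length(rest), ncol = ncol(Z), byrow = TRUE))
    D[rest, i] <- D[i, rest] <- rowMeans(d, na.rm = TRUE)
  }
  D
}

# run `draw(resample_seed)` B times, redrawing (with a warning) when a
# resample is degenerate (draw returns NULL)
run_resamples <- function(B, seed, stream, draw, max_redraw = 50L) {
  runs <- vector("list", B)
  redraws <- 0L
  for (b in seq_len(B)) {
    attempt <- 0L
    repeat {
      rs <- derive_seed(seed, b + attempt * (B + 17L), stream)
      lab <- draw(rs)
      if (!is.null(lab)) break
      attempt <- attempt + 1L
      redraws <- redraws + 1L
      if (attempt > max_redraw) abort("Too many degenerate resamples.")
    }
    runs[[b]] <- lab
  }
  if (redraws > 0) {
    inform(sprintf("%d degenerate resample(s) redrawn.", redraws))
  }
  runs
}

finish_consensus <- function(label_runs, k, B, mode, full) {
  analytes <- sort(names(label_runs[[1]]))
  A <- length(analytes)
  C <- matrix(0, A, A, dimnames = list(analytes, analytes))
  for (lab in label_runs) {
    lab <- lab[analytes]
    C <- C + outer(lab, lab, "==")
  }
  M <- C / length(label_runs)
  final <- cutree(hclust(as.dist(1 - M), method = "complete"), k = k)
  labels <- tibble(analyte = analytes, cluster = unname(final))
  per_cluster <- labels |>
    group_by(.data$cluster) |>
    summarise(
      n_analytes = dplyr::n(),
      consensus = {
        members <- .data$analyte
        if (length(members) < 2) {
          1 # a singleton always co-clusters with itself
        } else {
          sub <- M[members, members]
          mean(sub[upper.tri(sub)])
        }
      },
      .groups = "drop"
    )
  structure(
    list(
      M = M, labels = labels, k = k, per_cluster = per_cluster,
      avg_consensus = mean(per_cluster$consensus), B = B, mode = mode,
      full = full
    ),
    class = "ontokine_consensus"
  )
}

#' @export
print.ontokine_consensus <- function(x, ...) {
  cat("<ontokine_consensus: ", x$mode, "> k=", x$k, ", B=", x$B,
    ", average consensus=", sprintf("%.1f%%", 100 * x$avg_consensus),
    if (!is.null(x$ari)) sprintf(", ARI vs reference=%.3f", x$ari),
    "\n",
    sep = ""
  )
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.ontokine_consensus <- function(x, ...) {
  left_join(x$labels, x$per_cluster, by = "cluster")
}

#' @exportS3Method generics::glance
glance.ontokine_consensus <- function(x, ...) {
  tibble(
    mode = x$mode, k = x$k, B = x$B,
    avg_consensus = x$avg_consensus,
    ari = x$ari %||% NA_real_
  )
}
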