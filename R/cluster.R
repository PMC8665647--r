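#' Complete-linkage clustering of a distance matrix
#'
#' Standard agglomerative clustering with complete linkage. The distance
#' matrix rows are kept in lexicographic analyte order (as produced by
#' [trajectory_distances()]), which fixes the merge order when distances
#' tie.
#'
#' @param D Symmetric nonnegative distance matrix with zero diagonal.
#' @param k Number of clusters (`2 <= k <= nrow(D)`).
#' @return Object of class `ontokine_clust`: `labels` tibble (`analyte`,
#'   `cluster`), `k`, `asw` (average silhouette width at `k`), `hclust`,
#'   `D`.
#' @export
cluster_trajectories <- function(D, k) {
  check_distance_matrix(D)
  if (k < 2) abort("`k` must be at least 2.")
  if (k > nrow(D)) abort("`k` exceeds the number of analytes.")
  hc <- hclust(as.dist(D), method = "complete")
  cl <- cutree(hc, k = k)
  structure(
    list(
      labels = tibble(analyte = names(cl), cluster = unname(cl)),
      k = k,
      asw = silhouette_width(D, cl)$asw,
      hclust = hc,
      D = D
    ),
    class = "ontokine_clust"
  )
}

#' @export
print.ontokine_clust <- function(x, ...) {
  cat("<ontokine_clust> k=", x$k, ", ASW=", round(x$asw, 3), "\n", sep = "")
  print(table(cluster = x$labels$cluster))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.ontokine_clust <- function(x, ...) x$labels

#' @exportS3Method generics::glance
glance.ontokine_clust <- function(x, ...) {
  tibble(k = x$k, asw = x$asw, n_analytes = nrow(x$labels))
}

#' Silhouette widths from a distance matrix
#'
#' For item i with within-cluster mean distance `a(i)` and smallest mean
#' distance to another cluster `b(i)`, the silhouette is
#' `s(i) = (b - a) / max(a, b)`; members of singleton clusters take
#' `s(i) = 0` by convention.
#'
#' @param D Distance matrix.
#' @param labels Integer cluster labels aligned with the rows of `D`.
#' @return List with `widths` (tibble `analyte`, `cluster`, `silhouette`)
#'   and `asw` (their mean).
#' @export
silhouette_width <- function(D, labels) {
  n <- nrow(D)
  labels <- as.integer(labels)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(labels == labels[i])
    if (length(own) == 1) {
      s[i] <- 0
      next
    }
    a <- mean(D[i, setdiff(own, i)])
    b <- min(vapply(
      setdiff(unique(labels), labels[i]),
      function(cl) mean(D[i, labels == cl]),
      numeric(1)
    ))
    s[i] <- (b - a) / max(a, b)
  }
  list(
    widths = tibble(
      analyte = rownames(D) %||% as.character(seq_len(n)),
      cluster = labels, silhouette = s
    ),
    asw = mean(s)
  )
}

#' Select the number of clusters by average silhouette width
#'
#' Cuts the complete-linkage tree at each candidate `k` and picks the `k`
#' maximizing the average silhouette width; ties go to the smaller `k`.
#'
#' @param D Distance matrix.
#' @param k_range Candidate cluster counts (subset of `2..n-1`).
#' @return List `k` (the selected value) and `asw` (tibble `k`, `asw`).
#' @export
select_k <- function(D, k_range = 2:8) {
  check_distance_matrix(D)
  k_range <- sort(unique(as.integer(k_range)))
  if (min(k_range) < 2 || max(k_range) > nrow(D) - 1) {
    abort("`k_range` must lie within [2, n_analytes - 1].")
  }
  hc <- hclust(as.dist(D), method = "complete")
  asw <- map_dbl(k_range, function(k) {
    silhouette_width(D, cutree(hc, k = k))$asw
  })
  list(
    k = k_range[which.max(asw)], # which.max takes the first (smallest) tie
    asw = tibble(k = k_range, asw = asw)
  )
}

#' Export a merge tree in Newick format
#'
#' Topology-only Newick string of the complete-linkage dendrogram.
#'
#' @param hc An `hclust` object (or `ontokine_clust`).
#' @return Single Newick string.
#' @export
merge_tree_newick <- function(hc) {
  if (inherits(hc, "ontokine_clust")) hc <- hc$hclust
  lab <- hc$labels %||% as.character(seq_len(nrow(hc$merge) + 1))
  lab <- gsub("[(),;: ]", "_", lab)
  rec <- function(i) {
    if (i < 0) {
      lab[-i]
    } else {
      sprintf("(%s,%s)", rec(hc$merge[i, 1]), rec(hc$merge[i, 2]))
    }
  }
  paste0(rec(nrow(hc$merge)), ";")
}

check_distance_matrix <- function(D) {
  if (!is.matrix(D) || nrow(D) != ncol(D)) abort("`D` must be a square matrix.")
  if (any(D < 0)) abort("Distances must be nonnegative.")
  if (any(abs(diag(D)) > 1e-12)) abort("`D` must have a zero diagonal.")
  if (max(abs(D - t(D))) > 1e-8) abort("`D` must be symmetric.")
  invisible(D)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two clusterings of the same items
#' (1 = identical up to label permutation).
#'
#' @param labels1,labels2 Tibbles (`analyte`, `cluster`) or named/plain
#'   label vectors over the same items.
#' @return Scalar ARI.
#' @export
adjusted_rand <- function(labels1, labels2) {
  as_vec <- function(x) {
    if (is.data.frame(x)) setNames(x$cluster, x$analyte) else x
  }
  a <- as_vec(labels1)
  b <- as_vec(labels2)
  if (!is.null(names(a)) && !is.null(names(b))) {
    common <- intersect(names(a), names(b))
    if (!length(common)) abort("No common items between the partitions.")
    a <- a[common]
    b <- b[common]
  }
  if (length(a) != length(b)) abort("Partitions must cover the same items.")
  if (identical(as.integer(factor(a, levels = unique(a))),
    as.integer(factor(b, levels = unique(b))))) {
    return(1) # identical partitions, incl. the all-singleton case where
    # the chance-corrected denominator degenerates
  }
  mclust::adjustedRandIndex(a, b)
}
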