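#' Hierarchical merge tree of per-cell FRAP parameters
#'
#' Agglomerative clustering under Euclidean distance on (optionally
#' z-scored) parameter columns. Average linkage by default, the usual
#' companion of adaptive tree cutting; complete and Ward linkage are
#' available. Deterministic given the input order (distance ties are broken
#' by the merge order of the underlying agglomeration, which is stable for a
#' fixed row order).
#'
#' @param param_matrix Numeric matrix or data frame, cells x variables, with
#'   rownames identifying cells.
#' @param standardize Z-score each column first. Default TRUE.
#' @param linkage `"average"` (default), `"complete"`, or `"ward"`.
#' @return An [stats::hclust] tree.
#' @export
frap_dendrogram <- function(param_matrix, standardize = TRUE,
                            linkage = c("average", "complete", "ward")) {
  linkage <- match.arg(linkage)
  m <- as.matrix(param_matrix)
  if (nrow(m) < 3) abort("need at least 3 cells to build a dendrogram")
  if (any(!is.finite(m))) {
    bad <- rownames(m)[!complete.cases(m) | apply(!is.finite(m), 1, any)]
    abort(paste("non-finite parameter values for cells:",
                paste(head(bad, 5), collapse = ", ")))
  }
  if (standardize) {
    m <- apply(m, 2, function(col) {
      s <- sd(col)
      if (s > 0) (col - mean(col)) / s else col - mean(col)
    })
  }
  method <- if (linkage == "ward") "ward.D2" else linkage
  hclust(dist(m), method = method)
}

#' Adaptive cut of a dendrogram
#'
#' Chooses the number of clusters without a fixed cut height: candidate
#' partitions come from [stats::cutree] at `K = 1..k_max`, and K is selected
#' by the gap statistic (uniform reference distribution, `firstSEmax` rule),
#' which supports K = 1 when the data show no cluster structure. Clusters
#' smaller than `min_cluster_size` are then merged into the cluster with the
#' nearest centroid. With fewer than `2 * min_cluster_size` observations a
#' single cluster is returned with a warning.
#'
#' @param tree An [stats::hclust] tree.
#' @param data The (standardized, if the tree was) numeric matrix the tree
#'   was built from; needed by the gap statistic and for centroid merging.
#' @param min_cluster_size Minimum cells per cluster. Default 5.
#' @param k_max Largest K considered. Default 6 (capped by size).
#' @param n_ref Reference datasets for the gap statistic. Default 50.
#' @param seed Seed for the reference draws; fixed so the cut is
#'   deterministic. Default 20.
#' @return Integer vector of cluster labels (1..K, arbitrary order; see
#'   [label_clusters_by_if()] for the labeling convention).
#' @export
cut_frap_tree <- function(tree, data, min_cluster_size = 5, k_max = 6,
                          n_ref = 50, seed = 20) {
  data <- as.matrix(data)
  n <- nrow(data)
  if (n < 2 * min_cluster_size) {
    warn(sprintf("only %d cells (< 2 x min_cluster_size); returning one cluster", n))
    return(rep(1L, n))
  }
  k_max <- min(k_max, floor(n / min_cluster_size), n - 1)
  if (k_max < 2) return(rep(1L, n))
  # reference datasets must be re-clustered from scratch; only the observed
  # data reuse the prebuilt tree
  hc_method <- tree$method
  cluster_fun <- function(x, k) {
    tr <- if (identical(nrow(x), n) && isTRUE(all.equal(x, data,
                                                        check.attributes = FALSE))) {
      tree
    } else {
      hclust(dist(x), method = hc_method)
    }
    list(cluster = cutree(tr, k = k))
  }
  gap <- withr::with_seed(as.integer(seed), {
    cluster::clusGap(data, FUN = cluster_fun, K.max = k_max, B = n_ref,
                     verbose = FALSE)
  })
  k <- cluster::maxSE(gap$Tab[, "gap"], gap$Tab[, "SE.sim"],
                      method = "firstSEmax")
  labels <- cutree(tree, k = k)
  enforce_min_size(labels, data, min_cluster_size)
}

# Merge clusters below the size floor into the nearest remaining centroid.
enforce_min_size <- function(labels, data, min_size) {
  repeat {
    sizes <- table(labels)
    small <- names(sizes)[sizes < min_size]
    if (!length(small) || length(sizes) == 1) break
    lab <- small[which.min(sizes[small])]
    centroids <- rowsum(data, labels) / as.vector(table(labels))
    others <- setdiff(rownames(centroids), lab)
    d <- apply(centroids[others, , drop = FALSE], 1, function(ct) {
      sqrt(sum((ct - centroids[lab, ])^2))
    })
    labels[labels == as.integer(lab)] <- as.integer(others[which.min(d)])
  }
  as.integer(factor(labels))   # relabel 1..K without gaps
}

#' Apply the immobile-fraction labeling convention
#'
#' Renumbers clusters in decreasing order of mean immobile fraction, so
#' cluster 1 is always the high-binding subpopulation. Ties in the mean are
#' broken by larger cluster size, then by first appearance in the input
#' (noted in a message when it happens).
#'
#' @param labels Integer cluster labels, one per cell.
#' @param if_values Immobile fraction per cell (any consistent scale).
#' @return Integer labels 1..K with cluster 1 = highest mean immobile
#'   fraction.
#' @export
label_clusters_by_if <- function(labels, if_values) {
  stopifnot(length(labels) == length(if_values))
  d <- tibble(label = labels, if_value = if_values,
              order = seq_along(labels))
  summary <- d |>
    dplyr::group_by(.data$label) |>
    dplyr::summarize(mean_if = mean(.data$if_value), n = dplyr::n(),
                     first = min(.data$order), .groups = "drop")
  if (anyDuplicated(summary$mean_if)) {
    inform("tied cluster means; breaking ties by size, then input order")
  }
  summary <- summary |>
    dplyr::arrange(dplyr::desc(.data$mean_if), dplyr::desc(.data$n),
                   .data$first)
  remap <- setNames(seq_len(nrow(summary)), summary$label)
  as.integer(remap[as.character(labels)])
}

#' Ratio of cluster-1 to cluster-2 cell counts
#'
#' @param assignments Tibble with a `cluster_label` column (and optional
#'   grouping columns).
#' @param ... Grouping columns (tidy-select, e.g. `health_state, condition`);
#'   the ratio is computed within each group.
#' @return Tibble with per-group counts `n_cluster1`, `n_cluster2` and
#'   `ratio_1_to_2` (`NA` with a warning where cluster 2 is absent).
#' @export
#' @examples
#' cluster_ratio(tibble::tibble(cluster_label = rep(1:2, c(30, 20))))
cluster_ratio <- function(assignments, ...) {
  out <- assignments |>
    dplyr::group_by(...) |>
    dplyr::summarize(
      n_cluster1 = sum(.data$cluster_label == 1),
      n_cluster2 = sum(.data$cluster_label == 2),
      .groups = "drop") |>
    dplyr::mutate(ratio_1_to_2 = ifelse(.data$n_cluster2 > 0,
                                        .data$n_cluster1 / .data$n_cluster2,
                                        NA_real_))
  if (any(is.na(out$ratio_1_to_2))) {
    warn("cluster 2 absent in some groups; ratio undefined there")
  }
  out
}

#' Subpopulation discovery on a per-cell parameter table
#'
#' Runs the dendrogram + adaptive cut per donor per condition (mirroring how
#' heterogeneous cohorts are clustered donor-wise before same-numbered
#' clusters are combined across donors within a health state), then applies
#' the immobile-fraction labeling convention within each run. Only converged
#' cells are clustered.
#'
#' @param params Parameter table from [fit_frap()].
#' @param vars `"multivariate"` (default): z-scored immobile fraction, a1/a2
#'   ratio and both half-times; `"if-only"`: the immobile fraction alone,
#'   the variable used for cluster segregation.
#' @param min_cluster_size,linkage,k_max,n_ref,seed Passed to
#'   [frap_dendrogram()] / [cut_frap_tree()].
#' @return Assignment tibble: `cell_id`, `donor_id`, `health_state`,
#'   `condition`, `cluster_label`.
#' @export
cluster_frap <- function(params, vars = c("multivariate", "if-only"),
                         min_cluster_size = 5,
                         linkage = c("average", "complete", "ward"),
                         k_max = 6, n_ref = 50, seed = 20) {
  vars <- match.arg(vars)
  linkage <- match.arg(linkage)
  cols <- if (vars == "multivariate") {
    c("immobile_fraction_pct", "ratio_a1_a2", "t_half_fast_s", "t_half_slow_s")
  } else {
    "immobile_fraction_pct"
  }
  params |>
    dplyr::filter(.data$converged) |>
    dplyr::group_by(.data$donor_id, .data$health_state, .data$condition) |>
    dplyr::group_modify(function(d, key) {
      m <- as.matrix(d[, cols])
      rownames(m) <- d$cell_id
      if (nrow(d) < 2 * min_cluster_size) {
        warn(sprintf("stratum %s/%s: only %d cells; single cluster",
                     key$donor_id, key$condition, nrow(d)))
        labels <- rep(1L, nrow(d))
      } else {
        ms <- apply(m, 2, function(col) {
          s <- sd(col); if (s > 0) (col - mean(col)) / s else col - mean(col)
        })
        tree <- frap_dendrogram(m, standardize = TRUE, linkage = linkage)
        labels <- cut_frap_tree(tree, ms, min_cluster_size, k_max, n_ref, seed)
      }
      tibble(cell_id = d$cell_id,
             cluster_label = label_clusters_by_if(
               labels, d$immobile_fraction_pct))
    }) |>
    dplyr::ungroup() |>
    dplyr::select("cell_id", "donor_id", "health_state", "condition",
                  "cluster_label")
}
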