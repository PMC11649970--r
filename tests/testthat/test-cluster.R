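test_that("nearest points merge first and duplicates merge at height zero", {
  m <- matrix(c(0, 1, 10), ncol = 1)
  tree <- frap_dendrogram(m, standardize = FALSE)
  expect_equal(sort(tree$merge[1, ]), c(-2, -1))   # {0, 1} first
  m2 <- matrix(c(1, 1, 5, 9), ncol = 1)
  tree2 <- frap_dendrogram(m2, standardize = FALSE)
  expect_equal(tree2$height[1], 0)
})

test_that("average-linkage heights match a brute-force oracle", {
  set.seed(17)
  m <- matrix(rnorm(80), nrow = 20)
  tree <- frap_dendrogram(m, standardize = FALSE, linkage = "average")
  expect_true(all(diff(tree$height) >= -1e-12))    # monotone merges
  expect_equal(sort(tree$height), naive_average_linkage_heights(m),
               tolerance = 1e-10)
})

test_that("non-finite parameter values are rejected with the cell named", {
  m <- matrix(rnorm(20), ncol = 2,
              dimnames = list(paste0("cell_", 1:10), NULL))
  m[4, 2] <- NA
  expect_error(frap_dendrogram(m), "cell_4")
})

test_that("the adaptive cut finds the true number of groups", {
  set.seed(5)
  two <- matrix(c(rnorm(50, 0.60, 0.02), rnorm(50, 0.40, 0.02)), ncol = 1)
  lab <- cut_frap_tree(frap_dendrogram(two, standardize = FALSE), two)
  expect_equal(length(unique(lab)), 2)
  truth <- rep(1:2, each = 50)
  agreement <- max(mean(lab == truth), mean(lab == 3 - truth))
  expect_gte(agreement, 0.95)

  blob <- matrix(rnorm(60, 0.5, 0.01), ncol = 1)
  expect_equal(length(unique(
    cut_frap_tree(frap_dendrogram(blob, standardize = FALSE), blob))), 1)

  three <- matrix(c(rnorm(40, 0.2, 0.02), rnorm(40, 0.5, 0.02),
                    rnorm(40, 0.8, 0.02)), ncol = 1)
  expect_equal(length(unique(
    cut_frap_tree(frap_dendrogram(three, standardize = FALSE), three))), 3)
})

test_that("tiny inputs fall back to a single cluster with a warning", {
  m <- matrix(rnorm(8), ncol = 1)
  expect_warning(lab <- cut_frap_tree(frap_dendrogram(m, standardize = FALSE),
                                      m, min_cluster_size = 5),
                 "one cluster")
  expect_equal(lab, rep(1L, 8))
})

test_that("row order does not change memberships on tie-free data", {
  set.seed(23)
  x <- matrix(c(rnorm(30, 0.6, 0.02), rnorm(30, 0.4, 0.02)), ncol = 1)
  ids <- paste0("cell_", 1:60)
  perm <- sample(60)
  lab_a <- cut_frap_tree(frap_dendrogram(x, standardize = FALSE), x)
  xp <- x[perm, , drop = FALSE]
  lab_b <- cut_frap_tree(frap_dendrogram(xp, standardize = FALSE), xp)
  # compare partitions as sets of member-id groups
  canon <- function(ids, labels) {
    sort(vapply(split(ids, labels),
                function(g) paste(sort(g), collapse = ","), ""))
  }
  expect_equal(unname(canon(ids, lab_a)), unname(canon(ids[perm], lab_b)))
})

test_that("cluster 1 is the highest-immobile-fraction cluster", {
  labels <- rep(c(1, 2), each = 10)
  if_values <- c(rnorm(10, 0.4, 0.01), rnorm(10, 0.6, 0.01))
  out <- label_clusters_by_if(labels, if_values)
  expect_equal(out, rep(c(2L, 1L), each = 10))
  expect_equal(label_clusters_by_if(rep(1, 5), runif(5)), rep(1L, 5))
  out3 <- label_clusters_by_if(rep(1:3, each = 4),
                               rep(c(0.3, 0.5, 0.7), each = 4))
  expect_equal(out3, rep(c(3L, 2L, 1L), each = 4))
})

test_that("cluster ratio counts label 1 over label 2 per group", {
  a <- tibble::tibble(cluster_label = rep(1:2, c(30, 20)))
  expect_equal(cluster_ratio(a)$ratio_1_to_2, 1.5)
  b <- tibble::tibble(cluster_label = rep(1:2, c(10, 10)))
  expect_equal(cluster_ratio(b)$ratio_1_to_2, 1)
  c_only2 <- tibble::tibble(cluster_label = rep(2L, 8))
  expect_equal(cluster_ratio(c_only2)$ratio_1_to_2, 0)
  d_only1 <- tibble::tibble(cluster_label = rep(1L, 8))
  expect_warning(r <- cluster_ratio(d_only1), "undefined")
  expect_true(is.na(r$ratio_1_to_2))
})

test_that("preset mixtures are recovered near their cluster weights", {
  # clustering operates on the generator's immobile fractions directly:
  # the statistical question is whether the 2-SD-separated mixture is
  # resolved with weights close to the preset's
  for (state in c("healthy", "oa")) {
    preset <- frap_preset(state)
    sim <- simulate_frap_cells(preset, n_cells = 200, seed = 41,
                               acq = quick_acq(n_pre = 2, post_duration = 2.5))
    x <- matrix(sim$truth$if_frac, ncol = 1)
    lab <- cut_frap_tree(frap_dendrogram(x, standardize = FALSE), x)
    lab <- label_clusters_by_if(lab, sim$truth$if_frac)
    w1 <- mean(lab == 1)
    expect_lt(abs(w1 - preset$weights[1]), 0.08)
  }
})

test_that("cluster_frap runs per stratum and applies the labeling rule", {
  set.seed(71)
  params <- tibble::tibble(
    cell_id = paste0("cell_", 1:80),
    donor_id = rep(c("d1", "d2"), each = 40),
    health_state = "oa", condition = "control",
    immobile_fraction_pct = c(rnorm(25, 60, 1.5), rnorm(15, 40, 1.5),
                              rnorm(20, 62, 1.5), rnorm(20, 42, 1.5)),
    ratio_a1_a2 = rnorm(80, 1.2, 0.05),
    t_half_fast_s = rnorm(80, 1.6, 0.05),
    t_half_slow_s = rnorm(80, 14, 0.5),
    converged = TRUE)
  out <- cluster_frap(params, vars = "if-only")
  expect_equal(nrow(out), 80)
  means <- out |>
    dplyr::inner_join(params, by = c("cell_id", "donor_id")) |>
    dplyr::group_by(donor_id, cluster_label) |>
    dplyr::summarize(m = mean(immobile_fraction_pct), .groups = "drop")
  for (d in c("d1", "d2")) {
    sub <- means[means$donor_id == d, ]
    expect_equal(sub$cluster_label[which.max(sub$m)], 1L)
  }
})
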