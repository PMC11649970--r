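test_that("exact Mann-Whitney p-values match independent references", {
  # textbook fully separated case: U = 0, both tails have mass 1/20
  out <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(out$statistic, 0)
  expect_equal(out$p_value, 0.1)
  expect_equal(out$method, "exact")

  # tie-free samples, all sizes up to 6: agree with wilcox.test's exact path
  set.seed(29)
  for (n in 2:6) {
    for (m in 2:6) {
      x <- rnorm(n); y <- rnorm(m)
      ours <- mann_whitney_u(x, y)
      ref <- wilcox.test(x, y, exact = TRUE, correct = FALSE)
      expect_equal(ours$statistic, unname(ref$statistic))
      expect_equal(ours$p_value, ref$p.value)
      expect_equal(mann_whitney_u(x, y, "less")$p_value,
                   wilcox.test(x, y, alternative = "less",
                               exact = TRUE)$p.value)
    }
  }
})

test_that("U statistics obey the rank-sum identities", {
  x <- c(1.2, 3.4, 3.4, 5)
  y <- c(0.5, 3.4, 6, 7, 8)
  u_xy <- mann_whitney_u(x, y)$statistic
  u_yx <- mann_whitney_u(y, x)$statistic
  expect_equal(u_xy + u_yx, length(x) * length(y))
  expect_equal(mann_whitney_u(x, y)$p_value, mann_whitney_u(y, x)$p_value)
  # identical multisets sit at the center of the null
  z <- c(1, 2, 2, 3)
  expect_equal(mann_whitney_u(z, z)$statistic, length(z)^2 / 2)
  expect_error(mann_whitney_u(numeric(0), z), "nonempty")
})

test_that("exact and normal approximations agree closely at n = m = 8", {
  set.seed(31)
  for (i in 1:10) {
    x <- rnorm(8); y <- rnorm(8, 0.5)
    p_exact <- mann_whitney_u(x, y)$p_value
    p_norm <- mann_whitney_u(x, y, exact_limit = 0)$p_value
    expect_equal(mann_whitney_u(x, y, exact_limit = 0)$method, "normal")
    expect_lt(abs(p_exact - p_norm), 0.02)
  }
})

test_that("significance stars use strict conventional thresholds", {
  expect_equal(significance_stars(c(0.0005, 0.009, 0.03, 0.05, 0.2)),
               c("***", "**", "*", "", ""))
  expect_error(significance_stars(1.2), "\\[0, 1\\]")
  expect_error(significance_stars(-0.1), "\\[0, 1\\]")
})

test_that("group summaries report mean, sample SD and n per parameter", {
  params <- tibble::tibble(
    cell_id = paste0("c", 1:5),
    donor_id = "d1", health_state = c("a", "a", "a", "b", "b"),
    condition = "control",
    immobile_fraction_pct = c(7, 7, 7, 1, 3),
    ratio_a1_a2 = 1, t_half_fast_s = 1, t_half_slow_s = 10,
    converged = c(TRUE, TRUE, TRUE, TRUE, TRUE))
  out <- summarize_frap(params, health_state)
  a_if <- out[out$health_state == "a" &
                out$parameter == "immobile_fraction_pct", ]
  expect_equal(a_if$mean, 7); expect_equal(a_if$sd, 0); expect_equal(a_if$n, 3)
  b_if <- out[out$health_state == "b" &
                out$parameter == "immobile_fraction_pct", ]
  expect_equal(b_if$mean, 2); expect_equal(b_if$sd, sqrt(2))

  # non-converged rows never enter; singleton groups warn
  params$converged[5] <- FALSE
  expect_warning(out2 <- summarize_frap(params, health_state), "fewer than 2")
  expect_equal(out2[out2$health_state == "b" &
                      out2$parameter == "immobile_fraction_pct", ]$n, 1)
})

test_that("treatment-vs-control effects carry p, direction and stars", {
  set.seed(37)
  mk <- function(cond, values) {
    tibble::tibble(
      cell_id = paste0(cond, "_", seq_along(values)), donor_id = "d1",
      health_state = "oa", condition = cond,
      immobile_fraction_pct = values, ratio_a1_a2 = 1,
      t_half_fast_s = 1, t_half_slow_s = 10, converged = TRUE)
  }
  ctrl_vals <- rnorm(40, 50, 2)
  params <- dplyr::bind_rows(
    mk("control", ctrl_vals),
    mk("same", ctrl_vals),                 # treatment identical to control
    mk("shifted", rnorm(40, 70, 2)))       # +10 SD shift
  assignments <- params |>
    dplyr::transmute(cell_id, donor_id, health_state, condition,
                     cluster_label = 1L)
  out <- condition_effects(params, assignments)
  same <- out[out$condition == "same", ]
  expect_gt(same$p_value, 0.9)
  expect_equal(same$stars, "")
  shifted <- out[out$condition == "shifted", ]
  expect_lt(shifted$p_value, 0.001)
  expect_equal(shifted$direction, 1L)
  expect_equal(shifted$stars, "***")
})

test_that("strata without a control are flagged, others still computed", {
  mk <- function(state, cond, n = 12, mean = 50) {
    tibble::tibble(
      cell_id = paste(state, cond, seq_len(n), sep = "_"), donor_id = "d1",
      health_state = state, condition = cond,
      immobile_fraction_pct = rnorm(n, mean, 2), ratio_a1_a2 = 1,
      t_half_fast_s = 1, t_half_slow_s = 10, converged = TRUE)
  }
  set.seed(41)
  params <- dplyr::bind_rows(
    mk("oa", "control"), mk("oa", "BMP7", mean = 55),
    mk("healthy", "BMP7"))               # healthy stratum has no control
  assignments <- params |>
    dplyr::transmute(cell_id, donor_id, health_state, condition,
                     cluster_label = 1L)
  out <- condition_effects(params, assignments)
  healthy <- out[out$health_state == "healthy", ]
  expect_true(is.na(healthy$p_value))
  expect_match(healthy$note, "no control")
  oa <- out[out$health_state == "oa", ]
  expect_false(is.na(oa$p_value))
})
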