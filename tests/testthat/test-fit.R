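test_that("noiseless two-component curves are recovered to high precision", {
  truth <- kinetic_truth(0.5, 1, 1.5, 15, f0 = 0.3)
  fit <- fit_frap_trace(normalize_frap(noiseless_trace(truth)))
  amp <- truth_amplitudes(truth)
  expect_true(fit$converged)
  expect_lt(fit$rss, 1e-10)
  expect_equal(fit$params[["f0"]], 0.3, tolerance = 1e-3)
  expect_equal(fit$params[["a1"]], amp$a1, tolerance = 1e-3)
  expect_equal(fit$params[["a2"]], amp$a2, tolerance = 1e-3)
  expect_equal(fit$params[["t_half_fast"]], 1.5, tolerance = 1e-3)
  expect_equal(fit$params[["t_half_slow"]], 15, tolerance = 1e-3)
  expect_equal(fit$derived$if_frac, 0.5, tolerance = 1e-3)
})

test_that("components come back ordered fast < slow from any start order", {
  truth <- kinetic_truth(0.3, 2, 1, 20, f0 = 0.25)
  norm <- normalize_frap(noiseless_trace(truth))
  default <- fit_frap_trace(norm)
  reversed <- fit_frap_trace(norm, options = frap_fit_options(
    starts = list(c(15, 1), c(40, 3), c(5, 0.5))))
  expect_lt(default$params[["t_half_fast"]], default$params[["t_half_slow"]])
  expect_equal(reversed$params, default$params, tolerance = 1e-6)
})

test_that("a flat curve yields zero amplitudes and a fully immobile pool", {
  tr <- noiseless_trace(healthy_truth())
  tr$intensity[tr$phase == "post"] <- 0.3
  fit <- fit_frap_trace(normalize_frap(tr))
  expect_lt(fit$params[["a1"]] + fit$params[["a2"]], 0.01)
  expect_gt(fit$derived$if_frac, 0.98)
})

test_that("the one-component model recovers single-component truth", {
  truth <- kinetic_truth(0, Inf, 1, 15, f0 = 0.3)   # free fluorophore
  norm <- normalize_frap(noiseless_trace(truth))
  fit1 <- fit_frap_trace(norm, components = 1)
  expect_true(fit1$converged)
  expect_equal(fit1$params[["a1"]], 0.7, tolerance = 1e-3)
  expect_equal(fit1$params[["t_half_fast"]], 1, tolerance = 1e-3)
  expect_equal(fit1$params[["a2"]], 0)
  expect_lt(fit1$derived$if_frac, 0.01)
  expect_equal(fit1$derived$recovery_pct, 100, tolerance = 0.5)

  # nested models: one component can never beat two on two-component data
  norm2 <- normalize_frap(noiseless_trace(kinetic_truth(0.4, 1, 1, 20)))
  expect_gte(fit_frap_trace(norm2, components = 1)$rss + 1e-12,
             fit_frap_trace(norm2, components = 2)$rss)
})

test_that("derived parameters follow the bleach-corrected definitions", {
  d <- derive_frap_parameters(0.3, 0.175, 0.175)
  expect_equal(d$if_frac, 0.5)
  expect_equal(d$ratio, 1)
  expect_equal(d$recovery_pct, 50)
  # full recovery and no recovery limits
  expect_equal(derive_frap_parameters(0.3, 0.35, 0.35)$if_frac, 0)
  expect_equal(derive_frap_parameters(0.3, 0.35, 0.35)$recovery_pct, 100)
  expect_equal(derive_frap_parameters(0.3, 0, 0)$if_frac, 1)
  # uncorrected switch
  expect_equal(derive_frap_parameters(0.3, 0.2, 0.2,
                                      if_definition = "uncorrected")$if_frac,
               0.3)
  expect_true(derive_frap_parameters(0.5, 0.2, 0)$ratio_undefined)
  expect_error(derive_frap_parameters(1, 0.1, 0.1), "f0")
  expect_error(derive_frap_parameters(0.3, -0.1, 0.1), "amplitudes")
})

test_that("preconditions on the post-bleach window are enforced", {
  tr <- noiseless_trace(healthy_truth(),
                        acq = frap_acquisition(post_duration = 4))
  expect_error(fit_frap_trace(normalize_frap(tr)), "10 s|20 post")
  raw <- noiseless_trace(healthy_truth())
  expect_error(fit_frap_trace(raw), "normalized")
})

test_that("cohort fitting is deterministic, flags bad cells, keeps the rest", {
  sim <- simulate_frap_cells(fixed_preset(healthy_truth()), n_cells = 6,
                             seed = 31, noise = frap_noise(sigma_add = 0))
  norm <- normalize_frap(sim$traces)
  # flatten one cell post-bleach: no recovery signal
  flat_id <- "cell_0003"
  norm$normalized_intensity[norm$cell_id == flat_id &
                              norm$phase == "post"] <- 0.3
  tab <- suppressMessages(fit_frap(norm))
  expect_equal(nrow(tab), 6)
  good <- tab |> dplyr::filter(cell_id != flat_id)
  expect_true(all(good$converged))
  expect_equal(good$immobile_fraction_pct, rep(60.82, 5), tolerance = 1e-3)
  expect_equal(good$t_half_slow_s, rep(15.04, 5), tolerance = 1e-3)
  flat_row <- tab |> dplyr::filter(cell_id == flat_id)
  expect_gt(flat_row$immobile_fraction_pct, 98)

  tab2 <- suppressMessages(fit_frap(norm))
  expect_identical(tab, tab2)
  expect_error(fit_frap(norm[0, ]), "no traces")
})

test_that("tidy, glance and autoplot expose the fit", {
  fit <- fit_frap_trace(normalize_frap(noiseless_trace(healthy_truth())))
  td <- tidy(fit)
  expect_equal(td$term,
               c("f0", "a1", "a2", "t_half_fast", "t_half_slow"))
  gl <- glance(fit)
  expect_equal(gl$immobile_fraction_pct, 60.82, tolerance = 1e-3)
  expect_true(gl$converged)
  expect_s3_class(autoplot(fit), "ggplot")
})
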