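#' Fitting options for the recovery model
#'
#' Box bounds and convergence settings for the bounded Levenberg-Marquardt
#' fit. Bounds are physical-plausibility limits on a 60 s observation
#' window, loose enough not to bind at typical transcription-factor values:
#' amplitudes in `[0, 1.5]`, bleach floor in `[0, 0.95]`, fast half-time in
#' `[0.05, 30]` s, slow half-time in `[0.5, 300]` s. Three deterministic
#' starts bracket the fast/slow time scales (1/15 s, 0.5/5 s, 3/40 s); the
#' start with the lowest residual sum of squares wins, and components are
#' reordered after convergence so `t_half_fast < t_half_slow`.
#'
#' A converged fit additionally requires identifiable half-times: a
#' half-time pinned at a box bound while its amplitude is non-negligible
#' (> `amp_negligible`), or with a relative standard error above
#' `max_rel_se`, marks the cell `converged = FALSE`; such cells stay in the
#' parameter table but are excluded from downstream statistics.
#'
#' @param lower,upper Named numeric bounds for `f0`, `a1`, `a2`,
#'   `t_half_fast`, `t_half_slow`.
#' @param starts List of length-2 numeric vectors: fast/slow half-time
#'   starting pairs.
#' @param max_eval Maximum function evaluations per start. Default 2000.
#' @param tol Relative tolerance on parameters and cost. Default 1e-8.
#' @param max_rel_se Maximum relative standard error of a half-time for the
#'   fit to count as identifiable. Default 0.5.
#' @param amp_negligible Amplitude below which a component's half-time is
#'   unconstrained and therefore not checked. Default 0.01.
#' @param if_definition `"corrected"` (default) derives the immobile fraction
#'   from the bleach-depth-corrected span, `1 - (a1 + a2) / (1 - f0)`;
#'   `"uncorrected"` uses `1 - (f0 + a1 + a2)`.
#'
#' @return A list of class `frap_fit_options`.
#' @export
frap_fit_options <- function(lower = c(f0 = 0, a1 = 0, a2 = 0,
                                       t_half_fast = 0.05, t_half_slow = 0.5),
                             upper = c(f0 = 0.95, a1 = 1.5, a2 = 1.5,
                                       t_half_fast = 30, t_half_slow = 300),
                             starts = list(c(1, 15), c(0.5, 5), c(3, 40)),
                             max_eval = 2000, tol = 1e-8,
                             max_rel_se = 0.5, amp_negligible = 0.01,
                             if_definition = c("corrected", "uncorrected")) {
  structure(list(lower = lower, upper = upper, starts = starts,
                 max_eval = max_eval, tol = tol, max_rel_se = max_rel_se,
                 amp_negligible = amp_negligible,
                 if_definition = match.arg(if_definition)),
            class = "frap_fit_options")
}

# Residuals over the free parameters: 5 for the two-component model
# (f0, a1, a2, th_fast, th_slow), 3 for the nested one-component model
# (f0, a1, th_fast) with a2 fixed at zero.
model_residuals <- function(p, t, y) {
  if (length(p) == 3) {
    y - frap_recovery(t, p[1], p[2], 0, p[3], Inf)
  } else {
    y - frap_recovery(t, p[1], p[2], p[3], p[4], p[5])
  }
}

# Run bounded LM from one start; returns NULL on hard failure.
run_start <- function(p0, t, y, lower, upper, opts) {
  tryCatch(
    minpack.lm::nls.lm(
      par = p0, lower = unname(lower), upper = unname(upper),
      fn = model_residuals, t = t, y = y,
      control = minpack.lm::nls.lm.control(
        maxiter = min(opts$max_eval, 1024), ftol = opts$tol^1.5,
        ptol = opts$tol^1.5, maxfev = opts$max_eval)),
    error = function(e) NULL)
}

#' Fit the two-component recovery model to one cell
#'
#' Unweighted least squares of
#' `F(t) = f0 + a1 (1 - 2^(-t/t_half_fast)) + a2 (1 - 2^(-t/t_half_slow))`
#' over the post-bleach points of a normalized trace, by bounded
#' Levenberg-Marquardt from multiple deterministic starts. See
#' [frap_fit_options()] for bounds, starts, and the identifiability rules
#' behind the `converged` flag.
#'
#' @param norm_trace Normalized trace tibble for a single cell (from
#'   [normalize_frap()]), with at least 20 post-bleach points spanning at
#'   least 10 s.
#' @param components 2 (default) or 1; with 1 the slow component is fixed at
#'   zero (`a2 = 0`), the nested model appropriate for freely diffusing
#'   controls.
#' @param options A [frap_fit_options()] list.
#'
#' @return An object of class `frap_fit`: fitted parameters, derived
#'   quantities (immobile fraction, a1/a2 ratio, recovery percentage),
#'   standard errors, diagnostics, and the fitted data. Use [tidy()],
#'   [glance()], [autoplot()] on it.
#' @export
#' @examples
#' tr <- simulate_frap_trace(kinetic_truth(0.5, 1, 1.5, 15),
#'                           noise = frap_noise(sigma_add = 0), seed = 1)
#' fit <- fit_frap_trace(normalize_frap(tr))
#' glance(fit)
fit_frap_trace <- function(norm_trace, components = 2,
                           options = frap_fit_options()) {
  stopifnot(components %in% c(1, 2), inherits(options, "frap_fit_options"))
  if (!"normalized_intensity" %in% names(norm_trace)) {
    abort("trace is not normalized; run normalize_frap() first")
  }
  if (dplyr::n_distinct(norm_trace$cell_id) != 1) {
    abort("fit_frap_trace() expects a single cell; use fit_frap() for cohorts")
  }
  post <- norm_trace |> dplyr::filter(.data$phase == "post")
  t <- post$time_rel_s
  y <- post$normalized_intensity
  if (length(t) < 20 || (max(t) - min(t)) < 10) {
    abort(sprintf("cell '%s': need >= 20 post-bleach points spanning >= 10 s",
                  post$cell_id[1]))
  }

  f0_start <- min(max(y[1], options$lower["f0"]), options$upper["f0"])
  span <- max(mean(tail(y, 10)) - y[1], 0.05)
  free <- if (components == 1) c(1, 2, 4) else 1:5
  lower <- options$lower[free]
  upper <- options$upper[free]

  best <- NULL
  n_starts_used <- 0L
  for (hs in options$starts) {
    p0_full <- c(f0_start, if (components == 1) c(span, 0) else
      c(span / 2, span / 2), hs)
    p0 <- pmin(pmax(p0_full[free], unname(lower)), unname(upper))
    fit <- run_start(p0, t, y, lower, upper, options)
    n_starts_used <- n_starts_used + 1L
    if (is.null(fit)) next
    rss <- sum(residuals(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) {
    return(new_frap_fit(rep(NA_real_, 5), rep(NA_real_, 5), Inf, length(t),
                        FALSE, n_starts_used, components, options, post,
                        reason = "no start converged"))
  }

  p_free <- coef(best$fit)
  se_free <- tryCatch(sqrt(diag(stats::vcov(best$fit))),
                      error = function(e) rep(NA_real_, length(p_free)))
  p <- c(NA_real_, NA_real_, 0, NA_real_, Inf)   # one-component template
  se <- c(NA_real_, NA_real_, 0, NA_real_, NA_real_)
  p[free] <- p_free
  se[free] <- se_free
  if (components == 2 && p[4] > p[5]) {    # enforce fast < slow by relabeling
    p <- p[c(1, 3, 2, 5, 4)]
    se <- se[c(1, 3, 2, 5, 4)]
  }

  converged <- best$fit$info %in% 1:4
  reason <- NA_character_
  for (i in c(4, 5)) {
    amp_i <- p[i - 2]
    if (components == 1 && i == 5) next
    if (amp_i <= options$amp_negligible) next
    at_bound <- p[i] >= unname(options$upper[i]) * 0.999 ||
      p[i] <= unname(options$lower[i]) * 1.001
    rel_se <- se[i] / p[i]
    if (at_bound || !is.finite(rel_se) || rel_se > options$max_rel_se) {
      converged <- FALSE
      reason <- sprintf("half-time %s not identifiable", names(options$lower)[i])
    }
  }

  new_frap_fit(p, se, best$rss, length(t), converged, n_starts_used,
               components, options, post, reason = reason)
}

new_frap_fit <- function(p, se, rss, n_points, converged, n_starts_used,
                         components, options, data, reason = NA_character_) {
  names(p) <- names(se) <- c("f0", "a1", "a2", "t_half_fast", "t_half_slow")
  derived <- if (all(is.finite(p[1:3]))) {
    derive_frap_parameters(unname(p["f0"]), unname(p["a1"]), unname(p["a2"]),
                           if_definition = options$if_definition)
  } else {
    tibble(if_frac = NA_real_, ratio = NA_real_, recovery_pct = NA_real_,
           if_clipped = FALSE, ratio_undefined = TRUE)
  }
  structure(
    list(params = p, se = se, derived = derived, rss = rss,
         n_points = n_points, converged = converged,
         n_starts_used = n_starts_used, components = components,
         options = options, data = data, reason = reason),
    class = "frap_fit")
}

#' @export
print.frap_fit <- function(x, ...) {
  cat(sprintf("<frap_fit> %d-component, %s (rss %.3g, %d points)\n",
              x$components, if (x$converged) "converged" else "NOT converged",
              x$rss, x$n_points))
  print(round(x$params, 4))
  cat(sprintf("immobile fraction %.1f%%, a1/a2 %s, recovery %.1f%%\n",
              100 * x$derived$if_frac,
              ifelse(x$derived$ratio_undefined, "undefined",
                     sprintf("%.3f", x$derived$ratio)),
              x$derived$recovery_pct))
  invisible(x)
}

#' Derived FRAP parameters from fitted amplitudes
#'
#' The immobile fraction is the share of the bleach-depth-corrected span
#' left unrecovered, `1 - (a1 + a2) / (1 - f0)` (default), or the
#' uncorrected `1 - (f0 + a1 + a2)`; the recovery percentage is its
#' complement (x100). Values are clipped into `[0, 1]`, with clipping
#' reported in the `if_clipped` column. `ratio = a1/a2` is flagged undefined
#' when `a2 = 0`.
#'
#' @param f0,a1,a2 Fitted bleach floor and amplitudes (vectorized).
#' @param if_definition `"corrected"` or `"uncorrected"`.
#' @return Tibble with `if_frac`, `ratio`, `recovery_pct`, `if_clipped`,
#'   `ratio_undefined`.
#' @export
#' @examples
#' derive_frap_parameters(0.3, 0.175, 0.175)  # if_frac 0.5, ratio 1
derive_frap_parameters <- function(f0, a1, a2,
                                   if_definition = c("corrected",
                                                     "uncorrected")) {
  if_definition <- match.arg(if_definition)
  if (any(f0 >= 1)) abort("`f0` must be < 1")
  if (any(a1 < 0 | a2 < 0)) abort("amplitudes must be >= 0")
  recovered <- switch(if_definition,
                      corrected = (a1 + a2) / (1 - f0),
                      uncorrected = f0 + a1 + a2)
  if_raw <- 1 - recovered
  if_frac <- pmin(pmax(if_raw, 0), 1)
  tibble(
    if_frac = if_frac,
    ratio = ifelse(a2 > 0, a1 / a2, NA_real_),
    recovery_pct = 100 * recovered,
    if_clipped = abs(if_frac - if_raw) > 1e-12,
    ratio_undefined = a2 <= 0
  )
}

#' Fit the recovery model across a cohort
#'
#' Per-cell batch fit: one row per cell with metadata, fitted parameters,
#' derived quantities, and diagnostics. Cells whose fit fails the
#' convergence/identifiability checks are retained with `converged = FALSE`
#' (and a reason) so downstream statistics can exclude them transparently; a
#' message reports the exclusion count.
#'
#' @param norm_traces Normalized trace tibble (any number of cells).
#' @param components 2 (default) or 1.
#' @param options A [frap_fit_options()] list.
#' @return Tibble with one row per cell: `cell_id`, `donor_id`,
#'   `health_state`, `condition`, `f0`, `a1`, `a2`, `t_half_fast_s`,
#'   `t_half_slow_s`, `immobile_fraction_pct`, `ratio_a1_a2`,
#'   `recovery_pct`, `rss`, `n_points`, `converged`, `n_starts_used`,
#'   `reason`.
#' @export
fit_frap <- function(norm_traces, components = 2,
                     options = frap_fit_options()) {
  if (!nrow(norm_traces)) abort("no traces to fit")
  rows <- norm_traces |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::group_map(function(d, key) {
      d <- d |> dplyr::mutate(cell_id = key$cell_id)
      fit <- tryCatch(fit_frap_trace(d, components, options),
                      error = function(e) e)
      meta <- d |>
        dplyr::slice(1) |>
        dplyr::select("cell_id", "donor_id", "health_state", "condition")
      if (inherits(fit, "error")) {
        return(dplyr::bind_cols(meta, tibble(
          f0 = NA_real_, a1 = NA_real_, a2 = NA_real_,
          t_half_fast_s = NA_real_, t_half_slow_s = NA_real_,
          immobile_fraction_pct = NA_real_, ratio_a1_a2 = NA_real_,
          recovery_pct = NA_real_, rss = NA_real_, n_points = NA_integer_,
          converged = FALSE, n_starts_used = 0L,
          reason = conditionMessage(fit))))
      }
      dplyr::bind_cols(meta, tibble(
        f0 = fit$params[["f0"]], a1 = fit$params[["a1"]],
        a2 = fit$params[["a2"]],
        t_half_fast_s = fit$params[["t_half_fast"]],
        t_half_slow_s = fit$params[["t_half_slow"]],
        immobile_fraction_pct = 100 * fit$derived$if_frac,
        ratio_a1_a2 = fit$derived$ratio,
        recovery_pct = fit$derived$recovery_pct,
        rss = fit$rss, n_points = fit$n_points,
        converged = fit$converged, n_starts_used = fit$n_starts_used,
        reason = fit$reason))
    }) |>
    dplyr::bind_rows()
  n_bad <- sum(!rows$converged)
  if (n_bad) {
    inform(sprintf("%d of %d cells flagged non-converged and excluded from downstream statistics",
                   n_bad, nrow(rows)))
  }
  rows
}
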