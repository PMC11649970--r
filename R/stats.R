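#' Mann-Whitney U test
#'
#' Rank-sum comparison of two independent samples. The statistic is the
#' Mann-Whitney U for `x`: the number of pairs with `x > y`, counting ties
#' as 1/2, so `U_x + U_y = n * m` always. For small samples (both sizes
#' <= `exact_limit`) the p-value is exact, by enumeration of all
#' `choose(n + m, n)` equally likely group assignments of the pooled values
#' (ties handled naturally); otherwise the normal approximation with tie
#' correction and continuity correction is used.
#'
#' @param x,y Numeric samples (nonempty).
#' @param alternative `"two.sided"` (default), `"less"` (x stochastically
#'   smaller), or `"greater"`.
#' @param exact_limit Largest per-group size for exact enumeration.
#'   Default 8.
#' @return One-row tibble: `statistic` (U for x), `p_value`, `method`
#'   (`"exact"` or `"normal"`), `n_x`, `n_y`.
#' @export
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6))  # U = 0, p = 0.1
mann_whitney_u <- function(x, y,
                           alternative = c("two.sided", "less", "greater"),
                           exact_limit = 8) {
  alternative <- match.arg(alternative)
  if (!length(x) || !length(y)) abort("both samples must be nonempty")
  if (any(!is.finite(c(x, y)))) abort("samples must be finite")
  n <- length(x); m <- length(y)
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n)]) - n * (n + 1) / 2

  if (n <= exact_limit && m <= exact_limit) {
    u_all <- u_null_distribution(r, n)
    p <- switch(alternative,
      less = mean(u_all <= u + 1e-9),
      greater = mean(u_all >= u - 1e-9),
      two.sided = {
        center <- n * m / 2
        mean(abs(u_all - center) >= abs(u - center) - 1e-9)
      })
    method <- "exact"
  } else {
    mu <- n * m / 2
    nn <- n + m
    ties <- table(r)
    sigma2 <- n * m / 12 * ((nn + 1) - sum(ties^3 - ties) / (nn * (nn - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      sigma <- sqrt(sigma2)
      z_less <- (u - mu + 0.5) / sigma
      z_greater <- (u - mu - 0.5) / sigma
      p <- switch(alternative,
        less = stats::pnorm(z_less),
        greater = stats::pnorm(z_greater, lower.tail = FALSE),
        two.sided = min(1, 2 * min(stats::pnorm(z_less),
                                   stats::pnorm(z_greater,
                                                lower.tail = FALSE))))
    }
    method <- "normal"
  }
  tibble(statistic = u, p_value = p, method = method, n_x = n, n_y = m)
}

# Null distribution of U over all assignments of n pooled ranks to group x.
u_null_distribution <- function(pooled_ranks, n) {
  idx <- utils::combn(length(pooled_ranks), n)
  colSums(matrix(pooled_ranks[idx], nrow = n)) - n * (n + 1) / 2
}

#' Per-group mean +/- SD summary of FRAP parameters
#'
#' Group-level averages of the fitted parameters (converged cells only),
#' with sample SDs (n - 1 denominator) and group sizes — the per-state
#' summary table format.
#'
#' @param params Parameter table from [fit_frap()].
#' @param ... Grouping columns (tidy-eval), e.g. `health_state` or
#'   `health_state, donor_id`.
#' @param variables Character vector of parameter columns to summarize.
#' @return Long tibble: group columns, `parameter`, `mean`, `sd`, `n`;
#'   groups of fewer than 2 cells carry `sd = NA` and a warning.
#' @export
summarize_frap <- function(params, ...,
                           variables = c("immobile_fraction_pct",
                                         "ratio_a1_a2", "t_half_fast_s",
                                         "t_half_slow_s")) {
  out <- params |>
    dplyr::filter(.data$converged) |>
    tidyr::pivot_longer(dplyr::all_of(variables), names_to = "parameter") |>
    dplyr::group_by(..., .data$parameter) |>
    dplyr::summarize(mean = mean(.data$value), sd = sd(.data$value),
                     n = dplyr::n(), .groups = "drop")
  if (any(out$n < 2)) {
    warn("groups with fewer than 2 cells have undefined SD")
  }
  out
}

#' Significance stars at the conventional thresholds
#'
#' `"***"` for p < 0.001, `"**"` for p < 0.01, `"*"` for p < 0.05 (strict
#' inequalities), otherwise the empty string.
#'
#' @param p Probability in `[0, 1]` (vectorized).
#' @return Character vector.
#' @export
#' @examples
#' significance_stars(c(0.0005, 0.03, 0.05))
significance_stars <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
    abort("`p` must lie in [0, 1]")
  }
  dplyr::case_when(p < 0.001 ~ "***", p < 0.01 ~ "**", p < 0.05 ~ "*",
                   TRUE ~ "")
}

#' Treatment-versus-control effect matrix per cluster and health state
#'
#' Within each (health state, cluster) stratum, compares every treatment
#' condition against the control with a Mann-Whitney U test on one fitted
#' parameter, reporting the p-value, the sign of the median difference, and
#' a star annotation. Strata lacking the control (or with empty samples) are
#' retained with `p_value = NA` and a note. No multiple-testing correction
#' is applied by default (per-comparison significance is reported raw); set
#' `adjust = "BH"` for Benjamini-Hochberg, which is recorded in the
#' `p_adjust` attribute-free `adjust_method` column.
#'
#' @param params Parameter table from [fit_frap()].
#' @param assignments Cluster assignments from [cluster_frap()].
#' @param control_label Condition label of the control. Default
#'   `"control"`.
#' @param variable Parameter column compared. Default
#'   `"immobile_fraction_pct"`.
#' @param adjust `"none"` (default) or `"BH"`.
#' @return Tibble: `health_state`, `cluster_label`, `condition`, `n_treat`,
#'   `n_control`, `statistic`, `p_value`, `direction` (-1/0/+1 sign of the
#'   median difference), `stars`, `note`, `adjust_method`.
#' @export
condition_effects <- function(params, assignments, control_label = "control",
                              variable = "immobile_fraction_pct",
                              adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  d <- params |>
    dplyr::filter(.data$converged) |>
    dplyr::inner_join(assignments |>
                        dplyr::select("cell_id", "cluster_label"),
                      by = "cell_id")
  strata <- d |>
    dplyr::distinct(.data$health_state, .data$cluster_label,
                    .data$condition) |>
    dplyr::filter(.data$condition != control_label)
  rows <- purrr::pmap(strata, function(health_state, cluster_label,
                                       condition) {
    treat <- d[[variable]][d$health_state == health_state &
                             d$cluster_label == cluster_label &
                             d$condition == condition]
    ctrl <- d[[variable]][d$health_state == health_state &
                            d$cluster_label == cluster_label &
                            d$condition == control_label]
    base <- tibble(health_state = health_state,
                   cluster_label = cluster_label, condition = condition,
                   n_treat = length(treat), n_control = length(ctrl))
    if (!length(ctrl)) {
      return(base |> dplyr::mutate(statistic = NA_real_, p_value = NA_real_,
                                   direction = NA_integer_, stars = "",
                                   note = "no control stratum"))
    }
    test <- mann_whitney_u(treat, ctrl)
    base |>
      dplyr::mutate(statistic = test$statistic, p_value = test$p_value,
                    direction = as.integer(sign(median(treat) - median(ctrl))),
                    stars = "", note = NA_character_)
  })
  out <- dplyr::bind_rows(rows)
  if (adjust == "BH") {
    out$p_value <- stats::p.adjust(out$p_value, method = "BH")
  }
  out |>
    dplyr::mutate(
      stars = significance_stars(dplyr::coalesce(.data$p_value, 1)),
      adjust_method = adjust)
}
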