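#' Tidy a single-cell FRAP fit
#'
#' @param x A `frap_fit` from [fit_frap_trace()].
#' @param ... Unused.
#' @return Tibble with one row per model parameter: `term`, `estimate`,
#'   `std.error`.
#' @method tidy frap_fit
#' @export
tidy.frap_fit <- function(x, ...) {
  tibble(term = names(x$params),
         estimate = unname(x$params),
         std.error = unname(x$se))
}

#' One-row summary of a single-cell FRAP fit
#'
#' @param x A `frap_fit`.
#' @param ... Unused.
#' @return One-row tibble with the derived parameters and diagnostics.
#' @method glance frap_fit
#' @export
glance.frap_fit <- function(x, ...) {
  tibble(
    immobile_fraction_pct = 100 * x$derived$if_frac,
    ratio_a1_a2 = x$derived$ratio,
    recovery_pct = x$derived$recovery_pct,
    t_half_fast_s = x$params[["t_half_fast"]],
    t_half_slow_s = x$params[["t_half_slow"]],
    rss = x$rss, n_points = x$n_points, components = x$components,
    converged = x$converged, n_starts_used = x$n_starts_used
  )
}

#' Plot a fitted recovery curve over the data
#'
#' @param object A `frap_fit`.
#' @param ... Unused.
#' @return A ggplot: post-bleach points with the fitted curve.
#' @method autoplot frap_fit
#' @export
autoplot.frap_fit <- function(object, ...) {
  d <- object$data
  grid <- tibble(time_rel_s = seq(0, max(d$time_rel_s), length.out = 400))
  p <- object$params
  grid$fitted <- frap_recovery(grid$time_rel_s, p["f0"], p["a1"], p["a2"],
                               p["t_half_fast"], p["t_half_slow"])
  ggplot2::ggplot(d, ggplot2::aes(.data$time_rel_s,
                                  .data$normalized_intensity)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_line(data = grid, ggplot2::aes(y = .data$fitted),
                       color = "#c0392b", linewidth = 0.8) +
    ggplot2::labs(x = "time after bleach (s)", y = "normalized intensity",
                  title = sprintf("%s: IF %.1f%%, t½ %.2g / %.3g s",
                                  d$cell_id[1], 100 * object$derived$if_frac,
                                  p[["t_half_fast"]], p[["t_half_slow"]])) +
    ggplot2::theme_minimal()
}

#' Averaged recovery curves by group
#'
#' Mean normalized recovery with an SD ribbon per group, the standard
#' population-level FRAP display.
#'
#' @param norm_traces Normalized trace tibble.
#' @param group Column to facet colors by (tidy-eval). Default `health_state`.
#' @return A ggplot.
#' @export
plot_recovery <- function(norm_traces, group = "health_state") {
  d <- norm_traces |>
    dplyr::filter(.data$phase == "post") |>
    dplyr::group_by(.data$time_rel_s, grp = .data[[group]]) |>
    dplyr::summarize(mean_i = mean(.data$normalized_intensity),
                     sd_i = sd(.data$normalized_intensity), .groups = "drop")
  ggplot2::ggplot(d, ggplot2::aes(.data$time_rel_s, .data$mean_i,
                                  color = .data$grp, fill = .data$grp)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean_i - .data$sd_i,
                                      ymax = .data$mean_i + .data$sd_i),
                         alpha = 0.2, color = NA) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time after bleach (s)", y = "normalized intensity",
                  color = group, fill = group) +
    ggplot2::theme_minimal()
}

#' Cluster heat-map of per-cell FRAP parameters
#'
#' Cells ordered by (cluster, immobile fraction), z-scored parameters on
#' tiles — the single-cell display used to show subpopulation structure.
#'
#' @param params Parameter table from [fit_frap()].
#' @param assignments Cluster assignment tibble from [cluster_frap()].
#' @return A ggplot.
#' @export
plot_cluster_heatmap <- function(params, assignments) {
  d <- params |>
    dplyr::inner_join(assignments |>
                        dplyr::select("cell_id", "cluster_label"),
                      by = "cell_id") |>
    dplyr::filter(.data$converged) |>
    dplyr::arrange(.data$cluster_label,
                   dplyr::desc(.data$immobile_fraction_pct)) |>
    dplyr::mutate(cell_order = dplyr::row_number()) |>
    dplyr::select("cell_id", "cell_order", "cluster_label",
                  "immobile_fraction_pct", "ratio_a1_a2",
                  "t_half_fast_s", "t_half_slow_s") |>
    tidyr::pivot_longer(c("immobile_fraction_pct", "ratio_a1_a2",
                          "t_half_fast_s", "t_half_slow_s"),
                        names_to = "parameter") |>
    dplyr::group_by(.data$parameter) |>
    dplyr::mutate(z = as.numeric(scale(.data$value))) |>
    dplyr::ungroup()
  ggplot2::ggplot(d, ggplot2::aes(.data$parameter, .data$cell_order,
                                  fill = .data$z)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2980b9", high = "#c0392b") +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$cluster_label),
                        scales = "free_y", space = "free_y") +
    ggplot2::labs(x = NULL, y = "cells (by cluster, IF)", fill = "z-score") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}
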