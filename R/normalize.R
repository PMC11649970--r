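#' Normalize FRAP traces against the pre-bleach plateau
#'
#' Divides every intensity of a cell by the mean of that cell's last
#' `n_pre_norm` pre-bleach intensities (after optional constant background
#' subtraction), and rebases time so the first post-bleach frame sits at
#' `t = 0`. Pre-bleach frames keep their normalized values (at negative
#' rebased times) for quality control; the model fit uses only the post
#' block. Normalization is scale-invariant: multiplying all raw intensities
#' of a cell by any positive constant leaves the result unchanged.
#'
#' @param traces Trace tibble (validated).
#' @param n_pre_norm Number of trailing pre-bleach frames to average.
#'   Default 10.
#' @param background Constant offset subtracted from every raw intensity
#'   before normalization. Default 0 (none); a message notes a nonzero value.
#'
#' @return The trace tibble with added columns `normalized_intensity` and
#'   `time_rel_s` (seconds relative to the first post-bleach frame).
#' @export
#' @examples
#' tr <- simulate_frap_trace(kinetic_truth(0.5, 1, 1.5, 15), seed = 1)
#' norm <- normalize_frap(tr)
#' norm$time_rel_s[norm$phase == "post"][1]  # 0
normalize_frap <- function(traces, n_pre_norm = 10, background = 0) {
  validate_frap_traces(traces)
  if (background != 0) {
    inform(sprintf("subtracting constant background %g before normalization",
                   background))
  }
  one <- function(d, key) {
    id <- key$cell_id
    pre <- d$intensity[d$phase == "pre"] - background
    if (length(pre) < n_pre_norm) {
      abort(sprintf("cell '%s': %d pre-bleach frames but n_pre_norm = %d",
                    id, length(pre), n_pre_norm))
    }
    denom <- mean(tail(pre, n_pre_norm))
    if (!is.finite(denom) || denom <= 0) {
      abort(sprintf("cell '%s': nonpositive normalization denominator (%g)",
                    id, denom))
    }
    t0 <- d$time_s[d$phase == "post"][1]
    d |>
      dplyr::mutate(normalized_intensity = (.data$intensity - background) / denom,
                    time_rel_s = .data$time_s - t0)
  }
  traces |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::group_modify(~ one(.x, .y)) |>
    dplyr::ungroup() |>
    dplyr::relocate("cell_id")
}

#' Double-normalize against a reference trace (acquisition-bleaching drift)
#'
#' Divides each cell's normalized intensity by the normalized intensity of a
#' reference trace (for example, an unbleached cell in the same field) at the
#' same frame index, correcting slow acquisition bleaching. Off by default in
#' the pipeline: the protocol this package models reports no such correction.
#'
#' @param traces Normalized trace tibble (from [normalize_frap()]).
#' @param reference One-cell normalized trace tibble, frame-aligned with
#'   every cell in `traces`.
#' @return `traces` with `normalized_intensity` replaced by the corrected
#'   values.
#' @export
drift_correct <- function(traces, reference) {
  if (!"normalized_intensity" %in% names(traces) ||
      !"normalized_intensity" %in% names(reference)) {
    abort("both inputs must carry `normalized_intensity` (run normalize_frap() first)")
  }
  if (dplyr::n_distinct(reference$cell_id) != 1) {
    abort("`reference` must contain exactly one cell")
  }
  ref <- reference |>
    dplyr::select("frame_index", ref_value = "normalized_intensity")
  out <- traces |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::group_modify(function(d, key) {
      if (!identical(sort(d$frame_index), sort(ref$frame_index))) {
        abort(sprintf("cell '%s': frame grid does not match the reference",
                      key$cell_id))
      }
      d |>
        dplyr::left_join(ref, by = "frame_index") |>
        dplyr::mutate(normalized_intensity =
                        .data$normalized_intensity / .data$ref_value) |>
        dplyr::select(-"ref_value")
    }) |>
    dplyr::ungroup() |>
    dplyr::relocate("cell_id")
  out
}
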