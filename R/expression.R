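#' Relative expression by the comparative Ct method
#'
#' Livak 2^-ddCt quantification: the target gene's cycle threshold is
#' normalized to a reference gene within each group
#' (`dCt = Ct_target - Ct_reference`), and the treated group's dCt is
#' compared to the untreated control's
#' (`fold = 2^-(dCt_treated - dCt_control)`). Assumes perfect doubling per
#' cycle; each Ct should be the mean over its technical replicates.
#' Vectorized over treated-group Ct values.
#'
#' @param ct_target_treated,ct_ref_treated Target- and reference-gene Ct in
#'   the treated group.
#' @param ct_target_control,ct_ref_control Same for the untreated control.
#' @return Numeric fold change(s).
#' @export
#' @examples
#' relative_expression(25, 20, 27, 20)  # ddCt = -2, fold = 4
relative_expression <- function(ct_target_treated, ct_ref_treated,
                                ct_target_control, ct_ref_control) {
  cts <- list(ct_target_treated, ct_ref_treated, ct_target_control,
              ct_ref_control)
  if (any(vapply(cts, function(v) length(v) == 0 || any(!is.finite(v)),
                 logical(1)))) {
    abort("all four Ct groups are required and must be finite")
  }
  d_ct_treated <- ct_target_treated - ct_ref_treated
  d_ct_control <- ct_target_control - ct_ref_control
  2^(-(d_ct_treated - d_ct_control))
}

#' Fold-change table from a tidy Ct table
#'
#' Aggregates replicate Ct values (mean per sample/gene/condition), then
#' reports each gene's fold change in every non-control condition relative
#' to the control, normalized to the reference gene. Mean Ct above
#' `high_ct_limit` is flagged as near the detection limit.
#'
#' @param ct_table Tibble with columns `sample`, `gene`, `condition`, `ct`.
#' @param reference_gene Housekeeping gene. Default `"GAPDH"`.
#' @param control_label Untreated condition label. Default `"control"`.
#' @param high_ct_limit Flagging threshold for mean Ct. Default 35.
#' @return Tibble: `gene`, `condition`, `fold_change`, `mean_ct_target`,
#'   `high_ct_flag`.
#' @export
fold_change_table <- function(ct_table, reference_gene = "GAPDH",
                              control_label = "control",
                              high_ct_limit = 35) {
  need <- c("sample", "gene", "condition", "ct")
  missing_cols <- setdiff(need, names(ct_table))
  if (length(missing_cols)) {
    abort(paste("Ct table lacks columns:",
                paste(missing_cols, collapse = ", ")))
  }
  means <- ct_table |>
    dplyr::group_by(.data$gene, .data$condition) |>
    dplyr::summarize(ct = mean(.data$ct), .groups = "drop")
  ref <- means |>
    dplyr::filter(.data$gene == reference_gene) |>
    dplyr::select("condition", ct_ref = "ct")
  if (!nrow(ref)) {
    abort(sprintf("reference gene '%s' absent from the Ct table",
                  reference_gene))
  }
  targets <- means |>
    dplyr::filter(.data$gene != reference_gene) |>
    dplyr::left_join(ref, by = "condition")
  ctrl <- targets |>
    dplyr::filter(.data$condition == control_label) |>
    dplyr::select("gene", ct_target_control = "ct",
                  ct_ref_control = "ct_ref")
  if (!nrow(ctrl)) {
    abort(sprintf("control condition '%s' absent from the Ct table",
                  control_label))
  }
  targets |>
    dplyr::filter(.data$condition != control_label) |>
    dplyr::inner_join(ctrl, by = "gene") |>
    dplyr::mutate(
      fold_change = relative_expression(.data$ct, .data$ct_ref,
                                        .data$ct_target_control,
                                        .data$ct_ref_control),
      mean_ct_target = .data$ct,
      high_ct_flag = .data$ct > high_ct_limit) |>
    dplyr::select("gene", "condition", "fold_change", "mean_ct_target",
                  "high_ct_flag")
}
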