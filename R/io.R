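#' Validate a FRAP trace table
#'
#' Checks the per-cell invariants of the long trace format: required columns,
#' strictly increasing times and frame indices, and exactly one contiguous
#' `pre` block followed by one contiguous `post` block with at least one
#' frame each. Violations raise an error naming the offending cell.
#'
#' @param traces Trace tibble (see [simulate_frap_trace()] for the schema).
#' @return The input, invisibly, if valid.
#' @export
validate_frap_traces <- function(traces) {
  need <- c("cell_id", "donor_id", "health_state", "condition",
            "frame_index", "time_s", "phase", "intensity")
  missing_cols <- setdiff(need, names(traces))
  if (length(missing_cols)) {
    abort(paste("trace table lacks required columns:",
                paste(missing_cols, collapse = ", ")))
  }
  bad_phase <- setdiff(unique(traces$phase), c("pre", "post"))
  if (length(bad_phase)) {
    abort(paste("unknown phase labels:", paste(bad_phase, collapse = ", ")))
  }
  check_cell <- function(d) {
    id <- d$cell_id[1]
    if (any(!is.finite(d$intensity)) || any(d$intensity < 0)) {
      abort(sprintf("cell '%s': intensities must be finite and >= 0", id))
    }
    if (any(diff(d$time_s) <= 0)) {
      abort(sprintf("cell '%s': times must be strictly increasing", id))
    }
    if (any(diff(d$frame_index) <= 0)) {
      abort(sprintf("cell '%s': frame indices must be strictly increasing", id))
    }
    r <- rle(d$phase)
    if (!identical(r$values, c("pre", "post"))) {
      abort(sprintf(
        "cell '%s': phases must form one contiguous pre block then one contiguous post block",
        id))
    }
    invisible(NULL)
  }
  traces |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::group_walk(~ check_cell(.x |> dplyr::mutate(cell_id = .y$cell_id)))
  invisible(traces)
}

#' Read / write FRAP trace tables
#'
#' Trace tables are comma-separated UTF-8 text with one header row and one
#' row per frame, columns `cell_id, donor_id, health_state, condition,
#' frame_index, time_s, phase, intensity`. Reading validates every cell's
#' invariants (monotone times, one pre block then one post block) and rejects
#' malformed input rather than repairing it; writing is a full-precision
#' round trip.
#'
#' @param path File path.
#' @return `read_frap_traces()`: a validated trace tibble (empty input with a
#'   valid header yields an empty tibble).
#' @export
read_frap_traces <- function(path) {
  spec <- readr::cols(
    cell_id = readr::col_character(), donor_id = readr::col_character(),
    health_state = readr::col_character(), condition = readr::col_character(),
    frame_index = readr::col_integer(), time_s = readr::col_double(),
    phase = readr::col_character(), intensity = readr::col_double()
  )
  traces <- readr::read_csv(path, col_types = spec, progress = FALSE)
  problems <- readr::problems(traces)
  if (nrow(problems)) {
    abort(sprintf("malformed rows in '%s' (first at line %d): %s", path,
                  problems$row[1] + 1L, problems$expected[1]))
  }
  if (nrow(traces)) validate_frap_traces(traces)
  traces
}

#' @param traces Trace tibble to write.
#' @rdname read_frap_traces
#' @export
write_frap_traces <- function(traces, path) {
  validate_frap_traces(traces)
  readr::write_csv(traces, path, progress = FALSE)
  invisible(path)
}

#' Circular bleach-region definition
#'
#' @param center_x,center_y ROI center in pixel coordinates (0-based pixel
#'   indices; the center of pixel `(r, c)` is at `(x = c, y = r)`).
#' @param diameter ROI diameter in micrometers. Default 2.9, a typical
#'   nuclear spot-bleach region.
#' @param pixel_size Micrometers per pixel. Default 0.12.
#' @return A list of class `frap_roi`.
#' @export
frap_roi <- function(center_x, center_y, diameter = 2.9, pixel_size = 0.12) {
  if (!is.finite(diameter) || diameter <= 0) abort("`diameter` must be > 0")
  if (!is.finite(pixel_size) || pixel_size <= 0) abort("`pixel_size` must be > 0")
  structure(list(center_x = center_x, center_y = center_y,
                 diameter = diameter, pixel_size = pixel_size),
            class = "frap_roi")
}

# Logical mask of pixels whose (0-based) center lies strictly inside the ROI.
roi_mask <- function(roi, n_rows, n_cols) {
  r_px <- (roi$diameter / 2) / roi$pixel_size
  cols <- matrix(0:(n_cols - 1), n_rows, n_cols, byrow = TRUE)
  rows <- matrix(0:(n_rows - 1), n_rows, n_cols)
  (cols - roi$center_x)^2 + (rows - roi$center_y)^2 < r_px^2
}

#' Extract a mean-intensity FRAP trace from an image stack
#'
#' Averages, per frame, the pixels whose centers fall strictly inside a
#' circular ROI (half-open membership, 0-based pixel indices) and labels the
#' first `acq$n_pre` frames `pre` and the remainder `post` on the acquisition
#' time grid. The arithmetic mean (not the sum) is used so the trace does not
#' depend on ROI size.
#'
#' @param stack 3-D numeric array, frames x rows x cols, or a list of
#'   matrices (one per frame).
#' @param roi A [frap_roi()].
#' @param acq A [frap_acquisition()]; the stack must have more than
#'   `acq$n_pre` frames.
#' @param cell_id,donor_id,health_state,condition Metadata for the trace.
#' @return A trace tibble.
#' @export
extract_roi_trace <- function(stack, roi, acq = frap_acquisition(),
                              cell_id = "cell_001", donor_id = "donor_1",
                              health_state = "unknown", condition = "control") {
  stopifnot(inherits(roi, "frap_roi"), inherits(acq, "frap_acquisition"))
  if (is.list(stack)) {
    stack <- simplify2array(stack)        # rows x cols x frames
    stack <- aperm(stack, c(3, 1, 2))
  }
  if (length(dim(stack)) != 3) {
    abort("`stack` must be a frames x rows x cols array")
  }
  n_frames <- dim(stack)[1]; n_rows <- dim(stack)[2]; n_cols <- dim(stack)[3]
  if (n_frames < acq$n_pre + 1) {
    abort(sprintf("stack has %d frames; need at least n_pre + 1 = %d",
                  n_frames, acq$n_pre + 1))
  }
  r_px <- (roi$diameter / 2) / roi$pixel_size
  if (roi$center_x - r_px < -0.5 || roi$center_x + r_px > n_cols - 0.5 ||
      roi$center_y - r_px < -0.5 || roi$center_y + r_px > n_rows - 0.5) {
    abort("ROI extends outside the image bounds")
  }
  mask <- roi_mask(roi, n_rows, n_cols)
  if (!any(mask)) abort("ROI contains no pixel centers")
  intensity <- vapply(seq_len(n_frames),
                      function(f) mean(stack[f, , ][mask]), numeric(1))
  grid <- acquisition_times(acq)
  n_post <- n_frames - acq$n_pre
  dt <- 1 / acq$frame_rate
  t_post <- grid$pre[acq$n_pre] + acq$bleach_duration + dt +
    (seq_len(n_post) - 1) * dt
  tibble(
    cell_id = cell_id, donor_id = donor_id, health_state = health_state,
    condition = condition,
    frame_index = seq_len(n_frames) - 1L,
    time_s = c(grid$pre, t_post),
    phase = rep(c("pre", "post"), c(acq$n_pre, n_post)),
    intensity = intensity
  )
}

#' Read a multi-frame grayscale TIFF as a frames x rows x cols array
#'
#' @param path TIFF file path.
#' @return 3-D numeric array.
#' @export
read_image_stack <- function(path) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    abort("reading TIFF stacks requires the 'tiff' package")
  }
  frames <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (is.matrix(frames)) frames <- list(frames)
  arr <- simplify2array(frames)
  aperm(arr, c(3, 1, 2))
}
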