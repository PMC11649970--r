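#' Confocal FRAP acquisition settings
#'
#' Describes the imaging protocol of a spot-bleach FRAP experiment: a block of
#' pre-bleach frames, a short bleach pulse, and a post-bleach recovery phase
#' sampled at a fixed frame rate. Defaults match a typical nuclear
#' transcription-factor protocol on a laser-scanning confocal: 25 pre-bleach
#' frames, a 60 ms single-iteration bleach, and 60 s of recovery at
#' 4 frames/s, with the last 10 pre-bleach frames used for normalization.
#'
#' @param frame_rate Frames per second. Default 4.
#' @param n_pre Number of pre-bleach frames. Default 25.
#' @param post_duration Seconds of post-bleach acquisition. Default 60.
#' @param bleach_duration Duration of the bleach pulse in seconds, modelled as
#'   a gap in the timestamp grid only (no frames are recorded during the
#'   pulse). Default 0.06.
#' @param n_pre_norm Number of trailing pre-bleach frames averaged to form the
#'   normalization denominator. Default 10.
#'
#' @return A list of class `frap_acquisition`.
#' @export
#' @examples
#' acq <- frap_acquisition()
#' acq$frame_rate
frap_acquisition <- function(frame_rate = 4, n_pre = 25, post_duration = 60,
                             bleach_duration = 0.06, n_pre_norm = 10) {
  vals <- c(frame_rate = frame_rate, n_pre = n_pre,
            post_duration = post_duration, bleach_duration = bleach_duration,
            n_pre_norm = n_pre_norm)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    abort("all acquisition settings must be finite and strictly positive")
  }
  if (n_pre_norm > n_pre) {
    abort("`n_pre_norm` cannot exceed `n_pre`")
  }
  structure(
    list(frame_rate = frame_rate, n_pre = as.integer(n_pre),
         post_duration = post_duration, bleach_duration = bleach_duration,
         n_pre_norm = as.integer(n_pre_norm)),
    class = "frap_acquisition"
  )
}

#' @export
print.frap_acquisition <- function(x, ...) {
  cat(sprintf(
    "<frap_acquisition> %d pre frames, %.0f ms bleach, %g s post at %g fps (last %d pre frames for normalization)\n",
    x$n_pre, 1000 * x$bleach_duration, x$post_duration, x$frame_rate, x$n_pre_norm))
  invisible(x)
}

# Acquisition time grid. Pre frames start at t = 0; the bleach pulse sits
# between the last pre frame and the first post frame; post frames span
# [0, post_duration] on the model clock (frap_recovery() time).
acquisition_times <- function(acq) {
  dt <- 1 / acq$frame_rate
  t_pre <- (seq_len(acq$n_pre) - 1) * dt
  n_post <- floor(acq$post_duration * acq$frame_rate) + 1L
  t_model <- (seq_len(n_post) - 1) * dt
  t_post <- t_pre[acq$n_pre] + acq$bleach_duration + dt + t_model
  list(pre = t_pre, post = t_post, model = t_model, n_post = n_post)
}

#' Additive acquisition noise model for simulated traces
#'
#' @param sigma_add Standard deviation of additive Gaussian noise on the
#'   normalized intensity scale. Default 0.02.
#' @param drift_rate Per-frame multiplicative acquisition-bleaching factor;
#'   frame k (0-based) is scaled by `(1 - drift_rate)^k`. Default 0 (off).
#'
#' @return A list of class `frap_noise`.
#' @export
frap_noise <- function(sigma_add = 0.02, drift_rate = 0) {
  if (!is.finite(sigma_add) || sigma_add < 0) {
    abort("`sigma_add` must be >= 0")
  }
  if (!is.finite(drift_rate) || drift_rate < 0 || drift_rate >= 0.01) {
    abort("`drift_rate` must lie in [0, 0.01)")
  }
  structure(list(sigma_add = sigma_add, drift_rate = drift_rate),
            class = "frap_noise")
}
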