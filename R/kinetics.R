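#' Ground-truth kinetic parameters for a simulated FRAP cell
#'
#' The diffusion-uncoupled two-component interpretation of a FRAP curve splits
#' the tagged protein pool into a fast, freely diffusing component (amplitude
#' `a1`), a slow, transiently DNA-bound component (amplitude `a2`), and an
#' immobile remainder that does not exchange within the observation window.
#' A truth record parameterizes that decomposition by the immobile fraction,
#' the a1/a2 ratio, the two recovery half-times, and the bleach floor `f0`
#' (normalized intensity immediately after the bleach pulse).
#'
#' `ratio = Inf` is the single-component limit (`a2 = 0`), useful for free
#' fluorophore controls that recover fully through diffusion alone.
#'
#' @param if_frac Immobile fraction, in `[0, 1]`.
#' @param ratio Amplitude ratio a1/a2, `> 0` (may be `Inf`).
#' @param t_half_fast Fast-component recovery half-time, seconds.
#' @param t_half_slow Slow-component recovery half-time, seconds; must exceed
#'   `t_half_fast`.
#' @param f0 Bleach floor on the normalized scale, in `[0, 1)`.
#'
#' @return One-row tibble with the validated parameters.
#' @export
#' @examples
#' kinetic_truth(if_frac = 0.5, ratio = 1, t_half_fast = 1.5, t_half_slow = 15)
kinetic_truth <- function(if_frac, ratio, t_half_fast, t_half_slow, f0 = 0.3) {
  if (!is.finite(if_frac) || if_frac < 0 || if_frac > 1) {
    abort("`if_frac` must lie in [0, 1]")
  }
  if (is.na(ratio) || ratio <= 0) {
    abort("`ratio` must be > 0 (Inf allowed for a single component)")
  }
  if (!is.finite(t_half_fast) || !is.finite(t_half_slow) ||
      t_half_fast <= 0 || t_half_slow <= t_half_fast) {
    abort("half-times must satisfy 0 < t_half_fast < t_half_slow")
  }
  if (!is.finite(f0) || f0 < 0 || f0 >= 1) {
    abort("`f0` must lie in [0, 1)")
  }
  tibble(if_frac = if_frac, ratio = ratio, t_half_fast = t_half_fast,
         t_half_slow = t_half_slow, f0 = f0)
}

#' Component amplitudes implied by a truth record
#'
#' The mobile recovery span is `M = (1 - if_frac) * (1 - f0)`; it is divided
#' between the fast and slow components in proportion `ratio`:
#' `a1 = M * ratio / (1 + ratio)`, `a2 = M / (1 + ratio)`, so `a1/a2 = ratio`
#' and `a1 + a2 = M`.
#'
#' @param truth Tibble of truth records (`if_frac`, `ratio`, `f0` columns), as
#'   from [kinetic_truth()]. Vectorized over rows.
#'
#' @return Tibble with columns `a1`, `a2`.
#' @export
#' @examples
#' truth_amplitudes(kinetic_truth(0.5, 1, 1.5, 15, f0 = 0))
truth_amplitudes <- function(truth) {
  m <- (1 - truth$if_frac) * (1 - truth$f0)
  w <- ifelse(is.infinite(truth$ratio), 1, truth$ratio / (1 + truth$ratio))
  tibble(a1 = m * w, a2 = m * (1 - w))
}

#' Two-component FRAP recovery model
#'
#' Normalized fluorescence after the bleach pulse:
#' `F(t) = f0 + a1 * (1 - 2^(-t / t_half_fast)) + a2 * (1 - 2^(-t / t_half_slow))`.
#' Half-times parameterize the exponentials directly (base 2), matching how
#' recovery half-times are reported; the equivalent exponential time constant
#' is `tau = t_half / ln 2`. `t = 0` is the first post-bleach frame, where
#' `F = f0`; the curve rises monotonically to the plateau `f0 + a1 + a2`, and
#' `1 - (f0 + a1 + a2)` is the bleach-depth-uncorrected immobile remainder.
#'
#' @param times Numeric vector of post-bleach times in seconds, `>= 0`.
#' @param f0 Bleach floor.
#' @param a1,a2 Fast and slow amplitudes (`a2 = 0` gives one component).
#' @param t_half_fast,t_half_slow Recovery half-times in seconds.
#'
#' @return Numeric vector of normalized intensities.
#' @export
#' @examples
#' frap_recovery(c(0, 1.5, 60), f0 = 0.3, a1 = 0.2, a2 = 0.2,
#'               t_half_fast = 1.5, t_half_slow = 15)
frap_recovery <- function(times, f0, a1, a2, t_half_fast, t_half_slow) {
  if (any(!is.finite(times)) || any(times < 0)) {
    abort("`times` must be finite and >= 0")
  }
  f0 + a1 * (1 - 2^(-times / t_half_fast)) + a2 * (1 - 2^(-times / t_half_slow))
}

#' Evaluate the recovery model for a truth record
#'
#' @param truth One-row tibble from [kinetic_truth()].
#' @param times Post-bleach times in seconds.
#' @return Numeric vector of normalized intensities.
#' @export
recovery_curve <- function(truth, times) {
  stopifnot(nrow(truth) == 1)
  amp <- truth_amplitudes(truth)
  frap_recovery(times, truth$f0, amp$a1, amp$a2,
                truth$t_half_fast, truth$t_half_slow)
}
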