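# Waveform conditioning: spiral-angle detrending, Savitzky-Golay denoising,
# band-pass splitting into respiratory and cardiac ranges.

#' Remove spiral-angle-dependent trends from raw waveforms
#'
#' Golden-angle acquisition makes trajectory-dependent amplitude deviations
#' (eddy-current-like) a smooth periodic function of the arm angle, while
#' physiological motion is broadband after reordering by angle. The
#' angle-dependent component is estimated per coil by least-squares harmonic
#' regression on `cos(k*theta), sin(k*theta)` up to the configured order
#' (an angular low-pass that is exact for any trend of harmonic order below
#' the cutoff, regardless of angle ordering or ties) and subtracted together
#' with the waveform mean.
#'
#' @param wf A raw `haptic_wf`.
#' @param arm_angle Arm angle per line, radians.
#' @param order Maximum harmonic order retained in the trend estimate;
#'   `0` (or `NULL`) disables the filter and returns the input unchanged.
#' @return A `haptic_wf`, stage `"detrended"`.
#' @export
detrend_by_angle <- function(wf, arm_angle, order = 8L) {
  stopifnot(inherits(wf, "haptic_wf"))
  if (is.null(order) || order <= 0)
    return(pt_waveforms(wf$t, wf$value, "detrended", wf$TR))
  L <- nrow(wf$value)
  if (length(arm_angle) != L) stopf("arm_angle length must equal n_lines")
  order <- as.integer(order)
  n_distinct <- length(unique(round(arm_angle, 10)))
  if (2 * order + 1 > n_distinct) {
    order <- max((n_distinct - 1) %/% 2, 0L)
    warnf("fewer distinct angles than harmonic terms; order reduced to %d",
          order)
    if (order == 0) return(pt_waveforms(wf$t, wf$value, "detrended", wf$TR))
  }
  X <- matrix(1, L, 2 * order + 1)
  for (h in seq_len(order)) {
    X[, 2 * h] <- cos(h * arm_angle)
    X[, 2 * h + 1] <- sin(h * arm_angle)
  }
  fit <- stats::lm.fit(X, wf$value)
  resid <- wf$value - X %*% fit$coefficients
  pt_waveforms(wf$t, resid, "detrended", wf$TR)
}

#' Savitzky-Golay denoising
#'
#' Standard least-squares polynomial smoothing per coil; the `signal`
#' package's filter matrix fits the polynomial on truncated windows at the
#' record edges.
#'
#' @param wf A `haptic_wf`.
#' @param window Odd window length in samples, `> polyorder`.
#' @param polyorder Polynomial order.
#' @return A `haptic_wf`, stage `"denoised"`.
#' @export
sgolay_denoise <- function(wf, window = 21L, polyorder = 3L) {
  stopifnot(inherits(wf, "haptic_wf"))
  if (window %% 2 != 1 || window <= polyorder)
    stopf("Savitzky-Golay window must be odd and > polyorder")
  if (window >= nrow(wf$value))
    stopf("Savitzky-Golay window (%d) must be shorter than the record (%d)",
          window, nrow(wf$value))
  out <- apply(wf$value, 2, function(x)
    signal::sgolayfilt(x, p = polyorder, n = window))
  pt_waveforms(wf$t, out, "denoised", wf$TR)
}

#' Analytic variance gain of a Savitzky-Golay filter on white noise
#'
#' Sum of squared central-row filter coefficients: the factor by which the
#' interior-sample variance of white noise is reduced.
#'
#' @param window,polyorder Filter parameters as in [sgolay_denoise()].
#' @return Scalar gain in (0, 1].
#' @export
sgolay_noise_gain <- function(window, polyorder) {
  coefs <- signal::sgolay(p = polyorder, n = window)
  sum(coefs[(window + 1) / 2, ]^2)
}

#' Whole-record zero-phase band-pass
#'
#' Applied in the frequency domain over the entire record (non-causal by
#' design): the waveform spectrum is masked with a raised-cosine band whose
#' half-cosine transitions span `transition_frac` of each edge frequency.
#' The mean is removed. Respiratory and cardiac defaults are 0.05-0.9 Hz and
#' 1-20 Hz.
#'
#' @param wf A `haptic_wf`.
#' @param band Length-2 numeric, `c(f_lo, f_hi)` in Hz.
#' @param transition_frac Transition half-width as a fraction of each edge.
#' @param stage Stage label for the output (`"resp_band"` / `"card_band"`).
#' @return A `haptic_wf` in the requested band.
#' @export
bandpass <- function(wf, band, transition_frac = 0.2, stage = "resp_band") {
  stopifnot(inherits(wf, "haptic_wf"), length(band) == 2, band[1] < band[2])
  n <- nrow(wf$value)
  fs <- 1 / wf$TR
  if (n * wf$TR < 0.99 / band[1])
    stopf("record (%.3g s) shorter than one period of the low band edge",
          n * wf$TR)
  f_hi <- band[2]
  if (f_hi > fs / 2) {
    warnf("band upper edge %.3g Hz above Nyquist %.3g Hz; clipped", f_hi,
          fs / 2)
    f_hi <- fs / 2
  }
  f <- (seq_len(n) - 1) / n * fs
  f <- pmin(f, fs - f)   # two-sided (aliased) frequency axis
  mask <- band_mask(f, band[1], f_hi, transition_frac)
  out <- apply(wf$value, 2, function(x) {
    X <- stats::fft(x - mean(x))
    Re(stats::fft(X * mask, inverse = TRUE)) / n
  })
  pt_waveforms(wf$t, out, stage, wf$TR)
}

# Raised-cosine band mask at frequencies f.
band_mask <- function(f, f_lo, f_hi, w) {
  lo1 <- f_lo * (1 - w); lo2 <- f_lo * (1 + w)
  hi1 <- f_hi * (1 - w); hi2 <- f_hi * (1 + w)
  m <- numeric(length(f))
  m[f >= lo2 & f <= hi1] <- 1
  ramp_up <- f > lo1 & f < lo2
  m[ramp_up] <- 0.5 - 0.5 * cos(pi * (f[ramp_up] - lo1) / (lo2 - lo1))
  ramp_dn <- f > hi1 & f < hi2
  m[ramp_dn] <- 0.5 + 0.5 * cos(pi * (f[ramp_dn] - hi1) / (hi2 - hi1))
  m
}
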