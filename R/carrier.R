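# Per-line pilot-tone carrier estimation: first frequency, then amplitude.

#' Estimate the pilot-tone carrier per k-space line
#'
#' For every readout, the coil-combined (sum of per-coil magnitudes)
#' zero-padded spectrum of the Hann-windowed samples is peak-searched inside
#' the configured band around the nominal offset; the peak frequency is
#' refined first by quadratic interpolation of the log-magnitude and then by
#' one further three-point parabolic pass on single-frequency projections.
#' Per-coil amplitudes are then the magnitudes of the projection of that
#' line's raw samples onto the unit complex exponential at the shared refined
#' frequency, normalized by the sample count, so a pure tone of amplitude `A`
#' yields exactly `A`. The carrier phase is discarded throughout.
#'
#' Lines whose combined spectral peak does not rise above `snr_floor` times
#' the in-band median are flagged carrier-lost; their amplitudes are
#' interpolated from neighboring lines downstream.
#'
#' @param acq A `haptic_acq`.
#' @param search_halfwidth Half-width of the search band around the nominal
#'   offset, Hz.
#' @param pad_factor Zero-padding factor for the per-line spectrum.
#' @param snr_floor Peak-to-median ratio below which a line is flagged lost.
#' @return A `haptic_carrier` list: `freq` (Hz per line), `amp`
#'   (`n_lines x n_coils`, non-negative), `lost` (logical per line).
#' @export
estimate_carrier <- function(acq, search_halfwidth = 3e4, pad_factor = 4L,
                             snr_floor = 3) {
  L <- n_lines(acq); C <- n_coils(acq); S <- n_samples(acq)
  if (S < 32) stopf("carrier estimation requires >= 32 samples per readout")
  fs <- 1 / acq$dwell_time
  nfft <- as.integer(pad_factor) * S
  freqs <- (seq_len(nfft) - 1) / nfft * fs
  # fold the nominal offset into [0, fs): negative offsets appear aliased
  f0 <- acq$f_off_nominal %% fs
  band <- which(freqs >= f0 - search_halfwidth & freqs <= f0 + search_halfwidth)
  if (length(band) < 3)
    stopf("search band around %.3g Hz contains fewer than 3 spectral bins", f0)

  win <- 0.5 - 0.5 * cos(2 * pi * (seq_len(S) - 1) / (S - 1))  # Hann
  combined <- matrix(0, nfft, L)
  for (c in seq_len(C)) {
    xw <- t(acq$samples[, c, ]) * win             # S x L
    combined <- combined + Mod(stats::mvfft(rbind(xw,
      matrix(0i, nfft - S, L))))
  }
  spec <- combined[band, , drop = FALSE]
  peak_rel <- max.col(t(spec), ties.method = "first")
  peak_val <- spec[cbind(peak_rel, seq_len(L))]
  med_val <- apply(spec, 2, stats::median)
  lost <- !(peak_val > snr_floor * med_val) | peak_val <= 0

  # stage 1: quadratic interpolation of log-magnitude around the peak bin
  df <- fs / nfft
  pk <- band[peak_rel]
  delta <- numeric(L)
  ok <- pk > 1 & pk < nfft
  lm <- function(i) log(pmax(combined[cbind(i, seq_len(L))], 1e-300))
  yl <- lm(pmax(pk - 1, 1)); yc <- lm(pk); yr <- lm(pmin(pk + 1, nfft))
  den <- yl - 2 * yc + yr
  delta[ok] <- ifelse(abs(den[ok]) > 1e-300,
                      0.5 * (yl[ok] - yr[ok]) / den[ok], 0)
  delta <- pmax(pmin(delta, 0.5), -0.5)
  f_hat <- freqs[pk] + delta * df

  # stage 2: one parabolic pass on windowed projection magnitudes at
  # f_hat +/- h, which reduces the residual interpolation bias quadratically
  tau <- (seq_len(S) - 1) * acq$dwell_time
  proj_mag <- function(f) {
    # combined |projection| per line at per-line frequencies f
    E <- exp(-2i * pi * outer(tau, f))            # S x L
    m <- numeric(L)
    for (c in seq_len(C))
      m <- m + Mod(colSums(t(acq$samples[, c, ]) * win * E))
    m
  }
  h <- 0.1 * df
  y0 <- proj_mag(f_hat); ylo <- proj_mag(f_hat - h); yhi <- proj_mag(f_hat + h)
  den2 <- ylo - 2 * y0 + yhi
  d2 <- ifelse(abs(den2) > 1e-300, 0.5 * (ylo - yhi) / den2, 0)
  f_hat <- f_hat + pmax(pmin(d2, 1), -1) * h

  # amplitude: magnitude of the unwindowed single-frequency correlation,
  # normalized by n_samples
  E <- exp(-2i * pi * outer(tau, f_hat))          # S x L
  amp <- matrix(0, L, C)
  for (c in seq_len(C))
    amp[, c] <- Mod(colSums(t(acq$samples[, c, ]) * E)) / S
  structure(list(freq = f_hat, amp = amp, lost = lost),
            class = "haptic_carrier")
}

#' Raw pilot-tone waveforms from a carrier estimate
#'
#' One amplitude sample per TR per coil; carrier-lost lines are linearly
#' interpolated so the uniform-TR sampling assumed by all subsequent filters
#' holds.
#'
#' @param carrier A `haptic_carrier` from [estimate_carrier()].
#' @param acq The acquisition the estimate came from (for timing).
#' @return A `haptic_wf` waveform object, stage `"raw"`.
#' @export
carrier_waveforms <- function(carrier, acq) {
  amp <- carrier$amp
  if (any(carrier$lost)) {
    good <- which(!carrier$lost)
    if (length(good) < 2)
      stopf("carrier lost on %d/%d lines; cannot form a waveform",
            sum(carrier$lost), length(carrier$lost))
    for (c in seq_len(ncol(amp)))
      amp[, c] <- stats::approx(acq$line_time[good], amp[good, c],
                                xout = acq$line_time, rule = 2)$y
  }
  pt_waveforms(acq$line_time, amp, "raw", acq$TR)
}

pt_waveforms <- function(t, value, stage, TR) {
  value <- as.matrix(value)
  if (length(t) != nrow(value)) stopf("waveform t/value length mismatch")
  if (length(t) > 1 && any(diff(t) <= 0))
    stopf("waveform times must be strictly increasing")
  if (any(!is.finite(value))) stopf("waveform values must be finite")
  structure(list(t = as.numeric(t), value = value, stage = stage, TR = TR),
            class = "haptic_wf")
}

#' @export
print.haptic_wf <- function(x, ...) {
  cat(sprintf("<haptic_wf stage=%s> %d samples x %d coils, fs = %.5g Hz\n",
              x$stage, nrow(x$value), ncol(x$value), 1 / x$TR))
  invisible(x)
}
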