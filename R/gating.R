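# Cardiac trigger detection, ECG matching, gating metrics, retrospective
# binning.

# Topographic prominence of peak i in x: height above the higher of the two
# bases, where each base is the minimum between the peak and the nearest
# sample exceeding the peak on that side (record edge if none).
peak_prominence <- function(x, peaks) {
  n <- length(x)
  vapply(peaks, function(i) {
    h <- x[i]
    lo <- i - 1
    while (lo >= 1 && x[lo] <= h) lo <- lo - 1
    left_base <- min(x[max(lo + 1, 1):i])
    hi <- i + 1
    while (hi <= n && x[hi] <= h) hi <- hi + 1
    right_base <- min(x[i:min(hi - 1, n)])
    h - max(left_base, right_base)
  }, 0)
}

#' Detect cardiac triggers from the cardiac navigator
#'
#' The first derivative of the cardiac waveform (central differences) is
#' normalized so its 10th percentile maps to 0 and its 98th percentile to 1.
#' Candidate triggers are strict local maxima of this normalized derivative;
#' a minimum separation of `window_s` (0.375 s, a 160 bpm ceiling) is
#' enforced by keeping the larger of two conflicting peaks, and surviving
#' peaks must have topographic prominence greater than `prominence` (0.5).
#' The detection is invariant to positive affine transforms of the input by
#' construction of the normalization.
#'
#' @param card_nav Cardiac navigator samples.
#' @param fs Sampling rate in Hz (`> 40`).
#' @param t0 Time of the first sample, seconds.
#' @param window_s Minimum peak separation, seconds.
#' @param prominence Minimum topographic prominence after normalization.
#' @param p_lo,p_hi Normalization percentiles.
#' @return A `haptic_triggers` with source `"PT"`.
#' @export
detect_triggers <- function(card_nav, fs, t0 = 0, window_s = 0.375,
                            prominence = 0.5, p_lo = 10, p_hi = 98) {
  if (fs <= 40) stopf("sampling rate must exceed 40 Hz for cardiac triggering")
  n <- length(card_nav)
  if (n / fs < 2) stopf("record must be at least 2 s long")
  d <- c(card_nav[2] - card_nav[1],
         (card_nav[3:n] - card_nav[1:(n - 2)]) / 2,
         card_nav[n] - card_nav[n - 1])
  q <- stats::quantile(d, c(p_lo, p_hi) / 100, names = FALSE, type = 7)
  if (q[2] == q[1]) {
    warnf("flat waveform (p%g == p%g); no triggers detected", p_lo, p_hi)
    return(trigger_series(numeric(0), "PT"))
  }
  dn <- (d - q[1]) / (q[2] - q[1])

  cand <- which(dn[2:(n - 1)] > dn[1:(n - 2)] &
                  dn[2:(n - 1)] > dn[3:n]) + 1L
  if (!length(cand)) return(trigger_series(numeric(0), "PT"))
  # minimum separation: process by descending height, keep if no kept
  # neighbor within the window
  min_sep <- window_s * fs
  ord <- cand[order(dn[cand], decreasing = TRUE)]
  kept <- integer(0)
  for (i in ord)
    if (!length(kept) || min(abs(kept - i)) >= min_sep) kept <- c(kept, i)
  kept <- sort(kept)
  prom <- peak_prominence(dn, kept)
  kept <- kept[prom > prominence]
  trigger_series(t0 + (kept - 1) / fs, "PT")
}

#' Match pilot-tone triggers against reference R-waves
#'
#' For each consecutive pair of reference R-waves, PT events in the half-open
#' interval `[R_k, R_{k+1})` are counted: the first is matched with the
#' preceding R-wave `R_k`, additional events are false positives, and an
#' empty interval is a false negative at `R_k`. PT events before the first
#' and at/after the last R-wave lie outside every search window and are
#' ignored.
#'
#' @param pt A `haptic_triggers` of detected events.
#' @param ref A `haptic_triggers` of reference R-waves (`>= 2` events).
#' @return A `haptic_match` list: `pairs` (data frame `ref_time`, `pt_time`),
#'   `false_positive_times`, `false_negative_ref_times`, `n_windows`.
#' @export
match_triggers <- function(pt, ref) {
  stopifnot(inherits(pt, "haptic_triggers"), inherits(ref, "haptic_triggers"))
  rt <- ref$event_time
  if (length(rt) < 2) stopf("reference series must have >= 2 events")
  pt_t <- pt$event_time
  pairs_ref <- numeric(0); pairs_pt <- numeric(0)
  fp <- numeric(0); fn <- numeric(0)
  for (k in seq_len(length(rt) - 1)) {
    inside <- pt_t[pt_t >= rt[k] & pt_t < rt[k + 1]]
    if (length(inside) == 0) {
      fn <- c(fn, rt[k])
    } else {
      pairs_ref <- c(pairs_ref, rt[k]); pairs_pt <- c(pairs_pt, inside[1])
      if (length(inside) > 1) fp <- c(fp, inside[-1])
    }
  }
  structure(list(
    pairs = data.frame(ref_time = pairs_ref, pt_time = pairs_pt),
    false_positive_times = fp, false_negative_ref_times = fn,
    n_windows = length(rt) - 1L), class = "haptic_match")
}

#' Gating performance metrics
#'
#' Delay per matched pair is `pt - ref` in milliseconds; the mean delay and
#' the jitter (sample standard deviation, n-1 denominator) summarize it.
#' `n_triggers` counts the reference R-waves heading a search window, and the
#' failure rate is `100 * (n_fp + n_fn) / n_triggers`.
#'
#' @param match A `haptic_match` from [match_triggers()].
#' @return A `haptic_report` list: `mean_delay_ms`, `jitter_ms` (`NA` with
#'   fewer than 2 pairs), `n_triggers`, `n_fp`, `n_fn`, `failure_rate_pct`.
#' @export
gating_metrics <- function(match) {
  stopifnot(inherits(match, "haptic_match"))
  delays <- (match$pairs$pt_time - match$pairs$ref_time) * 1e3
  n_fp <- length(match$false_positive_times)
  n_fn <- length(match$false_negative_ref_times)
  n_triggers <- match$n_windows
  structure(list(
    mean_delay_ms = if (length(delays)) mean(delays) else NA_real_,
    jitter_ms = sample_sd(delays),
    n_triggers = n_triggers, n_fp = n_fp, n_fn = n_fn,
    failure_rate_pct = 100 * (n_fp + n_fn) / n_triggers),
    class = "haptic_report")
}

#' @export
print.haptic_report <- function(x, ...) {
  cat(sprintf(
    "<haptic_report> %d triggers: mean delay %.1f ms, jitter %.1f ms, FP %d, FN %d, failure rate %.2f%%\n",
    x$n_triggers, x$mean_delay_ms, x$jitter_ms, x$n_fp, x$n_fn,
    x$failure_rate_pct))
  invisible(x)
}

#' Assign retrospective cardiac and respiratory bins
#'
#' Cardiac bin for a line at time `t` inside trigger interval
#' `[T_k, T_{k+1})` is `floor(n_card * (t - T_k) / (T_{k+1} - T_k))`, clipped
#' to `n_card - 1`; lines before the first or at/after the last trigger are
#' unassigned (`NA`). Respiratory bins are equal-count amplitude quantiles of
#' the respiratory navigator (the XD-GRASP convention).
#'
#' @param resp_nav Respiratory navigator sampled at `line_time`.
#' @param triggers A `haptic_triggers` of cardiac triggers.
#' @param line_time Line times, seconds.
#' @param n_resp,n_card Bin counts (12 respiratory, 20 cardiac by default).
#' @return A `haptic_bins` list: `card_bin`, `resp_bin` (0-based integer
#'   vectors, `NA` when unassigned), `n_card`, `n_resp`.
#' @export
assign_bins <- function(resp_nav, triggers, line_time, n_resp = 12L,
                        n_card = 20L) {
  stopifnot(length(resp_nav) == length(line_time))
  L <- length(line_time)
  card_bin <- rep(NA_integer_, L)
  tt <- triggers$event_time
  if (length(tt) >= 2) {
    k <- findInterval(line_time, tt)
    inside <- k >= 1 & k < length(tt)
    phase <- (line_time[inside] - tt[k[inside]]) /
      (tt[k[inside] + 1] - tt[k[inside]])
    card_bin[inside] <- pmin(as.integer(floor(n_card * phase)),
                             n_card - 1L)
  }
  # equal-count amplitude quantiles over assigned lines
  qs <- stats::quantile(resp_nav, probs = seq(0, 1, length.out = n_resp + 1),
                        names = FALSE, type = 7)
  qs[1] <- -Inf; qs[n_resp + 1] <- Inf
  resp_bin <- as.integer(cut(resp_nav, breaks = qs, labels = FALSE,
                             include.lowest = TRUE)) - 1L
  structure(list(card_bin = card_bin, resp_bin = resp_bin,
                 n_card = n_card, n_resp = n_resp), class = "haptic_bins")
}
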