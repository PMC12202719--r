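# Pilot-tone interference cancellation: windowed sniffer-based least squares
# (EDITER) and the sinusoid-model subtraction baseline.

# Build the FIR design matrix for one window: rows = (line, sample) pairs,
# columns = sniffer channels x in-readout taps (-K..K) x line taps
# (-delta..delta), zero-padded at readout and window edges.
editer_design <- function(sniff, K, delta_lines) {
  w <- dim(sniff)[1]; ns <- dim(sniff)[2]; S <- dim(sniff)[3]
  taps_s <- -K:K
  taps_l <- -delta_lines:delta_lines
  P <- ns * length(taps_s) * length(taps_l)
  X <- matrix(0i, w * S, P)
  col <- 0L
  for (s in seq_len(ns)) for (dl in taps_l) for (ds in taps_s) {
    col <- col + 1L
    shifted <- matrix(0i, w, S)
    src_l <- seq_len(w) - dl
    ok_l <- src_l >= 1 & src_l <= w
    src_s <- seq_len(S) - ds
    ok_s <- src_s >= 1 & src_s <= S
    shifted[ok_l, ok_s] <- sniff[src_l[ok_l], s, src_s[ok_s]]
    X[, col] <- as.vector(t(shifted))  # readout-major to match y flattening
  }
  X
}

# Solve Hermitian normal equations through the eigendecomposition with a
# relative spectral cutoff: degenerate tap directions (a pure tone cannot
# identify all FIR taps) get the minimum-norm solution instead of a
# numerically explosive one, while identifiable directions are untouched.
solve_hermitian <- function(H, rhs, rel_tol = 1e-10) {
  eg <- eigen(H, symmetric = TRUE)
  lam <- Re(eg$values)
  keep <- lam > rel_tol * max(lam, 0)
  if (!any(keep)) return(structure(rhs * 0, fallback = TRUE))
  V <- eg$vectors[, keep, drop = FALSE]
  out <- V %*% ((Conj(t(V)) %*% rhs) / lam[keep])
  if (!all(keep)) attr(out, "fallback") <- TRUE
  out
}

#' Fit an EDITER interference model
#'
#' Partitions the line range into windows of `window_lines` lines; within each
#' window and for each imaging coil, solves the linear least-squares problem
#' expressing that coil's samples as a sum over sniffer coils of FIR-filtered
#' sniffer samples (taps spanning `-K..K` samples in-readout and optionally
#' `-delta_lines..delta_lines` adjacent lines). Windows whose concatenated
#' kernels have pairwise normalized correlation above
#' `group_corr_threshold` are merged into clusters, and one kernel per
#' cluster is refit on the pooled equations. The kernel similarity
#' `2 * Re(<ka, kb>) / (|ka|^2 + |kb|^2)` is deliberately sensitive to gain
#' and phase changes of the interference path, so a window whose coupling
#' truly changed is never pooled with its neighbors. The method assumes the
#' interference path is static within a window.
#'
#' @param acq A `haptic_acq` with at least one sniffer coil.
#' @param window_lines Lines per fitting window.
#' @param K In-readout FIR half-width (taps `2K+1` per sniffer).
#' @param delta_lines Cross-line FIR half-width (0 = within-line only).
#' @param group_corr_threshold Kernel-similarity threshold for window merging.
#' @param ridge Retained tuning slot for the rank-deficiency fallback
#'   (relative spectral cutoff is `1e-12`; see Details).
#' @return A `haptic_editer` model: `windows` (list of line-index vectors),
#'   `kernels` (per window: matrix taps x imaging coils), `group_id`,
#'   `residual_db` per window per coil.
#' @export
editer_fit <- function(acq, window_lines = 50L, K = 7L, delta_lines = 0L,
                       group_corr_threshold = 0.9) {
  si <- sniffer_idx(acq); ii <- imaging_idx(acq)
  if (length(si) < 1) stopf("EDITER requires at least one sniffer coil")
  L <- n_lines(acq); S <- n_samples(acq)
  P <- length(si) * (2 * K + 1) * (2 * delta_lines + 1)
  if (window_lines * S < P)
    stopf("window of %d lines x %d samples cannot identify %d kernel taps",
          window_lines, S, P)
  starts <- seq(1L, L, by = window_lines)
  windows <- lapply(starts, function(s) s:min(s + window_lines - 1L, L))
  nw <- length(windows)

  kernels <- vector("list", nw)
  residual_db <- matrix(0, nw, length(ii))
  Hs <- vector("list", nw)          # per-window normal equations, kept so
  rhss <- vector("list", nw)        # cluster refits pool equations cheaply
  n_fallback <- 0L
  for (w in seq_len(nw)) {
    lines <- windows[[w]]
    sniff <- acq$samples[lines, si, , drop = FALSE]
    X <- editer_design(sniff, K, delta_lines)
    H <- crossprod(Conj(X), X)
    Hs[[w]] <- H
    rhss[[w]] <- matrix(0i, P, length(ii))
    kern <- matrix(0i, P, length(ii))
    for (j in seq_along(ii)) {
      y <- as.vector(t(acq$samples[lines, ii[j], ]))
      rhs <- crossprod(Conj(X), y)
      rhss[[w]][, j] <- rhs
      beta <- solve_hermitian(H, rhs)
      if (isTRUE(attr(beta, "fallback"))) n_fallback <- n_fallback + 1L
      kern[, j] <- as.vector(beta)
      res <- y - X %*% beta
      residual_db[w, j] <- 10 * log10(sum(Mod(res)^2) /
                                        max(sum(Mod(y)^2), 1e-300))
    }
    kernels[[w]] <- kern
  }
  if (n_fallback > 0)
    warnf("%d of %d window fits were rank-deficient; minimum-norm solutions used",
          n_fallback, nw * length(ii))

  # group windows by kernel similarity (transitive closure of pairwise links)
  group_id <- seq_len(nw)
  if (nw > 1) {
    kv <- vapply(kernels, function(k) as.vector(k), complex(P * length(ii)))
    kv <- matrix(kv, ncol = nw)
    for (a in seq_len(nw - 1)) for (b in (a + 1):nw) {
      ea <- sum(Mod(kv[, a])^2); eb <- sum(Mod(kv[, b])^2)
      if (ea == 0 && eb == 0) next
      sim <- 2 * Re(sum(Conj(kv[, a]) * kv[, b])) / (ea + eb)
      if (sim > group_corr_threshold) {
        ga <- group_id[a]; gb <- group_id[b]
        group_id[group_id == gb] <- ga
      }
    }
    group_id <- match(group_id, unique(group_id))
    # refit one kernel per cluster by pooling the windows' normal equations
    for (g in unique(group_id)) {
      members <- which(group_id == g)
      if (length(members) < 2) next
      H <- Reduce(`+`, Hs[members])
      rhs <- Reduce(`+`, rhss[members])
      for (j in seq_along(ii)) {
        beta <- solve_hermitian(H, rhs[, j])
        for (w in members) kernels[[w]][, j] <- as.vector(beta)
      }
    }
  }
  structure(list(windows = windows, kernels = kernels, group_id = group_id,
                 residual_db = residual_db, K = K, delta_lines = delta_lines,
                 sniffer_idx = si, imaging_idx = ii),
            class = "haptic_editer")
}

#' @export
print.haptic_editer <- function(x, ...) {
  cat(sprintf(
    "<haptic_editer> %d windows -> %d kernel clusters; taps 2*%d+1 x %d sniffers\n",
    length(x$windows), length(unique(x$group_id)), x$K, length(x$sniffer_idx)))
  cat(sprintf("  median fitted residual: %.1f dB\n",
              stats::median(x$residual_db)))
  invisible(x)
}

#' Apply an EDITER model
#'
#' Subtracts the predicted interference (sniffer data filtered with each
#' window's cluster kernel) from every imaging coil; sniffer channels pass
#' through unchanged. The operation is linear in the data.
#'
#' @param model A `haptic_editer` from [editer_fit()].
#' @param acq The acquisition to clean (same geometry as the fit).
#' @return A `haptic_acq` with cleaned imaging coils.
#' @export
editer_apply <- function(model, acq) {
  L <- n_lines(acq); S <- n_samples(acq)
  covered <- sort(unlist(model$windows))
  if (!identical(covered, seq_len(L)))
    stopf("model windows do not cover all %d lines of the acquisition", L)
  out <- acq$samples
  si <- model$sniffer_idx; ii <- model$imaging_idx
  for (w in seq_along(model$windows)) {
    lines <- model$windows[[w]]
    sniff <- acq$samples[lines, si, , drop = FALSE]
    X <- editer_design(sniff, model$K, model$delta_lines)
    pred <- X %*% model$kernels[[w]]              # (w*S) x n_imaging
    for (j in seq_along(ii))
      out[lines, ii[j], ] <- out[lines, ii[j], ] -
        matrix(pred[, j], length(lines), S, byrow = TRUE)
  }
  acquisition_set(out, acq$line_time, acq$arm_angle, acq$dwell_time, acq$TR,
                  acq$f_off_nominal, acq$coil_role, acq$trajectory)
}

#' Sinusoid-model interference subtraction (baseline)
#'
#' Assumes a static sinusoidal carrier: one global frequency is estimated
#' from the average per-line spectrum (refined by quadratic interpolation and
#' a parabolic projection pass), then per line and per imaging coil the
#' complex amplitude is obtained by least-squares projection onto the unit
#' complex exponential at that frequency, and the fitted sinusoid is
#' subtracted from the readout. Carrier-lost lines are left unmodified and
#' counted.
#'
#' @param acq A `haptic_acq`.
#' @param search_halfwidth,pad_factor,snr_floor Carrier search parameters as
#'   in [estimate_carrier()].
#' @return A `haptic_acq` with the fitted sinusoid removed from imaging
#'   coils; attributes `"f_carrier"` and `"n_skipped"`.
#' @export
model_subtract <- function(acq, search_halfwidth = 3e4, pad_factor = 4L,
                           snr_floor = 3) {
  L <- n_lines(acq); S <- n_samples(acq)
  fs <- 1 / acq$dwell_time
  nfft <- as.integer(pad_factor) * S
  freqs <- (seq_len(nfft) - 1) / nfft * fs
  f0 <- acq$f_off_nominal %% fs
  band <- which(freqs >= f0 - search_halfwidth & freqs <= f0 + search_halfwidth)
  win <- 0.5 - 0.5 * cos(2 * pi * (seq_len(S) - 1) / (S - 1))
  ii <- imaging_idx(acq)

  # average coil-combined spectrum over all lines
  combined <- numeric(nfft)
  for (c in seq_len(n_coils(acq))) {
    xw <- t(acq$samples[, c, ]) * win
    combined <- combined + rowSums(Mod(stats::mvfft(
      rbind(xw, matrix(0i, nfft - S, L)))))
  }
  spec <- combined[band]
  pk <- band[which.max(spec)]
  if (max(spec) <= snr_floor * stats::median(spec) && L > 1)
    warnf("global carrier peak is weak (below the SNR floor)")
  df <- fs / nfft
  yl <- log(max(combined[max(pk - 1, 1)], 1e-300))
  yc <- log(max(combined[pk], 1e-300))
  yr <- log(max(combined[min(pk + 1, nfft)], 1e-300))
  den <- yl - 2 * yc + yr
  delta <- if (abs(den) > 1e-300) 0.5 * (yl - yr) / den else 0
  f_hat <- freqs[pk] + max(min(delta, 0.5), -0.5) * df

  tau <- (seq_len(S) - 1) * acq$dwell_time
  proj_mag_tot <- function(f) {
    e <- exp(-2i * pi * f * tau) * win
    m <- 0
    for (c in seq_len(n_coils(acq)))
      m <- m + sum(Mod(acq$samples[, c, ] %*% e))
    m
  }
  h <- 0.1 * df
  y0 <- proj_mag_tot(f_hat); ylo <- proj_mag_tot(f_hat - h)
  yhi <- proj_mag_tot(f_hat + h)
  den2 <- ylo - 2 * y0 + yhi
  if (abs(den2) > 1e-300) f_hat <- f_hat + max(min(0.5 * (ylo - yhi) / den2,
                                                   1), -1) * h

  # per-line skip flags from the per-line carrier check
  est <- estimate_carrier(acq, search_halfwidth, pad_factor, snr_floor)
  keep <- !est$lost
  e <- exp(2i * pi * f_hat * tau)
  out <- acq$samples
  for (c in ii) {
    z <- (acq$samples[, c, ] %*% Conj(e)) / S    # LS projection per line
    pred <- outer(as.vector(z), e)
    pred[!keep, ] <- 0
    out[, c, ] <- out[, c, ] - pred
  }
  res <- acquisition_set(out, acq$line_time, acq$arm_angle, acq$dwell_time,
                         acq$TR, acq$f_off_nominal, acq$coil_role,
                         acq$trajectory)
  attr(res, "f_carrier") <- f_hat
  attr(res, "n_skipped") <- sum(!keep)
  res
}

#' Cancellation diagnostics
#'
#' Per-window residual power ratio and total interference power removed per
#' imaging coil, comparing an acquisition before and after cancellation.
#'
#' @param before,after `haptic_acq` objects on the same geometry.
#' @param model Optional `haptic_editer` (adds window/group counts).
#' @return A `haptic_cancel_report` list.
#' @export
cancellation_report <- function(before, after, model = NULL) {
  ii <- imaging_idx(before)
  removed <- vapply(ii, function(c)
    sum(Mod(before$samples[, c, ])^2) - sum(Mod(after$samples[, c, ])^2), 0)
  rep <- list(power_removed = removed,
              total_ratio_db = 10 * log10(
                sum(Mod(after$samples[, ii, ])^2) /
                  sum(Mod(before$samples[, ii, ])^2)))
  if (!is.null(model)) {
    rep$n_windows <- length(model$windows)
    rep$n_groups <- length(unique(model$group_id))
    rep$residual_db <- model$residual_db
  }
  structure(rep, class = "haptic_cancel_report")
}
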