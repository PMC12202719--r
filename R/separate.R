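# Channel selection and blind source separation: correlation-gated coil
# subsets, SOBI respiratory extraction, PCA cardiac extraction.

# Max over lags +/-max_lag of the normalized cross-correlation magnitude.
xcorr_max <- function(x, y, max_lag) {
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(0)
  cc <- stats::ccf(x, y, lag.max = max_lag, plot = FALSE, demean = TRUE)
  max(abs(cc$acf))
}

#' Select coil channels by cross-correlation
#'
#' Respiratory mode: the channel with the highest total correlation to all
#' other channels seeds the set; channels whose peak lagged cross-correlation
#' with the seed exceeds the threshold (default 0.9) are accepted.
#'
#' Cardiac mode: the seed channel is supplied (physical proximity to the
#' heart) or chosen as the coil with maximum band-limited power (`"auto"`);
#' the threshold is lowered from 0.9 in 0.05 steps until at least
#' `min_accepted` channels (default 3, the literal "more than two") are
#' accepted, falling back to the set at the final threshold if it still has
#' at least two members.
#'
#' @param wf A band-passed `haptic_wf` (`resp_band` or `card_band`).
#' @param mode `"resp"` or `"card"`.
#' @param seed_channel Coil index for cardiac mode, or `"auto"`.
#' @param threshold Respiratory acceptance threshold.
#' @param thresholds Cardiac threshold sweep (descending).
#' @param min_accepted Cardiac stop rule (accepted count at which the sweep
#'   stops).
#' @param max_lag_s Cross-correlation lag search half-width, seconds.
#' @return List with `accepted` (coil indices, seed first), `seed`,
#'   `threshold_used`, and the correlation vector against the seed.
#' @export
select_channels <- function(wf, mode = c("resp", "card"),
                            seed_channel = "auto", threshold = 0.9,
                            thresholds = seq(0.9, 0.5, by = -0.05),
                            min_accepted = 3L, max_lag_s = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(wf, "haptic_wf"))
  p <- ncol(wf$value)
  if (p < 2) stopf("channel selection requires >= 2 coils")
  max_lag_s <- max_lag_s %||% if (mode == "resp") 1.0 else 0.1
  max_lag <- max(1L, round(max_lag_s / wf$TR))

  if (mode == "resp") {
    cm <- diag(1, p)
    for (i in seq_len(p - 1)) for (j in (i + 1):p)
      cm[i, j] <- cm[j, i] <- xcorr_max(wf$value[, i], wf$value[, j], max_lag)
    seed <- which.max(rowSums(cm) - 1)
    corr <- cm[, seed]
    accepted <- union(seed, which(corr > threshold))
    if (length(accepted) < 2)
      stopf("insufficient respiratory channels: only the seed coil exceeds %.2f",
            threshold)
    return(list(accepted = accepted, seed = seed, threshold_used = threshold,
                corr = corr))
  }

  if (identical(seed_channel, "auto"))
    seed <- which.max(colMeans(wf$value^2))
  else {
    seed <- as.integer(seed_channel)
    if (is.na(seed) || seed < 1 || seed > p)
      stopf("cardiac seed channel index %s out of range", seed_channel)
  }
  corr <- vapply(seq_len(p), function(j)
    if (j == seed) 1 else xcorr_max(wf$value[, j], wf$value[, seed], max_lag),
    0)
  for (tau in thresholds) {
    accepted <- union(seed, which(corr > tau))
    if (length(accepted) >= min_accepted)
      return(list(accepted = accepted, seed = seed, threshold_used = tau,
                  corr = corr))
  }
  accepted <- union(seed, which(corr > thresholds[length(thresholds)]))
  if (length(accepted) >= 2)
    return(list(accepted = accepted, seed = seed,
                threshold_used = thresholds[length(thresholds)], corr = corr))
  stopf("insufficient cardiac channels: fewer than 2 accepted at threshold %.2f",
        thresholds[length(thresholds)])
}

# Joint approximate diagonalization of a set of symmetric matrices by Jacobi
# (Givens) rotation sweeps; returns the orthogonal diagonalizer.
joint_diagonalize <- function(Rs, tol = 1e-8, max_sweeps = 100L) {
  m <- nrow(Rs[[1]])
  V <- diag(m)
  for (sweep in seq_len(max_sweeps)) {
    rotated <- FALSE
    for (p in seq_len(m - 1)) for (q in (p + 1):m) {
      a <- vapply(Rs, function(R) R[p, p] - R[q, q], 0)
      b <- vapply(Rs, function(R) R[p, q] + R[q, p], 0)
      ton <- sum(a * a) - sum(b * b)
      toff <- 2 * sum(a * b)
      theta <- 0.5 * atan2(toff, ton + sqrt(ton * ton + toff * toff))
      if (abs(sin(theta)) > tol) {
        rotated <- TRUE
        cs <- cos(theta); sn <- sin(theta)
        for (k in seq_along(Rs)) {
          R <- Rs[[k]]
          rp <- R[, p] * cs + R[, q] * sn
          rq <- -R[, p] * sn + R[, q] * cs
          R[, p] <- rp; R[, q] <- rq
          rp <- R[p, ] * cs + R[q, ] * sn
          rq <- -R[p, ] * sn + R[q, ] * cs
          R[p, ] <- rp; R[q, ] <- rq
          Rs[[k]] <- R
        }
        vp <- V[, p] * cs + V[, q] * sn
        vq <- -V[, p] * sn + V[, q] * cs
        V[, p] <- vp; V[, q] <- vq
      }
    }
    if (!rotated) break
  }
  V
}

#' Second-Order Blind Identification source separation
#'
#' Mean-removes and whitens the channels via eigendecomposition of the sample
#' covariance, then jointly diagonalizes symmetrized time-lagged covariance
#' matrices with Jacobi rotations. Returns all recovered source time courses.
#'
#' @param X Channel matrix (`n x p`, one column per accepted coil).
#' @param lags Integer lag set (samples).
#' @param tol Joint-diagonalization off-criterion tolerance.
#' @param max_sweeps Maximum Jacobi sweeps.
#' @return List with `sources` (`n x r`, unit variance columns) and `rank`.
#' @export
sobi <- function(X, lags = 1:50, tol = 1e-8, max_sweeps = 100L) {
  X <- as.matrix(X)
  n <- nrow(X)
  Xc <- sweep(X, 2, colMeans(X))
  C <- crossprod(Xc) / (n - 1)
  eg <- eigen(C, symmetric = TRUE)
  keep <- which(eg$values > max(eg$values) * 1e-10 & eg$values > 0)
  r <- length(keep)
  if (r < 2) {
    warnf("covariance rank < 2; falling back to the first principal component")
    s1 <- Xc %*% eg$vectors[, 1]
    return(list(sources = s1 / max(stats::sd(s1), 1e-30), rank = 1L))
  }
  W <- eg$vectors[, keep] %*% diag(1 / sqrt(eg$values[keep]), r)
  Z <- Xc %*% W                      # n x r, identity covariance
  Rs <- lapply(lags, function(tau) {
    R <- crossprod(Z[seq_len(n - tau), , drop = FALSE],
                   Z[(tau + 1):n, , drop = FALSE]) / (n - tau)
    (R + t(R)) / 2
  })
  V <- joint_diagonalize(Rs, tol, max_sweeps)
  S <- Z %*% V
  S <- sweep(S, 2, apply(S, 2, stats::sd), "/")
  list(sources = S, rank = r)
}

# Fraction of spectral power of x inside [f_lo, f_hi] at sampling rate fs.
band_power_fraction <- function(x, fs, f_lo, f_hi) {
  n <- length(x)
  P <- Mod(stats::fft(x - mean(x)))^2
  f <- (seq_len(n) - 1) / n * fs
  f <- pmin(f, fs - f)
  tot <- sum(P)
  if (tot == 0) return(0)
  sum(P[f >= f_lo & f <= f_hi]) / tot
}

#' Extract the respiratory navigator via SOBI
#'
#' Runs SOBI on the accepted respiratory channels and returns the recovered
#' source with the greatest fraction of spectral power inside the respiratory
#' band, polarity oriented so its correlation with the mean of the accepted
#' channels is positive, unit variance.
#'
#' @param wf A `resp_band` `haptic_wf` restricted to accepted channels.
#' @param band Respiratory band, Hz.
#' @param lags,tol,max_sweeps SOBI parameters, see [sobi()].
#' @return Numeric navigator (unit variance) with attribute `"source_index"`.
#' @export
extract_respiratory <- function(wf, band = c(0.05, 0.9), lags = 1:50,
                                tol = 1e-8, max_sweeps = 100L) {
  stopifnot(inherits(wf, "haptic_wf"))
  if (ncol(wf$value) < 2) stopf("respiratory extraction needs >= 2 channels")
  res <- sobi(wf$value, lags = lags, tol = tol, max_sweeps = max_sweeps)
  S <- as.matrix(res$sources)
  fs <- 1 / wf$TR
  frac <- apply(S, 2, band_power_fraction, fs = fs, f_lo = band[1],
                f_hi = band[2])
  j <- which.max(frac)
  nav <- S[, j]
  ref <- rowMeans(wf$value)
  if (safe_cor(nav, ref) < 0) nav <- -nav
  sdv <- stats::sd(nav)
  if (sdv > 0) nav <- nav / sdv
  attr(nav, "source_index") <- j
  nav
}

#' Extract the cardiac navigator via PCA
#'
#' First principal component of the mean-removed accepted cardiac channels,
#' unit variance, polarity oriented so its correlation with the seed channel
#' is positive. The symmetric eigensolver's deterministic ordering resolves
#' eigenvalue ties.
#'
#' @param wf A `card_band` `haptic_wf` restricted to accepted channels.
#' @param seed_col Column index of the seed channel within `wf$value`.
#' @return Numeric navigator (unit variance).
#' @export
extract_cardiac <- function(wf, seed_col = 1L) {
  stopifnot(inherits(wf, "haptic_wf"))
  if (ncol(wf$value) < 2) stopf("cardiac extraction needs >= 2 channels")
  if (all(wf$value == 0)) stopf("cardiac channels are identically zero")
  pc <- stats::prcomp(wf$value, center = TRUE, scale. = FALSE)
  nav <- pc$x[, 1]
  if (safe_cor(nav, wf$value[, seed_col]) < 0) nav <- -nav
  sdv <- stats::sd(nav)
  if (sdv == 0) stopf("first principal component has zero variance")
  nav / sdv
}

#' Full navigator extraction pipeline
#'
#' Carrier estimation, angle detrending, Savitzky-Golay denoising, band
#' splitting, channel selection and source extraction, producing one cardiac
#' and one respiratory navigator sampled once per TR.
#'
#' @param acq A `haptic_acq`.
#' @param cfg A configuration list (see [haptic_default_config()]).
#' @return A `haptic_nav` list: `t`, `resp`, `card`, `resp_channels`,
#'   `card_channels`, plus a `details` list (thresholds reached, carrier
#'   frequency stats, stage waveforms).
#' @export
extract_navigators <- function(acq, cfg = haptic_default_config()) {
  carrier <- estimate_carrier(acq, cfg$carrier$search_halfwidth,
                              cfg$carrier$pad_factor, cfg$carrier$snr_floor)
  raw <- carrier_waveforms(carrier, acq)
  det <- detrend_by_angle(raw, acq$arm_angle, cfg$detrend$order)
  den <- sgolay_denoise(det, cfg$sgolay$window, cfg$sgolay$polyorder)
  wr <- bandpass(den, cfg$bands$resp, cfg$bands$transition_frac, "resp_band")
  wc <- bandpass(den, cfg$bands$card, cfg$bands$transition_frac, "card_band")

  sel_r <- select_channels(wr, "resp", threshold = cfg$select$resp_threshold,
                           max_lag_s = cfg$select$max_lag_resp)
  resp <- extract_respiratory(
    pt_waveforms(wr$t, wr$value[, sel_r$accepted, drop = FALSE], "resp_band",
                 wr$TR),
    band = cfg$bands$resp, lags = seq_len(cfg$sobi$n_lags),
    tol = cfg$sobi$tol, max_sweeps = cfg$sobi$max_sweeps)

  sel_c <- select_channels(wc, "card", seed_channel = cfg$select$card_seed,
                           thresholds = cfg$select$card_thresholds,
                           min_accepted = cfg$select$card_min_accepted,
                           max_lag_s = cfg$select$max_lag_card)
  card <- extract_cardiac(
    pt_waveforms(wc$t, wc$value[, sel_c$accepted, drop = FALSE], "card_band",
                 wc$TR),
    seed_col = match(sel_c$seed, sel_c$accepted))

  structure(list(
    t = acq$line_time, resp = as.numeric(resp), card = as.numeric(card),
    resp_channels = sel_r$accepted, card_channels = sel_c$accepted,
    details = list(
      resp_seed = sel_r$seed, card_seed = sel_c$seed,
      card_threshold = sel_c$threshold_used,
      resp_threshold = sel_r$threshold_used,
      carrier_freq_mean = mean(carrier$freq[!carrier$lost]),
      carrier_freq_sd = stats::sd(carrier$freq[!carrier$lost]),
      n_carrier_lost = sum(carrier$lost))), class = "haptic_nav")
}

#' @export
print.haptic_nav <- function(x, ...) {
  cat(sprintf("<haptic_nav> %d samples; resp coils {%s}, card coils {%s}\n",
              length(x$t), paste(x$resp_channels, collapse = ","),
              paste(x$card_channels, collapse = ",")))
  invisible(x)
}
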