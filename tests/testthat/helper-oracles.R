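# Fixture builders and independent oracles shared across the suite.

# Minimal hand-built acquisition (no simulator) for container/validation tests.
make_tiny_acq <- function(L = 5L, C = 3L, S = 40L, seed = 1,
                          with_traj = TRUE) {
  set.seed(seed)
  samples <- array(complex(real = stats::rnorm(L * C * S),
                           imaginary = stats::rnorm(L * C * S)), c(L, C, S))
  acquisition_set(
    samples, line_time = (0:(L - 1)) * 0.005,
    arm_angle = ((0:(L - 1)) * 2.39996) %% (2 * pi),
    dwell_time = 1e-6, TR = 0.005, f_off_nominal = 4e5,
    coil_role = c(rep("imaging", C - 1L), "sniffer"),
    trajectory = if (with_traj) array(stats::rnorm(L * S * 2), c(L, S, 2))
                 else NULL)
}

# Acquisition whose samples are a pure complex tone per coil with a chosen
# per-line amplitude matrix (rows = lines, cols = coils).
make_tone_acq <- function(amp, f_tone, S = 128L, dwell = 1e-6, TR = 0.005,
                          roles = NULL, phase = rep(0, ncol(amp))) {
  L <- nrow(amp); C <- ncol(amp)
  tau <- (0:(S - 1)) * dwell
  samples <- array(0i, c(L, C, S))
  for (c in seq_len(C))
    samples[, c, ] <- outer(amp[, c], exp(2i * pi * f_tone * tau +
                                            1i * phase[c]))
  acquisition_set(
    samples, line_time = (0:(L - 1)) * TR,
    arm_angle = ((0:(L - 1)) * 2.39996) %% (2 * pi),
    dwell_time = dwell, TR = TR, f_off_nominal = f_tone,
    coil_role = roles %||% rep("imaging", C))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

rms <- function(x) sqrt(mean(abs(x)^2))

# Brute-force trigger oracle: same detection rule as detect_triggers but
# computed by direct O(n^2) scans, sharing no code with the implementation.
oracle_triggers <- function(x, fs, t0 = 0, window_s = 0.375, prom_min = 0.5,
                            p_lo = 10, p_hi = 98) {
  n <- length(x)
  d <- numeric(n)
  d[1] <- x[2] - x[1]
  d[n] <- x[n] - x[n - 1]
  for (i in 2:(n - 1)) d[i] <- (x[i + 1] - x[i - 1]) / 2
  q <- stats::quantile(d, c(p_lo, p_hi) / 100, names = FALSE, type = 7)
  if (q[2] == q[1]) return(numeric(0))
  dn <- (d - q[1]) / (q[2] - q[1])
  cand <- integer(0)
  for (i in 2:(n - 1))
    if (dn[i] > dn[i - 1] && dn[i] > dn[i + 1]) cand <- c(cand, i)
  if (!length(cand)) return(numeric(0))
  ord <- cand[order(dn[cand], decreasing = TRUE)]
  kept <- integer(0)
  for (i in ord) {
    clash <- FALSE
    for (j in kept) if (abs(j - i) < window_s * fs) clash <- TRUE
    if (!clash) kept <- c(kept, i)
  }
  kept <- sort(kept)
  ok <- logical(length(kept))
  for (m in seq_along(kept)) {
    i <- kept[m]
    lo <- 0L
    for (j in seq(i - 1, 1)) if (dn[j] > dn[i]) { lo <- j; break }
    left_base <- min(dn[(lo + 1):i])
    hi <- n + 1L
    for (j in seq(i + 1, n)) if (dn[j] > dn[i]) { hi <- j; break }
    right_base <- min(dn[i:(hi - 1)])
    ok[m] <- (dn[i] - max(left_base, right_base)) > prom_min
  }
  t0 + (kept[ok] - 1) / fs
}

# Small pipeline configuration used by smoke/determinism tests.
small_cfg <- function(duration = 20) {
  cfg <- haptic_default_config()
  cfg$sim$duration <- duration
  cfg
}
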