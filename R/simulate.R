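# Synthetic golden-angle spiral acquisition simulator.
#
# Generates multi-coil raw readouts in which a pilot-tone carrier, offset from
# the imaging center frequency, is amplitude-modulated per coil by known
# cardiac and respiratory waveforms. Sniffer channels couple to the carrier
# but carry no imaging-volume signal, so every downstream stage (carrier
# estimation, detrending, source separation, cancellation, gating,
# reconstruction) has an exact ground truth.

#' Generate ground-truth physiological waveforms
#'
#' Builds a cardiac waveform as a train of asymmetric pulse templates (fast
#' upstroke, slow decay, so the derivative-based trigger has a well-defined
#' peak) placed at beat onsets with configurable rate variability, and a
#' respiratory waveform as a smooth quasi-sinusoid with slow amplitude and
#' phase drift, both sampled on the TR grid.
#'
#' @param duration Record length in seconds (`>= 10`).
#' @param TR Repetition time in seconds; sampling period of the waveforms.
#' @param heart_rate List with `bpm` (30-162) and `jitter_frac`
#'   (per-beat RR standard deviation as a fraction of the mean RR).
#' @param resp_rate_hz Respiratory rate in Hz (0.05-0.9).
#' @param rhythm `"regular"` or `"arrhythmic"`; arrhythmic mode inserts
#'   skipped and ectopic beats at rate `arrhythmia_rate`.
#' @param arrhythmia_rate Per-beat probability of a rhythm disturbance.
#' @param resp_amplitude Peak respiratory amplitude (0 disables respiration).
#' @param seed RNG seed; identical seeds give identical output.
#' @return A `haptic_physio` list: `t`, `resp`, `card`, `beat_time`, `rhythm`,
#'   `TR`.
#' @export
gen_physio <- function(duration, TR, heart_rate = list(bpm = 60,
                                                       jitter_frac = 0.03),
                       resp_rate_hz = 0.25, rhythm = c("regular", "arrhythmic"),
                       arrhythmia_rate = 0.15, resp_amplitude = 1, seed = 1) {
  rhythm <- match.arg(rhythm)
  if (duration < 10) stopf("duration must be >= 10 s")
  hr_hz <- heart_rate$bpm / 60
  if (hr_hz < 0.5 || hr_hz > 2.7)
    stopf("heart rate %.3g Hz outside the 0.5-2.7 Hz design band",
          hr_hz)
  if (resp_rate_hz < 0.05 || resp_rate_hz > 0.9)
    stopf("respiratory rate %.3g Hz outside the 0.05-0.9 Hz design band",
          resp_rate_hz)
  set.seed(as.integer(seed))
  t <- seq(0, duration - TR / 2, by = TR)
  rr <- 60 / heart_rate$bpm
  refractory <- 0.375

  # beat onsets: jittered intervals, with optional skips / ectopics
  beats <- numeric(0)
  b <- rr * 0.5
  while (b < duration) {
    beats <- c(beats, b)
    iv <- rr * (1 + heart_rate$jitter_frac * stats::rnorm(1))
    iv <- max(iv, refractory + 0.025)
    if (rhythm == "arrhythmic" && stats::runif(1) < arrhythmia_rate) {
      if (stats::runif(1) < 0.5) iv <- iv * 2           # skipped beat
      else iv <- max(0.55 * iv, refractory + 0.025)     # ectopic (early) beat
    }
    b <- b + iv
  }
  if (rhythm == "regular" && length(beats) > 1 &&
      any(diff(beats) <= refractory))
    stopf("internal: regular rhythm produced an interval <= %.3f s", refractory)

  # cardiac pulse template: gamma-like, peak 1 at u = tp
  tp <- 0.12
  template <- function(u) ifelse(u >= 0 & u < 8 * tp,
                                 (u / tp)^2 * exp(2 * (1 - u / tp)), 0)
  card <- numeric(length(t))
  for (bk in beats) {
    idx <- which(t >= bk & t < bk + 8 * tp)
    card[idx] <- card[idx] + template(t[idx] - bk)
  }

  # respiration: quasi-sinusoid with slow seeded drift, bounded in [-1, 1]
  if (resp_amplitude == 0) {
    resp <- numeric(length(t))
  } else {
    drift_f <- c(0.011, 0.017, 0.029)
    drift_ph <- stats::runif(3, 0, 2 * pi)
    amp_drift <- 0.9 + 0.1 * sin(2 * pi * drift_f[1] * t + drift_ph[1])
    ph_drift <- 0.3 * sin(2 * pi * drift_f[2] * t + drift_ph[2]) +
      0.2 * sin(2 * pi * drift_f[3] * t + drift_ph[3])
    resp <- resp_amplitude * amp_drift *
      sin(2 * pi * resp_rate_hz * t + ph_drift)
    resp <- pmax(pmin(resp, 1), -1)
  }
  structure(list(t = t, resp = resp, card = card, beat_time = beats,
                 rhythm = rhythm, TR = TR), class = "haptic_physio")
}

#' Generate a per-coil pilot-tone coupling model
#'
#' Draws baseline carrier amplitudes, modulation depths, carrier phases and
#' leakage gains for a coil array. Imaging coils see the motion-modulated
#' carrier; sniffer coils are distant from the imaging volume so their
#' modulation depths are zero and they carry no phantom signal.
#'
#' @param n_imaging,n_sniffer Coil counts.
#' @param pt_volts Signal-generator amplitude analog; baseline amplitude is
#'   `A0 = a0_per_volt * pt_volts` per unit coil gain.
#' @param a0_per_volt Volts-to-amplitude scale (arbitrary units).
#' @param m_card,m_resp Reference modulation depths (fractions of A0); each
#'   coil gets a depth drawn within a factor of the reference.
#' @param eddy_eps Relative amplitude of the spiral-angle-dependent
#'   deviation. Eddy-current-like deviations originate in the scanner and
#'   receive chain, not in body motion, so they affect sniffer and imaging
#'   channels alike (unlike the motion modulation, which sniffers never see).
#' @param eddy_order Harmonic order of the angle-dependent term (must stay
#'   below the detrending cutoff for the angular low-pass to remove it).
#' @param leak_coherent Broadband generator leakage common to all coils
#'   (removable by sniffer-based cancellation), relative to A0.
#' @param leak_incoherent Per-coil leakage invisible to the sniffers
#'   (receiver-local, not removable), relative to A0.
#' @param sniffer_pt_gain Carrier/leakage coupling gain of sniffer coils
#'   relative to imaging coils. Sniffer channels are chosen to sense the
#'   interference strongly, which keeps the cancellation kernels small so
#'   little sniffer thermal noise is re-injected into the imaging data.
#' @param seed RNG seed.
#' @return A `haptic_coupling` list.
#' @export
make_coupling <- function(n_imaging, n_sniffer, pt_volts = 0.4,
                          a0_per_volt = 400, m_card = 0.008, m_resp = 0.05,
                          eddy_eps = 0.01, eddy_order = 3L,
                          leak_coherent = 0.01, leak_incoherent = 0.005,
                          sniffer_pt_gain = 8, seed = 1) {
  set.seed(as.integer(seed))
  nc <- n_imaging + n_sniffer
  gain_rel <- c(rep(1, n_imaging), rep(sniffer_pt_gain, n_sniffer))
  A0 <- a0_per_volt * pt_volts * stats::runif(nc, 0.7, 1.3) * gain_rel
  mc <- c(m_card * stats::runif(n_imaging, 0.4, 1.4), rep(0, n_sniffer))
  mr <- c(m_resp * stats::runif(n_imaging, 0.5, 1.3), rep(0, n_sniffer))
  if (any(abs(mc) + abs(mr) >= 1))
    stopf("modulation depths must satisfy |m_card| + |m_resp| < 1")
  phase <- stats::runif(nc, 0, 2 * pi)
  eddy_coef <- matrix(stats::rnorm(2 * eddy_order, sd = 1 / sqrt(eddy_order)),
                      nrow = 2)   # cos/sin coefficients per harmonic
  structure(list(
    n_imaging = n_imaging, n_sniffer = n_sniffer, A0 = A0,
    m_card = mc, m_resp = mr, phase = phase,
    eddy_eps = rep(eddy_eps, nc),
    eddy_order = eddy_order, eddy_coef = eddy_coef,
    leak_coherent = leak_coherent, leak_incoherent = leak_incoherent,
    leak_gain = stats::runif(nc, 0.7, 1.3) * gain_rel,
    phantom_sens = c(stats::runif(n_imaging, 0.6, 1.2), rep(0, n_sniffer)),
    pt_volts = pt_volts, a0_per_volt = a0_per_volt), class = "haptic_coupling")
}

# Band-limited periodic eddy term g(theta), zero-mean, unit-ish scale.
eddy_g <- function(theta, coupling) {
  g <- numeric(length(theta))
  for (h in seq_len(coupling$eddy_order))
    g <- g + coupling$eddy_coef[1, h] * cos(h * theta) +
      coupling$eddy_coef[2, h] * sin(h * theta)
  g
}

# Closed-form per-line carrier amplitude A_c(t), the quantity carrier
# estimation must recover.
true_amplitudes <- function(truth, coupling, arm_angle) {
  L <- length(truth$t)
  nc <- length(coupling$A0)
  g <- eddy_g(arm_angle, coupling)
  A <- matrix(0, L, nc)
  for (c in seq_len(nc))
    A[, c] <- coupling$A0[c] *
      (1 + coupling$m_resp[c] * truth$resp + coupling$m_card[c] * truth$card +
         coupling$eddy_eps[c] * g)
  A
}

#' Spiral trajectory for one arm angle set
#'
#' Archimedean spiral with linear radius growth (so sample density is
#' radial-like and |k| ramp weights are the matching density compensation),
#' rotated per line by the golden-angle increment.
#'
#' @param arm_angle Starting angle per line, radians.
#' @param n_samples Samples per readout.
#' @param kmax Maximum |k| in cycles per FOV unit.
#' @param n_turns Number of spiral turns per arm.
#' @return Array `[n_lines, n_samples, 2]` of (kx, ky).
#' @export
spiral_trajectory <- function(arm_angle, n_samples, kmax, n_turns = 3) {
  s <- (seq_len(n_samples) - 1) / (n_samples - 1)
  r <- kmax * s
  phi0 <- 2 * pi * n_turns * s
  L <- length(arm_angle)
  traj <- array(0, c(L, n_samples, 2))
  for (l in seq_len(L)) {
    phi <- phi0 + arm_angle[l]
    traj[l, , 1] <- r * cos(phi)
    traj[l, , 2] <- r * sin(phi)
  }
  traj
}

#' Analytic ellipse phantom
#'
#' A Shepp-Logan-like phantom of a few uniform ellipses with closed-form
#' k-space, used as the desired signal the cancellation stage must preserve.
#'
#' @param ellipses Data frame with columns `x0, y0, a, b, angle_deg,
#'   intensity` in FOV units (FOV spans \[-0.5, 0.5\]).
#' @return A `haptic_phantom` object with `$ellipses` and methods
#'   [phantom_kspace()] / [phantom_image()].
#' @export
phantom_model <- function(ellipses = default_ellipses()) {
  need <- c("x0", "y0", "a", "b", "angle_deg", "intensity")
  if (nrow(ellipses) > 0 && !all(need %in% names(ellipses)))
    stopf("ellipse table must have columns %s", paste(need, collapse = ", "))
  structure(list(ellipses = ellipses), class = "haptic_phantom")
}

#' @rdname phantom_model
#' @export
default_ellipses <- function() {
  data.frame(
    x0 = c(0, -0.08, 0.1), y0 = c(0, 0.05, -0.06),
    a = c(0.32, 0.1, 0.07), b = c(0.24, 0.08, 0.1),
    angle_deg = c(0, 20, -35), intensity = c(1, 0.6, -0.4))
}

#' Evaluate phantom k-space at arbitrary coordinates
#'
#' Closed form: the transform of a uniform unit disk is
#' `J1(2*pi*rho)/rho` (area `pi` at DC), scaled, rotated and shifted per
#' ellipse.
#'
#' @param phantom A `haptic_phantom`.
#' @param kx,ky Coordinates in cycles per FOV unit.
#' @return Complex vector of k-space values.
#' @export
phantom_kspace <- function(phantom, kx, ky) {
  out <- complex(real = numeric(length(kx)))
  for (i in seq_len(nrow(phantom$ellipses))) {
    e <- phantom$ellipses[i, ]
    th <- e$angle_deg * pi / 180
    kxr <- kx * cos(th) + ky * sin(th)
    kyr <- -kx * sin(th) + ky * cos(th)
    rho <- sqrt((e$a * kxr)^2 + (e$b * kyr)^2)
    amp <- ifelse(rho < 1e-12, pi * e$a * e$b,
                  e$a * e$b * besselJ(2 * pi * rho, 1) / pmax(rho, 1e-12))
    out <- out + e$intensity * amp * exp(-2i * pi * (kx * e$x0 + ky * e$y0))
  }
  out
}

#' Rasterize the phantom image
#'
#' @param phantom A `haptic_phantom`.
#' @param grid Image matrix size.
#' @return `grid x grid` real matrix over the FOV \[-0.5, 0.5\]^2.
#' @export
phantom_image <- function(phantom, grid = 64L) {
  x <- (seq_len(grid) - 1 - grid / 2) / grid
  img <- matrix(0, grid, grid)
  for (i in seq_len(nrow(phantom$ellipses))) {
    e <- phantom$ellipses[i, ]
    th <- e$angle_deg * pi / 180
    xr <- outer(x - e$x0, x - e$y0, function(u, v) u * cos(th) + v * sin(th))
    yr <- outer(x - e$x0, x - e$y0, function(u, v) -u * sin(th) + v * cos(th))
    img <- img + e$intensity * ((xr / e$a)^2 + (yr / e$b)^2 <= 1)
  }
  img
}

#' Simulate a multi-coil acquisition with pilot-tone interference
#'
#' Each readout carries (unless `noise_only`) the phantom signal along its
#' spiral trajectory, plus the pilot-tone carrier
#' `A_c(t_line) * exp(i*(2*pi*f_off*tau + psi_line + phase_c))` whose
#' per-line amplitude follows the physiological truth and the
#' angle-dependent eddy term, plus broadband generator leakage (a common
#' source scaled per coil, and a per-coil incoherent component), plus
#' complex Gaussian thermal noise. The generator is not synchronized to the
#' scanner, so the carrier phase `psi_line` is incoherent from line to line
#' (while staying common to all coils); downstream processing uses only the
#' carrier amplitude. Sniffer channels couple to the carrier and common
#' leakage but carry no phantom signal and no motion modulation.
#'
#' @param truth A `haptic_physio` from [gen_physio()].
#' @param coupling A `haptic_coupling` from [make_coupling()].
#' @param acq_cfg List with `n_samples`, `dwell_time`, `f_off`,
#'   `golden_angle_deg`, `n_turns`, `kmax` (defaults from the `sim`/`recon`
#'   sections of [haptic_default_config()]).
#' @param noise_sd Thermal noise SD per real/imag component.
#' @param noise_only If `TRUE`, omit the phantom signal (noise-only scan with
#'   the same acquisition parameters).
#' @param phantom A `haptic_phantom`, or `NULL` to omit the phantom.
#' @param seed RNG seed for the noise draws.
#' @param return_components If `TRUE`, attach a `components` attribute with
#'   the separate `phantom`, `carrier`, `leak_coherent`, `leak_incoherent`
#'   and `noise` arrays (oracle accounting for the cancellation tests).
#' @return A `haptic_acq`.
#' @export
simulate_acquisitions <- function(truth, coupling, acq_cfg = list(),
                                  noise_sd = 1, noise_only = FALSE,
                                  phantom = phantom_model(), seed = 1,
                                  return_components = FALSE) {
  defs <- haptic_default_config()$sim
  cfg <- merge_config(list(n_samples = defs$n_samples,
                           dwell_time = defs$dwell_time, f_off = defs$f_off,
                           golden_angle_deg = defs$golden_angle_deg,
                           n_turns = 3, kmax = 32), acq_cfg)
  L <- length(truth$t)
  nc <- length(coupling$A0)
  S <- as.integer(cfg$n_samples)
  if (cfg$f_off > 0.5 / cfg$dwell_time)
    warnf("PT offset %.3g Hz exceeds half the sampling bandwidth; the carrier will alias",
          cfg$f_off)
  set.seed(as.integer(seed))
  arm_angle <- (cfg$golden_angle_deg * pi / 180 * (seq_len(L) - 1)) %% (2 * pi)
  tau <- (seq_len(S) - 1) * cfg$dwell_time
  A <- true_amplitudes(truth, coupling, arm_angle)
  carrier_t <- exp(2i * pi * cfg$f_off * tau)

  roles <- c(rep("imaging", coupling$n_imaging),
             rep("sniffer", coupling$n_sniffer))
  # unsynchronized generator: per-line carrier phase, common to all coils
  psi <- stats::runif(L, 0, 2 * pi)
  samples <- array(0i, c(L, nc, S))
  comp <- if (return_components)
    list(phantom = array(0i, c(L, nc, S)), carrier = array(0i, c(L, nc, S)),
         leak_coherent = array(0i, c(L, nc, S)),
         leak_incoherent = array(0i, c(L, nc, S)),
         noise = array(0i, c(L, nc, S)))
  else NULL

  # carrier per coil: rank-1 outer product of A[,c] and the within-readout tone
  for (c in seq_len(nc)) {
    car <- outer(A[, c] * exp(1i * psi), carrier_t * exp(1i * coupling$phase[c]))
    samples[, c, ] <- samples[, c, ] + car
    if (return_components) comp$carrier[, c, ] <- car
  }

  # broadband generator leakage: common complex white source, scaled per coil,
  # proportional to the mean imaging-coil carrier amplitude
  A0bar <- mean(coupling$A0[seq_len(coupling$n_imaging)])
  if (coupling$leak_coherent > 0) {
    src <- matrix(complex(real = stats::rnorm(L * S),
                          imaginary = stats::rnorm(L * S)), L, S) / sqrt(2)
    for (c in seq_len(nc)) {
      lk <- coupling$leak_coherent * A0bar * coupling$leak_gain[c] * src
      samples[, c, ] <- samples[, c, ] + lk
      if (return_components) comp$leak_coherent[, c, ] <- lk
    }
  }
  # incoherent per-coil leakage (imaging coils only; invisible to sniffers)
  if (coupling$leak_incoherent > 0) {
    for (c in seq_len(coupling$n_imaging)) {
      w <- matrix(complex(real = stats::rnorm(L * S),
                          imaginary = stats::rnorm(L * S)), L, S) / sqrt(2)
      lk <- coupling$leak_incoherent * A0bar * w
      samples[, c, ] <- samples[, c, ] + lk
      if (return_components) comp$leak_incoherent[, c, ] <- lk
    }
  }

  trajectory <- spiral_trajectory(arm_angle, S, cfg$kmax, cfg$n_turns)
  if (!noise_only && !is.null(phantom) && nrow(phantom$ellipses) > 0) {
    kx <- trajectory[, , 1]; ky <- trajectory[, , 2]
    pk <- matrix(phantom_kspace(phantom, as.vector(kx), as.vector(ky)), L, S)
    pg <- (acq_cfg$phantom_gain %||% defs$phantom_gain) * S
    for (c in seq_len(coupling$n_imaging)) {
      ph <- coupling$phantom_sens[c] * pg * pk
      samples[, c, ] <- samples[, c, ] + ph
      if (return_components) comp$phantom[, c, ] <- ph
    }
  }

  if (noise_sd > 0) {
    for (c in seq_len(nc)) {
      nz <- matrix(complex(real = stats::rnorm(L * S, sd = noise_sd),
                           imaginary = stats::rnorm(L * S, sd = noise_sd)),
                   L, S)
      samples[, c, ] <- samples[, c, ] + nz
      if (return_components) comp$noise[, c, ] <- nz
    }
  }

  acq <- acquisition_set(samples, truth$t, arm_angle, cfg$dwell_time,
                         truth$TR, cfg$f_off, roles, trajectory)
  if (return_components) attr(acq, "components") <- comp
  acq
}
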