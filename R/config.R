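# Run configuration: every tunable of every stage, with validated defaults.

#' Default run configuration
#'
#' Returns the full set of tunables for simulation, navigator extraction,
#' interference cancellation, gating and reconstruction. Values that the
#' method prescribes (band edges, trigger rules, bin counts, TR, view-sharing
#' arm counts) are fixed here as defaults; the rest are the package's own
#' documented choices.
#'
#' @return A nested list with components `sim`, `carrier`, `detrend`,
#'   `sgolay`, `bands`, `select`, `sobi`, `editer`, `model_sub`, `trigger`,
#'   `bins`, `recon`, `sweep`.
#' @export
haptic_default_config <- function() {
  list(
    sim = list(
      duration = 90,            # s of acquisition
      TR = 5.32e-3,             # s per line -> 187.97 Hz navigator rate
      n_samples = 128L,         # samples per readout
      dwell_time = 1e-6,        # s -> 1 MHz readout bandwidth
      f_off = 4e5,              # Hz, PT carrier offset from center
      n_imaging = 5L,
      n_sniffer = 3L,
      golden_angle_deg = 137.507764,
      heart_rate_bpm = 60,
      hr_jitter_frac = 0.03,    # per-beat RR variability (fraction of RR)
      resp_rate_hz = 0.25,
      rhythm = "regular",
      arrhythmia_rate = 0.15,   # per-beat probability of skip/ectopic event
      pt_volts = 0.4,           # signal-generator analog; A0 = a0_per_volt * V
      a0_per_volt = 400,
      m_card = 0.008,           # cardiac modulation depth, fraction of A0
      m_resp = 0.05,            # respiratory modulation depth, fraction of A0
      eddy_eps = 0.01,          # angle-dependent amplitude deviation, rel. A0
      eddy_order = 3L,          # harmonic order of the eddy term g(theta)
      leak_coherent = 0.01,     # broadband generator leakage, rel. A0,
                                # common source seen by every coil
      leak_incoherent = 0.005,  # per-coil leakage not seen by sniffers
      noise_sd = 1,             # thermal noise SD per real/imag component
      phantom_gain = 0.05,      # phantom k-space scale relative to noise floor
      phantom = TRUE
    ),
    carrier = list(
      search_halfwidth = 3e4,   # Hz around the nominal offset
      pad_factor = 4L,          # zero-padding for the per-line spectrum
      snr_floor = 3             # peak/median ratio below which a line is
                                # flagged "carrier lost"
    ),
    detrend = list(order = 8L), # angular harmonic order; 0 disables
    sgolay = list(window = 21L, polyorder = 3L),
    bands = list(resp = c(0.05, 0.9), card = c(1, 20),
                 transition_frac = 0.2),
    select = list(
      resp_threshold = 0.9,
      card_thresholds = seq(0.9, 0.5, by = -0.05),
      card_min_accepted = 3L,   # "more than two"; final-threshold fallback 2
      card_seed = "auto",       # coil index, or "auto" = max card-band power
      max_lag_resp = 1.0,       # s, cross-correlation search lag
      max_lag_card = 0.1
    ),
    sobi = list(n_lags = 50L, tol = 1e-8, max_sweeps = 100L),
    editer = list(window_lines = 50L, K = 7L, delta_lines = 0L,
                  group_corr_threshold = 0.9),
    model_sub = list(),
    trigger = list(window_s = 0.375, prominence = 0.5, p_lo = 10, p_hi = 98),
    bins = list(n_resp = 12L, n_card = 20L),
    recon = list(grid = 64L, osf = 2, kernel_width = 4L, n_turns = 3,
                 roi_diameter_frac = 0.53, noise_arms = 550L),
    sweep = list(volts = c(0.01, 0.02, 0.04, 0.06, 0.08, 0.1,
                           0.2, 0.4, 0.6, 0.8, 1),
                 duration = 30)
  )
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

#' Load and validate a run configuration
#'
#' Reads a YAML file whose structure mirrors [haptic_default_config()]; any
#' field not present keeps its default. Every field is validated against its
#' documented range.
#'
#' @param path Optional YAML file; `NULL` returns validated defaults.
#' @param overrides Optional list merged on top (highest precedence).
#' @return A validated configuration list.
#' @export
read_config <- function(path = NULL, overrides = NULL) {
  cfg <- haptic_default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stopf("config file '%s' does not exist", path)
    cfg <- merge_config(cfg, yaml::read_yaml(path))
  }
  if (!is.null(overrides)) cfg <- merge_config(cfg, overrides)
  validate_config(cfg)
}

#' Validate a configuration list
#'
#' @param cfg A configuration list in the shape of [haptic_default_config()].
#' @return `cfg` (with integer-like fields coerced), or an error naming the
#'   offending field.
#' @export
validate_config <- function(cfg) {
  chk <- function(ok, field, msg)
    if (!isTRUE(ok)) stopf("config field %s invalid: %s", field, msg)
  s <- cfg$sim
  chk(is_scalar_num(s$duration) && s$duration >= 10, "sim.duration", ">= 10 s")
  chk(is_scalar_num(s$TR) && s$TR > 0, "sim.TR", "> 0")
  chk(is_scalar_num(s$dwell_time) && s$dwell_time > 0, "sim.dwell_time", "> 0")
  chk(s$n_samples >= 32, "sim.n_samples", ">= 32")
  hr_hz <- s$heart_rate_bpm / 60
  chk(hr_hz >= 0.5 && hr_hz <= 2.7, "sim.heart_rate_bpm",
      "cardiac rate must be 0.5-2.7 Hz (30-162 bpm)")
  chk(s$resp_rate_hz >= 0.05 && s$resp_rate_hz <= 0.9, "sim.resp_rate_hz",
      "respiratory rate must be 0.05-0.9 Hz")
  chk(s$rhythm %in% c("regular", "arrhythmic"), "sim.rhythm",
      "'regular' or 'arrhythmic'")
  chk(s$m_card >= 0 && s$m_resp >= 0 && s$m_card + s$m_resp < 1,
      "sim.m_card/m_resp", "depths must be >= 0 with sum < 1")
  chk(s$pt_volts >= 0, "sim.pt_volts", ">= 0")
  chk(s$noise_sd >= 0, "sim.noise_sd", ">= 0")
  chk(s$n_imaging >= 1, "sim.n_imaging", ">= 1")
  b <- cfg$bands
  chk(b$resp[1] > 0 && b$resp[1] < b$resp[2], "bands.resp", "0 < lo < hi")
  chk(b$card[1] > 0 && b$card[1] < b$card[2], "bands.card", "0 < lo < hi")
  g <- cfg$sgolay
  chk(g$window %% 2 == 1 && g$window > g$polyorder, "sgolay",
      "window must be odd and > polyorder")
  tcf <- cfg$trigger
  chk(tcf$window_s > 0, "trigger.window_s", "> 0")
  chk(tcf$p_lo < tcf$p_hi, "trigger.p_lo/p_hi", "p_lo < p_hi")
  chk(cfg$bins$n_resp >= 1 && cfg$bins$n_card >= 1, "bins", ">= 1")
  e <- cfg$editer
  chk(e$window_lines >= 1 && e$K >= 0 && e$delta_lines >= 0, "editer",
      "window_lines >= 1, K >= 0, delta_lines >= 0")
  chk(cfg$select$resp_threshold > 0 && cfg$select$resp_threshold < 1,
      "select.resp_threshold", "in (0, 1)")
  r <- cfg$recon
  chk(r$grid >= 16 && r$osf >= 1.5, "recon", "grid >= 16, osf >= 1.5")
  chk(r$roi_diameter_frac > 0 && r$roi_diameter_frac <= 1,
      "recon.roi_diameter_frac", "in (0, 1]")
  cfg
}
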