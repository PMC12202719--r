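# End-to-end orchestration: simulate -> extract -> cancel -> gate -> recon,
# plus the pilot-tone amplitude sweep experiment.

#' Restrict an acquisition to a subset of lines
#'
#' @param acq A `haptic_acq`.
#' @param lines Line indices (increasing).
#' @return A `haptic_acq` on the subset.
#' @export
subset_lines <- function(acq, lines) {
  acquisition_set(acq$samples[lines, , , drop = FALSE], acq$line_time[lines],
                  acq$arm_angle[lines], acq$dwell_time, acq$TR,
                  acq$f_off_nominal, acq$coil_role,
                  if (is.null(acq$trajectory)) NULL
                  else acq$trajectory[lines, , , drop = FALSE])
}

sim_from_config <- function(cfg, seed, pt_volts = NULL, noise_only = FALSE,
                            duration = NULL, truth = NULL) {
  s <- cfg$sim
  truth <- truth %||% gen_physio(
    duration %||% s$duration, s$TR,
    heart_rate = list(bpm = s$heart_rate_bpm, jitter_frac = s$hr_jitter_frac),
    resp_rate_hz = s$resp_rate_hz, rhythm = s$rhythm,
    arrhythmia_rate = s$arrhythmia_rate, seed = derive_seed(seed, "physio"))
  coupling <- make_coupling(
    s$n_imaging, s$n_sniffer, pt_volts = pt_volts %||% s$pt_volts,
    a0_per_volt = s$a0_per_volt, m_card = s$m_card, m_resp = s$m_resp,
    eddy_eps = s$eddy_eps, eddy_order = s$eddy_order,
    leak_coherent = s$leak_coherent, leak_incoherent = s$leak_incoherent,
    seed = derive_seed(seed, "coupling"))
  acq <- simulate_acquisitions(
    truth, coupling,
    acq_cfg = list(n_samples = s$n_samples, dwell_time = s$dwell_time,
                   f_off = s$f_off, golden_angle_deg = s$golden_angle_deg,
                   n_turns = cfg$recon$n_turns, kmax = cfg$recon$grid / 2,
                   phantom_gain = s$phantom_gain),
    noise_sd = s$noise_sd, noise_only = noise_only,
    phantom = if (isTRUE(s$phantom) && !noise_only) phantom_model() else NULL,
    seed = derive_seed(seed, "noise"))
  list(truth = truth, coupling = coupling, acq = acq)
}

# Band-pass the scalar truth cardiac waveform the same way the navigator is,
# for like-with-like correlation scoring.
bandpassed_truth_card <- function(truth, cfg) {
  wf <- pt_waveforms(truth$t, matrix(truth$card, ncol = 1), "raw", truth$TR)
  bandpass(wf, cfg$bands$card, cfg$bands$transition_frac, "card_band")$value[, 1]
}

#' Run the full pipeline on one simulated acquisition
#'
#' Simulates an acquisition from the configuration, extracts navigators,
#' detects and scores triggers against the ground-truth beat onsets, assigns
#' retrospective bins, and (optionally) applies interference cancellation.
#' All artifacts are written to `out_dir` with a manifest; the run is
#' deterministic given `seed`.
#'
#' @param cfg Configuration list from [read_config()].
#' @param out_dir Output directory (created if missing); `NULL` skips all
#'   file output.
#' @param seed Run seed, expanded per stage by a fixed counter scheme.
#' @param cancel `"editer"`, `"model"` or `"none"`.
#' @param write_clean If `TRUE`, also write the cleaned acquisition
#'   container (large).
#' @return Invisible list with `truth`, `acq`, `nav`, `triggers`, `match`,
#'   `report`, `bins`, `clean` (cleaned acquisition or `NULL`),
#'   `cancel_report`, `manifest`.
#' @export
run_pipeline <- function(cfg = haptic_default_config(), out_dir = NULL,
                         seed = 1, cancel = c("editer", "model", "none"),
                         write_clean = FALSE) {
  cancel <- match.arg(cancel)
  cfg <- validate_config(cfg)
  sim <- sim_from_config(cfg, seed)
  truth <- sim$truth; acq <- sim$acq

  nav <- extract_navigators(acq, cfg)
  fs <- 1 / acq$TR
  triggers <- detect_triggers(nav$card, fs, t0 = nav$t[1],
                              window_s = cfg$trigger$window_s,
                              prominence = cfg$trigger$prominence,
                              p_lo = cfg$trigger$p_lo,
                              p_hi = cfg$trigger$p_hi)
  ref <- trigger_series(truth$beat_time, "truth")
  match <- match_triggers(triggers, ref)
  report <- gating_metrics(match)
  bins <- assign_bins(nav$resp, triggers, nav$t,
                      n_resp = cfg$bins$n_resp, n_card = cfg$bins$n_card)

  clean <- NULL; cancel_rep <- NULL
  if (cancel == "editer") {
    model <- editer_fit(acq, cfg$editer$window_lines, cfg$editer$K,
                        cfg$editer$delta_lines,
                        cfg$editer$group_corr_threshold)
    clean <- editer_apply(model, acq)
    cancel_rep <- cancellation_report(acq, clean, model)
  } else if (cancel == "model") {
    clean <- model_subtract(acq, cfg$carrier$search_halfwidth,
                            cfg$carrier$pad_factor, cfg$carrier$snr_floor)
    cancel_rep <- cancellation_report(acq, clean)
  }

  corr_card <- safe_cor(nav$card, bandpassed_truth_card(truth, cfg))
  corr_resp <- safe_cor(nav$resp, truth$resp)

  report_full <- list(
    gating = unclass(report),
    corr_card_truth = corr_card, corr_resp_truth = corr_resp,
    n_triggers_detected = length(triggers$event_time),
    n_true_beats = length(truth$beat_time),
    resp_channels = nav$resp_channels, card_channels = nav$card_channels,
    card_threshold = nav$details$card_threshold,
    carrier_freq_mean_hz = nav$details$carrier_freq_mean,
    carrier_freq_sd_hz = nav$details$carrier_freq_sd,
    n_carrier_lost = nav$details$n_carrier_lost,
    cancellation = if (!is.null(cancel_rep))
      list(method = cancel,
           total_ratio_db = cancel_rep$total_ratio_db,
           n_windows = cancel_rep$n_windows %||% NA,
           n_groups = cancel_rep$n_groups %||% NA)
      else list(method = "none"),
    seed = seed)

  manifest <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    nav_path <- file.path(out_dir, "nav.csv")
    write_navigators(nav, nav_path)
    trig_path <- file.path(out_dir, "triggers_pt.csv")
    write_triggers(triggers, trig_path)
    ref_path <- file.path(out_dir, "triggers_truth.csv")
    write_triggers(ref, ref_path)
    bins_path <- file.path(out_dir, "bins.csv")
    utils::write.csv(data.frame(t = nav$t, card_bin = bins$card_bin,
                                resp_bin = bins$resp_bin),
                     bins_path, row.names = FALSE)
    rep_path <- file.path(out_dir, "report.json")
    jsonlite::write_json(report_full, rep_path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    files <- c(nav = "nav.csv", triggers_pt = "triggers_pt.csv",
               triggers_truth = "triggers_truth.csv", bins = "bins.csv",
               report = "report.json")
    if (write_clean && !is.null(clean)) {
      write_acquisitions(clean, file.path(out_dir, "clean.acq"))
      files <- c(files, clean = "clean.acq")
    }
    manifest <- list(seed = seed, cancel = cancel, config = cfg,
                     files = as.list(files))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(list(truth = truth, acq = acq, nav = nav, triggers = triggers,
                 match = match, report = report, bins = bins, clean = clean,
                 cancel_report = cancel_rep, report_full = report_full,
                 manifest = manifest))
}

#' Pilot-tone amplitude sweep experiment
#'
#' For each amplitude: a fresh simulation with a common physiological truth
#' and common noise realizations (a paired design, so the jitter and
#' noise-ratio trends are not masked by realization noise), full navigator
#' extraction and triggering for the jitter against truth beats, and
#' noise-only reconstructions without cancellation, with sinusoid-model
#' subtraction and with EDITER for the noise ratios against a shared
#' no-pilot-tone reference. A failing amplitude marks its row invalid and
#' the sweep continues.
#'
#' @param cfg Configuration list; `cfg$sweep$duration` sets the per-amplitude
#'   record length.
#' @param volts Amplitude grid (signal-generator volt analogs).
#' @param seed Run seed.
#' @return Data frame with columns `volts`, `jitter_ms`, `nr_baseline`,
#'   `nr_model`, `nr_editer`, `valid`.
#' @export
run_amplitude_sweep <- function(cfg = haptic_default_config(),
                                volts = NULL, seed = 1) {
  cfg <- validate_config(cfg)
  volts <- volts %||% cfg$sweep$volts
  if (length(volts) < 3) stopf("amplitude sweep needs >= 3 amplitudes")
  dur <- cfg$sweep$duration
  cfg$sim$phantom <- FALSE       # jitter and noise ratio need no phantom

  s <- cfg$sim
  truth <- gen_physio(
    dur, s$TR,
    heart_rate = list(bpm = s$heart_rate_bpm, jitter_frac = s$hr_jitter_frac),
    resp_rate_hz = s$resp_rate_hz, rhythm = s$rhythm,
    arrhythmia_rate = s$arrhythmia_rate, seed = derive_seed(seed, "physio"))
  ref <- trigger_series(truth$beat_time, "truth")

  arms <- seq_len(min(cfg$recon$noise_arms, round(dur / s$TR)))
  grid <- cfg$recon$grid
  # shared reference: no PT transmission, cancellation off
  ref_sim <- sim_from_config(cfg, seed, pt_volts = 0, noise_only = TRUE,
                             duration = dur, truth = truth)
  ref_img <- grid_recon(subset_lines(ref_sim$acq, arms), grid = grid,
                        osf = cfg$recon$osf,
                        kernel_width = cfg$recon$kernel_width)

  out <- data.frame(volts = volts, jitter_ms = NA_real_,
                    nr_baseline = NA_real_, nr_model = NA_real_,
                    nr_editer = NA_real_, valid = FALSE)
  for (i in seq_along(volts)) {
    out$jitter_ms[i] <- tryCatch({
      run <- sim_from_config(cfg, seed, pt_volts = volts[i], duration = dur,
                             truth = truth)
      nav <- extract_navigators(run$acq, cfg)
      trig <- detect_triggers(nav$card, 1 / s$TR, t0 = nav$t[1],
                              window_s = cfg$trigger$window_s,
                              prominence = cfg$trigger$prominence,
                              p_lo = cfg$trigger$p_lo, p_hi = cfg$trigger$p_hi)
      gating_metrics(match_triggers(trig, ref))$jitter_ms
    }, error = function(e) {
      warnf("amplitude %.3g V: navigator extraction failed: %s", volts[i],
            conditionMessage(e))
      NA_real_
    })
    ratios <- tryCatch({
      nz <- sim_from_config(cfg, seed, pt_volts = volts[i], noise_only = TRUE,
                            duration = dur, truth = truth)$acq
      nz <- subset_lines(nz, arms)
      rec <- function(a) grid_recon(a, grid = grid, osf = cfg$recon$osf,
                                    kernel_width = cfg$recon$kernel_width)
      nr <- function(img) noise_ratio(img, ref_img,
                                      cfg$recon$roi_diameter_frac)$ratio
      base_img <- rec(nz)
      mod_img <- rec(model_subtract(nz, cfg$carrier$search_halfwidth,
                                    cfg$carrier$pad_factor,
                                    cfg$carrier$snr_floor))
      emodel <- editer_fit(nz, cfg$editer$window_lines, cfg$editer$K,
                           cfg$editer$delta_lines,
                           cfg$editer$group_corr_threshold)
      ed_img <- rec(editer_apply(emodel, nz))
      c(nr(base_img), nr(mod_img), nr(ed_img))
    }, error = function(e) {
      warnf("amplitude %.3g V: noise-ratio branch failed: %s", volts[i],
            conditionMessage(e))
      rep(NA_real_, 3)
    })
    out[i, c("nr_baseline", "nr_model", "nr_editer")] <- ratios
    out$valid[i] <- !is.na(out$jitter_ms[i]) && !any(is.na(ratios))
  }
  out
}
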