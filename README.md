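# haptic: high-amplitude pilot-tone gating with interference cancellation

Pilot tone (PT) is a contactless physiological navigator for MRI: a
continuous RF carrier transmitted near (but outside) the imaging band is
amplitude-modulated by body motion as it couples into the receive array,
giving a cardiac and respiratory signal sampled once per k-space line —
no ECG leads, no bellows. At low field (0.55T) the cardiac modulation is
tiny, so the carrier must be driven at high amplitude; that in turn leaks
interference into the imaging bandwidth. This package implements the
resulting two-sided method for raw multi-coil acquisitions:

* **navigator extraction** — per-line carrier frequency/amplitude
  estimation, spiral-angle detrending, Savitzky–Golay denoising, band-pass
  splitting (0.05–0.9 Hz respiratory / 1–20 Hz cardiac),
  cross-correlation channel selection, SOBI (respiratory) and PCA
  (cardiac) source extraction;
* **interference cancellation** — EDITER: windowed least-squares FIR
  kernels mapping dedicated *sniffer* coils (channels that sense the
  carrier but negligible anatomy) onto each imaging coil, with
  kernel-similarity window grouping; plus the sinusoid-model subtraction
  baseline;
* **gating** — derivative-based trigger detection (10th/98th-percentile
  normalization, 0.375-s refractory window, topographic prominence > 0.5),
  R-wave matching with mean-delay/jitter/failure-rate metrics, and
  retrospective 12 × 20 respiratory × cardiac binning;
* **evaluation** — density-compensated gridding reconstruction with view
  sharing (17 arms/frame, 55-arm footprint) and the noise-ratio metric on
  noise-only scans;
* **simulation** — a golden-angle spiral acquisition generator with known
  physiological ground truth, so every stage above is verifiable without
  scanner data.

## The model in brief

Each readout of coil *c* carries the carrier
`A_c(t) · exp(i(2π f_off τ + ψ(t) + φ_c))` with per-line amplitude

    A_c(t) = A0_c · (1 + m_resp,c · r(t) + m_card,c · c(t) + ε · g(θ(t)))

where `r`, `c` are the respiratory and cardiac waveforms, `g(θ)` an
arm-angle-dependent (eddy-current-like) deviation, and `ψ(t)` the
unsynchronized generator phase, which is discarded — only amplitude is
used. The per-TR amplitude estimates are the raw PT waveforms; EDITER
models each imaging coil's interference as `Σ_s k_s ⊛ sniffer_s` per
time window and subtracts the prediction. Trigger jitter is the sample SD
of PT-minus-reference trigger time differences; the failure rate is
`100 · (FP + FN) / n_triggers`; the noise ratio is the ROI noise SD of a
cancellation-on reconstruction over a no-PT reference.

## Worked example

```r
library(haptic)
cfg <- haptic_default_config()
cfg$sim$duration <- 30                      # 30-s run for the example
res <- run_pipeline(cfg, seed = 42, cancel = "editer")
print(res$acq); print(res$triggers); print(res$report)
```

prints (numbers from this exact call):

```
<haptic_acq> 5639 lines x 8 coils (5 imaging, 3 sniffer) x 128 samples
  TR = 5.32 ms, dwell = 1 us, nominal PT offset = 400 kHz
  duration = 30 s
<haptic_triggers> 31 PT events, span 29.24 s, median interval 0.984 s
<haptic_report> 29 triggers: mean delay 44.8 ms, jitter 3.3 ms, FP 0, FN 0, failure rate 0.00%
```

So at the default 0.4 V carrier setting the cardiac navigator triggers on
every simulated beat (29 scoring windows, no false positives or
negatives) with 3.3 ms jitter against the true beat onsets; the mean
44.8 ms delay is the fixed offset between beat onset and the upstroke
peak the detector locks onto. The same run reports
`corr(cardiac navigator, truth) = 0.938`,
`corr(respiratory navigator, truth) = 0.995`, and EDITER removes 30.5 dB
of carrier interference from the imaging coils.

The amplitude-sweep experiment (`run_amplitude_sweep`) reproduces the
method's central trade-off: jitter falls with carrier amplitude to a
plateau of a few ms, while the residual-interference noise ratio rises
monotonically, with EDITER ≤ model subtraction ≤ no cancellation at
every amplitude.

A thin CLI wraps the same functions for shell use; see
`inst/cli/haptic` (`simulate`, `extract`, `cancel`, `gate`,
`noise-ratio`, `run`, `sweep`, each with `--config`).

## Scope

Pulse-sequence design, scanner/antenna hardware, GIRF trajectory
correction, constrained (TFD / XD-GRASP-style) reconstruction and
prospective (real-time) gating are out of scope; binning and view-sharing
reconstruction are included, constrained reconstruction itself is not.
See the methods vignette (`vignettes/haptic-methods.Rmd`) for the full
model description, parameter rationale and limitations.
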