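---
title: "Pilot-tone navigator extraction and interference cancellation: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pilot-tone navigator extraction and interference cancellation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(haptic)
```

This vignette is the package's own account of its science: the signal
model, what each stage assumes, which tunables matter and why their
defaults are what they are, what the synthetic generator does and does
not emulate, and where the design was genuinely open.

## 1. Signal model

A pilot-tone (PT) transmitter emits a continuous carrier offset
`f_off` (default 400 kHz) from the imaging center frequency. Body motion
modulates the coupling between transmitter and each receive coil, so the
complex samples of readout line `l`, coil `c` contain

```
A_c(t_l) * exp(i * (2*pi*f_off*tau + psi_l + phi_c))
```

with per-line amplitude

```
A_c(t) = A0_c * (1 + m_resp,c * r(t) + m_card,c * c(t) + eps * g(theta(t)))
```

- `r(t)`, `c(t)`: unit-scale respiratory and cardiac waveforms;
- `m_resp,c`, `m_card,c`: per-coil modulation depths (fractions of the
  baseline `A0_c`);
- `g(theta)`: a smooth periodic function of the spiral-arm angle, the
  trajectory-dependent (eddy-current-like) amplitude deviation. It
  originates in the scanner and receive chain, so it is common to
  imaging and sniffer channels; only the motion terms are specific to
  coils that see the imaging volume;
- `psi_l`: the generator phase. The generator is not synchronized to the
  scanner, so `psi_l` is incoherent from line to line (while common to
  all coils within a line); the pipeline therefore uses only the carrier
  amplitude and discards phase throughout.

Besides the tonal carrier, a real generator leaks broadband noise that
scales with its output amplitude. The model splits this into a *coherent*
component (one common source, coupled into every coil with a per-coil
gain — removable by sniffer-based cancellation) and an *incoherent*
per-coil component (receiver-local effects such as quantization that no
external reference can predict — the irreducible noise cost of a high
carrier amplitude). The incoherent term is what makes the noise ratio
grow monotonically with PT amplitude even under ideal cancellation.

## 2. Pipeline stages and their parameters

### Carrier estimation (`estimate_carrier`)

Per line: the coil-combined (sum of per-coil magnitudes) spectrum of the
Hann-windowed, 4x zero-padded readout is peak-searched within
+/- 30 kHz of the nominal offset; the peak is refined by quadratic
interpolation of log-magnitude and one further three-point parabolic
pass on projection magnitudes. Amplitude per coil is the magnitude of
the projection of the *unwindowed* samples onto the refined frequency,
normalized by the sample count, so a pure tone of amplitude `A` returns
exactly `A`. One shared frequency per line stabilizes low-amplitude
coils ("first frequency, then amplitude"). Lines whose peak does not
exceed 3x the in-band median are flagged carrier-lost and linearly
interpolated in the waveform, keeping the uniform-TR sampling the
filters assume. In the noiseless limit the estimator inverts the
simulator's amplitude model to ~1e-15 relative error.

### Angle detrending (`detrend_by_angle`)

After golden-angle reordering, physiological motion is broadband in the
angle dimension while `g(theta)` is low-order periodic. The trend is
estimated by least-squares harmonic regression on
`cos(k*theta), sin(k*theta)` up to order 8 (comfortably above the
simulated eddy order 3, far below motion bandwidth) and subtracted;
harmonic regression is an angular low-pass that is exact for trends
within the cutoff and indifferent to ties or non-uniform angle coverage.
Order 0 disables the stage.

### Denoising and band splitting

Savitzky-Golay smoothing with window 21 samples (~112 ms at
TR = 5.32 ms) and polynomial order 3: long enough to suppress broadband
amplitude noise, shorter than half the 0.375-s cardiac refractory window
so upstrokes are not blunted. Band splitting is a whole-record Fourier
mask (non-causal by design — this is a retrospective method) with
raised-cosine transitions spanning 20% of each edge: respiratory
0.05-0.9 Hz, cardiac 1-20 Hz. Records shorter than one period of the low
edge are rejected; the default 90-s and sweep 30-s records both pass.

### Channel selection and source extraction

Correlation is the maximum-magnitude normalized cross-correlation over
lags of +/- 1 s (respiratory) or +/- 0.1 s (cardiac) to absorb inter-coil
delays; zero-lag only would penalize coils far from the seed.
Respiratory: the coil with the highest total correlation to the others
seeds the set; coils above 0.9 are accepted; SOBI (whitening followed by
joint diagonalization of 50 time-lagged covariance matrices, Jacobi
sweeps to 1e-8) separates sources, and the source with the largest
spectral-power fraction inside the respiratory band is the navigator.
SOBI returns sources in no meaningful order, so in-band power is the
selection heuristic; which source the original method used is not
determinable, making this a documented package decision.
Cardiac: the seed coil is user-supplied (physical proximity to the
heart) or `"auto"` (maximum cardiac-band power — a documented deviation
for unattended runs); the threshold sweeps 0.90 down to 0.50 in 0.05
steps until at least three coils are accepted. The stop rule follows the
literal "more than two"; because accepted counts of two are also
plausible in practice, the final threshold falls back to two members
before erroring. PC1 of the accepted coils is the cardiac navigator.
Both navigators are unit-variance with polarity fixed by positive
correlation with the channel mean (respiratory) or the seed coil
(cardiac); eigenvalue ties resolve deterministically through the
symmetric eigensolver's ordering.

### EDITER cancellation (`editer_fit` / `editer_apply`)

Windows of 50 lines (~266 ms) assume a static interference path within
the window. Per window and imaging coil, least squares expresses the
coil's samples as sniffer samples convolved with FIR kernels of +/- 7
in-readout taps (cross-line taps available via `delta_lines`, default
off for spiral data, which has no Cartesian line axis). Window size and
tap count are identifiability-driven: 50 x 128 samples against 45
unknowns. The normal equations are solved through an eigendecomposition
with a relative spectral cutoff of 1e-10: a pure tone cannot identify
all taps, and the minimum-norm solution leaves predictions on fitted
data unchanged while avoiding numerically explosive kernels. Windows
whose kernels are similar under `2*Re<ka,kb>/(|ka|^2+|kb|^2)` (> 0.9)
are pooled and refit; this similarity is deliberately sensitive to gain
and phase changes of the path, so a window whose coupling truly changed
is never pooled. The sinusoid-model baseline estimates one global
frequency, then per-line per-coil complex amplitudes by projection;
because physiological modulation is frozen within a 128-us readout it
removes the tonal carrier essentially completely — its real weakness,
reproduced here, is the broadband leakage it cannot model.

### Trigger detection and scoring

The normalized derivative rule: central differences, affine
normalization mapping the 10th percentile to 0 and the 98th to 1,
strict local maxima, a 0.375-s minimum separation (160 bpm ceiling;
the larger peak wins a conflict), and topographic prominence > 0.5.
Normalization makes detection invariant to positive affine transforms
of the navigator. Matching uses half-open windows `[R_k, R_k+1)`: first
PT event matches, extras are false positives, an empty window is a false
negative; events before the first or at/after the last reference R-wave
are outside every window and ignored. `n_triggers` counts the reference
R-waves heading a window — the convention under which the arrhythmia
cohort's printed failure rates are exactly recomputable from their
printed counts. Jitter uses the sample SD (n-1); the choice is
undocumented upstream and fixed here for reproducibility.

### Binning and reconstruction

Cardiac bins divide each trigger interval into 20 equal phase fractions;
respiratory bins are 12 equal-count amplitude quantiles of the
navigator (amplitude, not phase, following the retrospective-binning
convention of the reconstruction family this feeds). Gridding is
adjoint Kaiser-Bessel interpolation (oversampling 2, width-4 kernel,
Beatty beta, analytic deapodization) with |k| ramp density compensation —
exact for the simulator's linear-radius spiral, and chosen over Voronoi
weights as trajectory-specific but assumption-free here. View sharing
reconstructs 55-arm footprints every 17 arms; at TR = 5.32 ms these are
292.6 / 90.4 ms (the rounded 300 / 93 ms labels elsewhere follow from
the same arm counts; frame timing here follows the arms). The noise
ratio is the SD of magnitude pixels in a centered circular ROI of 53% of
the FOV — a 16-cm circle on a 30-cm FOV analog — for a noise-only test
image over a no-PT reference. Magnitude statistics are Rayleigh-biased
but ratio-consistent.

## 3. What the generator emulates, and what it does not

Emulated: the modulated off-resonance carrier with per-coil depths and
phases; incoherent generator phase; sniffer channels with zero motion
modulation, no phantom signal, and ~8x carrier coupling (sniffers are
selected to sense interference strongly; small kernels re-inject little
sniffer noise); arm-angle-dependent amplitude deviations common to all
channels; coherent and incoherent broadband leakage proportional to
carrier amplitude; complex Gaussian thermal noise; noise-only scans;
an analytic ellipse phantom with closed-form k-space; regular rhythm
with per-beat RR jitter and an arrhythmic mode with skipped/ectopic
beats; seed determinism throughout.

Not emulated: Bloch dynamics and bSSFP banding, coil-sensitivity
spatial structure, B0 drift, receiver saturation/quantization beyond the
incoherent-leakage abstraction, gradient-impulse-response trajectory
errors, and in-vivo waveform morphology (the cardiac template is a
gamma-like pulse with a fast upstroke — sufficient for a
derivative-based trigger, not a model of a ballistocardiogram).
Passing tests therefore demonstrate correctness of the algorithms under
this physics, not in-vivo performance.

Default study conditions: TR 5.32 ms (187.97 Hz navigator rate), 128
samples/readout at 1 MHz bandwidth, 5 imaging + 3 sniffer coils, 90-s
records (30 s per sweep amplitude, 550 arms per noise image, 64x64
grid) — sized so the full suite and experiments run comfortably on a
single CPU while keeping every estimate well-conditioned. Modulation
depths default to m_card = 0.8% and m_resp = 5% of A0 with PT "volts"
mapped as A0 = 400*V: within the plausible low-field ranges, and
placing the 0.2/0.4 V working points in the same qualitative regime as
the measured trade-off (jitter plateau of a few ms; noise increases of
~5%/~24% at 0.2/0.4 V with EDITER). The amplitude sweep reuses one
physiological truth and one noise realization across amplitudes (a
paired design): trends along the amplitude axis are then not masked by
realization noise. These values were fixed once, before the acceptance
suite was written.

## 4. Numerical choices and degenerate inputs

- Frequency refinement: Hann window for estimation, two-stage parabolic
  interpolation; amplitude read-out unwindowed at the refined frequency.
- Flat trigger waveforms (P98 == P10) yield zero triggers with a warning
  rather than dividing by zero; empty PT series make every window a
  false negative; jitter with fewer than two pairs is NA.
- SOBI covariance rank < 2 falls back to PC1 with a warning; all-zero
  cardiac channels are an error.
- Detrending with fewer distinct angles than harmonic terms shortens the
  order with a warning; order 0 is the exact identity.
- Band edges above Nyquist are clipped with a warning.
- File round-trips are bit-exact: numeric payloads are written with 17
  significant digits (IEEE-754 round-trip), triggers and navigators as
  plain CSV. The acquisition container is a single text file with a JSON
  header and named numeric blocks — portable, diff-able, and
  dependency-free.
- All randomness flows from one run seed expanded per stage by a fixed
  counter scheme, so stages are individually reproducible.

## 5. Known limitations

- EDITER's static-window assumption leaves residual interference where
  the carrier amplitude changes within a window (motion modulation);
  the residual grows with modulation depth and carrier amplitude. This
  is inherent to the method and visible in the sweep's noise ratios.
- Window grouping rarely pools windows on noisy data (the similarity is
  diluted by noise-dominated taps); grouping then behaves conservatively
  — correctness is unaffected, pooled-fit variance reduction is not
  realized.
- The respiratory band's 0.05-Hz lower edge is only ~4.5 cycles in a
  90-s record; very slow drifts are partially indistinguishable from
  respiration.
- Real-time (causal) operation is explicitly out of scope: every filter
  here sees the whole record.
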