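# Synthetic acquisition generator: physiological truth, coupling physics,
# phantom, determinism.

test_that("regular rhythm places the expected number of beats at the set rate", {
  truth <- gen_physio(90, 5.32e-3, heart_rate = list(bpm = 60,
                                                     jitter_frac = 0.03),
                      seed = 11)
  expect_true(abs(length(truth$beat_time) - 90) <= 1)
  iv <- diff(truth$beat_time)
  expect_true(all(iv > 0.375))
  expect_true(all(abs(iv - 1) < 4 * 0.03))   # jittered around 1.0 s
  # waveforms bounded, grids match
  expect_true(all(abs(truth$resp) <= 1))
  expect_equal(length(truth$t), length(truth$card))
})

test_that("zero respiratory amplitude yields an identically zero waveform", {
  truth <- gen_physio(20, 5e-3, resp_amplitude = 0, seed = 2)
  expect_true(all(truth$resp == 0))
})

test_that("physiology generation is seed-deterministic", {
  a <- gen_physio(30, 5.32e-3, rhythm = "arrhythmic", seed = 5)
  b <- gen_physio(30, 5.32e-3, rhythm = "arrhythmic", seed = 5)
  expect_identical(a, b)
  c <- gen_physio(30, 5.32e-3, rhythm = "arrhythmic", seed = 6)
  expect_false(identical(a$beat_time, c$beat_time))
})

test_that("arrhythmic mode disturbs intervals; out-of-band rates are rejected", {
  truth <- gen_physio(60, 5.32e-3, rhythm = "arrhythmic",
                      arrhythmia_rate = 0.3, seed = 9)
  iv <- diff(truth$beat_time)
  expect_gt(stats::sd(iv) / mean(iv), 0.1)   # far above the 3% regular jitter
  expect_error(gen_physio(30, 5.32e-3, heart_rate = list(bpm = 170,
                                                         jitter_frac = 0)),
               "0.5-2.7")
  expect_error(gen_physio(30, 5.32e-3, resp_rate_hz = 0.02), "0.05-0.9")
  expect_error(gen_physio(5, 5.32e-3), ">= 10")
})

test_that("noiseless zero-modulation carrier is constant at A0 per coil", {
  truth <- gen_physio(10, 5e-3, resp_amplitude = 0, seed = 1)
  cp <- make_coupling(3, 2, m_card = 0, m_resp = 0, eddy_eps = 0,
                      leak_coherent = 0, leak_incoherent = 0, seed = 2)
  acq <- simulate_acquisitions(truth, cp, noise_sd = 0, phantom = NULL,
                               seed = 3)
  # cardiac depth is zero, so A_c(t) = A0_c exactly; check raw sample moduli
  for (c in seq_along(cp$A0))
    expect_equal(as.vector(Mod(acq$samples[, c, ])),
                 rep(cp$A0[c], n_lines(acq) * n_samples(acq)),
                 tolerance = 1e-12)
})

test_that("navigator sampling follows TR and lines count follows duration", {
  truth <- gen_physio(10, 5.32e-3, seed = 1)
  expect_equal(length(truth$t), round(10 / 5.32e-3))
  expect_equal(1 / diff(truth$t)[1], 187.97, tolerance = 1e-4)
})

test_that("noiseless carrier amplitudes are recovered in closed form", {
  truth <- gen_physio(10, 5e-3, seed = 4)
  cp <- make_coupling(2, 1, leak_coherent = 0, leak_incoherent = 0, seed = 5)
  acq <- simulate_acquisitions(truth, cp, noise_sd = 0, phantom = NULL,
                               seed = 6)
  est <- estimate_carrier(acq)
  A <- haptic:::true_amplitudes(truth, cp, acq$arm_angle)
  expect_lt(max(abs(est$amp - A) / A), 1e-6)
})

test_that("carrier component scales linearly with A0", {
  truth <- gen_physio(10, 5e-3, seed = 4)
  cp1 <- make_coupling(2, 1, pt_volts = 0.2, leak_coherent = 0,
                       leak_incoherent = 0, seed = 5)
  cp2 <- make_coupling(2, 1, pt_volts = 0.6, leak_coherent = 0,
                       leak_incoherent = 0, seed = 5)
  a1 <- simulate_acquisitions(truth, cp1, noise_sd = 0, phantom = NULL,
                              seed = 6)
  a2 <- simulate_acquisitions(truth, cp2, noise_sd = 0, phantom = NULL,
                              seed = 6)
  expect_equal(a2$samples, a1$samples * 3, tolerance = 1e-12)
})

test_that("noise-only mode carries no phantom energy and simulator is seeded", {
  truth <- gen_physio(10, 5e-3, seed = 4)
  cp <- make_coupling(2, 1, seed = 5)
  n1 <- simulate_acquisitions(truth, cp, noise_sd = 1, noise_only = TRUE,
                              seed = 7, return_components = TRUE)
  expect_true(all(attr(n1, "components")$phantom == 0))
  n2 <- simulate_acquisitions(truth, cp, noise_sd = 1, noise_only = TRUE,
                              seed = 7)
  expect_identical(n1$samples, n2$samples)
  # sniffer coils never carry phantom signal even with the phantom on
  m1 <- simulate_acquisitions(truth, cp, noise_sd = 0, seed = 7,
                              return_components = TRUE)
  comp <- attr(m1, "components")
  expect_true(all(comp$phantom[, sniffer_idx(m1), ] == 0))
  expect_gt(sum(Mod(comp$phantom[, imaging_idx(m1), ])^2), 0)
})

test_that("phantom k-space obeys DC and symmetry oracles", {
  ph <- phantom_model()
  # DC equals the analytic integrated intensity sum(I * pi * a * b)
  dc <- phantom_kspace(ph, 0, 0)
  want <- sum(ph$ellipses$intensity * pi * ph$ellipses$a * ph$ellipses$b)
  expect_equal(Re(dc), want, tolerance = 1e-12)
  expect_equal(Im(dc), 0, tolerance = 1e-12)
  # rasterized image sum converges to the same integral
  img <- phantom_image(ph, 256L)
  expect_equal(sum(img) / 256^2, want, tolerance = 0.02)
  # zero-ellipse phantom has identically zero k-space
  ph0 <- phantom_model(default_ellipses()[0, ])
  expect_true(all(phantom_kspace(ph0, c(0, 3, 5), c(1, -2, 0)) == 0))
  # single centered ellipse: |F| maximal at k = 0
  ph1 <- phantom_model(data.frame(x0 = 0, y0 = 0, a = 0.3, b = 0.2,
                                  angle_deg = 0, intensity = 1))
  kx <- seq(-10, 10, by = 0.5)
  vals <- Mod(phantom_kspace(ph1, kx, kx * 0))
  expect_equal(which.max(vals), which(kx == 0))
})

test_that("arm angles advance by the golden-angle increment modulo 2*pi", {
  truth <- gen_physio(10, 5e-3, seed = 1)
  cp <- make_coupling(2, 1, seed = 2)
  acq <- simulate_acquisitions(truth, cp, noise_sd = 0, phantom = NULL,
                               seed = 3)
  inc <- diff(acq$arm_angle) %% (2 * pi)
  expect_true(all(abs(inc - 137.507764 * pi / 180) < 1e-9))
})
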