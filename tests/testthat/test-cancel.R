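# EDITER interference cancellation and the sinusoid-model baseline.

# Acquisition with one imaging coil equal to a FIR-filtered copy of the
# sniffer channel (plus optional extra signal), for kernel-recovery oracles.
fir_acq <- function(L = 40L, S = 128L, taps = c(2.5), extra = NULL,
                    seed = 1, split_gains = NULL) {
  set.seed(seed)
  sniff <- matrix(complex(real = stats::rnorm(L * S),
                          imaginary = stats::rnorm(L * S)), L, S)
  K <- (length(taps) - 1) / 2
  img <- matrix(0i, L, S)
  for (k in seq_along(taps)) {
    ds <- k - 1 - K
    src <- seq_len(S) - ds
    ok <- src >= 1 & src <= S
    img[, ok] <- img[, ok] + taps[k] * sniff[, src[ok]]
  }
  if (!is.null(split_gains)) {
    half <- L %/% 2
    img[seq_len(half), ] <- split_gains[1] * sniff[seq_len(half), ]
    img[(half + 1):L, ] <- split_gains[2] * sniff[(half + 1):L, ]
  }
  if (!is.null(extra)) img <- img + extra
  samples <- array(0i, c(L, 2, S))
  samples[, 1, ] <- img
  samples[, 2, ] <- sniff
  acquisition_set(samples, (0:(L - 1)) * 0.005,
                  ((0:(L - 1)) * 2.39996) %% (2 * pi), 1e-6, 0.005, 4e5,
                  c("imaging", "sniffer"))
}

test_that("a proportional interference path is recovered to machine precision", {
  acq <- fir_acq(L = 10L, taps = 2.5)
  model <- editer_fit(acq, window_lines = 10L, K = 0L)
  expect_equal(length(model$windows), 1L)
  expect_lt(Mod(model$kernels[[1]][1, 1] - 2.5), 1e-10)
  clean <- editer_apply(model, acq)
  expect_lt(sum(Mod(clean$samples[, 1, ])^2) /
              sum(Mod(acq$samples[, 1, ])^2), 1e-20)
})

test_that("a known 3-tap kernel is identified and interference suppressed > 20 dB", {
  set.seed(61)
  L <- 60L; S <- 128L
  taps <- c(0.4 - 0.2i, 1.5 + 0.5i, -0.3 + 0.1i)
  # desired signal uncorrelated with the sniffer
  desired <- matrix(complex(real = stats::rnorm(L * S, sd = 0.5),
                            imaginary = stats::rnorm(L * S, sd = 0.5)), L, S)
  acq <- fir_acq(L = L, S = S, taps = taps, extra = desired, seed = 62)
  model <- editer_fit(acq, window_lines = 60L, K = 3L)
  # recovered taps sit at offsets -1, 0, +1 within the (2K+1)-tap kernel
  kern <- model$kernels[[1]][, 1]
  expect_lt(max(Mod(kern[3:5] - taps)), 0.02)
  clean <- editer_apply(model, acq)
  interference_before <- acq$samples[, 1, ] - desired
  residual_after <- clean$samples[, 1, ] - desired
  supp_db <- 10 * log10(sum(Mod(interference_before)^2) /
                          sum(Mod(residual_after)^2))
  expect_gt(supp_db, 20)
})

test_that("windows with distinct coupling group into exactly two clusters", {
  acq <- fir_acq(L = 40L, split_gains = c(1 + 0i, 2 + 1i), seed = 63)
  model <- editer_fit(acq, window_lines = 10L, K = 0L,
                      group_corr_threshold = 0.99)
  expect_equal(length(model$windows), 4L)
  expect_equal(length(unique(model$group_id)), 2L)
  expect_equal(model$group_id[1], model$group_id[2])
  expect_equal(model$group_id[3], model$group_id[4])
  expect_false(model$group_id[1] == model$group_id[3])
})

test_that("editer_apply identities: zero kernels and zero sniffers change nothing", {
  acq <- fir_acq(L = 20L, taps = 1.2, seed = 64)
  model <- editer_fit(acq, window_lines = 10L, K = 1L)
  zero_model <- model
  for (w in seq_along(zero_model$kernels))
    zero_model$kernels[[w]][] <- 0i
  expect_identical(editer_apply(zero_model, acq)$samples, acq$samples)

  acq0 <- acq
  acq0$samples[, 2, ] <- 0i
  expect_equal(editer_apply(model, acq0)$samples, acq0$samples)
})

test_that("fit/apply contract: partitions must match and sniffers are required", {
  acq <- fir_acq(L = 20L)
  model <- editer_fit(acq, window_lines = 10L, K = 0L)
  shorter <- subset_lines(acq, 1:15)
  expect_error(editer_apply(model, shorter), "cover")
  no_sniff <- acq
  no_sniff$coil_role <- c("imaging", "imaging")
  expect_error(editer_fit(no_sniff, window_lines = 10L), "sniffer")
  expect_error(editer_fit(acq, window_lines = 1L, K = 64L), "identify")
})

test_that("per-window fitted residual never exceeds input energy (projection)", {
  truth <- gen_physio(10, 5e-3, seed = 65)
  cp <- make_coupling(3, 2, seed = 66)
  acq <- simulate_acquisitions(truth, cp, noise_sd = 1, phantom = NULL,
                               seed = 67)
  model <- editer_fit(acq, window_lines = 50L, K = 7L)
  expect_true(all(model$residual_db <= 1e-9))
})

test_that("cross-line taps extend the model when delta_lines > 0", {
  acq <- fir_acq(L = 20L, taps = 1.1, seed = 68)
  model <- editer_fit(acq, window_lines = 20L, K = 1L, delta_lines = 1L)
  expect_equal(nrow(model$kernels[[1]]), 1L * 3L * 3L)
  clean <- editer_apply(model, acq)
  expect_lt(sum(Mod(clean$samples[, 1, ])^2) /
              sum(Mod(acq$samples[, 1, ])^2), 1e-15)
})

test_that("model subtraction removes a static pure tone to numerical precision", {
  amp <- matrix(3, 40, 2)
  f_bin <- 50 / (128 * 1e-6)             # on-grid tone
  acq <- make_tone_acq(amp, f_bin, roles = c("imaging", "sniffer"))
  clean <- model_subtract(acq)
  expect_lt(sum(Mod(clean$samples[, 1, ])^2) /
              sum(Mod(acq$samples[, 1, ])^2), 1e-12)
  # sniffer channel is untouched by the baseline method
  expect_identical(clean$samples[, 2, ], acq$samples[, 2, ])
})

test_that("per-line projection tracks slow amplitude modulation exactly", {
  # physiological modulation is frozen within one 128-us readout, so the
  # per-line complex-amplitude fit removes a modulated carrier as completely
  # as a static one; what the baseline cannot remove is broadband leakage
  L <- 400L; TR <- 5.32e-3
  f_bin <- 50 / (128 * 1e-6)
  t <- (0:(L - 1)) * TR
  static <- make_tone_acq(matrix(10, L, 1), f_bin, TR = TR)
  modded <- make_tone_acq(matrix(10 * (1 + 0.3 * sin(2 * pi * 1.2 * t))),
                          f_bin, TR = TR)
  e_in <- sum(Mod(modded$samples)^2)
  expect_lt(sum(Mod(model_subtract(static)$samples)^2) / e_in, 1e-12)
  expect_lt(sum(Mod(modded <- model_subtract(modded)$samples)^2) / e_in, 1e-12)
})

test_that("model subtraction cannot remove broadband generator leakage", {
  set.seed(70)
  L <- 200L; S <- 128L
  f_bin <- 50 / (S * 1e-6)
  acq <- make_tone_acq(matrix(10, L, 1), f_bin, S = S)
  leak <- array(complex(real = stats::rnorm(L * S, sd = 0.3),
                        imaginary = stats::rnorm(L * S, sd = 0.3)), c(L, 1, S))
  acq$samples <- acq$samples + leak
  clean <- model_subtract(acq)
  leak_energy <- sum(Mod(leak)^2)
  res <- sum(Mod(clean$samples)^2)
  # residual is the leakage (minus the sliver of it absorbed by the per-line
  # carrier projection, at most one complex dof of S per line)
  expect_gt(res, leak_energy * (1 - 3 / S))
  expect_lt(res, leak_energy * 1.05)
})

test_that("EDITER and model subtraction agree on static-tone interference", {
  set.seed(69)
  L <- 40L; S <- 128L
  f_bin <- 50 / (S * 1e-6)
  acq <- make_tone_acq(matrix(c(rep(4, L), rep(2, L)), L, 2), f_bin,
                       roles = c("imaging", "sniffer"),
                       phase = c(0.3, 1.1))
  ed <- editer_apply(editer_fit(acq, window_lines = L, K = 0L), acq)
  ms <- model_subtract(acq)
  e_in <- sum(Mod(acq$samples[, 1, ])^2)
  expect_lt(sum(Mod(ed$samples[, 1, ])^2) / e_in, 1e-12)
  expect_lt(sum(Mod(ms$samples[, 1, ])^2) / e_in, 1e-12)
})

test_that("EDITER removes almost no desired signal (phantom preservation)", {
  # static coupling isolates the desired-signal-removal effect: the fitted
  # kernels then cancel the interference exactly, and whatever else changes
  # is phantom signal absorbed by the kernel fit. With window grouping the
  # pooled fit spans the whole record, so the absorbed fraction of the
  # phantom is the subspace ratio P/N of the pooled least squares.
  truth <- gen_physio(30, 5.32e-3, seed = 71)
  cp <- make_coupling(4, 3, m_card = 0, m_resp = 0, eddy_eps = 0,
                      leak_incoherent = 0, seed = 72)
  acq <- simulate_acquisitions(truth, cp, noise_sd = 0, seed = 73,
                               return_components = TRUE)
  comp <- attr(acq, "components")
  # a noiseless static tone leaves degenerate tap directions, so the
  # minimum-norm fallback is expected here
  model <- suppressWarnings(editer_fit(acq, window_lines = 50L, K = 7L))
  expect_equal(length(unique(model$group_id)), 1L)   # static -> one cluster
  clean <- editer_apply(model, acq)
  ii <- which(acq$coil_role == "imaging")
  # k-space: the absorbed fraction is the pooled-LS subspace ratio, a couple
  # of percent at most
  kdist <- rms(clean$samples[, ii, ] - comp$phantom[, ii, ]) /
    rms(comp$phantom[, ii, ])
  expect_lt(kdist, 0.03)
  # reconstruction: the absorbed component carries the generator's random
  # per-line phase, so it adds incoherently in the image while the phantom
  # adds coherently — the phantom-only reconstruction error is < 1% RMS
  ph_acq <- acq
  ph_acq$samples <- comp$phantom
  img_clean <- grid_recon(clean, grid = 64L)
  img_ref <- grid_recon(ph_acq, grid = 64L)
  idist <- rms(img_clean$pixels - img_ref$pixels) / rms(img_ref$pixels)
  expect_lt(idist, 0.01)
})
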