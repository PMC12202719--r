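# Trigger detection, R-wave matching, gating metrics, binning.

test_that("a constant waveform yields no triggers, with a warning", {
  expect_warning(trig <- detect_triggers(rep(1, 1000), fs = 188), "flat")
  expect_length(trig$event_time, 0)
})

test_that("the 0.375-s window keeps only the larger of two close peaks", {
  fs <- 200
  t <- (0:(4 * fs - 1)) / fs
  # integrate two derivative bumps 0.2 s apart so the derivative peaks there
  d <- 0.05 + stats::dnorm(t, 1.0, 0.02) * 0.8 + stats::dnorm(t, 1.2, 0.02) * 1
  x <- cumsum(d) / fs
  trig <- detect_triggers(x, fs)
  in_pair <- trig$event_time[trig$event_time > 0.8 & trig$event_time < 1.4]
  expect_length(in_pair, 1L)
  expect_lt(abs(in_pair - 1.2), 0.05)   # the larger (later) peak survives
})

test_that("detection matches the brute-force oracle on a 60-s cardiac train", {
  truth <- gen_physio(60, 1 / 188, heart_rate = list(bpm = 60,
                                                     jitter_frac = 0.03),
                      seed = 81)
  set.seed(82)
  # light noise: the detector always sees a band-limited, denoised navigator
  nav <- truth$card + 0.005 * stats::rnorm(length(truth$card))
  trig <- detect_triggers(nav, 188)
  oracle <- oracle_triggers(nav, 188)
  expect_equal(trig$event_time, oracle)
  expect_true(abs(length(trig$event_time) - 60) <= 1)
  # one trigger at the upstroke of each beat
  m <- match_triggers(trig, trigger_series(truth$beat_time, "truth"))
  expect_lte(length(m$false_positive_times) + length(m$false_negative_ref_times),
             1)
})

test_that("detection is invariant to positive affine transforms", {
  truth <- gen_physio(30, 1 / 188, seed = 83)
  set.seed(84)
  nav <- truth$card + 0.1 * stats::rnorm(length(truth$card))
  a <- detect_triggers(nav, 188)
  b <- detect_triggers(5.7 * nav + 3.1, 188)
  expect_identical(a$event_time, b$event_time)
})

test_that("matching follows the half-open interval rule", {
  ref <- trigger_series(seq(0, 10, by = 1), "ECG")
  # shifted copies match one-to-one
  pt <- trigger_series(seq(0, 10, by = 1)[-11] + 0.12, "PT")
  m <- match_triggers(pt, ref)
  expect_equal(nrow(m$pairs), 10L)
  expect_length(m$false_positive_times, 0)
  expect_length(m$false_negative_ref_times, 0)
  expect_equal(m$pairs$pt_time - m$pairs$ref_time, rep(0.12, 10))

  # three PT events inside one interval: first matches, two false positives
  pt3 <- trigger_series(c(0.2, 1.2, 2.2, 2.5, 2.8, 3.2), "PT")
  m3 <- match_triggers(pt3, trigger_series(0:4, "ECG"))
  expect_equal(nrow(m3$pairs), 4L)
  expect_equal(m3$false_positive_times, c(2.5, 2.8))

  # a missing beat is exactly one false negative, others unaffected
  pt_miss <- trigger_series(c(0.2, 1.2, 3.2, 4.2), "PT")
  m_miss <- match_triggers(pt_miss, trigger_series(0:5, "ECG"))
  expect_equal(m_miss$false_negative_ref_times, 2)
  expect_equal(nrow(m_miss$pairs), 4L)

  # events outside [R_1, R_last) are ignored
  pt_out <- trigger_series(c(0.5, 1.5, 9.9, 10.4), "PT")
  m_out <- match_triggers(pt_out, trigger_series(1:10, "ECG"))
  expect_equal(nrow(m_out$pairs) + length(m_out$false_positive_times), 2L)
})

test_that("matching conserves events (hand-enumerated 10-beat oracle)", {
  set.seed(85)
  ref_t <- cumsum(stats::runif(11, 0.7, 1.3))
  pt_t <- sort(c(ref_t[-11] + 0.1, ref_t[3] + 0.4, ref_t[7] + 0.5))
  pt_t <- pt_t[pt_t != ref_t[5] + 0.1]          # drop one beat
  m <- match_triggers(trigger_series(pt_t, "PT"),
                      trigger_series(ref_t, "ECG"))
  in_scope <- pt_t[pt_t >= ref_t[1] & pt_t < ref_t[11]]
  expect_equal(nrow(m$pairs) + length(m$false_positive_times),
               length(in_scope))
  expect_equal(nrow(m$pairs) + length(m$false_negative_ref_times),
               length(ref_t) - 1L)
})

test_that("gating metrics implement the delay, jitter and failure-rate formulas", {
  mk <- function(delays_ms, n_windows, n_fp = 0, n_fn = 0) {
    structure(list(
      pairs = data.frame(ref_time = seq_along(delays_ms),
                         pt_time = seq_along(delays_ms) + delays_ms / 1e3),
      false_positive_times = rep(0.5, n_fp),
      false_negative_ref_times = rep(1, n_fn),
      n_windows = n_windows), class = "haptic_match")
  }
  r <- gating_metrics(mk(rep(100, 5), 5))
  expect_equal(r$mean_delay_ms, 100)
  expect_equal(r$jitter_ms, 0)
  r2 <- gating_metrics(mk(c(100, 110, 120), 3))
  expect_equal(r2$mean_delay_ms, 110)
  expect_equal(r2$jitter_ms, 10)       # sample SD, n-1 denominator
  r3 <- gating_metrics(mk(100, 1))
  expect_true(is.na(r3$jitter_ms))
  expect_equal(r3$mean_delay_ms, 100)
  r4 <- gating_metrics(mk(rep(90, 66), 80, n_fp = 12, n_fn = 2))
  expect_equal(r4$failure_rate_pct, 100 * 14 / 80)
})

test_that("cardiac bins split each RR interval into equal phases", {
  line_time <- seq(0, 10, by = 0.01)
  triggers <- trigger_series(seq(0.5, 9.5, by = 1), "PT")
  bins <- assign_bins(stats::runif(length(line_time)), triggers, line_time,
                      n_card = 20L)
  assigned <- !is.na(bins$card_bin)
  expect_true(all(line_time[!assigned] < 0.5 | line_time[!assigned] >= 9.5))
  counts <- table(bins$card_bin)
  expect_equal(length(counts), 20L)
  expect_lte(diff(range(counts)), 9 * 1)   # 9 intervals, +/-1 line per bin
  # phase formula oracle on a specific line
  i <- which.min(abs(line_time - 1.77))    # 0.27 into the [1.5, 2.5) interval
  expect_equal(bins$card_bin[i], floor(20 * (line_time[i] - 1.5) / 1))
})

test_that("respiratory bins are equal-count amplitude quantiles", {
  nav <- seq(-1, 1, length.out = 1200)    # monotone ramp
  bins <- assign_bins(nav, trigger_series(c(0, 1), "PT"),
                      seq(0, 6.388, length.out = 1200), n_resp = 12L)
  counts <- table(bins$resp_bin)
  expect_equal(length(counts), 12L)
  expect_lte(diff(range(counts)), 1)
  expect_true(all(diff(bins$resp_bin) >= 0))   # contiguous blocks on a ramp
})

test_that("fewer than two triggers leaves all cardiac bins unassigned", {
  bins <- assign_bins(stats::runif(100), trigger_series(5, "PT"),
                      seq(0, 9.9, by = 0.1))
  expect_true(all(is.na(bins$card_bin)))
})
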