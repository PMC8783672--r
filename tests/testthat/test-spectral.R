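test_that("band shares do exact bin-membership accounting", {
  freqs <- seq(0.5, 29.5, by = 1)
  # uniform TFR across the 30 1-Hz-step bins
  tfr <- matrix(1, nrow = 30, ncol = 10, dimnames = list(freqs, NULL))
  sh <- band_shares(tfr)
  expect_equal(unname(sh["theta"]), 4 / 30)
  expect_equal(unname(sh["alpha"]), 4 / 30)
  expect_equal(unname(sh["beta"]), 14 / 30)
  expect_lte(sum(sh), 1)
  # arbitrary matrix: shares equal the explicit bin sums
  set.seed(51)
  tfr2 <- matrix(rlnorm(30 * 7), nrow = 30, dimnames = list(freqs, NULL))
  sh2 <- band_shares(tfr2)
  p <- rowMeans(tfr2)
  expect_equal(unname(sh2["beta"]),
               sum(p[freqs >= 16.5 & freqs <= 29.5]) / sum(p))
})

test_that("a 6 Hz tone concentrates in theta and matches the convolution oracle", {
  rec <- tone_recording(6, dur = 30, tone_from = 10)
  ev <- list(onset_s = 10)
  tfr <- event_tfr(rec, ev)
  sh <- band_shares(tfr)
  expect_gt(sh["theta"] / (sh["theta"] + sh["alpha"] + sh["beta"]), 0.8)
  # brute-force time-domain Morlet convolution at mid-event samples
  fs <- rec$sampling_rate
  cfg <- spectral_config()
  x <- rec$channels[, "Fz"]
  at <- round((11.5 + 0:3 * 0.25) * fs)
  for (f in c(5.5, 6.5, 10.5)) {
    row <- which(cfg$freqs == f)
    direct <- bf_morlet_power(x, fs, f, cfg$n_cycles, at)
    got <- morlet_tfr(x, fs, cfg$freqs, cfg$n_cycles)[row, at]
    expect_equal(unname(got), unname(direct), tolerance = 1e-6)
  }
})

test_that("stationary signals are nulled by baseline correction", {
  set.seed(52)
  rec <- tone_recording(10, dur = 30, tone_from = 0, amp = 1)
  tfr <- event_tfr(rec, list(onset_s = 10))
  # event window identical to baseline: subtraction leaves ~nothing anywhere
  raw <- morlet_tfr(rec$channels[, "Fz"], 200, spectral_config()$freqs)
  expect_lt(max(tfr) / max(raw), 0.02)
})

test_that("events too close to the recording edge raise margin-error", {
  rec <- tone_recording(6, dur = 10, tone_from = 0)
  expect_error(event_tfr(rec, list(onset_s = 0.2)), "margin-error")
  expect_error(event_tfr(rec, list(onset_s = 8)), "margin-error")
  expect_error(event_tfr(rec, list(onset_s = 5),
                         spectral_config(channel = "Cz")),
               "channel-not-found")
})

test_that("type profiles average events and are invariant to rescaling", {
  sim <- simulate_psg(small_sim_config(seed = 14, per_type = 3L))
  emg <- emg_tone_flags(emg_signal(sim$recording),
                        sim$recording$sampling_rate)
  truth <- classify_events(sim$truth, sim$hypnogram, emg)
  prof <- type_relative_power(sim$recording, truth)
  expect_s3_class(prof, "spectral_profile")
  expect_true(all(prof$rel_power >= 0 & prof$rel_power <= 1))
  agg <- tapply(prof$rel_power, prof$type, sum)
  expect_true(all(agg <= 1 + 1e-12))
  # amplitude rescaling leaves shares unchanged
  rec2 <- sim$recording
  rec2$channels <- rec2$channels * 250
  prof2 <- type_relative_power(rec2, truth)
  expect_equal(prof$rel_power, prof2$rel_power)
  # averaging idempotence: duplicating an event leaves its profile unchanged
  one <- truth[which(truth$type == "T-M+")[1], ]
  two <- arousal_events(rbind(as.data.frame(one),
                              transform(as.data.frame(one),
                                        onset_s = onset_s + 60)))
  two$type <- one$type; two$rem_discarded <- FALSE
  p1 <- type_relative_power(sim$recording, one)
  # same event twice at different times: shares stay close to the single-event
  # profile only if both copies see similar signal; instead duplicate exactly:
  dup <- arousal_events(rbind(as.data.frame(one), as.data.frame(one)),
                        check = FALSE)
  p2 <- type_relative_power(sim$recording, dup)
  expect_equal(p1$rel_power, p2$rel_power)
})

test_that("planted spectral contrasts are recovered per type", {
  sim <- simulate_psg(small_sim_config(seed = 15, per_type = 4L,
                                       duration_h = 1.5))
  emg <- emg_tone_flags(emg_signal(sim$recording),
                        sim$recording$sampling_rate)
  truth <- classify_events(sim$truth, sim$hypnogram, emg)
  prof <- type_relative_power(sim$recording, truth)
  g <- function(ty, bd) prof$rel_power[prof$type == ty & prof$band == bd]
  # T-M+ planted beta-dominant, T+M- planted theta-dominant
  expect_gt(g("T-M+", "beta"), g("T+M-", "beta"))
  expect_gt(g("T+M-", "theta"), g("T-M+", "theta"))
})
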