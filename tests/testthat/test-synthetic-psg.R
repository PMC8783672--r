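test_that("identical seeds reproduce the night bit for bit", {
  cfg <- small_sim_config(seed = 91, per_type = 1L, duration_h = 0.5)
  s1 <- simulate_psg(cfg)
  s2 <- simulate_psg(cfg)
  expect_identical(s1$recording$channels, s2$recording$channels)
  expect_identical(as.data.frame(s1$truth), as.data.frame(s2$truth))
  expect_identical(unclass(s1$hypnogram), unclass(s2$hypnogram))
  s3 <- simulate_psg(small_sim_config(seed = 92, per_type = 1L,
                                      duration_h = 0.5))
  expect_false(identical(s1$recording$channels, s3$recording$channels))
})

test_that("an explicit plan is echoed as ground truth", {
  hyp <- hypnogram(rep("N2", 40))                # 20 min, no transitions
  cfg <- small_sim_config(seed = 93, duration_h = 1 / 3)
  cfg$stage_sequence <- hyp
  cfg$arousal_plan <- data.frame(onset_s = 300, duration_s = 5,
                                 type = "T-M+")
  sim <- simulate_psg(cfg)
  expect_equal(nrow(sim$truth), 1L)
  expect_equal(sim$truth$onset_s, 300)
  expect_equal(sim$truth$t_status, "T-")
  expect_equal(sim$truth$m_status, "M+")
})

test_that("invalid plans are rejected", {
  hyp <- hypnogram(rep("N2", 40))
  cfg <- small_sim_config(seed = 94, duration_h = 1 / 3)
  cfg$stage_sequence <- hyp
  cfg$arousal_plan <- data.frame(onset_s = c(300, 305), duration_s = c(5, 5),
                                 type = "T-M-")
  expect_error(simulate_psg(cfg), "plan-error")   # < 10 s apart
  cfg$arousal_plan <- data.frame(onset_s = 300, duration_s = 20,
                                 type = "T-M-")
  expect_error(simulate_psg(cfg), "plan-error")   # duration outside [3, 15]
  cfg$arousal_plan <- data.frame(onset_s = 300, duration_s = 5,
                                 type = "T+M-")
  expect_error(simulate_psg(cfg), "plan-error")   # no stage change nearby
})

test_that("planted boosts clear twice the surrounding local median", {
  cfg <- small_sim_config(seed = 95, per_type = 2L, band_boost = 4,
                          secondary_boost = 1)
  sim <- simulate_psg(cfg)
  bp <- compute_band_powers(sim$recording)
  det_band <- c(beta = "beta", theta = "theta_low", alpha = "alpha_broad")
  primary <- c("T-M+" = "beta", "T+M-" = "theta", "T+M+" = "beta",
               "T-M-" = "alpha")
  for (r in seq_len(nrow(sim$truth))) {
    ev <- sim$truth[r, ]
    b <- det_band[[primary[[ev$type]]]]
    span <- (ev$onset_s + 1):(ev$onset_s + ev$duration_s)
    around <- setdiff(max(1, ev$onset_s - 30):min(bp$n_epochs,
                                                  ev$onset_s + ev$duration_s + 30),
                      span)
    ratio <- mean(bp$power[span, b, "Fz"]) /
      bf_median(bp$power[around, b, "Fz"])
    expect_gt(ratio, 2)
  }
})

test_that("the background spectrum of quiet epochs matches the configured comb", {
  cfg <- small_sim_config(seed = 96, per_type = 0L, duration_h = 1.5,
                          noise_rms = 0.05, channel_gain_range = c(1, 1))
  sim <- simulate_psg(cfg)
  fs <- sim$recording$sampling_rate
  x <- sim$recording$channels[, "Fz"]
  st <- rep(unclass(sim$hypnogram), each = 30)
  amp <- arousalscape:::stage_amplitudes(cfg$background_spectrum)
  bands <- detection_config()$bands
  # rectangular-window DFT is leakage-free for the integer-frequency
  # background, so measured band power should equal the configured
  # sum(A^2)/2 times the DFT scale N^2/2, up to the small noise floor
  rect_band_power <- function(seg, band) {
    n <- length(seg)
    tot <- 0
    for (k in band[1]:band[2]) {
      re <- sum(seg * cos(-2 * pi * k * (0:(n - 1)) / n))
      im <- sum(seg * sin(-2 * pi * k * (0:(n - 1)) / n))
      tot <- tot + re^2 + im^2
    }
    tot
  }
  for (stage in c("N2", "N3", "REM")) {
    idx <- which(st == stage)
    idx <- idx[seq_len(length(idx) - 20)][-seq_len(20)]  # clear border ramps
    if (length(idx) < 100) next
    use <- idx[seq(1, length(idx), length.out = 100)]
    for (b in names(bands)) {
      meas <- vapply(use, function(e) {
        rect_band_power(x[((e - 1) * fs + 1):(e * fs)], bands[[b]])
      }, 0)
      ref <- arousalscape:::comb_band_power(amp[, stage], bands[[b]]) *
        fs^2 / 2
      expect_lt(abs(bf_median(meas) - ref) / ref, 0.10)
    }
  }
})

test_that("a quiet night produces at most a minimal false-positive floor", {
  cfg <- small_sim_config(seed = 97, per_type = 0L, duration_h = 2)
  sim <- simulate_psg(cfg)
  ev <- detect_arousals(sim$recording, sim$hypnogram)
  expect_lte(nrow(ev) / 2, 2)                    # <= 2 false events per hour
})

test_that("cohort generation is deterministic, parameterized and degenerate-safe", {
  cfg <- cohort_config(seed = 31, n_subjects = 30)
  c1 <- simulate_cohort(cfg)
  c2 <- simulate_cohort(cfg)
  expect_identical(c1$abeta_centiloid, c2$abeta_centiloid)
  expect_identical(attr(c1, "params")$beta_abeta_TmMp, -2.3)
  expect_true(all(c1[, c("dens_TpMp", "dens_TpMm", "dens_TmMp",
                         "dens_TmMm")] > 0))
  expect_equal(mean(c1$cognition_global), 0, tolerance = 1e-12)
  tiny <- simulate_cohort(cohort_config(seed = 32, n_subjects = 2))
  expect_equal(nrow(tiny), 2L)                   # generator accepts, models may refuse
  expect_error(fit_abeta_model(tiny), "at least 10")
})

test_that("end-to-end psg cohort mode measures densities from detected events", {
  co <- simulate_cohort(cohort_config(seed = 33, n_subjects = 2),
                        mode = "psg",
                        psg_config = small_sim_config(seed = 1, per_type = 1L,
                                                      duration_h = 0.5))
  expect_equal(nrow(co), 2L)
  dens <- as.matrix(co[, c("dens_TpMp", "dens_TpMm", "dens_TmMp",
                           "dens_TmMm")])
  expect_true(all(dens >= 0))
  expect_gt(sum(dens), 0)
})
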