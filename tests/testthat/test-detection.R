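test_that("global thresholds are per-band, per-channel whole-night medians", {
  pw <- array(0, dim = c(61, 3, 1))
  pw[, 1, 1] <- c(1:5, rep(3, 56))
  pw[, 2, 1] <- 7
  pw[, 3, 1] <- rlnorm(61)
  bp <- make_bp(pw)
  g <- global_thresholds(bp)
  expect_equal(g["theta_low", 1], 3)
  expect_equal(g["alpha_broad", 1], 7)
  expect_equal(g["beta", 1], bf_median(pw[, 3, 1]))
})

test_that("constant power yields no candidates (strict inequality)", {
  pw <- array(5, dim = c(120, 3, 2))
  bp <- make_bp(pw)
  thr <- local_thresholds(bp)
  ev <- assemble_events(bp, thr, hypnogram(rep("N2", 4)))
  expect_equal(nrow(ev), 0L)
})

test_that("local thresholds select quiet epochs with 10-epoch flanks and edge rule", {
  set.seed(21)
  pw <- array(rlnorm(90 * 3), dim = c(90, 3, 1))
  emg <- rep(FALSE, 90)
  emg[31:60] <- TRUE                            # window 2 interior all active
  bp <- make_bp(pw, emg)
  thr <- local_thresholds(bp)
  # window 2: median over nearest 10 quiet epochs before (21:30) and after (61:70)
  expect_equal(thr$local[1, 1, 2], bf_median(pw[c(21:30, 61:70), 1, 1]))
  # first window: fewer than 10 preceding quiet epochs exist; uses all within + after
  expect_equal(thr$local[1, 1, 1], bf_median(pw[c(1:30, 61:70), 1, 1]))
  # all quiet + constant power: every local median equals the constant
  bpc <- make_bp(array(4, dim = c(90, 3, 1)))
  thrc <- local_thresholds(bpc)
  expect_true(all(thrc$local == 4))
})

test_that("fully EMG-active recordings fall back to the global median with warning", {
  pw <- array(rlnorm(90 * 3), dim = c(90, 3, 1))
  bp <- make_bp(pw, emg_active = rep(TRUE, 90))
  expect_warning(thr <- local_thresholds(bp), "fallback")
  expect_equal(thr$fallback_windows, 1:3)
  expect_equal(thr$local[, 1, 2], global_thresholds(bp)[, 1])
})

test_that("run length, separation merging and wake-onset discard follow the rules", {
  base <- array(1, dim = c(120, 3, 1))
  hyp <- hypnogram(rep("N2", 4))
  mk <- function(idx) {
    pw <- base
    pw[idx, 1, 1] <- 10                        # >> 2x local and global medians
    make_bp(pw)
  }
  # 3 consecutive suprathreshold epochs -> one 3-s event
  ev <- assemble_events(mk(11:13), local_thresholds(mk(11:13)), hyp)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$onset_s, 10)
  expect_equal(ev$duration_s, 3)
  # 2 consecutive -> nothing
  ev2 <- assemble_events(mk(11:12), local_thresholds(mk(11:12)), hyp)
  expect_equal(nrow(ev2), 0L)
  # two runs 12 s apart stay separate; 8 s apart merge
  far <- mk(c(11:13, 26:28))
  evf <- assemble_events(far, local_thresholds(far), hyp)
  expect_equal(nrow(evf), 2L)
  near <- mk(c(11:13, 22:24))
  evn <- assemble_events(near, local_thresholds(near), hyp)
  expect_equal(nrow(evn), 1L)
  expect_equal(evn$duration_s, 14)
  # onset in a wake epoch is discarded
  hw <- hypnogram(c("W", "N2", "N2", "N2"))
  evw <- assemble_events(mk(11:13), local_thresholds(mk(11:13)), hw)
  expect_equal(nrow(evw), 0L)
  # long events are flagged awakening candidates (span crosses a window
  # boundary so that neither 30-s local median is dominated by the event)
  lng <- mk(23:40)
  evl <- assemble_events(lng, local_thresholds(lng), hyp)
  expect_equal(evl$duration_s, 18)
  expect_true(evl$awakening_candidate)
})

test_that("assemble_events matches the brute-force enumeration on random inputs", {
  set.seed(31)
  for (i in 1:12) {
    n_ep <- sample(c(60, 150, 300), 1)
    bp <- random_bp(n_ep, n_ch = sample(1:3, 1))
    stages <- random_stages(ceiling(n_ep / 30))
    hyp <- hypnogram(stages)
    got <- suppressWarnings(
      assemble_events(bp, local_thresholds(bp), hyp))
    want <- bf_detect(bp$power, bp$emg_active, stages)
    expect_equal(got$onset_s, want$onset_s)
    expect_equal(got$duration_s, want$duration_s)
    expect_equal(got$channels, want$channels)
    expect_equal(got$bands, want$bands)
    expect_equal(got$awakening_candidate, want$awakening_candidate)
  }
})

test_that("raising the local multiplier never increases the event count", {
  set.seed(32)
  bp <- random_bp(300, n_ch = 2)
  hyp <- hypnogram(random_stages(10))
  thr <- local_thresholds(bp)
  counts <- vapply(c(2, 2.5, 3, 4, 6), function(m) {
    nrow(assemble_events(bp, thr, hyp, detection_config(local_multiplier = m)))
  }, 0L)
  expect_true(all(diff(counts) <= 0))
})

test_that("detection is invariant to a global amplitude rescaling", {
  sim <- simulate_psg(small_sim_config(seed = 5, per_type = 2L,
                                       duration_h = 0.5))
  ev1 <- detect_arousals(sim$recording, sim$hypnogram)
  rec2 <- sim$recording
  rec2$channels[, eeg_labels(rec2)] <- rec2$channels[, eeg_labels(rec2)] * 1e3
  ev2 <- detect_arousals(rec2, sim$hypnogram)
  expect_equal(ev1$onset_s, ev2$onset_s)
  expect_equal(ev1$duration_s, ev2$duration_s)
  expect_equal(ev1$bands, ev2$bands)
  expect_equal(ev1$channels, ev2$channels)
  expect_equal(ev1$peak_ratio, ev2$peak_ratio)
})

test_that("detect_arousals recovers planted events on a short night", {
  sim <- simulate_psg(small_sim_config(seed = 8))
  ev <- detect_arousals(sim$recording, sim$hypnogram)
  perf <- evaluate_detection(ev, sim$truth)
  expect_gte(perf$recall, 0.9)
  expect_gte(perf$precision, 0.9)
  expect_error(
    detect_arousals(sim$recording, hypnogram(rep("N2", 10))),
    "pairing-error")
})
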