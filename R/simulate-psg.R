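# Synthetic polysomnography with ground-truth arousals.
#
# The EEG background is a 1-Hz-spaced harmonic comb (random phases drawn
# once per night, deterministic per-stage amplitudes interpolated smoothly
# across stage borders) plus a white-noise floor. A deterministic-amplitude
# background keeps the configured per-stage band powers exact and makes the
# planted arousals -- multiplicative band-power boosts with 100-ms ramps --
# the only suprathreshold structure, which is the intended study condition
# for a detector thresholding on medians. Channels share the comb (scalp
# EEG is strongly correlated across derivations) with per-channel gains and
# independent noise; the EMG is white noise with RMS bursts co-timed with
# M+ events.

#' Per-stage background spectrum defaults
#'
#' Amplitude model per stage: `gain * (f + 1)^(-slope/2)` times Gaussian
#' oscillatory peaks (`1 + g * exp(-(f - f0)^2 / 2)`). Values are
#' calibrated so that adjacent-stage power ratios inside every detection
#' band stay below the detector's local multiplier of 2 -- stage borders in
#' real EEG are not arousals and must not be scored as such.
#'
#' @return named list per stage with `slope`, `gain`, `peaks`
#'   (data frame `f0`, `g`).
#' @export
stage_spectra <- function() {
  pk <- function(f0 = numeric(), g = numeric()) data.frame(f0 = f0, g = g)
  list(
    W   = list(slope = 1.0, gain = 1.00, peaks = pk(10, 0.5)),
    N1  = list(slope = 1.2, gain = 1.00, peaks = pk(c(5.5, 10), c(0.8, 0.3))),
    N2  = list(slope = 1.4, gain = 1.10,
               peaks = pk(c(5.5, 10, 13), c(0.5, 0.3, 1.2))),
    N3  = list(slope = 1.6, gain = 1.25, peaks = pk(c(2, 10), c(1.0, 0.25))),
    REM = list(slope = 1.2, gain = 0.90, peaks = pk(c(5.5, 10), c(0.7, 0.25))))
}

stage_amplitudes <- function(spectra = stage_spectra(), freqs = 1:30) {
  amp <- sapply(spectra, function(s) {
    a <- s$gain * (freqs + 1)^(-s$slope / 2)
    if (nrow(s$peaks)) {
      for (i in seq_len(nrow(s$peaks))) {
        a <- a * (1 + s$peaks$g[i] * exp(-(freqs - s$peaks$f0[i])^2 / 2))
      }
    }
    a
  })
  rownames(amp) <- freqs
  amp                                        # [freq, stage]
}

# analytic band power of the comb for one stage: sum of A^2/2 over the
# integer frequencies inside [lo, hi] (inclusive)
comb_band_power <- function(amp_col, band, freqs = 1:30) {
  sum(amp_col[freqs >= band[1] & freqs <= band[2]]^2) / 2
}

#' Simulation configuration for a synthetic PSG night
#'
#' Defaults mirror the recording conditions the pipeline targets: 200 Hz,
#' 11 EEG derivations plus a submental EMG, an 8-hour night of cyclic
#' sleep. Arousal amplitudes are generator calibration choices: the primary
#' band of each type is boosted `band_boost`-fold in power (secondary band
#' `secondary_boost`-fold), and M+ events carry an EMG burst at
#' `emg_burst_gain` times baseline RMS with 100-ms on/off ramps spanning
#' the full event.
#'
#' @param seed integer; fully determines the night.
#' @param duration_h night length in hours (default 8).
#' @param sampling_rate Hz (default 200).
#' @param eeg_labels EEG channel labels (default the 10-20 set
#'   F3/Fz/F4/C3/Cz/C4/P3/Pz/P4/O1/O2).
#' @param n_per_type named counts of planted arousals per type (default 20
#'   each); ignored when `arousal_plan` is given.
#' @param arousal_plan optional data frame `onset_s`, `duration_s`, `type`
#'   overriding automatic placement (onsets on the 1-s grid; invariants
#'   checked).
#' @param stage_sequence optional [hypnogram()]; default a cyclic template
#'   via [make_cycle_hypnogram()].
#' @param band_boost,secondary_boost power boost factors (defaults 8, 3).
#' @param emg_burst_gain EMG burst RMS multiple (default 4).
#' @param emg_baseline_rms baseline EMG RMS (default 1).
#' @param noise_rms white-noise floor, as a fraction of background RMS
#'   (default 0.15).
#' @param channel_gain_range range of the per-channel multiplicative gain
#'   (default `c(0.85, 1.15)`; set `c(1, 1)` for gain-matched channels).
#' @param background_spectrum per-stage spectrum, see [stage_spectra()].
#' @param min_event_gap minimum spacing between planted onsets and from
#'   pre-existing stage changes, seconds (default 120; comfortably above
#'   the 10-s invariant so that ground-truth typing is unambiguous).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, duration_h = 8, sampling_rate = 200,
                       eeg_labels = c("F3", "Fz", "F4", "C3", "Cz", "C4",
                                      "P3", "Pz", "P4", "O1", "O2"),
                       n_per_type = c("T+M+" = 20L, "T+M-" = 20L,
                                      "T-M+" = 20L, "T-M-" = 20L),
                       arousal_plan = NULL, stage_sequence = NULL,
                       band_boost = 8, secondary_boost = 3,
                       emg_burst_gain = 4, emg_baseline_rms = 1,
                       noise_rms = 0.15, channel_gain_range = c(0.85, 1.15),
                       background_spectrum = stage_spectra(),
                       min_event_gap = 120) {
  stopifnot(band_boost > 1, duration_h > 0, sampling_rate >= 64)
  structure(list(seed = as.integer(seed), duration_h = duration_h,
                 sampling_rate = as.integer(sampling_rate),
                 eeg_labels = eeg_labels, emg_label = "EMG",
                 n_per_type = n_per_type, arousal_plan = arousal_plan,
                 stage_sequence = stage_sequence, band_boost = band_boost,
                 secondary_boost = secondary_boost,
                 emg_burst_gain = emg_burst_gain,
                 emg_baseline_rms = emg_baseline_rms, noise_rms = noise_rms,
                 channel_gain_range = channel_gain_range,
                 background_spectrum = background_spectrum,
                 min_event_gap = min_event_gap),
            class = "sim_config")
}

# spectral bands each arousal type expresses (primary first); profile-band
# edges so the planted contrast is recoverable by type_relative_power()
type_boost_bands <- function() {
  list("T-M+" = c("beta", "alpha"),
       "T+M-" = c("theta", "alpha"),
       "T+M+" = c("beta", "theta"),
       "T-M-" = c("alpha", "beta"))
}

# Injection spans the detector's band (the reporting bands 4.5-7.5 /
# 8.5-11.5 / 16.5-29.5 are strict subsets), so a planted boost g scales
# the detection-band power by exactly g while remaining fully visible to
# the spectral profiling.
profile_band_edges <- function() {
  list(theta = c(3, 7), alpha = c(7, 11), beta = c(16, 30))
}

#' Cyclic template hypnogram
#'
#' Deterministic sequence of ~90-minute sleep cycles: a 5-min sleep
#' latency, N1-N2-N3-N2-REM cycles, and a brief 1-min awakening inside
#' each later cycle, truncated to the requested duration.
#'
#' @param duration_h night length in hours.
#' @return a [hypnogram()].
#' @export
make_cycle_hypnogram <- function(duration_h) {
  n <- round(duration_h * 120)
  cyc1 <- c(rep("W", 10), rep("N1", 10), rep("N2", 40), rep("N3", 40),
            rep("N2", 30), rep("REM", 50))
  cyck <- c(rep("N1", 6), rep("N2", 44), rep("N3", 30), rep("N2", 28),
            rep("W", 2), rep("REM", 70))
  st <- cyc1
  while (length(st) < n) st <- c(st, cyck)
  hypnogram(st[seq_len(n)])
}

alt_stage <- function(s) {
  c(N1 = "N2", N2 = "N1", N3 = "N2", REM = "N1")[[s]]
}

# Place planted arousals, inserting stage flips for T+ events so that
# ground truth agrees with the classifier's half-epoch rule. Returns the
# (possibly modified) hypnogram and the plan.
auto_plan <- function(hyp, n_per_type, min_gap) {
  # stage flips planted for T+ events introduce a second boundary up to
  # 75 s from the T+ onset epoch's midpoint; 120 s keeps every other
  # planted onset > 15 s away from it, so ground-truth T labels stay exact
  min_gap <- max(min_gap, 120)
  st <- unclass(hyp)
  n <- length(st)
  changes <- which(st[-1L] != st[-n])          # boundary after epoch k
  change_t <- 30 * changes
  cand <- which(st != "W")
  cand <- cand[cand > 4L & cand < n - 4L]
  near_change <- vapply(cand, function(k) {
    any(abs(30 * (k - 0.5) - change_t) < min_gap)
  }, TRUE)
  cand <- cand[!near_change]
  cand <- sample(cand)
  need <- rep(names(n_per_type), times = n_per_type)
  need <- sample(need)
  chosen_k <- integer(0)
  plan <- list()
  for (ty in need) {
    m_minus <- grepl("M-", ty, fixed = TRUE)
    ok <- if (m_minus) st[cand] != "REM" else rep(TRUE, length(cand))
    pick <- NA_integer_
    for (i in which(ok)) {
      k <- cand[i]
      if (all(abs(30 * (k - 0.5) - 30 * (chosen_k - 0.5)) >= min_gap)) {
        pick <- i; break
      }
    }
    if (is.na(pick)) {
      stop("plan-error: cannot place ", length(need),
           " arousals with min_event_gap = ", min_gap,
           " in a ", round(n / 120, 1), "-h night")
    }
    k <- cand[pick]
    cand <- cand[-pick]
    chosen_k <- c(chosen_k, k)
    dur <- sample(4:8, 1)
    if (grepl("T+", ty, fixed = TRUE)) {
      if (runif(1) < 0.5 && k >= 2L) {        # first-half variant: flip k, k+1
        a <- alt_stage(st[k])
        st[k:(k + 1L)] <- a
        onset <- 30 * (k - 1L) + sample(2:12, 1)
      } else {                                 # second-half variant: flip k+1, k+2
        a <- alt_stage(st[k])
        st[(k + 1L):(k + 2L)] <- a
        onset <- 30 * (k - 1L) + sample(16:22, 1)
      }
    } else {
      onset <- 30 * (k - 1L) + sample(2:20, 1)
    }
    plan[[length(plan) + 1L]] <- data.frame(onset_s = onset,
                                            duration_s = dur, type = ty)
  }
  plan <- if (length(plan)) do.call(rbind, plan) else
    data.frame(onset_s = numeric(), duration_s = numeric(),
               type = character())
  plan <- plan[order(plan$onset_s), , drop = FALSE]
  rownames(plan) <- NULL
  list(hyp = hypnogram(st), plan = plan)
}

check_plan <- function(plan, hyp) {
  if (nrow(plan) == 0L) return(invisible(TRUE))
  if (!all(plan$type %in% ASCAPE_TYPES)) stop("plan-error: unknown arousal type")
  if (any(plan$duration_s < 3 | plan$duration_s > 15)) {
    stop("plan-error: planned durations must lie in [3, 15] s")
  }
  o <- order(plan$onset_s)
  gaps <- plan$onset_s[o][-1L] -
    (plan$onset_s[o][-nrow(plan)] + plan$duration_s[o][-nrow(plan)])
  if (any(gaps < 10)) stop("plan-error: planned arousals must be >= 10 s apart")
  tcls <- classify_transition(plan$onset_s, hyp)
  want <- ifelse(grepl("T+", plan$type, fixed = TRUE), "T+", "T-")
  if (!all(tcls == want)) {
    stop("plan-error: planned T status inconsistent with the hypnogram")
  }
  invisible(TRUE)
}

cos_ramp_env <- function(len, fs, lo = 0, hi = 1, ramp_s = 0.1) {
  nr <- min(round(ramp_s * fs), floor(len / 2))
  env <- rep(hi, len)
  if (nr > 0) {
    up <- lo + (hi - lo) * (1 - cos(pi * seq_len(nr) / nr)) / 2
    env[seq_len(nr)] <- up
    env[(len - nr + 1L):len] <- rev(up)
  }
  env
}

# Planted events are phase-aligned amplifications of the background's own
# band components: multiplying each in-band harmonic by sqrt(boost) scales
# the band power by exactly `boost` in every 1-s epoch of the event.
# Incoherent injection (new tones or narrowband noise) would interfere
# with the background comb, so the realized per-second boost would be
# random and could even cancel -- planted events must not fade below
# threshold mid-event.

#' Simulate a synthetic PSG night with ground-truth arousals
#'
#' @param config a [sim_config()].
#' @param subject_id subject identifier (default `"sim"`).
#' @return list of class `psg_simulation`: `recording`
#'   (a [psg_recording()]), `hypnogram`, `truth` (ground-truth
#'   [arousal_events()]), and `config`.
#' @export
simulate_psg <- function(config = sim_config(), subject_id = "sim") {
  set.seed(config$seed)
  fs <- config$sampling_rate
  hyp <- config$stage_sequence %||% make_cycle_hypnogram(config$duration_h)
  if (is.null(config$arousal_plan)) {
    ap <- auto_plan(hyp, config$n_per_type, config$min_event_gap)
    hyp <- ap$hyp
    plan <- ap$plan
  } else {
    plan <- config$arousal_plan
  }
  check_plan(plan, hyp)

  n_ep <- length(hyp)
  n <- n_ep * 30L * fs
  freqs <- 1:30
  amp <- stage_amplitudes(config$background_spectrum, freqs)  # [freq, stage]
  stage_idx <- match(unclass(hyp), colnames(amp))

  # harmonic comb with smooth 30-s amplitude transitions at stage borders
  phases <- runif(length(freqs), 0, 2 * pi)
  t_mid <- (seq_len(n_ep) - 0.5) * 30
  t_all <- (seq_len(n) - 1) / fs
  comb <- numeric(n)
  for (i in seq_along(freqs)) {
    a_ep <- amp[i, stage_idx]
    a <- stats::approx(t_mid, a_ep, xout = t_all, rule = 2)$y
    comb <- comb + a * sin(2 * pi * freqs[i] * t_all + phases[i])
  }
  rm(t_all)
  noise_sd <- config$noise_rms * sqrt(mean(comb^2))

  # planted arousal components, shared across channels like the comb
  boost_tab <- type_boost_bands()
  edges <- profile_band_edges()
  arousal_sig <- numeric(n)
  truth <- list()
  for (r in seq_len(nrow(plan))) {
    onset <- plan$onset_s[r]; dur <- plan$duration_s[r]
    ty <- plan$type[r]
    span <- (round(onset * fs) + 1L):(round((onset + dur) * fs))
    stage_on <- stage_at(hyp, onset)
    bands_r <- boost_tab[[ty]]
    env <- cos_ramp_env(length(span), fs)
    t_span <- (span - 1) / fs
    for (j in seq_along(bands_r)) {
      g <- if (j == 1L) config$band_boost else config$secondary_boost
      b <- edges[[bands_r[j]]]
      f_in <- ceiling(b[1]):floor(b[2])
      comp <- numeric(length(span))
      for (f in f_in) {
        comp <- comp + (sqrt(g) - 1) * amp[f, stage_on] *
          sin(2 * pi * f * t_span + phases[f])
      }
      arousal_sig[span] <- arousal_sig[span] + env * comp
    }
    truth[[r]] <- data.frame(
      subject_id = subject_id, onset_s = onset, duration_s = dur,
      t_status = substr(ty, 1, 2), m_status = substr(ty, 3, 4), type = ty,
      stage_at_onset = stage_on,
      bands = paste(sort(bands_r), collapse = ","), channels = "all")
  }

  # EEG channels: shared comb + arousal signal, per-channel gain and noise
  n_eeg <- length(config$eeg_labels)
  gains <- runif(n_eeg, config$channel_gain_range[1],
                 config$channel_gain_range[2])
  channels <- matrix(0, nrow = n, ncol = n_eeg + 1L,
                     dimnames = list(NULL, c(config$eeg_labels,
                                             config$emg_label)))
  base <- comb + arousal_sig
  rm(comb, arousal_sig)
  for (j in seq_len(n_eeg)) {
    channels[, j] <- gains[j] * base + rnorm(n, sd = noise_sd)
  }
  rm(base)

  # EMG: white baseline with RMS bursts during M+ events
  emg_env <- rep(1, n)
  for (r in seq_len(nrow(plan))) {
    if (grepl("M+", plan$type[r], fixed = TRUE)) {
      onset <- plan$onset_s[r]; dur <- plan$duration_s[r]
      span <- (round(onset * fs) + 1L):(round((onset + dur) * fs))
      emg_env[span] <- 1 + cos_ramp_env(length(span), fs) *
        (config$emg_burst_gain - 1)
    }
  }
  channels[, config$emg_label] <- rnorm(n, sd = config$emg_baseline_rms) *
    emg_env

  rec <- psg_recording(subject_id, channels, fs, config$emg_label)
  truth <- if (length(truth)) arousal_events(do.call(rbind, truth)) else
    arousal_events()
  structure(list(recording = rec, hypnogram = hyp, truth = truth,
                 config = config),
            class = "psg_simulation")
}

#' Compare detected events against ground truth
#'
#' A truth event is recalled when at least one detected event overlaps its
#' half-open span; a detected event is a true positive when it overlaps
#' some truth event. Typing accuracy is computed over recalled truth
#' events whose first overlapping detected event carries the same type
#' label.
#'
#' @param detected a (typed) [arousal_events()] table.
#' @param truth the ground-truth table from [simulate_psg()].
#' @return list: `recall`, `precision`, `typing_accuracy` (`NA` if
#'   detected events are untyped), `n_detected`, `n_truth`.
#' @export
evaluate_detection <- function(detected, truth) {
  overlaps <- function(o1, d1, o2, d2) o1 < o2 + d2 & o2 < o1 + d1
  n_t <- nrow(truth); n_d <- nrow(detected)
  if (n_t == 0L || n_d == 0L) {
    return(list(recall = if (n_t) 0 else NA_real_,
                precision = if (n_d) 0 else NA_real_,
                typing_accuracy = NA_real_, n_detected = n_d, n_truth = n_t))
  }
  first_match <- integer(n_t)
  for (i in seq_len(n_t)) {
    hit <- which(overlaps(detected$onset_s, detected$duration_s,
                          truth$onset_s[i], truth$duration_s[i]))
    first_match[i] <- if (length(hit)) hit[1L] else NA_integer_
  }
  det_tp <- vapply(seq_len(n_d), function(j) {
    any(overlaps(truth$onset_s, truth$duration_s,
                 detected$onset_s[j], detected$duration_s[j]))
  }, TRUE)
  matched <- which(!is.na(first_match))
  typing <- if (length(matched) && !anyNA(detected$type[first_match[matched]])) {
    mean(detected$type[first_match[matched]] == truth$type[matched])
  } else NA_real_
  list(recall = length(matched) / n_t, precision = mean(det_tp),
       typing_accuracy = typing, n_detected = n_d, n_truth = n_t)
}
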