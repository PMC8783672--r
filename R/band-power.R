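#' Detection configuration
#'
#' All tunables of the arousal detector. Detection bands follow the
#' lower-theta / broad-alpha / beta scheme with the sigma spindle range
#' (11-16 Hz) excluded: by default broad-alpha is truncated at 11 Hz so
#' that no sigma mass can enter any detection band
#' (`sigma_exclusion = TRUE`); set it to `FALSE` to use the full 7-13 Hz
#' alpha band. Band edges are inclusive on the 1-Hz periodogram grid of
#' 1-second epochs.
#'
#' @param sigma_exclusion truncate broad-alpha at 11 Hz (default `TRUE`).
#' @param local_multiplier suprathreshold requires power > this multiple of
#'   the 30-s adaptive local median (default 2).
#' @param global_multiplier ... and > this multiple of the whole-night
#'   median (default 1).
#' @param min_run minimum number of consecutive suprathreshold 1-s epochs
#'   forming an event (default 3).
#' @param min_separation events closer than this (s) are merged (default 10).
#' @param max_duration events longer than this (s) are flagged
#'   `awakening_candidate` and excluded from densities (default 15).
#' @param emg_k EMG epoch is active when its RMS exceeds `emg_k` times the
#'   rolling-median baseline RMS (default 2).
#' @param emg_window rolling-median window for the EMG baseline, seconds
#'   (default 60).
#' @param emg_highpass EMG high-pass cutoff in Hz (default 10).
#' @param keep_rem_m_minus retain REM events without EMG-tone increase
#'   (default `FALSE`: they are marked `rem_discarded`).
#' @return a list of class `detection_config`.
#' @export
detection_config <- function(sigma_exclusion = TRUE,
                             local_multiplier = 2,
                             global_multiplier = 1,
                             min_run = 3L,
                             min_separation = 10,
                             max_duration = 15,
                             emg_k = 2,
                             emg_window = 60,
                             emg_highpass = 10,
                             keep_rem_m_minus = FALSE) {
  alpha <- if (isTRUE(sigma_exclusion)) c(7, 11) else c(7, 13)
  structure(list(
    bands = list(theta_low = c(3, 7), alpha_broad = alpha, beta = c(16, 30)),
    sigma_exclusion = sigma_exclusion,
    local_multiplier = local_multiplier,
    global_multiplier = global_multiplier,
    min_run = as.integer(min_run),
    min_separation = min_separation,
    max_duration = max_duration,
    emg_k = emg_k, emg_window = emg_window, emg_highpass = emg_highpass,
    keep_rem_m_minus = keep_rem_m_minus
  ), class = "detection_config")
}

hann_window <- function(n) 0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / n)

#' Per-second EEG band powers
#'
#' Splits each EEG channel into non-overlapping 1-second epochs and
#' computes, per epoch, the Hann-tapered periodogram mass summed over each
#' detection band (frequency bins at 1-Hz resolution; band edges
#' inclusive). EMG-activity flags for the same 1-s grid are computed with
#' [emg_tone_flags()].
#'
#' @param rec a [psg_recording()] (duration >= 60 s, rate >= 64 Hz).
#' @param config a [detection_config()].
#' @return object of class `band_power`: list with `power` (array
#'   `[epoch, band, channel]`), `emg_active` (logical per epoch), `bands`,
#'   `fs`, `n_epochs`, `subject_id`.
#' @export
compute_band_powers <- function(rec, config = detection_config()) {
  stopifnot(inherits(rec, "psg_recording"))
  fs <- rec$sampling_rate
  if (fs != round(fs)) stop("sampling rate must be an integer number of Hz")
  fs <- as.integer(fs)
  max_edge <- max(vapply(config$bands, max, 0))
  if (fs < 2 * max_edge + 4) {
    stop("nyquist-error: sampling rate ", fs,
         " Hz cannot resolve the ", max_edge, " Hz band edge")
  }
  if (psg_duration(rec) < 60) stop("signal shorter than 60 s")
  n_ep <- floor(nrow(rec$channels) / fs)
  labs <- eeg_labels(rec)
  w <- hann_window(fs)
  band_rows <- lapply(config$bands, function(b) {
    which((0:(fs - 1)) >= b[1] & (0:(fs - 1)) <= b[2])
  })
  pw <- array(0, dim = c(n_ep, length(config$bands), length(labs)),
              dimnames = list(NULL, names(config$bands), labs))
  for (ch in labs) {
    m <- matrix(rec$channels[seq_len(n_ep * fs), ch], nrow = fs) * w
    P <- Mod(stats::mvfft(m))^2
    for (b in seq_along(band_rows)) {
      pw[, b, ch] <- colSums(P[band_rows[[b]], , drop = FALSE])
    }
  }
  emg <- emg_tone_flags(emg_signal(rec), fs, config)[seq_len(n_ep)]
  structure(list(subject_id = rec$subject_id, power = pw, emg_active = emg,
                 bands = config$bands, fs = fs, n_epochs = n_ep),
            class = "band_power")
}

#' EMG tone-increase flags per 1-second epoch
#'
#' The EMG is high-passed (Butterworth, order 4, zero-phase) above
#' `emg_highpass` Hz; per 1-s epoch RMS is compared against a rolling
#' median of the per-epoch RMS over `emg_window` seconds, which is robust
#' to the short bursts it is meant to detect. An epoch is flagged active
#' when its RMS strictly exceeds `emg_k` times that local baseline.
#'
#' @param emg numeric EMG samples.
#' @param sampling_rate Hz.
#' @param config a [detection_config()].
#' @return logical vector, one flag per whole second of signal.
#' @export
emg_tone_flags <- function(emg, sampling_rate, config = detection_config()) {
  fs <- as.integer(round(sampling_rate))
  n_ep <- floor(length(emg) / fs)
  if (n_ep < 1L) stop("EMG shorter than one epoch")
  hp <- emg[seq_len(n_ep * fs)]
  if (config$emg_highpass > 0 && config$emg_highpass < fs / 2) {
    bf <- signal::butter(4, config$emg_highpass / (fs / 2), type = "high")
    hp <- signal::filtfilt(bf, hp)
  }
  r <- sqrt(colMeans(matrix(hp^2, nrow = fs)))
  k <- min(2L * floor(config$emg_window / 2) + 1L,
           2L * floor((n_ep - 1L) / 2) + 1L)
  base <- if (n_ep >= 3L) stats::runmed(r, k, endrule = "median") else rep(stats::median(r), n_ep)
  flags <- as.vector(r > config$emg_k * base)
  flags[is.na(flags)] <- FALSE   # e.g. emg_k = Inf over a silent baseline
  flags
}
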