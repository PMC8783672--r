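#' Spectral analysis configuration
#'
#' Parameters of the Morlet time-frequency profiling of arousal onsets. The
#' reporting bands (theta 4.5-7.5 Hz, alpha 8.5-11.5 Hz, beta 16.5-29.5 Hz)
#' are summed from a 1-Hz-step frequency grid spanning 0.5-30 Hz, and
#' relative power is each band's share of the full 0.5-30 Hz total.
#'
#' @param channel EEG channel analysed (default `"Fz"`).
#' @param n_cycles Morlet cycles (default 7, the usual compromise between
#'   time and frequency resolution at these frequencies).
#' @param freqs analysis frequencies in Hz (default `seq(0.5, 29.5, 1)`,
#'   30 bins covering 0.5-30 Hz).
#' @param window_s analysed event window after onset, seconds (default 3).
#' @param baseline_s pre-onset baseline length, seconds (default 0.5).
#' @param baseline_mode `"subtract"` (per-frequency baseline power
#'   subtraction floored at 0, the default), `"divide"`, or `"zscore"`.
#' @return list of class `spectral_config`.
#' @export
spectral_config <- function(channel = "Fz", n_cycles = 7,
                            freqs = seq(0.5, 29.5, by = 1),
                            window_s = 3, baseline_s = 0.5,
                            baseline_mode = c("subtract", "divide", "zscore")) {
  structure(list(channel = channel, n_cycles = n_cycles, freqs = freqs,
                 window_s = window_s, baseline_s = baseline_s,
                 baseline_mode = match.arg(baseline_mode),
                 bands = list(theta = c(4.5, 7.5), alpha = c(8.5, 11.5),
                              beta = c(16.5, 29.5))),
            class = "spectral_config")
}

morlet_kernel <- function(f, fs, n_cycles) {
  sigma_t <- n_cycles / (2 * pi * f)
  half <- ceiling(3.5 * sigma_t * fs)
  t <- (-half:half) / fs
  w <- exp(2i * pi * f * t) * exp(-t^2 / (2 * sigma_t^2))
  w / sqrt(sum(Mod(w)^2))                     # unit-energy normalization
}

# 'same'-aligned complex FFT convolution
conv_same <- function(x, k) {
  nx <- length(x); nk <- length(k)
  n <- stats::nextn(nx + nk - 1L, 2)
  X <- stats::fft(c(x, rep(0, n - nx)))
  K <- stats::fft(c(k, rep(0, n - nk)))
  full <- stats::fft(X * K, inverse = TRUE) / n
  half <- (nk - 1L) %/% 2L
  full[(half + 1L):(half + nx)]
}

#' Morlet time-frequency power of a signal segment
#'
#' @param x numeric signal.
#' @param fs sampling rate (Hz).
#' @param freqs analysis frequencies.
#' @param n_cycles wavelet cycles.
#' @return power matrix `[frequency, time]` with `freqs` as rownames.
#' @export
morlet_tfr <- function(x, fs, freqs = seq(0.5, 29.5, 1), n_cycles = 7) {
  out <- matrix(0, nrow = length(freqs), ncol = length(x),
                dimnames = list(freqs, NULL))
  for (i in seq_along(freqs)) {
    out[i, ] <- Mod(conv_same(x, morlet_kernel(freqs[i], fs, n_cycles)))^2
  }
  out
}

#' Time-frequency power of one arousal's first seconds
#'
#' Morlet transform of the configured channel over
#' `[onset, onset + window_s)` at the configured frequency grid, corrected
#' against the `baseline_s` pre-onset window: per frequency, the mean
#' baseline power is subtracted and negative values floored at 0 (or
#' divided / z-scored, per `baseline_mode`). Events with insufficient
#' pre- or post-onset signal raise `"margin-error"`.
#'
#' @param rec a [psg_recording()].
#' @param event single-row event (or list with `onset_s`).
#' @param config a [spectral_config()].
#' @return baseline-corrected power matrix `[frequency, time]`.
#' @export
event_tfr <- function(rec, event, config = spectral_config()) {
  fs <- rec$sampling_rate
  if (!config$channel %in% colnames(rec$channels)) {
    stop("channel-not-found: ", config$channel, "; available: ",
         paste(colnames(rec$channels), collapse = ", "))
  }
  onset <- event$onset_s
  i0 <- round(onset * fs)                       # sample index of onset (0-based)
  n_pre <- round(config$baseline_s * fs)
  n_win <- round(config$window_s * fs)
  if (i0 - n_pre < 0 || i0 + n_win > nrow(rec$channels)) {
    stop("margin-error: event at ", onset,
         " s lacks the required pre/post signal margin")
  }
  # pad with available signal so wavelet edges do not bleed into the window
  pad <- ceiling(3.5 * config$n_cycles / (2 * pi * min(config$freqs)) * fs)
  a <- max(0L, i0 - n_pre - pad)
  b <- min(nrow(rec$channels), i0 + n_win + pad)
  seg <- rec$channels[(a + 1L):b, config$channel]
  tfr <- morlet_tfr(seg, fs, config$freqs, config$n_cycles)
  win_cols <- (i0 - a + 1L):(i0 - a + n_win)
  base_cols <- (i0 - a - n_pre + 1L):(i0 - a)
  P <- tfr[, win_cols, drop = FALSE]
  B <- tfr[, base_cols, drop = FALSE]
  mu <- rowMeans(B)
  switch(config$baseline_mode,
         subtract = pmax(P - mu, 0),
         divide = P / pmax(mu, .Machine$double.eps),
         zscore = (P - mu) / pmax(apply(B, 1, stats::sd),
                                  .Machine$double.eps))
}

#' Band shares of a time-frequency matrix
#'
#' Collapses time, then sums frequency bins falling inside each reporting
#' band (edges inclusive) and divides by the total over all analysis
#' frequencies. Exact bin-membership accounting: a uniform TFR over 30
#' 1-Hz-step bins yields theta 4/30, alpha 4/30, beta 14/30.
#'
#' @param tfr power matrix `[frequency, time]` with frequencies as
#'   rownames, or a vector of per-frequency power.
#' @param freqs frequency grid (defaults to the rownames).
#' @param bands named list of band edges.
#' @return named numeric vector of band shares (fractions of total power).
#' @export
band_shares <- function(tfr, freqs = NULL,
                        bands = spectral_config()$bands) {
  if (is.matrix(tfr)) {
    if (is.null(freqs)) freqs <- as.numeric(rownames(tfr))
    p <- rowMeans(tfr)
  } else {
    p <- tfr
    if (is.null(freqs)) stop("freqs required when tfr is a vector")
  }
  total <- sum(p)
  vapply(bands, function(b) sum(p[freqs >= b[1] & freqs <= b[2]]) / total, 0)
}

#' Per-type relative spectral power of arousals
#'
#' Averages the baseline-corrected TFR across all retained events of each
#' arousal type, collapses time, sums into the reporting bands and
#' normalizes by total 0.5-30 Hz power. Types with no retained events are
#' absent from the output (never zero-filled). Events failing the margin
#' requirement are skipped with a message.
#'
#' @param rec a [psg_recording()].
#' @param events a typed [arousal_events()] table.
#' @param config a [spectral_config()].
#' @return data frame of class `spectral_profile`: `subject_id`, `type`,
#'   `band`, `rel_power`, `n_events` (long format).
#' @export
type_relative_power <- function(rec, events, config = spectral_config()) {
  ev <- retained_events(events)
  out <- list()
  for (ty in intersect(ASCAPE_TYPES, unique(ev$type))) {
    rows <- which(ev$type == ty)
    acc <- NULL; n_ok <- 0L
    for (i in rows) {
      tfr <- tryCatch(event_tfr(rec, ev[i, ], config), error = function(e) {
        if (grepl("margin-error", conditionMessage(e))) {
          message("skipping event at ", ev$onset_s[i], " s: ",
                  conditionMessage(e))
          NULL
        } else stop(e)
      })
      if (is.null(tfr)) next
      acc <- if (is.null(acc)) tfr else acc + tfr
      n_ok <- n_ok + 1L
    }
    if (n_ok == 0L) next
    shares <- band_shares(acc / n_ok, config$freqs, config$bands)
    out[[ty]] <- data.frame(subject_id = rec$subject_id, type = ty,
                            band = names(shares), rel_power = unname(shares),
                            n_events = n_ok)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(subject_id = character(), type = character(),
               band = character(), rel_power = numeric(),
               n_events = integer())
  rownames(res) <- NULL
  class(res) <- c("spectral_profile", "data.frame")
  res
}
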