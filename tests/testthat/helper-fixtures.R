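# Fixture builders shared across test files. Everything is generated in
# code; no data files.

# band_power object straight from a power array (bypasses any signal)
make_bp <- function(power, emg_active = rep(FALSE, dim(power)[1]),
                    subject_id = "t") {
  if (is.null(dimnames(power)[[2]])) {
    dimnames(power) <- list(NULL,
                            c("theta_low", "alpha_broad", "beta")[seq_len(dim(power)[2])],
                            paste0("ch", seq_len(dim(power)[3])))
  }
  structure(list(subject_id = subject_id, power = power,
                 emg_active = emg_active,
                 bands = detection_config()$bands, fs = 200L,
                 n_epochs = dim(power)[1]),
            class = "band_power")
}

random_bp <- function(n_ep, n_ch = 2, seed = NULL, spike_frac = 0.06) {
  if (!is.null(seed)) set.seed(seed)
  pw <- array(rlnorm(n_ep * 3 * n_ch, meanlog = 0, sdlog = 0.4),
              dim = c(n_ep, 3, n_ch))
  # sprinkle suprathreshold stretches so events actually form
  n_spike <- max(1, round(spike_frac * n_ep / 4))
  for (ci in seq_len(n_ch)) {
    starts <- sample(seq_len(max(1, n_ep - 6)), n_spike)
    for (s in starts) {
      len <- sample(2:6, 1)
      b <- sample(1:3, 1)
      pw[s:min(s + len, n_ep), b, ci] <- pw[s:min(s + len, n_ep), b, ci] * 8
    }
  }
  emg <- runif(n_ep) < 0.05
  make_bp(pw, emg)
}

random_stages <- function(n, seed = NULL, p_w = 0.1) {
  if (!is.null(seed)) set.seed(seed)
  st <- character(n)
  st[1] <- sample(c("W", "N1", "N2"), 1)
  trans <- c(W = 0.3, N1 = 0.25, N2 = 0.12, N3 = 0.1, REM = 0.1)
  for (i in 2:n) {
    if (runif(1) < trans[st[i - 1]]) {
      st[i] <- sample(setdiff(c("W", "N1", "N2", "N3", "REM"), st[i - 1]), 1)
    } else st[i] <- st[i - 1]
  }
  st
}

# small sinusoid-on-noise recording for spectral tests
tone_recording <- function(freq, fs = 200, dur = 30, amp = 1,
                           tone_from = 10, noise_sd = 0,
                           subject_id = "tone") {
  n <- dur * fs
  t <- (0:(n - 1)) / fs
  x <- numeric(n)
  sel <- t >= tone_from
  x[sel] <- amp * sin(2 * pi * freq * t[sel])
  if (noise_sd > 0) x <- x + rnorm(n, sd = noise_sd)
  ch <- cbind(Fz = x, EMG = rnorm(n, sd = 0.01))
  psg_recording(subject_id, ch, fs, "EMG")
}

small_sim_config <- function(seed, per_type = 3L, duration_h = 1,
                             ...) {
  sim_config(seed = seed, duration_h = duration_h,
             eeg_labels = c("Fz", "Cz", "Pz"),
             n_per_type = stats::setNames(rep(as.integer(per_type), 4),
                                          c("T+M+", "T+M-", "T-M+", "T-M-")),
             ...)
}
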