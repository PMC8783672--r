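# Independent brute-force oracles. Deliberately written as plain loops with
# their own median/run/overlap logic so they share no code path with the
# implementation they check.

bf_median <- function(x) {
  s <- sort(x)
  n <- length(s)
  if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
}

# full re-implementation of the two-step detector on a power array
# [epoch, band, channel] with EMG flags and 30-s stage labels
bf_detect <- function(power, emg_active, stages,
                      loc_mult = 2, glob_mult = 1, min_run = 3,
                      min_sep = 10, max_dur = 15, n_flank = 10) {
  n_ep <- dim(power)[1]; n_b <- dim(power)[2]; n_c <- dim(power)[3]
  bands <- dimnames(power)[[2]]; chans <- dimnames(power)[[3]]
  glob <- matrix(0, n_b, n_c)
  for (b in 1:n_b) for (ci in 1:n_c) glob[b, ci] <- bf_median(power[, b, ci])
  n_win <- ceiling(n_ep / 30)
  quiet <- which(!emg_active)
  loc <- array(NA_real_, c(n_b, n_c, n_win))
  for (w in 1:n_win) {
    a <- (w - 1) * 30 + 1; z <- min(w * 30, n_ep)
    sel <- c(rev(quiet[quiet < a])[seq_len(min(n_flank, sum(quiet < a)))],
             quiet[quiet >= a & quiet <= z],
             quiet[quiet > z][seq_len(min(n_flank, sum(quiet > z)))])
    sel <- sel[!is.na(sel)]
    for (b in 1:n_b) for (ci in 1:n_c) {
      loc[b, ci, w] <- if (length(sel)) bf_median(power[sel, b, ci]) else
        glob[b, ci]
    }
  }
  # per-channel supra flags and runs
  cand <- list()
  for (ci in 1:n_c) {
    supra <- rep(FALSE, n_ep)
    fired <- vector("list", n_ep)
    for (e in 1:n_ep) {
      w <- (e - 1) %/% 30 + 1
      for (b in 1:n_b) {
        if (power[e, b, ci] > loc_mult * loc[b, ci, w] &&
            power[e, b, ci] > glob_mult * glob[b, ci]) {
          supra[e] <- TRUE
          fired[[e]] <- c(fired[[e]], bands[b])
        }
      }
    }
    e <- 1
    while (e <= n_ep) {
      if (supra[e]) {
        s <- e
        while (e < n_ep && supra[e + 1]) e <- e + 1
        if (e - s + 1 >= min_run) {
          cand[[length(cand) + 1]] <- list(
            s = s, e = e, ch = chans[ci],
            bands = unique(unlist(fired[s:e])))
        }
      }
      e <- e + 1
    }
  }
  if (!length(cand)) return(data.frame(onset_s = numeric(),
                                       duration_s = numeric(),
                                       channels = character(),
                                       bands = character(),
                                       awakening_candidate = logical()))
  # merge overlapping spans across channels, iterated to fixed point
  repeat {
    done <- TRUE
    i <- 1
    while (i < length(cand)) {
      j <- i + 1
      while (j <= length(cand)) {
        a <- cand[[i]]; b <- cand[[j]]
        if (a$s <= b$e && b$s <= a$e) {
          cand[[i]] <- list(s = min(a$s, b$s), e = max(a$e, b$e),
                            ch = union(a$ch, b$ch),
                            bands = union(a$bands, b$bands))
          cand[[j]] <- NULL
          done <- FALSE
        } else j <- j + 1
      }
      i <- i + 1
    }
    if (done) break
  }
  ord <- order(sapply(cand, function(x) x$s))
  cand <- cand[ord]
  # drop wake onsets
  keep <- sapply(cand, function(x) {
    stages[min((x$s - 1) %/% 30 + 1, length(stages))] != "W"
  })
  cand <- cand[keep]
  if (!length(cand)) return(data.frame(onset_s = numeric(),
                                       duration_s = numeric(),
                                       channels = character(),
                                       bands = character(),
                                       awakening_candidate = logical()))
  # merge events separated by less than min_sep seconds
  out <- list(cand[[1]])
  for (x in cand[-1]) {
    cur <- out[[length(out)]]
    if ((x$s - 1) - cur$e < min_sep) {
      out[[length(out)]] <- list(s = min(cur$s, x$s), e = max(cur$e, x$e),
                                 ch = union(cur$ch, x$ch),
                                 bands = union(cur$bands, x$bands))
    } else out[[length(out) + 1]] <- x
  }
  data.frame(
    onset_s = sapply(out, function(x) x$s - 1),
    duration_s = sapply(out, function(x) x$e - x$s + 1),
    channels = sapply(out, function(x) paste(sort(x$ch), collapse = ",")),
    bands = sapply(out, function(x) paste(sort(x$bands), collapse = ",")),
    awakening_candidate = sapply(out, function(x) (x$e - x$s + 1) > max_dur))
}

# T status via the window formulation: T+ iff some stage-change boundary b
# satisfies b - 15 <= onset < b + 15
bf_transition <- function(onset, stages) {
  n <- length(stages)
  bounds <- 30 * which(stages[-1] != stages[-n])
  if (any(bounds - 15 <= onset & onset < bounds + 15)) "T+" else "T-"
}

# M status by explicit second-by-second overlap
bf_emg_status <- function(onset, dur, flags) {
  for (s in seq_along(flags)) {
    if (flags[s] && (s - 1) < onset + dur && s > onset) return("M+")
  }
  "M-"
}

# direct-sum DFT band power with Hann taper (inclusive integer band edges)
bf_band_power <- function(x, band) {
  n <- length(x)
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / n)
  xw <- x * w
  total <- 0
  for (k in band[1]:band[2]) {
    re <- sum(xw * cos(-2 * pi * k * (0:(n - 1)) / n))
    im <- sum(xw * sin(-2 * pi * k * (0:(n - 1)) / n))
    total <- total + re^2 + im^2
  }
  total
}

# direct time-domain Morlet convolution power at given output samples
bf_morlet_power <- function(x, fs, f, n_cycles, at) {
  sigma_t <- n_cycles / (2 * pi * f)
  half <- ceiling(3.5 * sigma_t * fs)
  tt <- (-half:half) / fs
  kern <- exp(2i * pi * f * tt) * exp(-tt^2 / (2 * sigma_t^2))
  kern <- kern / sqrt(sum(Mod(kern)^2))
  vapply(at, function(i) {
    acc <- 0 + 0i
    for (j in -half:half) {
      src <- i - j
      if (src >= 1 && src <= length(x)) {
        acc <- acc + x[src] * kern[j + half + 1]
      }
    }
    Mod(acc)^2
  }, 0)
}

# run-enumeration WASO (minutes) and awakening count
bf_waso_awak <- function(stages) {
  n <- length(stages)
  first_sleep <- NA
  for (i in 1:n) if (stages[i] != "W") { first_sleep <- i; break }
  if (is.na(first_sleep)) return(NULL)
  last_sleep <- NA
  for (i in n:1) if (stages[i] != "W") { last_sleep <- i; break }
  w_ep <- 0; runs <- 0; in_run <- FALSE
  if (last_sleep > first_sleep) {
    for (i in (first_sleep + 1):last_sleep) {
      if (stages[i] == "W") {
        w_ep <- w_ep + 1
        if (!in_run) { runs <- runs + 1; in_run <- TRUE }
      } else in_run <- FALSE
    }
  }
  list(waso_min = w_ep * 0.5, n_awakenings = runs)
}

# rank-based Spearman with midrank ties
bf_spearman <- function(x, y) {
  midrank <- function(v) {
    r <- numeric(length(v))
    for (i in seq_along(v)) {
      r[i] <- sum(v < v[i]) + (sum(v == v[i]) + 1) / 2
    }
    r
  }
  rx <- midrank(x); ry <- midrank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}
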