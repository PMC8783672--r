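#' Assemble arousal events from thresholded band powers
#'
#' A 1-s epoch is suprathreshold on a channel if, in at least one band, its
#' power strictly exceeds both `local_multiplier` times the 30-s adaptive
#' median and `global_multiplier` times the whole-night median of that same
#' band (both conditions within one band; across bands the rule is OR).
#' Per-channel runs of at least `min_run` consecutive suprathreshold epochs
#' become candidate events; candidates overlapping across channels are
#' merged (union of spans, channels and bands); events whose onset falls in
#' a wake epoch are discarded; events separated by less than
#' `min_separation` seconds are merged; events longer than `max_duration`
#' seconds are flagged `awakening_candidate` (retained in the table but
#' excluded from arousal densities downstream).
#'
#' @param bp a `band_power` object.
#' @param thr a `threshold_set` from [local_thresholds()].
#' @param hyp a [hypnogram()] paired with the recording.
#' @param config a [detection_config()].
#' @return an [arousal_events()] table (typing columns unset).
#' @export
assemble_events <- function(bp, thr, hyp, config = detection_config()) {
  stopifnot(inherits(bp, "band_power"), inherits(thr, "threshold_set"),
            inherits(hyp, "hypnogram"))
  n_ep <- bp$n_epochs
  if (abs(floor(n_ep / 30) - length(hyp)) > 1L) {
    stop(sprintf("pairing-error: %d signal epochs vs %d hypnogram epochs",
                 floor(n_ep / 30), length(hyp)))
  }
  bands <- dimnames(bp$power)[[2]]
  chans <- dimnames(bp$power)[[3]]
  win <- thr$window_of

  # per-channel candidate runs, remembering which bands fired where
  cand <- list()
  for (ci in seq_along(chans)) {
    p <- bp$power[, , ci, drop = FALSE]
    dim(p) <- dim(bp$power)[1:2]
    loc <- t(thr$local[, ci, win])            # [epoch, band]
    glob <- matrix(thr$global[, ci], nrow = n_ep, ncol = length(bands),
                   byrow = TRUE)
    hit <- (p > config$local_multiplier * loc) &
           (p > config$global_multiplier * glob)
    supra <- rowSums(hit) > 0
    r <- rle(supra)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    ok <- r$values & r$lengths >= config$min_run
    for (k in which(ok)) {
      span <- starts[k]:ends[k]
      fired <- bands[colSums(hit[span, , drop = FALSE]) > 0]
      ratio <- max(p[span, ] / loc[span, ])
      cand[[length(cand) + 1L]] <- list(
        s = starts[k], e = ends[k], channels = chans[ci], bands = fired,
        ratio = ratio)
    }
  }
  if (length(cand) == 0L) return(arousal_events())

  # merge candidates that overlap across channels (inclusive epoch spans)
  ord <- order(vapply(cand, `[[`, 0L, "s"), vapply(cand, `[[`, 0L, "e"))
  cand <- cand[ord]
  merged <- list(cand[[1L]])
  for (x in cand[-1L]) {
    cur <- merged[[length(merged)]]
    if (x$s <= cur$e) {
      cur$e <- max(cur$e, x$e)
      cur$channels <- union(cur$channels, x$channels)
      cur$bands <- union(cur$bands, x$bands)
      cur$ratio <- max(cur$ratio, x$ratio)
      merged[[length(merged)]] <- cur
    } else {
      merged[[length(merged) + 1L]] <- x
    }
  }

  # drop events whose onset epoch is wake
  onset_stage <- function(s) {
    k <- (s - 1L) %/% 30L + 1L
    unclass(hyp)[min(k, length(hyp))]
  }
  merged <- Filter(function(x) onset_stage(x$s) != "W", merged)
  if (length(merged) == 0L) return(arousal_events())

  # merge events closer than min_separation seconds
  out <- list(merged[[1L]])
  for (x in merged[-1L]) {
    cur <- out[[length(out)]]
    if ((x$s - 1L) - cur$e < config$min_separation) {
      cur$e <- max(cur$e, x$e)
      cur$channels <- union(cur$channels, x$channels)
      cur$bands <- union(cur$bands, x$bands)
      cur$ratio <- max(cur$ratio, x$ratio)
      out[[length(out)]] <- cur
    } else {
      out[[length(out) + 1L]] <- x
    }
  }

  df <- data.frame(
    subject_id = bp$subject_id,
    onset_s = vapply(out, function(x) x$s - 1, 0),
    duration_s = vapply(out, function(x) x$e - x$s + 1, 0),
    stage_at_onset = vapply(out, function(x) onset_stage(x$s), ""),
    bands = vapply(out, function(x) paste(sort(x$bands), collapse = ","), ""),
    channels = vapply(out, function(x) paste(sort(x$channels), collapse = ","), ""),
    peak_ratio = vapply(out, function(x) x$ratio, 0))
  df$awakening_candidate <- df$duration_s > config$max_duration
  arousal_events(df)
}

#' Detect arousals in a recording
#'
#' Composes [compute_band_powers()], [global_thresholds()] /
#' [local_thresholds()] and [assemble_events()]. Deterministic for fixed
#' input and configuration, and invariant to rescaling all EEG channels by
#' a common positive constant (both thresholds are medians of the same
#' quantity being tested).
#'
#' @param rec a [psg_recording()].
#' @param hyp a [hypnogram()].
#' @param config a [detection_config()].
#' @return an [arousal_events()] table.
#' @export
detect_arousals <- function(rec, hyp, config = detection_config()) {
  check_pairing(hyp, rec)
  bp <- compute_band_powers(rec, config)
  thr <- local_thresholds(bp)
  assemble_events(bp, thr, hyp, config)
}
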