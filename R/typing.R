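#' Transition status of an arousal (T+ / T-)
#'
#' An arousal is transition-associated (`"T+"`) when its onset falls within
#' 15 seconds of a sleep-stage change, operationalized on the 30-s epoch
#' grid: in the second half of an epoch preceding a stage change, or in the
#' first half of an epoch whose stage differs from the previous epoch's.
#' Intervals are half-open, so an onset exactly at mid-epoch (second 15)
#' belongs to the second half. The first epoch has no predecessor, so only
#' the look-ahead clause can fire there; symmetrically for the last.
#'
#' @param onset_s event onset(s) in seconds from recording start
#'   (vectorized).
#' @param hyp a [hypnogram()].
#' @return character vector of `"T+"` / `"T-"`.
#' @export
classify_transition <- function(onset_s, hyp) {
  stopifnot(inherits(hyp, "hypnogram"))
  st <- unclass(hyp)
  n <- length(st)
  k <- floor(onset_s / 30) + 1L          # 1-based epoch of onset
  if (any(onset_s < 0) || any(k > n)) {
    stop("pairing-error: onset beyond hypnogram span")
  }
  frac <- onset_s - 30 * (k - 1L)
  second_half <- frac >= 15
  tplus <- logical(length(onset_s))
  look_ahead <- second_half & k < n
  tplus[look_ahead] <- st[k[look_ahead] + 1L] != st[k[look_ahead]]
  look_back <- !second_half & k > 1L
  tplus[look_back] <- st[k[look_back]] != st[k[look_back] - 1L]
  ifelse(tplus, "T+", "T-")
}

#' EMG status of an arousal (M+ / M-)
#'
#' `"M+"` when any 1-s epoch overlapping the half-open event span
#' `[onset, onset + duration)` is flagged EMG-active; `"M-"` otherwise.
#' Flags adjacent to but outside the span never count (strict overlap).
#'
#' @param onset_s,duration_s event span in seconds (vectorized).
#' @param emg_active logical EMG-activity flag per 1-s epoch (from
#'   [emg_tone_flags()] or [compute_band_powers()]).
#' @return character vector of `"M+"` / `"M-"`.
#' @export
classify_emg <- function(onset_s, duration_s, emg_active) {
  n <- length(emg_active)
  mapply(function(o, d) {
    lo <- floor(o) + 1L                       # first 1-s epoch overlapped
    hi <- ceiling(o + d)                      # last (half-open span)
    if (hi > n || lo < 1L) stop("EMG flags do not cover event span")
    if (any(emg_active[lo:hi])) "M+" else "M-"
  }, onset_s, duration_s, USE.NAMES = FALSE)
}

#' REM constraint on typed arousals
#'
#' In REM sleep an arousal is, by scoring definition, accompanied by a
#' change in muscle tone: REM events without an EMG-tone increase
#' (`M-`) are marked `rem_discarded` and excluded from density counts
#' downstream (set `keep_rem_m_minus = TRUE` in [detection_config()] to
#' retain them).
#'
#' @param events a typed [arousal_events()] table.
#' @param config a [detection_config()].
#' @return the table with `rem_discarded` updated.
#' @export
apply_rem_rule <- function(events, config = detection_config()) {
  events$rem_discarded <- if (isTRUE(config$keep_rem_m_minus)) {
    rep(FALSE, nrow(events))
  } else {
    events$stage_at_onset == "REM" & events$m_status == "M-"
  }
  events
}

#' Classify detected arousals by transition and EMG-tone status
#'
#' Adds `t_status`, `m_status`, the combined `type` label
#' (`T+M+ / T+M- / T-M+ / T-M-`) and the REM-rule `rem_discarded` flag to a
#' detected event table. Classification depends only on onsets, stages and
#' EMG flags, never on signal amplitudes.
#'
#' @param events an [arousal_events()] table from [detect_arousals()].
#' @param hyp the paired [hypnogram()].
#' @param emg_active logical per-1-s-epoch EMG flags, or a `band_power`
#'   object carrying them.
#' @param config a [detection_config()].
#' @return the typed [arousal_events()] table.
#' @export
classify_events <- function(events, hyp, emg_active,
                            config = detection_config()) {
  if (inherits(emg_active, "band_power")) emg_active <- emg_active$emg_active
  if (nrow(events) == 0L) return(events)
  events$t_status <- classify_transition(events$onset_s, hyp)
  events$m_status <- classify_emg(events$onset_s, events$duration_s,
                                  emg_active)
  events$type <- paste0(events$t_status, events$m_status)
  apply_rem_rule(events, config)
}

#' Retained events for density computation
#'
#' Drops REM-discarded events and awakening candidates (> max duration).
#'
#' @param events a typed [arousal_events()] table.
#' @return filtered table.
#' @export
retained_events <- function(events) {
  events[!events$rem_discarded & !events$awakening_candidate, , drop = FALSE]
}
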