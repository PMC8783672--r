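#' Total sleep time
#'
#' Count of hypnogram epochs in any sleep stage (N1, N2, N3, REM) times
#' 30 s, returned in hours.
#'
#' @param hyp a [hypnogram()].
#' @return hours of sleep.
#' @export
total_sleep_time <- function(hyp) {
  stopifnot(inherits(hyp, "hypnogram"))
  n <- sum(unclass(hyp) != "W")
  if (n == 0L) stop("no-sleep-error: hypnogram contains no sleep epochs")
  n * 30 / 3600
}

sleep_onset_epoch <- function(hyp, rule = c("first", "three-consecutive")) {
  rule <- match.arg(rule)
  sleep <- unclass(hyp) != "W"
  if (!any(sleep)) stop("no-sleep-error: hypnogram contains no sleep epochs")
  if (rule == "first") return(which(sleep)[1L])
  r <- rle(sleep)
  ends <- cumsum(r$lengths)
  k <- which(r$values & r$lengths >= 3L)
  if (!length(k)) return(which(sleep)[1L])
  ends[k[1L]] - r$lengths[k[1L]] + 1L
}

#' Wake after sleep onset
#'
#' Minutes of wake strictly after sleep onset (first sleep epoch by
#' default; a 3-consecutive-epoch onset rule is available) and, by default,
#' before the final sleep epoch — the terminal lights-on wake tail is
#' excluded unless `include_tail = TRUE`.
#'
#' @param hyp a [hypnogram()].
#' @param onset_rule `"first"` (default) or `"three-consecutive"`.
#' @param include_tail count trailing wake after the last sleep epoch
#'   (default `FALSE`).
#' @return WASO in minutes.
#' @export
waso <- function(hyp, onset_rule = "first", include_tail = FALSE) {
  st <- unclass(hyp)
  on <- sleep_onset_epoch(hyp, onset_rule)
  last_sleep <- max(which(st != "W"))
  hi <- if (include_tail) length(st) else last_sleep
  if (hi <= on) return(0)
  sum(st[(on + 1L):hi] == "W") * 30 / 60
}

#' Number of full awakenings
#'
#' Maximal runs of consecutive wake epochs occurring after sleep onset and
#' (by default) before the final sleep epoch; runs shorter than `min_len`
#' epochs are ignored.
#'
#' @inheritParams waso
#' @param min_len minimum run length in 30-s epochs (default 1).
#' @return integer count.
#' @export
count_awakenings <- function(hyp, onset_rule = "first", min_len = 1L,
                             include_tail = FALSE) {
  st <- unclass(hyp)
  on <- sleep_onset_epoch(hyp, onset_rule)
  last_sleep <- max(which(st != "W"))
  hi <- if (include_tail) length(st) else last_sleep
  if (hi <= on) return(0L)
  r <- rle(st[(on + 1L):hi] == "W")
  sum(r$values & r$lengths >= min_len)
}

#' Hourly arousal densities per type
#'
#' Density of each arousal type in events per hour of total sleep time;
#' REM-discarded events and awakening candidates are excluded. The four
#' type densities sum to the total density by construction.
#'
#' @param events a typed [arousal_events()] table.
#' @param tst_h total sleep time in hours (> 0).
#' @return named list with `density` (per type), `total_density`.
#' @export
arousal_densities <- function(events, tst_h) {
  stopifnot(tst_h > 0)
  ev <- retained_events(events)
  counts <- table(factor(ev$type, levels = ASCAPE_TYPES))
  dens <- as.numeric(counts) / tst_h
  names(dens) <- ASCAPE_TYPES
  list(density = dens, total_density = nrow(ev) / tst_h)
}

#' Per-subject sleep and arousal summary metrics
#'
#' @param events a typed [arousal_events()] table for one subject.
#' @param hyp the subject's [hypnogram()].
#' @param onset_rule,include_tail passed to [waso()] /
#'   [count_awakenings()].
#' @return one-row data frame: `subject_id`, the four type densities
#'   (`dens_TpMp`, `dens_TpMm`, `dens_TmMp`, `dens_TmMm`),
#'   `total_density`, `waso_min`, `n_awakenings`, `tst_h`.
#' @export
sleep_metrics <- function(events, hyp, onset_rule = "first",
                          include_tail = FALSE) {
  tst <- total_sleep_time(hyp)
  d <- arousal_densities(events, tst)
  data.frame(
    subject_id = if (nrow(events)) events$subject_id[1L] else NA_character_,
    dens_TpMp = d$density[["T+M+"]], dens_TpMm = d$density[["T+M-"]],
    dens_TmMp = d$density[["T-M+"]], dens_TmMm = d$density[["T-M-"]],
    total_density = d$total_density,
    waso_min = waso(hyp, onset_rule, include_tail),
    n_awakenings = count_awakenings(hyp, onset_rule,
                                    include_tail = include_tail),
    tst_h = tst)
}
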