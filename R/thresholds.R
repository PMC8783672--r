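#' Whole-night (global) median thresholds
#'
#' Step one of the detector: for every channel and band, the median of the
#' per-1-s-epoch band power over the whole recording. An epoch can only be
#' part of an arousal if its power strictly exceeds this value in some
#' band.
#'
#' @param bp a `band_power` object from [compute_band_powers()].
#' @return matrix `[band, channel]` of medians.
#' @export
global_thresholds <- function(bp) {
  stopifnot(inherits(bp, "band_power"))
  apply(bp$power, c(2, 3), stats::median)
}

#' 30-second adaptive (local) median thresholds
#'
#' Step two: for each non-overlapping 30-s window, the per-band median over
#' the EMG-quiet 1-s epochs inside the window plus the nearest ten quiet
#' epochs before and after it (fewer at the recording edges). Windows with
#' no selectable quiet epoch at all fall back to the whole-night median and
#' are reported in `fallback_windows` with a warning.
#'
#' @param bp a `band_power` object.
#' @param n_flank number of quiet epochs taken on each side (default 10).
#' @return object of class `threshold_set`: list with `global`
#'   (`[band, channel]`), `local` (`[band, channel, window]`), `window_of`
#'   (window index per epoch) and `fallback_windows`.
#' @export
local_thresholds <- function(bp, n_flank = 10L) {
  stopifnot(inherits(bp, "band_power"))
  glob <- global_thresholds(bp)
  n_ep <- bp$n_epochs
  n_win <- ceiling(n_ep / 30)
  quiet_idx <- which(!bp$emg_active)
  nb <- dim(bp$power)[2]; nc <- dim(bp$power)[3]
  loc <- array(NA_real_, dim = c(nb, nc, n_win),
               dimnames = c(dimnames(glob), list(NULL)))
  fallback <- integer()
  for (wi in seq_len(n_win)) {
    a <- (wi - 1L) * 30L + 1L
    b <- min(wi * 30L, n_ep)
    inside <- quiet_idx[quiet_idx >= a & quiet_idx <= b]
    before <- utils::tail(quiet_idx[quiet_idx < a], n_flank)
    after <- utils::head(quiet_idx[quiet_idx > b], n_flank)
    sel <- c(before, inside, after)
    if (length(sel) == 0L) {
      loc[, , wi] <- glob
      fallback <- c(fallback, wi)
    } else {
      loc[, , wi] <- apply(bp$power[sel, , , drop = FALSE], c(2, 3),
                           stats::median)
    }
  }
  if (length(fallback)) {
    warning("local_thresholds: no quiet epochs selectable for window(s) ",
            paste(fallback, collapse = ", "),
            "; whole-night median used as fallback")
  }
  structure(list(global = glob, local = loc,
                 window_of = (seq_len(n_ep) - 1L) %/% 30L + 1L,
                 fallback_windows = fallback),
            class = "threshold_set")
}
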