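#' Polysomnography recording container
#'
#' Holds synchronized EEG channels and one submental EMG channel sampled at
#' a common rate. Channels are columns of a numeric matrix; exactly one
#' channel label is designated as EMG, all others are EEG.
#'
#' @param subject_id subject identifier.
#' @param channels numeric matrix, one column per channel, with column
#'   names as channel labels; or a named list of equal-length numeric
#'   vectors.
#' @param sampling_rate sampling rate in Hz (positive).
#' @param emg_label label of the EMG channel (must be a column name).
#' @param start_offset seconds from nominal recording start (default 0).
#' @return object of class `psg_recording`.
#' @examples
#' x <- matrix(rnorm(400), ncol = 2, dimnames = list(NULL, c("Fz", "EMG")))
#' rec <- psg_recording("s1", x, 200, "EMG")
#' psg_duration(rec)
#' @export
psg_recording <- function(subject_id, channels, sampling_rate, emg_label,
                          start_offset = 0) {
  if (is.list(channels) && !is.matrix(channels)) {
    lens <- lengths(channels)
    if (length(unique(lens)) != 1L) stop("all channels must have the same length")
    channels <- do.call(cbind, channels)
  }
  stopifnot(is.matrix(channels), is.numeric(channels))
  labels <- colnames(channels)
  if (is.null(labels) || anyDuplicated(labels)) {
    stop("channels must have unique column-name labels")
  }
  if (!is.numeric(sampling_rate) || sampling_rate <= 0) {
    stop("sampling_rate must be a positive number")
  }
  if (!emg_label %in% labels) {
    stop("channel-not-found: EMG label '", emg_label,
         "' not among: ", paste(labels, collapse = ", "))
  }
  if (length(labels) < 2L) stop("need at least one EEG channel besides the EMG")
  structure(
    list(subject_id = as.character(subject_id), channels = channels,
         sampling_rate = sampling_rate, emg_label = emg_label,
         start_offset = start_offset),
    class = "psg_recording")
}

#' @export
print.psg_recording <- function(x, ...) {
  cat("<psg_recording> subject ", x$subject_id, ": ",
      ncol(x$channels) - 1L, " EEG + 1 EMG channel(s), ",
      x$sampling_rate, " Hz, ",
      format(psg_duration(x) / 3600, digits = 3), " h\n", sep = "")
  cat("  EEG: ", paste(eeg_labels(x), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Recording duration in seconds
#' @param rec a [psg_recording()].
#' @export
psg_duration <- function(rec) nrow(rec$channels) / rec$sampling_rate

#' EEG channel labels of a recording
#' @param rec a [psg_recording()].
#' @export
eeg_labels <- function(rec) setdiff(colnames(rec$channels), rec$emg_label)

#' EMG samples of a recording
#' @param rec a [psg_recording()].
#' @export
emg_signal <- function(rec) rec$channels[, rec$emg_label]
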