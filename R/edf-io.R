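# Minimal EDF (European Data Format) reader/writer. EDF stores signals as
# 16-bit little-endian integers in fixed-duration data records, with a
# 256-byte global header plus 256 bytes per signal. Amplitudes are mapped
# linearly between the digital range and the declared physical range, so a
# round trip is exact up to the 16-bit quantization step of that range.

edf_pad <- function(x, width) {
  x <- substr(as.character(x), 1L, width)
  formatC(x, width = width, flag = "-")
}

edf_num <- function(x, width) {
  s <- formatC(x, format = "g", digits = width - 2L, width = 0L)
  if (nchar(s) > width) s <- formatC(signif(x, 6), format = "g", width = 0L)
  edf_pad(s, width)
}

#' Write a PSG recording to an EDF file
#'
#' Uses 1-second data records with `sampling_rate` samples per record and
#' per-channel physical ranges taken from the data (EDF amplitude units are
#' the file's physical-dimension fields; no other rescaling). Samples
#' beyond the last whole record are dropped.
#'
#' @param rec a [psg_recording()].
#' @param path output path.
#' @param physical_dim physical dimension string, default `"uV"`.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path, physical_dim = "uV") {
  stopifnot(inherits(rec, "psg_recording"))
  fs <- rec$sampling_rate
  if (fs != round(fs)) stop("write_edf requires an integer sampling rate")
  fs <- as.integer(fs)
  ns <- ncol(rec$channels)
  n_rec <- nrow(rec$channels) %/% fs
  if (n_rec < 1L) stop("format-error: recording shorter than one data record")
  labels <- colnames(rec$channels)

  pmin <- apply(rec$channels, 2, min)
  pmax <- apply(rec$channels, 2, max)
  flat <- pmax - pmin <= 0
  pmin[flat] <- pmin[flat] - 1
  pmax[flat] <- pmax[flat] + 1
  dmin <- -32768L; dmax <- 32767L

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8), edf_pad(rec$subject_id, 80),
    edf_pad(paste0("Startdate 01-JAN-2000 ", rec$subject_id), 80),
    edf_pad("01.01.00", 8), edf_pad("00.00.00", 8),
    edf_pad(256L * (1L + ns), 8), edf_pad("", 44),
    edf_pad(n_rec, 8), edf_pad("1", 8), edf_pad(ns, 4))
  writeChar(hdr, con, eos = NULL)
  field <- function(vals, width) {
    writeChar(paste0(vapply(vals, edf_pad, "", width = width), collapse = ""),
              con, eos = NULL)
  }
  field(labels, 16)
  field(rep("", ns), 80)
  field(rep(physical_dim, ns), 8)
  writeChar(paste0(vapply(pmin, edf_num, "", width = 8), collapse = ""), con, eos = NULL)
  writeChar(paste0(vapply(pmax, edf_num, "", width = 8), collapse = ""), con, eos = NULL)
  field(rep(dmin, ns), 8)
  field(rep(dmax, ns), 8)
  field(rep("", ns), 80)
  field(rep(fs, ns), 8)
  field(rep("", ns), 32)

  scale <- (dmax - dmin) / (pmax - pmin)
  n_use <- n_rec * fs
  dig <- matrix(0L, nrow = n_use, ncol = ns)
  for (j in seq_len(ns)) {
    d <- round((rec$channels[seq_len(n_use), j] - pmin[j]) * scale[j]) + dmin
    dig[, j] <- as.integer(pmin(pmax(d, dmin), dmax))
  }
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1L) * fs + 1L):(r * fs)
    writeBin(as.integer(as.vector(dig[idx, ])), con, size = 2L,
             endian = "little")
  }
  invisible(path)
}

#' Read a PSG recording from an EDF file
#'
#' Signals recorded at different rates within one file are resampled by
#' linear interpolation to the highest rate present among the requested
#' channels (documented behavior; the bundled writer always uses one rate).
#'
#' @param path EDF file path.
#' @param emg_label label of the EMG channel.
#' @param eeg_labels labels of the EEG channels to load; `NULL` loads all
#'   channels other than the EMG.
#' @return a [psg_recording()].
#' @export
read_edf <- function(path, emg_label, eeg_labels = NULL) {
  if (!file.exists(path)) stop("format-error: no such file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  version <- rd(8)
  if (!identical(version, "0")) stop("format-error: not an EDF file (version '", version, "')")
  patient <- rd(80); rd(80); rd(8); rd(8)
  hdr_bytes <- suppressWarnings(as.integer(rd(8))); rd(44)
  n_rec <- suppressWarnings(as.integer(rd(8)))
  rec_dur <- suppressWarnings(as.numeric(rd(8)))
  ns <- suppressWarnings(as.integer(rd(4)))
  if (anyNA(c(hdr_bytes, n_rec, rec_dur, ns)) || ns < 1L || n_rec < 1L) {
    stop("format-error: corrupt EDF header")
  }
  rdv <- function(width) vapply(seq_len(ns), function(i) rd(width), "")
  labels <- rdv(16); rdv(80); rdv(8)
  pmin <- as.numeric(rdv(8)); pmax <- as.numeric(rdv(8))
  dmin <- as.numeric(rdv(8)); dmax <- as.numeric(rdv(8))
  rdv(80)
  spr <- as.integer(rdv(8))
  rdv(32)

  want <- if (is.null(eeg_labels)) labels else unique(c(eeg_labels, emg_label))
  missing <- setdiff(want, labels)
  if (length(missing)) {
    stop("channel-not-found: ", paste(missing, collapse = ", "),
         "; available: ", paste(labels, collapse = ", "))
  }
  if (!emg_label %in% want) want <- c(want, emg_label)

  raw <- vector("list", ns)
  keep <- labels %in% want
  for (i in seq_len(ns)) raw[[i]] <- vector("list", n_rec)
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      v <- readBin(con, "integer", n = spr[i], size = 2L, endian = "little",
                   signed = TRUE)
      if (keep[i]) raw[[i]][[r]] <- v
    }
  }
  fs_out <- max(spr[keep]) / rec_dur
  idx <- match(want, labels)
  out <- matrix(0, nrow = round(n_rec * rec_dur * fs_out), ncol = length(want),
                dimnames = list(NULL, want))
  for (j in seq_along(idx)) {
    i <- idx[j]
    d <- unlist(raw[[i]], use.names = FALSE)
    g <- (pmax[i] - pmin[i]) / (dmax[i] - dmin[i])
    x <- (d - dmin[i]) * g + pmin[i]
    if (length(x) != nrow(out)) {
      t_in <- seq(0, by = rec_dur / spr[i], length.out = length(x))
      t_out <- seq(0, by = 1 / fs_out, length.out = nrow(out))
      x <- stats::approx(t_in, x, xout = t_out, rule = 2)$y
    }
    out[, j] <- x
  }
  psg_recording(subject_id = if (nzchar(patient)) patient else "unknown",
                channels = out, sampling_rate = fs_out,
                emg_label = emg_label)
}
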