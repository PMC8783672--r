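#' Arousal event table
#'
#' A data frame of arousal events, one row per event, sorted by onset. Time
#' convention: seconds from recording start, half-open intervals
#' `[onset, onset + duration)`. Events of the same subject must not
#' overlap.
#'
#' Columns: `subject_id`, `onset_s`, `duration_s`, `t_status`
#' (`"T+"`/`"T-"`/`NA`), `m_status` (`"M+"`/`"M-"`/`NA`), `type`,
#' `stage_at_onset`, `bands` (comma-joined), `channels` (comma-joined),
#' `peak_ratio`, `awakening_candidate`, `rem_discarded`.
#'
#' @param df data frame with at least `subject_id`, `onset_s`,
#'   `duration_s`; missing optional columns are filled with `NA`/defaults.
#' @param check validate invariants (sortedness is enforced by sorting;
#'   overlap raises `"event-overlap-error"`).
#' @return data frame of class `arousal_events`.
#' @export
arousal_events <- function(df = NULL, check = TRUE) {
  cols <- c("subject_id", "onset_s", "duration_s", "t_status", "m_status",
            "type", "stage_at_onset", "bands", "channels", "peak_ratio",
            "awakening_candidate", "rem_discarded")
  if (is.null(df) || nrow(df) == 0L) {
    out <- data.frame(subject_id = character(), onset_s = numeric(),
                      duration_s = numeric(), t_status = character(),
                      m_status = character(), type = character(),
                      stage_at_onset = character(), bands = character(),
                      channels = character(), peak_ratio = numeric(),
                      awakening_candidate = logical(),
                      rem_discarded = logical())
    class(out) <- c("arousal_events", "data.frame")
    return(out)
  }
  stopifnot(all(c("subject_id", "onset_s", "duration_s") %in% names(df)))
  defaults <- list(t_status = NA_character_, m_status = NA_character_,
                   type = NA_character_, stage_at_onset = NA_character_,
                   bands = "", channels = "", peak_ratio = NA_real_,
                   awakening_candidate = FALSE, rem_discarded = FALSE)
  for (nm in names(defaults)) if (!nm %in% names(df)) df[[nm]] <- defaults[[nm]]
  df <- df[order(df$subject_id, df$onset_s), cols, drop = FALSE]
  rownames(df) <- NULL
  if (check && nrow(df) > 1L) {
    same <- df$subject_id[-1L] == df$subject_id[-nrow(df)]
    gap <- df$onset_s[-1L] - (df$onset_s[-nrow(df)] + df$duration_s[-nrow(df)])
    if (any(same & gap < 0)) stop("event-overlap-error: overlapping events for a subject")
  }
  class(df) <- c("arousal_events", "data.frame")
  df
}

#' Write an event table to CSV
#'
#' Events are written sorted by onset; overlapping events raise
#' `"event-overlap-error"`. `read_events(write_events(x))` reproduces `x`
#' field for field.
#'
#' @param events an [arousal_events()] table.
#' @param path output CSV path.
#' @export
write_events <- function(events, path) {
  events <- arousal_events(as.data.frame(events))
  utils::write.csv(events, path, row.names = FALSE, quote = TRUE, na = "NA")
  invisible(path)
}

#' Read an event table from CSV
#' @param path CSV path written by [write_events()].
#' @return an [arousal_events()] table.
#' @export
read_events <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(subject_id = "character",
                                       bands = "character",
                                       channels = "character"))
  df$bands[is.na(df$bands)] <- ""
  df$channels[is.na(df$channels)] <- ""
  arousal_events(df)
}
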