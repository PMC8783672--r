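#' Sleep-stage hypnogram
#'
#' A hypnogram is an ordered sequence of 30-second sleep-stage epochs over
#' the AASM vocabulary `W, N1, N2, N3, REM`. Epoch `k` (1-based) covers the
#' half-open interval `[30 * (k - 1), 30 * k)` seconds from recording start.
#'
#' @param stages character vector of stages, each one of
#'   `"W", "N1", "N2", "N3", "REM"`.
#' @param epoch_length epoch length in seconds; only 30 is supported.
#' @return An object of class `hypnogram`: a character vector with
#'   attribute `epoch_length`.
#' @examples
#' hyp <- hypnogram(c("W", "N1", "N2", "N2", "REM"))
#' length(hyp)
#' @export
hypnogram <- function(stages, epoch_length = 30) {
  stages <- as.character(stages)
  if (length(stages) == 0L) stop("hypnogram must contain at least one epoch")
  bad <- setdiff(unique(stages), ASCAPE_STAGES)
  if (length(bad)) {
    stop("unknown sleep stage(s): ", paste(bad, collapse = ", "))
  }
  if (!identical(as.numeric(epoch_length), 30)) {
    stop("epoch_length must be 30 seconds")
  }
  structure(stages, epoch_length = 30, class = "hypnogram")
}

#' @export
print.hypnogram <- function(x, ...) {
  cat("<hypnogram> ", length(x), " x 30-s epochs (",
      format(length(x) / 120, digits = 3), " h)\n", sep = "")
  tab <- table(factor(unclass(x), levels = ASCAPE_STAGES))
  print(tab)
  invisible(x)
}

#' @export
`[.hypnogram` <- function(x, i) hypnogram(unclass(x)[i])

#' Stage at a given time
#'
#' @param hyp a [hypnogram()].
#' @param time_s time in seconds from recording start.
#' @return character vector of stages at those times.
#' @export
stage_at <- function(hyp, time_s) {
  stopifnot(inherits(hyp, "hypnogram"))
  k <- floor(time_s / 30) + 1L
  if (any(k < 1L | k > length(hyp))) {
    stop("pairing-error: time outside hypnogram span")
  }
  unclass(hyp)[k]
}

#' Default stage alias table
#'
#' Maps common lab dialect tokens (including AASM numeric codes
#' 0/1/2/3/5 and `R`) onto the canonical stage vocabulary. The alias table
#' is configuration: pass your own named vector to [read_hypnogram()] for
#' other dialects.
#'
#' @return named character vector, `names` are input tokens, values
#'   canonical stages.
#' @export
stage_aliases <- function() {
  c("W" = "W", "N1" = "N1", "N2" = "N2", "N3" = "N3", "REM" = "REM",
    "0" = "W", "1" = "N1", "2" = "N2", "3" = "N3", "4" = "N3", "5" = "REM",
    "R" = "REM", "WAKE" = "W", "S1" = "N1", "S2" = "N2", "S3" = "N3",
    "S4" = "N3")
}

#' Read a hypnogram file
#'
#' Two dialects are supported: `"lines"` (one stage token per line, possibly
#' comma-separated on a single line) and `"csv"` (a CSV with a `stage`
#' column, e.g. alongside an `onset` column). Unknown tokens raise an error
#' naming the offending line; they are never skipped.
#'
#' @param path file path.
#' @param dialect `"lines"` or `"csv"`.
#' @param aliases named character vector mapping file tokens to canonical
#'   stages; defaults to [stage_aliases()].
#' @return a [hypnogram()].
#' @export
read_hypnogram <- function(path, dialect = c("lines", "csv"),
                           aliases = stage_aliases()) {
  dialect <- match.arg(dialect)
  if (dialect == "lines") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    toks <- lapply(lines, function(l) trimws(strsplit(l, ",")[[1]]))
    line_of <- rep(seq_along(lines), lengths(toks))
    toks <- unlist(toks)
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (!"stage" %in% names(df)) stop("format-error: csv dialect needs a 'stage' column")
    toks <- trimws(as.character(df$stage))
    line_of <- seq_along(toks) + 1L
  }
  mapped <- aliases[toupper(toks)]
  if (anyNA(mapped)) {
    i <- which(is.na(mapped))[1L]
    stop(sprintf("stage-token-error: unknown stage token '%s' at line %d",
                 toks[i], line_of[i]))
  }
  hypnogram(unname(mapped))
}

#' Write a hypnogram file (one stage per line)
#'
#' @param hyp a [hypnogram()].
#' @param path file path.
#' @export
write_hypnogram <- function(hyp, path) {
  stopifnot(inherits(hyp, "hypnogram"))
  writeLines(unclass(hyp), path)
  invisible(path)
}

#' Check hypnogram / recording pairing
#'
#' The hypnogram duration (30 s per epoch) must be within one epoch of the
#' signal duration. Enforced at pairing time because a hypnogram file alone
#' cannot know the signal length.
#'
#' @param hyp a [hypnogram()].
#' @param rec a [psg_recording()].
#' @return invisibly `TRUE`, or a `"pairing-error"` condition.
#' @export
check_pairing <- function(hyp, rec) {
  n_sig <- floor(psg_duration(rec) / 30)
  if (abs(n_sig - length(hyp)) > 1L) {
    stop(sprintf(
      "pairing-error: hypnogram has %d epochs but signal spans %d",
      length(hyp), n_sig))
  }
  invisible(TRUE)
}
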