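#' Acquisition frame schedule
#'
#' Represents the sequence of contiguous time bins into which dynamic PET
#' list-mode data are histogrammed. Frames are stored in seconds (the unit
#' scanners print); model evaluation converts to minutes internally.
#'
#' @param start_s frame start times (s); first frame must start at 0.
#' @param end_s frame end times (s); frames must be contiguous,
#'   non-overlapping and of positive duration.
#' @return An object of class `frame_schedule`: a data.frame with columns
#'   `start_s`, `end_s`.
#' @seealso [parse_frame_spec] for the compact `"NxS,NxS,..."` notation.
#' @export
frame_schedule <- function(start_s, end_s) {
  if (length(start_s) != length(end_s) || length(start_s) == 0L)
    stop("start_s and end_s must be nonempty and of equal length", call. = FALSE)
  if (start_s[1L] != 0)
    stop("first frame must start at 0 s", call. = FALSE)
  if (any(end_s <= start_s))
    stop("every frame must have positive duration", call. = FALSE)
  if (length(start_s) > 1L && any(abs(start_s[-1L] - end_s[-length(end_s)]) > 1e-9))
    stop("frames must be contiguous and non-overlapping", call. = FALSE)
  structure(data.frame(start_s = as.numeric(start_s), end_s = as.numeric(end_s)),
            class = c("frame_schedule", "data.frame"))
}

#' Parse a compact frame-schedule specification
#'
#' Expands a text specification of the form `"NxS,NxS,..."` -- N frames of S
#' seconds each -- into a contiguous [frame_schedule]. The 60-min dynamic
#' protocol used throughout this package is
#' `"10x2,8x5,6x10,6x20,8x60,10x120,5x300"`: 53 frames totalling 3420 s.
#'
#' @param spec specification string; counts and durations are positive
#'   integers (seconds).
#' @return A [frame_schedule].
#' @examples
#' sched <- parse_frame_spec("10x2,8x5,6x10,6x20,8x60,10x120,5x300")
#' nrow(sched)      # 53
#' max(sched$end_s) # 3420
#' @export
parse_frame_spec <- function(spec) {
  if (!is.character(spec) || length(spec) != 1L || !nzchar(trimws(spec)))
    stop("frame spec must be a nonempty string", call. = FALSE)
  tokens <- strsplit(trimws(spec), ",", fixed = TRUE)[[1L]]
  durs <- numeric(0)
  for (tok in tokens) {
    m <- regmatches(tok, regexec("^\\s*([0-9]+)\\s*x\\s*([0-9]+)\\s*$", tok))[[1L]]
    if (length(m) != 3L)
      stop(sprintf("malformed frame token '%s' (expected NxS)", tok), call. = FALSE)
    n <- as.integer(m[2L]); s <- as.integer(m[3L])
    if (n < 1L || s < 1L)
      stop(sprintf("counts and durations must be positive in token '%s'", tok),
           call. = FALSE)
    durs <- c(durs, rep(s, n))
  }
  ends <- cumsum(durs)
  frame_schedule(start_s = c(0, ends[-length(ends)]), end_s = ends)
}

#' Serialize a frame schedule back to the compact notation
#'
#' Inverse of [parse_frame_spec] for schedules with integer-second frames.
#'
#' @param schedule a [frame_schedule].
#' @return A `"NxS,NxS,..."` string.
#' @export
format_frame_spec <- function(schedule) {
  durs <- schedule$end_s - schedule$start_s
  r <- rle(durs)
  paste(sprintf("%dx%d", r$lengths, as.integer(r$values)), collapse = ",")
}

#' @export
print.frame_schedule <- function(x, ...) {
  cat(sprintf("Frame schedule: %d frames, %g s total (%s)\n",
              nrow(x), max(x$end_s), format_frame_spec(x)))
  invisible(x)
}

# frame midpoints in minutes (internal model time unit)
frame_mid_min <- function(schedule) (schedule$start_s + schedule$end_s) / 120

#' Time-activity curve container
#'
#' A TAC pairs a [frame_schedule] with frame-averaged activity
#' concentrations (and optional per-frame standard deviations).
#'
#' @param schedule a [frame_schedule].
#' @param value frame-averaged concentrations, one per frame.
#' @param sd optional per-frame standard deviations.
#' @return An object of class `tac`: a data.frame with columns `start_s`,
#'   `end_s`, `value` (and `sd` if given).
#' @export
tac <- function(schedule, value, sd = NULL) {
  stopifnot(inherits(schedule, "frame_schedule"))
  if (length(value) != nrow(schedule))
    stop("one value per frame is required", call. = FALSE)
  df <- data.frame(start_s = schedule$start_s, end_s = schedule$end_s,
                   value = as.numeric(value))
  if (!is.null(sd)) {
    if (length(sd) != nrow(schedule))
      stop("one sd per frame is required", call. = FALSE)
    df$sd <- as.numeric(sd)
  }
  structure(df, class = c("tac", "data.frame"))
}

# recover the schedule from a TAC
tac_schedule <- function(x) frame_schedule(x$start_s, x$end_s)

#' @export
print.tac <- function(x, ...) {
  cat(sprintf("Time-activity curve: %d frames over %g min, peak %.4g, last-frame %.4g\n",
              nrow(x), max(x$end_s) / 60, max(x$value), x$value[nrow(x)]))
  invisible(x)
}

#' @export
plot.tac <- function(x, xlab = "Time (min)", ylab = "Concentration",
                     log_time = FALSE, add = FALSE, ...) {
  tm <- frame_mid_min(x)
  if (add) graphics::lines(tm, x$value, ...)
  else graphics::plot(tm, x$value, type = "b", xlab = xlab, ylab = ylab,
                      log = if (log_time) "x" else "", ...)
  invisible(x)
}
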