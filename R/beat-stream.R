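#' Construct a labeled beat stream
#'
#' A beat stream is the raw analysis input: an ordered sequence of beat
#' times (seconds from recording start) with one annotation label per beat
#' — `N` (normal/sinus), `V` (ventricular), `A` (atrial), `X` (artifact or
#' unknown). Timestamps lie on a 1/125 s grid, matching the digitization
#' resolution of clinical Holter systems.
#'
#' @param time_s Numeric vector of beat times in seconds, strictly
#'   increasing, within `[0, duration_s]`.
#' @param label Character vector of beat labels, same length as `time_s`,
#'   each one of `"N"`, `"V"`, `"A"`, `"X"`.
#' @param id Recording identifier.
#' @param start_clock_h Wall-clock hour in `[0, 24)` corresponding to
#'   `time_s = 0`.
#' @param duration_s Recording duration in seconds (defaults to the last
#'   beat time).
#'
#' @return An object of class `beat_stream`: a list with a `beats`
#'   data frame (`time_s`, `label`) and a `meta` list.
#' @examples
#' bs <- beat_stream(c(0.8, 1.6, 2.4), c("N", "N", "V"), id = "ex")
#' n_beats(bs)
#' @export
beat_stream <- function(time_s, label, id = "rec",
                        start_clock_h = 0,
                        duration_s = if (length(time_s)) max(time_s) else 0) {
  stopifnot(length(time_s) == length(label))
  x <- structure(
    list(
      beats = data.frame(time_s = as.numeric(time_s),
                         label = as.character(label),
                         stringsAsFactors = FALSE),
      meta = list(id = id, start_clock_h = start_clock_h,
                  duration_s = duration_s)
    ),
    class = "beat_stream"
  )
  validate_beat_stream(x)
  x
}

TICK_S <- 1 / 125  # Holter digitization grid

validate_beat_stream <- function(x) {
  stopifnot(inherits(x, "beat_stream"))
  b <- x$beats
  if (nrow(b)) {
    if (any(diff(b$time_s) <= 0))
      stop("beat times must be strictly increasing", call. = FALSE)
    if (b$time_s[1] < 0 || b$time_s[nrow(b)] > x$meta$duration_s + 1e-9)
      stop("beat times must lie within [0, duration]", call. = FALSE)
    off <- abs(b$time_s / TICK_S - round(b$time_s / TICK_S))
    if (any(off > 1e-6))
      stop("beat times must lie on the 1/125 s grid", call. = FALSE)
  }
  bad <- setdiff(unique(b$label), c("N", "V", "A", "X"))
  if (length(bad))
    stop("unknown beat labels: ", paste(bad, collapse = ", "), call. = FALSE)
  invisible(x)
}

#' @rdname beat_stream
#' @param x A `beat_stream`.
#' @export
n_beats <- function(x) nrow(x$beats)

#' @export
print.beat_stream <- function(x, ...) {
  b <- x$beats
  cat(sprintf("<beat_stream '%s'> %d beats over %.1f h (start clock %02.0f:00)\n",
              x$meta$id, nrow(b), x$meta$duration_s / 3600,
              x$meta$start_clock_h))
  if (nrow(b)) {
    tab <- table(factor(b$label, levels = c("N", "V", "A", "X")))
    cat("  labels:", paste(names(tab), tab, sep = "=", collapse = " "), "\n")
  }
  invisible(x)
}

# Wall-clock hour in [0, 24) of each beat (or arbitrary time vector).
clock_hours <- function(time_s, start_clock_h = 0) {
  (start_clock_h + time_s / 3600) %% 24
}

# Snap times to the digitization grid. Dividing by 125 (rather than
# multiplying by 1/125) yields the correctly-rounded double for k/125,
# which is also what parsing the 3-decimal CSV representation gives —
# so write/read round trips are bit-exact.
quantize_times <- function(time_s) round(time_s * 125) / 125
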