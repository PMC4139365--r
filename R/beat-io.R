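#' Read a beat annotation file
#'
#' Reads a beat stream from disk. The `csv` dialect is the package's
#' native two-column format (`time_s,label`). The `wfdb-ann` dialect
#' accepts the plain-text output of `rdann -v` style annotation dumps:
#' whitespace-separated columns where the second column is the elapsed
#' time in seconds (or a sample index when `fs` is given) and the third
#' the annotation mnemonic. Labels other than `N`, `V`, `A` are mapped to
#' `X` with a warning.
#'
#' @param path File to read.
#' @param dialect `"csv"` (default) or `"wfdb-ann"`.
#' @param id Recording identifier to attach (defaults to the file name).
#' @param start_clock_h Wall-clock hour of recording start.
#' @param fs For `wfdb-ann`: if supplied, the time column is interpreted
#'   as a sample index at this sampling frequency (Hz).
#' @return A [beat_stream()].
#' @export
read_beats <- function(path, dialect = c("csv", "wfdb-ann"),
                       id = basename(path), start_clock_h = 0, fs = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (dialect == "csv") {
    d <- utils::read.csv(path, colClasses = c("numeric", "character"))
    if (!all(c("time_s", "label") %in% names(d)))
      stop("CSV beat file must have columns time_s,label", call. = FALSE)
    time_s <- d$time_s
    label <- d$label
  } else {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    if (!length(lines)) {
      time_s <- numeric(0); label <- character(0)
    } else {
      parts <- strsplit(trimws(lines), "[[:space:]]+")
      if (any(lengths(parts) < 2))
        stop("malformed annotation line in ", path, call. = FALSE)
      # columns: [clock-time] elapsed-or-sample mnemonic ...
      has_clock <- lengths(parts) >= 3
      tcol <- vapply(parts, function(p) p[[1 + (length(p) >= 3)]], "")
      label <- vapply(parts, function(p) p[[min(3, length(p))]], "")
      time_s <- as.numeric(tcol)
      if (anyNA(time_s))
        stop("non-numeric time field in ", path, call. = FALSE)
      if (!is.null(fs)) time_s <- time_s / fs
      time_s <- quantize_times(time_s)
    }
  }
  bad <- !(label %in% c("N", "V", "A", "X"))
  if (any(bad)) {
    warning(sum(bad), " unknown beat label(s) mapped to X", call. = FALSE)
    label[bad] <- "X"
  }
  if (length(time_s) > 1) {
    drop <- which(diff(time_s) <= 0)
    if (length(drop))
      stop(sprintf("non-monotone timestamps in %s (first at data row %d)",
                   path, drop[1] + 1L), call. = FALSE)
  }
  beat_stream(time_s, label, id = id, start_clock_h = start_clock_h)
}

#' Build the normal-to-normal (NN) interval series
#'
#' HRV analysis operates on intervals between consecutive sinus beats
#' only. An interval is retained iff both of its bounding beats are
#' labeled `N` and its duration lies within physiological bounds; both
#' intervals adjacent to every ectopic/artifact beat (`V`, `A`, `X`) are
#' therefore removed, as is standard practice — ectopy corrupts both
#' neighboring intervals. Removed intervals are dropped, never
#' interpolated. An exclusion log records how many intervals were removed
#' and why.
#'
#' @param stream A [beat_stream()] with at least 3 beats.
#' @param bounds_ms Physiological interval bounds in ms
#'   (default `c(200, 3000)`).
#' @return An object of class `nn_series`: a list with `intervals` (data
#'   frame `onset_time_s`, `nn_ms`), `source` (recording id and start
#'   clock), and `exclusions` (named counts: `retained`, `ectopic_adjacent`,
#'   `out_of_bounds`, `total`).
#' @examples
#' bs <- beat_stream(seq(0, 4), c("N", "N", "V", "N", "N"))
#' nn <- build_nn(bs)
#' nn$intervals
#' nn$exclusions
#' @export
build_nn <- function(stream, bounds_ms = c(200, 3000)) {
  validate_beat_stream(stream)
  b <- stream$beats
  if (nrow(b) < 3) stop("need at least 3 beats", call. = FALSE)
  stopifnot(length(bounds_ms) == 2, bounds_ms[1] > 0,
            bounds_ms[2] > bounds_ms[1])

  n <- nrow(b)
  nn_ms <- diff(b$time_s) * 1000
  both_n <- b$label[-n] == "N" & b$label[-1] == "N"
  in_bounds <- nn_ms >= bounds_ms[1] & nn_ms <= bounds_ms[2]
  keep <- both_n & in_bounds

  if (sum(keep) < 2)
    stop("fewer than 2 NN intervals retained", call. = FALSE)

  excl <- c(
    retained = sum(keep),
    ectopic_adjacent = sum(!both_n),
    out_of_bounds = sum(both_n & !in_bounds),
    total = n - 1L
  )

  structure(
    list(
      intervals = data.frame(onset_time_s = b$time_s[-n][keep],
                             nn_ms = nn_ms[keep]),
      source = list(id = stream$meta$id,
                    start_clock_h = stream$meta$start_clock_h,
                    duration_s = stream$meta$duration_s,
                    bounds_ms = bounds_ms),
      exclusions = excl
    ),
    class = "nn_series"
  )
}

#' @export
print.nn_series <- function(x, ...) {
  e <- x$exclusions
  cat(sprintf("<nn_series '%s'> %d NN intervals (%.1f%% of %d excluded)\n",
              x$source$id, e[["retained"]],
              100 * (e[["total"]] - e[["retained"]]) / max(1, e[["total"]]),
              e[["total"]]))
  invisible(x)
}

#' Write the NN exclusion log as a sidecar CSV
#'
#' @param nn An `nn_series` from [build_nn()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_exclusion_log <- function(nn, path) {
  stopifnot(inherits(nn, "nn_series"))
  d <- data.frame(recording = nn$source$id,
                  reason = names(nn$exclusions),
                  count = as.integer(nn$exclusions))
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Segment a recording into clock-aligned analysis windows
#'
#' Tiles the 24-hour day into half-open windows `[start, end)` of equal
#' width, aligned to midnight, and assigns each NN interval (by its onset
#' clock time) and each beat to the window containing it. With a
#' recording shorter than 24 h, windows not covered are still returned
#' (empty).
#'
#' @param stream A [beat_stream()].
#' @param nn The matching `nn_series` (from [build_nn()]), or `NULL`.
#' @param bin_h Window width in hours; must divide 24. 3 h matches the
#'   per-window metric tables; 6 h gives the four quartiles of the day.
#' @return A list of `window` objects, each a list with `start_clock_h`,
#'   `end_clock_h`, `nn` (data frame slice), `beats` (data frame slice).
#' @examples
#' cfg <- sim_config(duration_h = 24, seed = 3)
#' bs <- generate_beat_times(cfg)
#' w <- segment_windows(bs, build_nn(bs), bin_h = 6)
#' sapply(w, function(x) nrow(x$nn))
#' @export
segment_windows <- function(stream, nn = NULL, bin_h = 3) {
  validate_beat_stream(stream)
  if (24 %% bin_h != 0)
    stop("bin_h must divide 24", call. = FALSE)
  nwin <- as.integer(24 / bin_h)
  starts <- (seq_len(nwin) - 1) * bin_h

  beat_clock <- clock_hours(stream$beats$time_s, stream$meta$start_clock_h)
  beat_bin <- pmin(floor(beat_clock / bin_h) + 1L, nwin)
  if (!is.null(nn)) {
    stopifnot(inherits(nn, "nn_series"))
    nn_clock <- clock_hours(nn$intervals$onset_time_s, nn$source$start_clock_h)
    nn_bin <- pmin(floor(nn_clock / bin_h) + 1L, nwin)
  }

  lapply(seq_len(nwin), function(i) {
    structure(
      list(
        start_clock_h = starts[i],
        end_clock_h = starts[i] + bin_h,
        beats = stream$beats[beat_bin == i, , drop = FALSE],
        nn = if (is.null(nn)) NULL
             else nn$intervals[nn_bin == i, , drop = FALSE]
      ),
      class = "analysis_window"
    )
  })
}
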