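#' Quantify ventricular arrhythmias in a beat stream
#'
#' Finds maximal runs of consecutive `V`-labeled beats. Runs of three or
#' more beats are ventricular-tachycardia (VT) episodes and contribute
#' all of their beats to the VT beat count; `V` beats in runs of length
#' one or two are counted as premature ventricular complexes (PVCs), so
#' the three totals are disjoint (a couplet counts as 2 PVCs). Each event
#' is timed by its first beat and assigned to the clock window containing
#' that time.
#'
#' @param stream A [beat_stream()].
#' @param bin_h Width of the time-of-day bins (hours, divides 24);
#'   default 6 gives the four quartiles of the day.
#' @return An object of class `arrhythmia_counts`: list with totals
#'   `pvc_count`, `vt_episode_count`, `vt_beat_count`, a per-window data
#'   frame `by_window` (`start_clock_h`, `end_clock_h`, `pvc`,
#'   `vt_episodes`, `vt_beats`), and `events` (one row per PVC or VT
#'   episode with onset time and run length).
#' @examples
#' bs <- beat_stream(seq(0.8, 4.0, by = 0.8),
#'                   c("N", "V", "V", "V", "N"))
#' classify_ventricular(bs)$vt_episode_count
#' @export
classify_ventricular <- function(stream, bin_h = 6) {
  validate_beat_stream(stream)
  if (24 %% bin_h != 0) stop("bin_h must divide 24", call. = FALSE)
  nwin <- as.integer(24 / bin_h)
  starts <- (seq_len(nwin) - 1) * bin_h
  empty_by_window <- data.frame(start_clock_h = starts,
                                end_clock_h = starts + bin_h,
                                pvc = 0L, vt_episodes = 0L, vt_beats = 0L)

  b <- stream$beats
  if (!nrow(b) || !any(b$label == "V")) {
    return(structure(
      list(pvc_count = 0L, vt_episode_count = 0L, vt_beat_count = 0L,
           by_window = empty_by_window,
           events = data.frame(onset_time_s = numeric(0),
                               onset_clock_h = numeric(0),
                               type = character(0), length = integer(0))),
      class = "arrhythmia_counts"))
  }

  r <- rle(b$label == "V")
  run_end <- cumsum(r$lengths)
  run_start <- run_end - r$lengths + 1L
  v_runs <- which(r$values)
  lens <- r$lengths[v_runs]
  onset <- b$time_s[run_start[v_runs]]
  onset_clock <- clock_hours(onset, stream$meta$start_clock_h)

  is_vt <- lens >= 3L
  # isolated/couplet V beats are PVCs, each beat counted
  events <- data.frame(
    onset_time_s = onset, onset_clock_h = onset_clock,
    type = ifelse(is_vt, "VT", "PVC"),
    length = lens
  )

  bin_of <- pmin(floor(onset_clock / bin_h) + 1L, nwin)
  by_window <- empty_by_window
  for (i in seq_along(lens)) {
    w <- bin_of[i]
    if (is_vt[i]) {
      by_window$vt_episodes[w] <- by_window$vt_episodes[w] + 1L
      by_window$vt_beats[w] <- by_window$vt_beats[w] + lens[i]
    } else {
      by_window$pvc[w] <- by_window$pvc[w] + lens[i]
    }
  }

  structure(
    list(pvc_count = sum(lens[!is_vt]),
         vt_episode_count = sum(is_vt),
         vt_beat_count = sum(lens[is_vt]),
         by_window = by_window,
         events = events),
    class = "arrhythmia_counts")
}

#' @export
print.arrhythmia_counts <- function(x, ...) {
  cat(sprintf("<arrhythmia_counts> %d PVCs, %d VT episodes (%d VT beats)\n",
              x$pvc_count, x$vt_episode_count, x$vt_beat_count))
  invisible(x)
}

#' Chi-square test of uniform event timing over the day
#'
#' Tests whether event counts in the four quartiles of the day
#' (midnight–6 AM, 6 AM–noon, noon–6 PM, 6 PM–midnight) depart from a
#' uniform distribution, using the chi-square goodness-of-fit statistic
#' \eqn{\sum (O_i - E_i)^2 / E_i} with \eqn{E_i = N/4} and 3 degrees of
#' freedom. Also reports the morning fold: the count in 6 AM–noon divided
#' by the count in the preceding quartile.
#'
#' @param counts Integer vector of per-bin event counts (default
#'   expectation: 4 quartile bins, equal probabilities).
#' @return A list of class `timing_test`: `observed`, `expected`,
#'   `chi2_statistic`, `dof`, `p_value`, `morning_fold` (NA with
#'   `fold_defined = FALSE` when the night quartile is empty), and
#'   `low_count` (TRUE when any expected count < 2, where the asymptotic
#'   test is unreliable).
#' @examples
#' chi2_uniformity(c(10, 25, 10, 10))
#' @export
chi2_uniformity <- function(counts) {
  stopifnot(is.numeric(counts), length(counts) >= 2, all(counts >= 0))
  total <- sum(counts)
  if (total < 1) stop("need at least one event", call. = FALSE)
  ct <- suppressWarnings(stats::chisq.test(counts))
  fold_defined <- length(counts) == 4 && counts[1] > 0
  structure(
    list(observed = as.numeric(counts),
         expected = as.numeric(ct$expected),
         chi2_statistic = unname(ct$statistic),
         dof = unname(ct$parameter),
         p_value = unname(ct$p.value),
         morning_fold = if (fold_defined) counts[2] / counts[1] else NA_real_,
         fold_defined = fold_defined,
         low_count = any(ct$expected < 2)),
    class = "timing_test")
}

#' @export
print.timing_test <- function(x, ...) {
  cat(sprintf("<timing_test> chi2 = %.3f (dof %d), p = %.4g\n",
              x$chi2_statistic, x$dof, x$p_value))
  if (x$fold_defined)
    cat(sprintf("  morning fold (6-12h vs 0-6h): %.2f\n", x$morning_fold))
  if (x$low_count)
    cat("  warning: expected count < 2 in some bin; asymptotic p unreliable\n")
  invisible(x)
}

#' Quartile fold-changes of event counts
#'
#' For per-quartile counts, returns each quartile's count relative to the
#' preceding quartile (cyclically), with the morning fold — quartile
#' `[6,12)` vs `[0,6)` — singled out. A zero denominator yields an
#' NA fold flagged as undefined, never an error.
#'
#' @param counts_by_window Either an `arrhythmia_counts` object (its PVC
#'   column is used unless `column` says otherwise) or a numeric vector
#'   of 4 quartile counts.
#' @param column For `arrhythmia_counts` input: one of `"pvc"`,
#'   `"vt_episodes"`, `"vt_beats"`.
#' @return A list: `counts`, data frame `folds` (`quartile`, `fold`,
#'   `defined`), `morning_fold`, `morning_fold_defined`.
#' @examples
#' fold_change(c(10, 25, 10, 10))$morning_fold
#' @export
fold_change <- function(counts_by_window, column = "pvc") {
  if (inherits(counts_by_window, "arrhythmia_counts")) {
    bw <- counts_by_window$by_window
    if (nrow(bw) != 4)
      stop("fold_change needs quartile (6-h) windows", call. = FALSE)
    counts <- bw[[column]]
  } else {
    counts <- as.numeric(counts_by_window)
    if (length(counts) != 4)
      stop("need 4 quartile counts", call. = FALSE)
  }
  prev <- counts[c(4, 1, 2, 3)]
  defined <- prev > 0
  folds <- ifelse(defined, counts / prev, NA_real_)
  # morning fold uses the preceding quartile within the same day
  morning_defined <- counts[1] > 0
  list(counts = counts,
       folds = data.frame(
         quartile = c("[0,6)", "[6,12)", "[12,18)", "[18,24)"),
         fold = folds, defined = defined),
       morning_fold = if (morning_defined) counts[2] / counts[1] else NA_real_,
       morning_fold_defined = morning_defined)
}
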