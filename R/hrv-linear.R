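#' Time-domain heart-rate variability
#'
#' Computes the standard time-domain markers from an NN interval series:
#' mean RR, mean heart rate, SDNN (standard deviation of NN intervals,
#' population form so that e.g. a perfectly alternating series has SDNN
#' equal to its half-range), CV (coefficient of variation, percent), and
#' rMSSD (root mean square of successive differences). rMSSD uses only
#' pairs of intervals that were adjacent in the source recording: pairs
#' broken by ectopic exclusion are skipped, never bridged.
#'
#' @param nn An `nn_series` from [build_nn()], or a data frame with
#'   columns `onset_time_s` and `nn_ms`.
#' @return A list of class `time_domain_result`: `n`, `mean_rr` (ms),
#'   `mean_hr` (bpm), `sdnn` (ms), `cv` (percent), `rmssd` (ms),
#'   `n_successive_pairs`.
#' @examples
#' bs <- beat_stream(seq(0, 10), rep("N", 11))
#' time_domain(build_nn(bs))$mean_hr
#' @export
time_domain <- function(nn) {
  iv <- nn_intervals(nn)
  if (nrow(iv) < 2) stop("need at least 2 NN intervals", call. = FALSE)
  x <- iv$nn_ms
  mean_rr <- mean(x)
  sdnn <- sqrt(mean((x - mean_rr)^2))
  succ <- successive_pairs(iv)
  rmssd <- if (any(succ)) {
    d <- diff(x)[succ]
    sqrt(mean(d^2))
  } else NA_real_
  structure(
    list(n = nrow(iv),
         mean_rr = mean_rr,
         mean_hr = 60000 / mean_rr,
         sdnn = sdnn,
         cv = sdnn / mean_rr * 100,
         rmssd = rmssd,
         n_successive_pairs = sum(succ)),
    class = "time_domain_result")
}

nn_intervals <- function(nn) {
  if (inherits(nn, "nn_series")) nn$intervals
  else {
    stopifnot(is.data.frame(nn), all(c("onset_time_s", "nn_ms") %in% names(nn)))
    nn
  }
}

# For interval i and i+1: TRUE when interval i+1 starts where interval i
# ends, i.e. no excluded interval sits between them.
successive_pairs <- function(iv) {
  n <- nrow(iv)
  if (n < 2) return(logical(0))
  expected_next <- iv$onset_time_s[-n] + iv$nn_ms[-n] / 1000
  abs(iv$onset_time_s[-1] - expected_next) < TICK_S / 2
}

#' Resample the RR tachogram onto a uniform grid
#'
#' Frequency-domain HRV needs an evenly sampled signal; the NN series is
#' sampled at the (irregular) beat times. This interpolates
#' `(onset_time, nn_ms)` with a cubic spline onto a uniform grid at `fs`
#' Hz and removes the mean. Windows containing an inter-interval gap
#' longer than `max_gap_s` (from heavy exclusion) are flagged unusable
#' rather than bridged by the spline.
#'
#' @param nn An `nn_series` or interval data frame (>= 10 intervals
#'   spanning >= 60 s).
#' @param fs Resampling frequency, Hz (default 4: Nyquist 2 Hz covers the
#'   high-frequency band with margin).
#' @param max_gap_s Largest tolerated gap between successive interval
#'   onsets, seconds.
#' @return List of class `tachogram`: `signal` (ms, mean removed), `fs`,
#'   `t0` (grid origin, s), `mean_ms`, `usable`, `max_gap_s`.
#' @export
resample_tachogram <- function(nn, fs = 4, max_gap_s = 10) {
  iv <- nn_intervals(nn)
  if (nrow(iv) < 10) stop("need at least 10 NN intervals", call. = FALSE)
  span <- diff(range(iv$onset_time_s))
  if (span < 60) stop("series must span at least 60 s", call. = FALSE)
  gap <- max(diff(iv$onset_time_s))
  usable <- gap <= max_gap_s
  grid <- iv$onset_time_s[1] + seq(0, floor(span * fs)) / fs
  f <- stats::splinefun(iv$onset_time_s, iv$nn_ms, method = "fmm")
  sig <- f(grid)
  structure(
    list(signal = sig - mean(sig), fs = fs, t0 = iv$onset_time_s[1],
         mean_ms = mean(sig), usable = usable, max_gap_s = gap),
    class = "tachogram")
}

#' Autoregressive (Burg) power spectral density with LF/HF band powers
#'
#' Fits an AR model of the given order by Burg's method
#' (`stats::ar.burg`) and evaluates the one-sided parametric spectrum
#' \deqn{P(f) = \frac{2\sigma^2/f_s}{\left|1 - \sum_k a_k
#'       e^{-2\pi i f k/f_s}\right|^2}, \quad 0 \le f \le f_s/2,}
#' on a dense grid, then integrates it over the low-frequency
#' (0.04–0.15 Hz) and high-frequency (0.15–0.40 Hz) bands. Band edges are
#' half-open `[lo, hi)` so no power is double-counted at 0.15 Hz.
#'
#' @param signal Evenly sampled, mean-removed tachogram (ms), e.g. the
#'   `signal` of [resample_tachogram()], or a `tachogram` object.
#' @param fs Sampling frequency in Hz (taken from a `tachogram` input).
#' @param order AR model order (default 16).
#' @param n_freq Number of grid points on `[0, fs/2]` (>= 512).
#' @param lf_band,hf_band Band edges in Hz.
#' @return List of class `spectral_result`: `freq` (Hz), `psd` (ms^2/Hz),
#'   `lf_power`, `hf_power` (ms^2), `lf_hf_ratio`, `ar_order`,
#'   `var_pred`.
#' @export
ar_psd <- function(signal, fs = 4, order = 16, n_freq = 1024,
                   lf_band = c(0.04, 0.15), hf_band = c(0.15, 0.40)) {
  if (inherits(signal, "tachogram")) {
    fs <- signal$fs
    signal <- signal$signal
  }
  if (length(signal) <= 3 * order)
    stop("signal length must exceed 3 * order", call. = FALSE)
  if (n_freq < 512) stop("n_freq must be at least 512", call. = FALSE)
  if (stats::sd(signal) == 0)
    stop("constant signal has no spectrum", call. = FALSE)

  fit <- stats::ar.burg(signal, aic = FALSE, order.max = order,
                        demean = TRUE)
  a <- fit$ar
  # Burg is stable by construction; guard against numerical blowup anyway.
  poles <- polyroot(c(-rev(a), 1))
  if (any(Mod(poles) >= 1))
    stop(sprintf("unstable AR fit: max pole modulus %.6f", max(Mod(poles))),
         call. = FALSE)

  freq <- seq(0, fs / 2, length.out = n_freq)
  ek <- exp(-2i * pi * outer(freq / fs, seq_along(a)))
  denom <- Mod(1 - as.vector(ek %*% a))^2
  psd <- (2 * fit$var.pred / fs) / denom

  lf <- band_power(freq, psd, lf_band)
  hf <- band_power(freq, psd, hf_band)
  structure(
    list(freq = freq, psd = psd,
         lf_power = lf, hf_power = hf,
         lf_hf_ratio = lf / hf,
         ar_order = order, var_pred = fit$var.pred,
         total_power = band_power(freq, psd, c(0, fs / 2 + 1e-9))),
    class = "spectral_result")
}

# Trapezoidal integral of the PSD over a half-open band [lo, hi).
band_power <- function(freq, psd, band) {
  sel <- freq >= band[1] & freq < band[2]
  if (sum(sel) < 2) return(0)
  f <- freq[sel]; p <- psd[sel]
  sum(diff(f) * (p[-1] + p[-length(p)]) / 2)
}

#' Windowed spectral analysis with sub-segment averaging
#'
#' Splits a window's NN series into sub-segments of `seg_s` seconds (5 min
#' default), resamples and fits an AR spectrum per usable sub-segment,
#' and averages the spectra before integrating band powers — the usual
#' guard against non-stationarity over multi-hour windows.
#'
#' @param nn An `nn_series` or interval data frame for one window.
#' @param seg_s Sub-segment length, seconds.
#' @inheritParams ar_psd
#' @param fs Resampling frequency, Hz.
#' @return A `spectral_result` (averaged), with `n_segments` used, or
#'   `NULL` when no sub-segment is usable.
#' @export
window_spectral <- function(nn, seg_s = 300, fs = 4, order = 16,
                            lf_band = c(0.04, 0.15), hf_band = c(0.15, 0.40)) {
  iv <- nn_intervals(nn)
  if (nrow(iv) < 10) return(NULL)
  t0 <- min(iv$onset_time_s)
  seg_id <- floor((iv$onset_time_s - t0) / seg_s)
  psds <- list()
  freq <- NULL
  for (s in unique(seg_id)) {
    seg <- iv[seg_id == s, , drop = FALSE]
    if (nrow(seg) < 10 || diff(range(seg$onset_time_s)) < 60) next
    tg <- resample_tachogram(seg, fs = fs)
    if (!tg$usable || length(tg$signal) <= 3 * order) next
    sp <- tryCatch(ar_psd(tg$signal, fs = fs, order = order,
                          lf_band = lf_band, hf_band = hf_band),
                   error = function(e) NULL)
    if (is.null(sp)) next
    freq <- sp$freq
    psds[[length(psds) + 1]] <- sp$psd
  }
  if (!length(psds)) return(NULL)
  psd <- Reduce(`+`, psds) / length(psds)
  lf <- band_power(freq, psd, lf_band)
  hf <- band_power(freq, psd, hf_band)
  structure(
    list(freq = freq, psd = psd, lf_power = lf, hf_power = hf,
         lf_hf_ratio = lf / hf, ar_order = order,
         n_segments = length(psds)),
    class = "spectral_result")
}
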