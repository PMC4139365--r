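#' Generate sinus beat times by integral pulse frequency modulation
#'
#' Emits a beat each time the running integral of an instantaneous rate
#' function crosses the next integer (the IPFM model). The rate, in
#' beats/s, is
#' \deqn{m(t) = \frac{M + A\cos(2\pi (t_{clock} - \phi)/24) + x_{frac}(t)}{60}
#'       \times \left(1 + d_{LF}\sin(2\pi f_{LF} t)
#'                      + d_{HF}\sin(2\pi f_{HF} t)\right)}
#' where \eqn{M} is the heart-rate mesor, \eqn{A} and \eqn{\phi} the
#' circadian amplitude and acrophase, \eqn{x_{frac}} the fractal rate
#' component (bpm), and \eqn{d_{LF}, d_{HF}} the autonomic modulation
#' depths. Beat times are quantized to the 1/125 s digitization grid.
#'
#' @param config A [sim_config()].
#' @return A [beat_stream()] with all beats labeled `N`.
#' @examples
#' cfg <- sim_config(duration_h = 0.5, hr_mesor = 60, hr_circ_amplitude = 0,
#'                   lf_depth = 0, hf_depth = 0, fractal_sd = 0)
#' bs <- generate_beat_times(cfg)
#' head(diff(bs$beats$time_s))  # all exactly 1 s at a constant 60 bpm
#' @export
generate_beat_times <- function(config) {
  validate_sim_config(config)
  dur_s <- config$duration_h * 3600
  dt <- 5 * TICK_S  # integration step; crossings are refined below
  tt <- seq(0, dur_s, by = dt)
  rate <- instantaneous_rate(tt, config)  # beats/s
  if (any(rate <= 0))
    stop("instantaneous rate is non-positive; modulation depths or ",
         "fractal_sd too large for hr_mesor", call. = FALSE)

  # Cumulative integral at grid resolution; each integer crossing emits
  # one beat. Per-step increments are far below 1, so at most one beat
  # per step; the crossing time is located by linear interpolation inside
  # the step, then snapped to the 1/125 s digitization grid.
  cum <- cumsum(rate * dt)
  hits <- which(diff(c(0, floor(cum))) >= 1)
  prev <- c(0, cum)[hits]
  frac <- (ceiling(prev + 1e-12) - prev) / (cum[hits] - prev)
  # increment k covers [tt[k], tt[k] + dt); prev is the integral at tt[k]
  time_s <- quantize_times(tt[hits] + frac * dt)
  time_s <- time_s[time_s <= dur_s]
  # quantization can collide only if two beats fall inside one tick;
  # impossible at physiological rates, but guard anyway
  keep <- c(TRUE, diff(time_s) > 0)
  time_s <- time_s[keep]

  beat_stream(time_s, rep("N", length(time_s)),
              id = sprintf("sim-seed%d", config$seed),
              start_clock_h = config$start_clock_h,
              duration_s = dur_s)
}

# Instantaneous beat rate in beats/s on a time grid (seconds from start).
instantaneous_rate <- function(tt, config) {
  tclock <- clock_hours(tt, config$start_clock_h)
  hr <- config$hr_mesor +
    config$hr_circ_amplitude * cos(2 * pi * (tclock - config$hr_acrophase) / 24)
  if (config$fractal_sd > 0) {
    hr <- hr + fractal_rate_component(tt, config)
  }
  lf_depth_t <- config$lf_depth
  if (config$lf_circ_frac > 0) {
    lf_depth_t <- lf_depth_t *
      (1 + config$lf_circ_frac *
         cos(2 * pi * (tclock - config$lf_circ_acrophase) / 24))
  }
  modulation <- 1 +
    lf_depth_t * sin(2 * pi * config$lf_freq * tt) +
    config$hf_depth * sin(2 * pi * config$hf_freq * tt)
  hr / 60 * modulation
}

# Fractal rate component (bpm) on an arbitrary grid: synthesized at 2 Hz
# (enough bandwidth to shape beat-to-beat scaling) and linearly
# interpolated. Sampled at n >= 256 even for short test recordings.
fractal_rate_component <- function(tt, config) {
  fs_noise <- 2
  n_noise <- max(256L, as.integer(ceiling(max(tt) * fs_noise)) + 2L)
  noise <- generate_fractal_noise(n_noise, config$fractal_alpha,
                                  sd = config$fractal_sd,
                                  seed = derive_seed(config$seed, "fractal"))
  stats::approx(x = seq_len(n_noise) / fs_noise, y = noise, xout = tt,
                rule = 2)$y
}

#' Inject ventricular ectopy into a sinus beat stream
#'
#' Places isolated premature ventricular complexes (PVCs) and ventricular
#' tachycardia (VT) episodes into an all-normal stream. Event times follow
#' an inhomogeneous Poisson process whose rate (events/hour) is a
#' half-wave-rectified cosine of wall-clock time,
#' \deqn{r(t) = r_0 \left(1 + (F - 1)\,
#'       \max(0, \cos(2\pi (t - \phi)/24))\right),}
#' so `F = pvc_morning_fold` controls a smooth surge peaking at the
#' configured acrophase. A PVC replaces one sinus beat with a `V` beat at
#' a shortened coupling interval (60% of the local RR) followed by a
#' compensatory pause (the next sinus beat is untouched). A VT episode
#' relabels a run of consecutive beats `V`, with run length uniform on
#' `[vt_len_min, vt_len_max]`.
#'
#' Injection never reorders timestamps and never changes the recording
#' duration.
#'
#' @param stream A [beat_stream()] containing only `N` beats.
#' @param config A [sim_config()] supplying the ectopy parameters and seed.
#' @return A `beat_stream` with `V` labels added.
#' @export
inject_ectopy <- function(stream, config) {
  validate_beat_stream(stream)
  validate_sim_config(config)
  if (any(stream$beats$label != "N"))
    stop("inject_ectopy expects an all-N stream", call. = FALSE)
  nb <- n_beats(stream)
  if (config$pvc_base_rate == 0 && config$vt_rate == 0) return(stream)
  if (nb < 10) stop("stream too short for ectopy injection", call. = FALSE)

  dur_h <- stream$meta$duration_s / 3600
  mean_len <- (config$vt_len_min + config$vt_len_max) / 2
  expected <- ectopy_rate_integral(config$pvc_base_rate,
                                   config$pvc_morning_fold,
                                   config$pvc_acrophase,
                                   stream$meta$start_clock_h, dur_h) +
    mean_len * ectopy_rate_integral(config$vt_rate, config$pvc_morning_fold,
                                    config$pvc_acrophase,
                                    stream$meta$start_clock_h, dur_h)
  if (expected > 0.5 * nb)
    stop("configured ectopy is denser than the underlying beat stream",
         call. = FALSE)

  beats <- stream$beats
  time_s <- beats$time_s
  label <- beats$label

  # VT episodes first (they claim longer runs), then PVCs in the gaps.
  vt_times <- thinned_event_times(config$vt_rate, config, stream,
                                  derive_seed(config$seed, "vt"))
  if (length(vt_times)) {
    old <- get_rng_state(); on.exit(restore_rng_state(old), add = TRUE)
    set.seed(derive_seed(config$seed, "vt") + 1L)
    # sample.int avoids the sample() scalar expansion when min == max
    lens <- config$vt_len_min - 1L +
      sample.int(config$vt_len_max - config$vt_len_min + 1L,
                 length(vt_times), replace = TRUE)
    for (i in seq_along(vt_times)) {
      k <- findInterval(vt_times[i], time_s)
      idx <- seq(k, k + lens[i] - 1)
      if (k < 2 || max(idx) > nb - 1) next
      if (any(label[c(idx - 1L, idx, max(idx) + 1L)] != "N")) next
      label[idx] <- "V"
    }
  }

  pvc_times <- thinned_event_times(config$pvc_base_rate, config, stream,
                                   derive_seed(config$seed, "pvc"))
  for (tv in pvc_times) {
    k <- findInterval(tv, time_s)
    if (k < 2 || k > nb - 1) next
    if (any(label[(k - 1):(k + 1)] != "N")) next
    coupled <- quantize_times(time_s[k - 1] + 0.6 * (time_s[k] - time_s[k - 1]))
    if (coupled <= time_s[k - 1] || coupled >= time_s[k + 1]) next
    time_s[k] <- coupled
    label[k] <- "V"
  }

  beat_stream(time_s, label, id = stream$meta$id,
              start_clock_h = stream$meta$start_clock_h,
              duration_s = stream$meta$duration_s)
}

# Inhomogeneous Poisson event times over the recording, by thinning
# against the peak rate of the half-wave-rectified cosine profile.
thinned_event_times <- function(base_rate, config, stream, seed) {
  if (base_rate <= 0) return(numeric(0))
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  dur_h <- stream$meta$duration_s / 3600
  rmax <- base_rate * max(1, config$pvc_morning_fold)
  n_cand <- stats::rpois(1, rmax * dur_h)
  if (n_cand == 0) return(numeric(0))
  cand <- sort(stats::runif(n_cand, 0, stream$meta$duration_s))
  tclock <- clock_hours(cand, stream$meta$start_clock_h)
  r <- ectopy_rate(tclock, base_rate, config$pvc_morning_fold,
                   config$pvc_acrophase)
  cand[stats::runif(n_cand) < r / rmax]
}

#' Time-of-day ectopy rate profile and its integral
#'
#' `ectopy_rate()` evaluates the half-wave-rectified cosine rate profile
#' (events/hour) at given clock hours; `ectopy_rate_integral()` integrates
#' it over a clock interval, giving the expected event count — useful for
#' checking empirical quartile fold-changes against the configured
#' profile.
#'
#' @param tclock_h Clock hours in `[0, 24)`.
#' @param base_rate Baseline rate, events/hour.
#' @param fold Peak-to-base fold of the profile.
#' @param acrophase_h Clock hour of the profile peak.
#' @param from_clock_h,duration_h Integration window: start clock hour and
#'   length in hours (may exceed 24 for multi-day spans).
#' @return Rate vector (events/hour), or expected count over the window.
#' @examples
#' # expected morning-vs-night quartile ratio of a 2.5-fold profile
#' m <- ectopy_rate_integral(20, 2.5, 9, 6, 6)
#' n <- ectopy_rate_integral(20, 2.5, 9, 0, 6)
#' m / n
#' @export
ectopy_rate <- function(tclock_h, base_rate, fold, acrophase_h) {
  base_rate * (1 + (fold - 1) * pmax(0, cos(2 * pi * (tclock_h - acrophase_h) / 24)))
}

#' @rdname ectopy_rate
#' @export
ectopy_rate_integral <- function(base_rate, fold, acrophase_h,
                                 from_clock_h, duration_h) {
  if (base_rate <= 0 || duration_h <= 0) return(0)
  f <- function(t) ectopy_rate(t %% 24, base_rate, fold, acrophase_h)
  stats::integrate(f, from_clock_h, from_clock_h + duration_h,
                   subdivisions = 400L, rel.tol = 1e-8)$value
}

#' Simulate a complete synthetic Holter recording
#'
#' Convenience wrapper: [generate_beat_times()] followed by
#' [inject_ectopy()].
#'
#' @param config A [sim_config()].
#' @return A [beat_stream()].
#' @export
simulate_holter <- function(config) {
  inject_ectopy(generate_beat_times(config), config)
}

#' Write and read beat streams as CSV
#'
#' The on-disk format is a two-column CSV with header `time_s,label`;
#' times are written with millisecond precision (exact for the 1/125 s
#' grid), so a write/read round trip reproduces the stream.
#'
#' @param stream A [beat_stream()].
#' @param path Output file path.
#' @return `write_beats()` returns `path` invisibly.
#' @export
write_beats <- function(stream, path) {
  validate_beat_stream(stream)
  b <- stream$beats
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("time_s,label", con)
  if (nrow(b))
    writeLines(sprintf("%.3f,%s", b$time_s, b$label), con)
  invisible(path)
}
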