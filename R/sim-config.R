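#' Simulator configuration for synthetic 24-hour Holter beat streams
#'
#' Bundles every parameter of the beat-stream generator: the circadian
#' heart-rate rhythm, low-/high-frequency autonomic modulation, the fractal
#' rate component, and the ventricular ectopy process with its morning
#' surge. All defaults describe a healthy large-mammal baseline recording;
#' a failing-heart condition is emulated by flattening the circadian
#' amplitude, lowering the fractal scaling exponent and switching on
#' ectopy (see the methods vignette).
#'
#' @param duration_h Recording duration in hours.
#' @param start_clock_h Clock time (hours in `[0, 24)`) at which the
#'   recording starts; time 0 of the stream maps to this wall-clock hour.
#' @param hr_mesor Rhythm-adjusted mean heart rate, beats/min.
#' @param hr_circ_amplitude Circadian amplitude of heart rate, beats/min.
#'   Must be strictly less than `hr_mesor`.
#' @param hr_acrophase Clock hour in `[0, 24)` at which the circadian
#'   heart-rate cosine peaks.
#' @param lf_freq,hf_freq Frequencies (Hz) of the low- and high-frequency
#'   autonomic modulation of instantaneous rate.
#' @param lf_depth,hf_depth Dimensionless modulation depths (fraction of
#'   the mean rate), each in `[0, 0.5)`.
#' @param lf_circ_frac Optional diurnal modulation of the low-frequency
#'   depth, in `[0, 1]`: the effective depth is
#'   `lf_depth * (1 + lf_circ_frac * cos(2*pi*(t_clock - lf_circ_acrophase)/24))`,
#'   emulating the sympathetic predominance of the waking hours; 0 (the
#'   default) keeps the depth constant.
#' @param lf_circ_acrophase Clock hour at which the low-frequency depth
#'   peaks.
#' @param fractal_alpha Target detrended-fluctuation scaling exponent of
#'   the fractal rate component, in `(0, 2)`.
#' @param fractal_sd Standard deviation of the fractal rate component,
#'   beats/min. Zero disables it.
#' @param pvc_base_rate Baseline rate of isolated premature ventricular
#'   complexes, events/hour.
#' @param pvc_morning_fold Peak-to-base fold of the time-of-day PVC rate
#'   profile (half-wave-rectified cosine); 1 gives a uniform rate.
#' @param pvc_acrophase Clock hour at which the PVC rate profile peaks.
#' @param vt_rate Rate of ventricular-tachycardia episodes, episodes/hour
#'   (same time-of-day profile as PVCs).
#' @param vt_len_min,vt_len_max Episode length bounds in beats; runs are
#'   uniform on `[vt_len_min, vt_len_max]` and must have `vt_len_min >= 3`.
#' @param seed Integer master seed; all sub-processes draw from streams
#'   derived from it, so a config fully determines the output.
#'
#' @return An object of class `sim_config` (a named list).
#' @examples
#' cfg <- sim_config(hr_mesor = 100, hr_circ_amplitude = 12, seed = 1)
#' cfg$hr_mesor
#' @export
sim_config <- function(duration_h = 24,
                       start_clock_h = 0,
                       hr_mesor = 100,
                       hr_circ_amplitude = 10,
                       hr_acrophase = 15,
                       lf_freq = 0.10,
                       lf_depth = 0.03,
                       hf_freq = 0.25,
                       hf_depth = 0.03,
                       lf_circ_frac = 0,
                       lf_circ_acrophase = 10,
                       fractal_alpha = 1.0,
                       fractal_sd = 4,
                       pvc_base_rate = 0,
                       pvc_morning_fold = 1,
                       pvc_acrophase = 9,
                       vt_rate = 0,
                       vt_len_min = 3,
                       vt_len_max = 8,
                       seed = 1L) {
  cfg <- list(
    duration_h = duration_h, start_clock_h = start_clock_h,
    hr_mesor = hr_mesor, hr_circ_amplitude = hr_circ_amplitude,
    hr_acrophase = hr_acrophase,
    lf_freq = lf_freq, lf_depth = lf_depth,
    hf_freq = hf_freq, hf_depth = hf_depth,
    lf_circ_frac = lf_circ_frac, lf_circ_acrophase = lf_circ_acrophase,
    fractal_alpha = fractal_alpha, fractal_sd = fractal_sd,
    pvc_base_rate = pvc_base_rate, pvc_morning_fold = pvc_morning_fold,
    pvc_acrophase = pvc_acrophase,
    vt_rate = vt_rate, vt_len_min = vt_len_min, vt_len_max = vt_len_max,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with(cfg, {
    if (!(duration_h > 0)) stop("duration_h must be positive", call. = FALSE)
    if (!(hr_mesor > hr_circ_amplitude && hr_circ_amplitude >= 0))
      stop("need hr_mesor > hr_circ_amplitude >= 0", call. = FALSE)
    if (hr_acrophase < 0 || hr_acrophase >= 24 ||
        pvc_acrophase < 0 || pvc_acrophase >= 24 ||
        start_clock_h < 0 || start_clock_h >= 24)
      stop("acrophases and start_clock_h must lie in [0, 24)", call. = FALSE)
    if (lf_depth < 0 || lf_depth >= 0.5 || hf_depth < 0 || hf_depth >= 0.5)
      stop("modulation depths must lie in [0, 0.5)", call. = FALSE)
    if (lf_circ_frac < 0 || lf_circ_frac > 1)
      stop("lf_circ_frac must lie in [0, 1]", call. = FALSE)
    if (lf_circ_acrophase < 0 || lf_circ_acrophase >= 24)
      stop("lf_circ_acrophase must lie in [0, 24)", call. = FALSE)
    if (fractal_alpha <= 0 || fractal_alpha >= 2)
      stop("fractal_alpha must lie in (0, 2)", call. = FALSE)
    if (fractal_sd < 0 || pvc_base_rate < 0 || vt_rate < 0)
      stop("rates and fractal_sd must be non-negative", call. = FALSE)
    if (pvc_morning_fold < 0)
      stop("pvc_morning_fold must be >= 0", call. = FALSE)
    if (vt_len_min < 3 || vt_len_max < vt_len_min)
      stop("need vt_len_max >= vt_len_min >= 3", call. = FALSE)
  })
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  duration %g h starting at clock %02.0f:00, seed %d\n",
              x$duration_h, x$start_clock_h, x$seed))
  cat(sprintf("  HR: mesor %g bpm, circadian amplitude %g bpm, acrophase %g h\n",
              x$hr_mesor, x$hr_circ_amplitude, x$hr_acrophase))
  cat(sprintf("  modulation: LF %g Hz depth %g, HF %g Hz depth %g\n",
              x$lf_freq, x$lf_depth, x$hf_freq, x$hf_depth))
  cat(sprintf("  fractal: alpha %g, sd %g bpm\n", x$fractal_alpha, x$fractal_sd))
  cat(sprintf("  ectopy: PVC %g/h (fold %g @ %g h), VT %g/h len [%d, %d]\n",
              x$pvc_base_rate, x$pvc_morning_fold, x$pvc_acrophase,
              x$vt_rate, x$vt_len_min, x$vt_len_max))
  invisible(x)
}

#' Read and write simulator configurations as YAML
#'
#' A `sim_config` serializes to a flat YAML mapping (one key per
#' parameter); reading validates the parameters, so a round trip
#' reproduces the configuration exactly.
#'
#' @param config A [sim_config()].
#' @param path YAML file path.
#' @return `write_sim_config()` returns `path` invisibly;
#'   `read_sim_config()` returns a validated `sim_config`.
#' @export
write_sim_config <- function(config, path) {
  validate_sim_config(config)
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  fields <- yaml::read_yaml(path)
  unknown <- setdiff(names(fields), names(formals(sim_config)))
  if (length(unknown))
    stop("unknown sim_config fields: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  do.call(sim_config, fields)
}

# Derive independent per-subprocess seeds from the master seed so that
# e.g. turning ectopy on does not perturb the underlying sinus stream.
derive_seed <- function(seed, which) {
  offsets <- c(fractal = 101L, beats = 211L, pvc = 307L, vt = 401L)
  (as.integer(seed) * 7919L + offsets[[which]]) %% 2147483647L
}
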