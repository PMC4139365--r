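test_that("sim_config validates its invariants", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(hr_mesor = 10, hr_circ_amplitude = 20), "mesor")
  expect_error(sim_config(lf_depth = 0.6), "depth")
  expect_error(sim_config(fractal_alpha = 2.3), "fractal_alpha")
  expect_error(sim_config(vt_len_min = 2), "vt_len")
  expect_error(sim_config(hr_acrophase = 24), "acrophase")
})

test_that("fractal noise has the requested moments and power-law spectrum", {
  x <- generate_fractal_noise(4096, alpha = 1, sd = 2, seed = 11)
  expect_equal(mean(x), 0, tolerance = 1e-12)
  expect_equal(sd(x), 2, tolerance = 1e-12)
  # identical seed -> identical draw; different seed -> different draw
  expect_identical(x, generate_fractal_noise(4096, 1, 2, seed = 11))
  expect_false(identical(x, generate_fractal_noise(4096, 1, 2, seed = 12)))

  # log-periodogram slope ~ -beta, beta = 2 alpha - 1: alpha 0.5 -> flat,
  # alpha 1 -> 1/f. Average periodograms over seeds to tame variance.
  slope_of <- function(alpha) {
    pg <- rowMeans(sapply(1:8, function(s) {
      x <- generate_fractal_noise(4096, alpha, 1, seed = s)
      Mod(fft(x)[2:1024])^2
    }))
    f <- (1:1023) / 4096
    unname(coef(lm(log(pg) ~ log(f)))[2])
  }
  expect_equal(slope_of(0.5), 0, tolerance = 0.1)
  expect_equal(slope_of(1.0), -1, tolerance = 0.1)
  expect_error(generate_fractal_noise(4096, alpha = 0), "alpha")
  expect_error(generate_fractal_noise(128, alpha = 1), "256")
})

test_that("DFA recovers the configured noise exponent", {
  a <- mean(vapply(1:20, function(s)
    dfa(generate_fractal_noise(8192, 0.8, 1, seed = s))$alpha1, 0.0))
  expect_lt(abs(a - 0.8), 0.05)
})

test_that("IPFM at constant 60 bpm emits exact 1-second intervals", {
  cfg <- sim_config(duration_h = 0.2, hr_mesor = 60, hr_circ_amplitude = 0,
                    lf_depth = 0, hf_depth = 0, fractal_sd = 0)
  bs <- generate_beat_times(cfg)
  expect_equal(unique(diff(bs$beats$time_s)), 1)
  expect_setequal(unique(bs$beats$label), "N")
  # fractal_sd = 0 and zero depths with circadian amplitude 0: periodic
  expect_equal(n_beats(bs), 720)
})

test_that("IPFM beat count matches the rate integral within one beat", {
  for (seed in 1:3) {
    cfg <- sim_config(duration_h = 0.5, hr_mesor = 90, hr_circ_amplitude = 8,
                      hr_acrophase = 15, lf_depth = 0.04, hf_depth = 0.04,
                      fractal_sd = 3, seed = seed)
    bs <- generate_beat_times(cfg)
    # fine-grid trapezoid integral of the rate (the integrand is smooth
    # between 0.5-s noise knots, so this is accurate to << 1 beat)
    tt <- seq(0, 1800, by = 0.005)
    r <- holterchaos:::instantaneous_rate(tt, cfg)
    integ <- sum((r[-1] + r[-length(r)]) / 2) * 0.005
    expect_lte(abs(n_beats(bs) - integ), 1)
  }
})

test_that("afternoon HR acrophase produces a morning rise", {
  cfg <- sim_config(duration_h = 24, hr_mesor = 90, hr_circ_amplitude = 10,
                    hr_acrophase = 15, lf_depth = 0, hf_depth = 0,
                    fractal_sd = 0)
  bs <- generate_beat_times(cfg)
  nn <- build_nn(bs)
  w <- segment_windows(bs, nn, bin_h = 6)
  hr <- vapply(w, function(x) time_domain(x$nn)$mean_hr, 0.0)
  expect_gt(hr[2], hr[1])  # [6,12) vs [0,6)
})

test_that("HF-only modulation puts the dominant spectral peak in the HF band", {
  cfg <- sim_config(duration_h = 0.5, hr_mesor = 80, hr_circ_amplitude = 0,
                    lf_depth = 0, hf_depth = 0.05, hf_freq = 0.25,
                    fractal_sd = 0)
  sp <- ar_psd(resample_tachogram(build_nn(generate_beat_times(cfg))))
  expect_equal(sp$freq[which.max(sp$psd)], 0.25, tolerance = 0.02)
})

test_that("zero-rate ectopy injection is the identity", {
  cfg <- sim_config(duration_h = 1, seed = 5)
  bs <- generate_beat_times(cfg)
  expect_identical(inject_ectopy(bs, cfg), bs)
})

test_that("degenerate VT length injects exactly 5-beat runs", {
  stream <- constant_stream(2, bpm = 100)
  cfg <- sim_config(duration_h = 2, vt_rate = 4, vt_len_min = 5,
                    vt_len_max = 5, pvc_base_rate = 0, seed = 21)
  out <- inject_ectopy(stream, cfg)
  runs <- rle(out$beats$label == "V")
  vlens <- runs$lengths[runs$values]
  expect_gt(length(vlens), 0)
  expect_true(all(vlens == 5))
})

test_that("ectopy injection preserves order, duration, and beat count", {
  stream <- constant_stream(2, bpm = 100)
  cfg <- sim_config(duration_h = 2, pvc_base_rate = 30, pvc_morning_fold = 2,
                    vt_rate = 2, seed = 31)
  out <- inject_ectopy(stream, cfg)
  expect_true(all(diff(out$beats$time_s) > 0))
  expect_identical(out$meta$duration_s, stream$meta$duration_s)
  expect_identical(n_beats(out), n_beats(stream))
  expect_gt(sum(out$beats$label == "V"), 0)
  # PVCs shorten the coupling interval; the compensatory pause follows
  pvc <- which(out$beats$label == "V" &
                 c("N", utils::head(out$beats$label, -1)) == "N" &
                 c(utils::tail(out$beats$label, -1), "N") == "N")
  pvc <- pvc[pvc > 1 & pvc < n_beats(out)]
  rr_before <- out$beats$time_s[pvc] - out$beats$time_s[pvc - 1]
  rr_after <- out$beats$time_s[pvc + 1] - out$beats$time_s[pvc]
  expect_true(all(rr_before < 0.6))  # coupling < underlying 0.6 s RR
  expect_true(all(rr_after > 0.6))   # compensatory pause
})

test_that("morning-surge profile reproduces its analytic quartile ratio", {
  stream <- constant_stream(24, bpm = 100)
  counts <- t(vapply(1:40, function(s) {
    cfg <- sim_config(duration_h = 24, pvc_base_rate = 20,
                      pvc_morning_fold = 2.5, pvc_acrophase = 9, seed = s)
    out <- inject_ectopy(stream, cfg)
    cl <- holterchaos:::clock_hours(out$beats$time_s[out$beats$label == "V"])
    c(night = sum(cl < 6), morning = sum(cl >= 6 & cl < 12))
  }, c(night = 0.0, morning = 0.0)))
  expected <- ectopy_rate_integral(20, 2.5, 9, 6, 6) /
    ectopy_rate_integral(20, 2.5, 9, 0, 6)
  ratio <- mean(counts[, "morning"]) / mean(counts[, "night"])
  # Monte-Carlo error of the count ratio at ~120 events/quartile/seed
  expect_equal(ratio, expected, tolerance = 0.08)
})

test_that("over-dense ectopy configuration raises a saturation error", {
  stream <- constant_stream(1, bpm = 60)
  cfg <- sim_config(duration_h = 1, pvc_base_rate = 5000, seed = 3)
  expect_error(inject_ectopy(stream, cfg), "denser")
})

test_that("beat CSV files round-trip exactly", {
  path <- withr::local_tempfile(fileext = ".csv")
  empty <- beat_stream(numeric(0), character(0), id = basename(path))
  write_beats(empty, path)
  expect_identical(readLines(path), "time_s,label")
  expect_equal(n_beats(read_beats(path)), 0)

  three <- beat_stream(c(0.8, 1.6, 2.4), c("N", "V", "N"),
                       id = basename(path))
  write_beats(three, path)
  got <- read_beats(path)
  expect_equal(got$beats, three$beats)

  for (seed in 1:5) {
    st <- random_stream(400, seed)
    st$meta$id <- basename(path)
    write_beats(st, path)
    back <- read_beats(path)
    expect_equal(back$beats, st$beats)
    expect_true(all(abs(back$beats$time_s * 125 -
                          round(back$beats$time_s * 125)) < 1e-9))
  }
})

test_that("simulator configurations round-trip through YAML", {
  cfg <- sim_config(hr_mesor = 96, fractal_alpha = 0.7, pvc_base_rate = 5,
                    lf_circ_frac = 0.3, seed = 9L)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_sim_config(cfg, path)
  back <- read_sim_config(path)
  expect_equal(back, cfg)

  writeLines("hr_mesor: 90\nnot_a_field: 1", path)
  expect_error(read_sim_config(path), "unknown sim_config fields")
})
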