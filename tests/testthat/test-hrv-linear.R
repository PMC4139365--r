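nn_from_ms <- function(ms, t0 = 0) {
  onset <- t0 + cumsum(c(0, utils::head(ms, -1))) / 1000
  data.frame(onset_time_s = onset, nn_ms = ms)
}

test_that("time-domain markers match closed forms", {
  const <- nn_from_ms(rep(1000, 20))
  td <- time_domain(const)
  expect_equal(td$mean_hr, 60)
  expect_equal(td$sdnn, 0)
  expect_equal(td$rmssd, 0)

  alt <- nn_from_ms(rep(c(800, 1000), 10))
  ta <- time_domain(alt)
  expect_equal(ta$mean_rr, 900)
  expect_equal(ta$sdnn, 100)
  expect_equal(ta$rmssd, 200)
  expect_equal(ta$cv, 100 / 900 * 100)
  expect_equal(ta$mean_hr, 60000 / 900)

  expect_error(time_domain(nn_from_ms(1000)), "at least 2")
})

test_that("cv and mean_hr are exact functions of sdnn and mean_rr", {
  for (seed in 1:10) {
    set.seed(seed)
    td <- time_domain(nn_from_ms(runif(50, 500, 1200)))
    expect_identical(td$cv, td$sdnn / td$mean_rr * 100)
    expect_identical(td$mean_hr, 60000 / td$mean_rr)
  }
})

test_that("rmssd skips successive pairs broken by exclusions", {
  # N N N V N N N at 1 s spacing: exclusion removes the two intervals
  # around V, leaving NN intervals whose onsets jump across the gap
  bs <- beat_stream(0:6, c("N", "N", "N", "V", "N", "N", "N"))
  nn <- build_nn(bs)
  td <- time_domain(nn)
  expect_equal(td$n, 4)
  expect_equal(td$n_successive_pairs, 2)  # (1,2) and (5,6); 2-5 is broken
})

test_that("tachogram resampling is exact on closed-form inputs", {
  const <- nn_from_ms(rep(800, 150))
  tg <- resample_tachogram(const)
  expect_true(tg$usable)
  expect_equal(max(abs(tg$signal)), 0, tolerance = 1e-9)
  span <- diff(range(const$onset_time_s))
  expect_length(tg$signal, floor(span * 4) + 1)

  # 0.1 Hz sinusoidal RR modulation -> dominant FFT bin at 0.1 Hz
  onset <- seq(0, 180, by = 0.8)
  iv <- data.frame(onset_time_s = onset,
                   nn_ms = 800 + 50 * sin(2 * pi * 0.1 * onset))
  tg2 <- resample_tachogram(iv)
  spec <- Mod(fft(tg2$signal))^2
  f <- (seq_along(spec) - 1) * 4 / length(spec)
  half <- f > 0 & f <= 2
  expect_equal(f[half][which.max(spec[half])], 0.1, tolerance = 0.01)

  # a >10 s gap flags the window unusable
  gap <- nn_from_ms(rep(800, 200))
  gap$onset_time_s[101:200] <- gap$onset_time_s[101:200] + 15
  expect_false(resample_tachogram(gap)$usable)

  expect_error(resample_tachogram(nn_from_ms(rep(800, 5))), "at least 10")
  expect_error(resample_tachogram(nn_from_ms(rep(100, 20))), "60 s")
})

test_that("AR spectrum of white noise splits power by bandwidth", {
  ratios <- vapply(1:10, function(s) {
    set.seed(s)
    ar_psd(rnorm(2048), fs = 4)$lf_hf_ratio
  }, 0.0)
  expect_equal(mean(ratios), 0.11 / 0.25, tolerance = 0.1)
})

test_that("AR spectrum localizes sinusoids into the right bands", {
  t <- (0:2047) / 4
  set.seed(7)
  hf_only <- ar_psd(sin(2 * pi * 0.25 * t) + rnorm(2048, sd = 0.05), fs = 4)
  expect_gt(hf_only$hf_power, 10 * hf_only$lf_power)

  set.seed(8)
  dual <- ar_psd(sin(2 * pi * 0.10 * t) + sin(2 * pi * 0.25 * t) +
                   rnorm(2048, sd = 0.05), fs = 4)
  expect_gt(dual$lf_hf_ratio, 0.5)
  expect_lt(dual$lf_hf_ratio, 2)
})

test_that("AR PSD is non-negative, satisfies Parseval, and scales correctly", {
  set.seed(12)
  x <- rnorm(1024)
  sp <- ar_psd(x, fs = 4)
  expect_true(all(sp$psd >= 0))
  expect_equal(sp$total_power, var(x), tolerance = 0.1)
  # lf/hf ratio invariant under amplitude rescaling
  sp2 <- ar_psd(5 * x, fs = 4)
  expect_equal(sp2$lf_hf_ratio, sp$lf_hf_ratio, tolerance = 1e-6)
  expect_equal(sp2$lf_power, 25 * sp$lf_power, tolerance = 1e-6)

  expect_error(ar_psd(rnorm(40), fs = 4, order = 16), "3 \\* order")
  expect_error(ar_psd(rep(1, 200), fs = 4), "constant")
})

test_that("windowed spectra average sub-segments and track hf_depth", {
  lfhf <- vapply(c(0.01, 0.03, 0.05), function(depth) {
    cfg <- sim_config(duration_h = 0.75, hr_mesor = 90,
                      hr_circ_amplitude = 0, lf_depth = 0.02,
                      hf_depth = depth, fractal_alpha = 1, fractal_sd = 1.5,
                      seed = 5)
    nn <- build_nn(generate_beat_times(cfg))
    window_spectral(nn)$lf_hf_ratio
  }, 0.0)
  # increasing HF modulation depth monotonically lowers LF/HF
  expect_true(all(diff(lfhf) < 0))

  cfg <- sim_config(duration_h = 0.5, hr_mesor = 90, hr_circ_amplitude = 0,
                    seed = 6)
  nn <- build_nn(generate_beat_times(cfg))
  ws <- window_spectral(nn)
  expect_gte(ws$n_segments, 5)
  expect_true(all(ws$psd >= 0))
})
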