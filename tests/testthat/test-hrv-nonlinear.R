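test_that("DFA recovers theoretical exponents for reference noises", {
  white <- vapply(1:10, function(s) {
    set.seed(s); dfa(rnorm(8192))$alpha1
  }, 0.0)
  expect_lt(abs(mean(white) - 0.5), 0.05)

  brown <- vapply(1:10, function(s) {
    set.seed(s); dfa(cumsum(rnorm(8192)))$alpha1
  }, 0.0)
  expect_lt(abs(mean(brown) - 1.5), 0.1)

  # long-range exponent of white noise is also 1/2
  white2 <- vapply(1:10, function(s) {
    set.seed(s); dfa(rnorm(8192))$alpha2
  }, 0.0)
  expect_lt(abs(mean(white2) - 0.5), 0.05)

  expect_error(dfa(rep(5, 1000)), "degenerate|constant")
  expect_error(dfa(rnorm(100)), "too short")
})

test_that("DFA is invariant under affine transforms of the input", {
  set.seed(3)
  x <- rnorm(2048)
  a <- dfa(x)
  b <- dfa(3.7 * x - 42)
  expect_equal(b$alpha1, a$alpha1, tolerance = 1e-10)
  expect_equal(b$alpha2, a$alpha2, tolerance = 1e-10)
})

test_that("correlation integral matches a brute-force distance-matrix oracle", {
  set.seed(21)
  x <- rnorm(400)
  m <- 5; tau <- 2; theiler <- m * tau
  r <- exp(seq(log(0.5), log(6), length.out = 12))
  ref <- ref_corr_integral(x, m, tau, r, theiler)
  got <- holterchaos:::.corr_integral_counts(t(delay_embed(x, m, tau)),
                                             r, as.integer(theiler))
  expect_equal(got$counts, ref$counts)
  expect_equal(got$npairs, ref$npairs)
})

test_that("correlation dimension recovers limit-cycle and noise dimensions", {
  # incommensurately sampled sinusoid = 1-dimensional limit cycle
  x <- sin(2 * pi * (1:2000) / (2.5 * pi * 2.9))
  cd1 <- correlation_dimension(x, m = 10)
  expect_lt(abs(cd1$cd - 1.0), 0.15)

  set.seed(4)
  cd3 <- correlation_dimension(rnorm(2000), m = 3)
  expect_gte(cd3$cd, 2.5)

  expect_error(correlation_dimension(rep(1, 2000)), "degenerate")
})

test_that("correlation curve is non-decreasing and the fit region is sane", {
  set.seed(9)
  res <- correlation_dimension(rnorm(1500), m = 4)
  expect_true(all(diff(res$curve$c_r) >= 0))
  expect_gte(res$n_fit_points, 3)
  expect_lt(res$scaling_range[1], res$scaling_range[2])
})

test_that("recurrence diagonal lines match a brute-force oracle exactly", {
  for (seed in c(2, 5)) {
    set.seed(seed)
    x <- as.numeric(arima.sim(list(ar = 0.8), 500))
    m <- 4; tau <- 1; theiler <- m * tau
    r <- sqrt(m) * sd(x) * 0.4
    ref <- ref_diag_lengths(x, m, tau, r, theiler, lmin = 2)
    got <- sort(as.integer(holterchaos:::.recurrence_diag_lengths(
      t(delay_embed(x, m, tau)), r, as.integer(theiler), 2L)))
    expect_identical(got, as.integer(ref))
  }
})

test_that("shannon entropy reproduces closed-form histogram values", {
  expect_equal(line_length_entropy(c(0, 12, 0)), 0)
  expect_equal(line_length_entropy(rep(5, 8)), 3)
  expect_equal(line_length_entropy(c(3, 1)),
               -(0.75 * log2(0.75) + 0.25 * log2(0.25)))

  # a noise-free periodic series and white noise differ in the direction
  # established by the brute-force reference implementation
  xp <- sin(2 * pi * (1:500) / (2.5 * pi * 2.9))
  set.seed(6); xn <- rnorm(500)
  se_p <- shannon_entropy(xp, m = 4)
  se_n <- shannon_entropy(xn, m = 4)
  ref_p <- ref_entropy_bits(ref_diag_lengths(xp, 4, 1, sqrt(4) * sd(xp), 4))
  ref_n <- ref_entropy_bits(ref_diag_lengths(xn, 4, 1, sqrt(4) * sd(xn), 4))
  expect_equal(se_p$se, ref_p)
  expect_equal(se_n$se, ref_n)
  expect_identical(se_p$se > se_n$se, ref_p > ref_n)

  # unreachable threshold -> no lines -> flagged undefined, not zero
  none <- shannon_entropy(xn, m = 4, threshold = 1e-9)
  expect_false(none$defined)
  expect_true(is.na(none$se))

  expect_error(shannon_entropy(rep(2, 500)), "degenerate")
})

test_that("measured alpha1 increases with the configured fractal exponent", {
  # sweep kept inside the physiological range: above ~1.2 the 1/125 s
  # timing quantization floor swamps the (tiny) fine-scale fluctuation
  # of very smooth noise and alpha1 is no longer recoverable
  alphas <- c(0.4, 0.6, 0.8, 1.0, 1.2)
  measured <- vapply(alphas, function(a) {
    mean(vapply(1:5, function(s) {
      cfg <- sim_config(duration_h = 2, hr_mesor = 90, hr_circ_amplitude = 0,
                        lf_depth = 0, hf_depth = 0, fractal_alpha = a,
                        fractal_sd = 4, seed = 100 * s)
      nn <- build_nn(generate_beat_times(cfg))
      dfa(nn$intervals$nn_ms)$alpha1
    }, 0.0))
  }, 0.0)
  expect_gt(cor(alphas, measured, method = "spearman"), 0.9)
})
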