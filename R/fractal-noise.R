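#' Generate fractal (power-law) noise by spectral synthesis
#'
#' Produces a zero-mean series whose power spectrum follows
#' \eqn{S(f) \propto f^{-\beta}} with \eqn{\beta = 2\alpha - 1}, so that
#' detrended fluctuation analysis of the series recovers the scaling
#' exponent `alpha`: `alpha = 0.5` gives white noise, `alpha = 1` classic
#' 1/f (pink) noise, `alpha = 1.5` Brownian-like noise. Synthesis shapes
#' Fourier amplitudes as \eqn{f^{-\beta/2}}, draws uniformly random
#' phases, and inverse-transforms; the result is rescaled to the requested
#' sample standard deviation.
#'
#' @param n Series length (at least 256).
#' @param alpha Target DFA scaling exponent, in `(0, 2)`.
#' @param sd Sample standard deviation of the output.
#' @param seed Integer seed; the draw is fully reproducible.
#' @return Numeric vector of length `n`, zero mean, standard deviation `sd`.
#' @examples
#' x <- generate_fractal_noise(1024, alpha = 1, sd = 1, seed = 42)
#' round(c(mean(x), sd(x)), 6)
#' @export
generate_fractal_noise <- function(n, alpha, sd = 1, seed = 1L) {
  if (alpha <= 0 || alpha >= 2)
    stop("alpha must lie in (0, 2)", call. = FALSE)
  if (n < 256)
    stop("n must be at least 256", call. = FALSE)
  n <- as.integer(n)
  beta <- 2 * alpha - 1

  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))

  # One-sided spectrum on frequencies k/n; hermitian completion below
  # makes the inverse transform real. No DC component, so the mean is 0.
  nhalf <- n %/% 2
  k <- seq_len(nhalf)
  amp <- (k / n)^(-beta / 2)
  phase <- stats::runif(nhalf, 0, 2 * pi)
  full <- complex(real = numeric(n))
  kpos <- if (n %% 2 == 0) k[-nhalf] else k   # bins with a conjugate mirror
  full[1 + kpos] <- complex(modulus = amp[kpos], argument = phase[kpos])
  full[n + 1 - kpos] <- Conj(full[1 + kpos])
  # Nyquist bin (even n) has no mirror and must be real.
  if (n %% 2 == 0) full[1 + nhalf] <- complex(real = amp[nhalf], imaginary = 0)

  x <- Re(stats::fft(full, inverse = TRUE)) / n
  x <- x - mean(x)
  s <- stats::sd(x)
  if (s > 0 && sd > 0) x <- x * (sd / s) else x <- x * 0
  x
}

# Save/restore the global RNG so seeded generators do not disturb the
# caller's random stream.
get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}
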