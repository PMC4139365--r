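#' Detrended fluctuation analysis (DFA)
#'
#' Quantifies fractal-like scaling of an interval series. The series is
#' mean-centered and integrated; the integrated profile is divided into
#' non-overlapping boxes of size `n` (partial tail boxes discarded), a
#' least-squares line is removed from each box, and the root-mean-square
#' fluctuation `F(n)` is collected over a range of box sizes. The scaling
#' exponents are the slopes of `log F(n)` vs `log n`: the short-range
#' exponent alpha1 over box sizes 4–16 and the long-range exponent alpha2
#' over 16–64 (the conventional ranges for beat-to-beat data).
#'
#' Reference values: uncorrelated noise gives alpha ~ 0.5, 1/f noise
#' alpha ~ 1, integrated white noise (Brownian) alpha ~ 1.5.
#'
#' @param x Numeric series (e.g. NN intervals in ms); length at least
#'   4 times the largest box size.
#' @param scales_short,scales_long Integer box-size ranges for the two
#'   slopes.
#' @return List of class `dfa_result`: `alpha1`, `alpha2`, `r2_1`,
#'   `r2_2` (fit R-squared per slope), and `fluctuations` (data frame
#'   `n`, `f`).
#' @examples
#' set.seed(1)
#' dfa(rnorm(4096))$alpha1  # ~ 0.5 for white noise
#' @export
dfa <- function(x, scales_short = 4:16, scales_long = 16:64) {
  x <- as.numeric(x)
  scales <- sort(unique(c(scales_short, scales_long)))
  if (length(x) < 4 * max(scales))
    stop("series too short: need length >= 4 * largest scale", call. = FALSE)
  if (stats::sd(x) == 0)
    stop("degenerate (constant) series: zero fluctuation", call. = FALSE)

  y <- cumsum(x - mean(x))
  fl <- vapply(scales, function(n) dfa_fluctuation(y, n), 0.0)
  if (any(fl == 0))
    stop("degenerate series: zero fluctuation at some scale", call. = FALSE)

  fit1 <- dfa_slope(scales, fl, range(scales_short))
  fit2 <- dfa_slope(scales, fl, range(scales_long))
  structure(
    list(alpha1 = fit1$slope, alpha2 = fit2$slope,
         r2_1 = fit1$r2, r2_2 = fit2$r2,
         fluctuations = data.frame(n = scales, f = fl)),
    class = "dfa_result")
}

# RMS fluctuation at one box size: linear detrend per non-overlapping box.
# The raw fluctuation is divided by the exact finite-size factor
# sqrt(1 - 4/n^2) — the expectation of F(n)^2 for uncorrelated input is
# sigma^2 (n^2 - 4)/(15 n), so this correction makes white noise scale as
# exactly n^(1/2) at every box size, removing the short-scale upward bias
# of the small (4-16 beat) range.
dfa_fluctuation <- function(y, n) {
  nbox <- length(y) %/% n
  ym <- matrix(y[seq_len(nbox * n)], nrow = n)
  X <- cbind(1, seq_len(n))
  beta <- solve(crossprod(X), crossprod(X, ym))
  res <- ym - X %*% beta
  sqrt(mean(res^2) / (1 - 4 / n^2))
}

dfa_slope <- function(scales, fl, rng) {
  sel <- scales >= rng[1] & scales <= rng[2]
  lx <- log(scales[sel]); ly <- log(fl[sel])
  fit <- stats::lm.fit(cbind(1, lx), ly)
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((ly - mean(ly))^2)
  list(slope = unname(fit$coefficients[2]),
       r2 = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_)
}

#' Delay embedding of a scalar series
#'
#' @param x Numeric series.
#' @param m Embedding dimension (>= 2).
#' @param tau Delay in samples.
#' @return Matrix with `length(x) - (m - 1) * tau` rows and `m` columns;
#'   row `i` is `(x[i], x[i + tau], ..., x[i + (m-1) tau])`.
#' @export
delay_embed <- function(x, m, tau = 1) {
  x <- as.numeric(x)
  stopifnot(m >= 2, tau >= 1)
  n_emb <- length(x) - (m - 1) * tau
  if (n_emb < 2) stop("series too short for this embedding", call. = FALSE)
  sapply(seq_len(m), function(k) x[seq_len(n_emb) + (k - 1) * tau])
}

#' Correlation dimension (Grassberger-Procaccia)
#'
#' Embeds the series in `m`-dimensional delay space, computes the
#' correlation integral `C(r)` — the fraction of vector pairs (beyond a
#' Theiler window of `m * tau` samples, which suppresses trivially close
#' temporal neighbors) whose Euclidean distance is below `r` — over a
#' grid of thresholds, and estimates the dimension as the slope of
#' `log C(r)` vs `log r` over the small-`r` scaling region.
#'
#' By default the threshold grid spans the 0.1%–50% quantiles of the
#' pairwise distance distribution (estimated on a random pair sample)
#' and the slope is fitted over grid points with `C(r) <= c_max` and at
#' least `min_pairs` contributing pairs, where the log-log curve is
#' closest to linear.
#'
#' @param x Numeric series; at least 100 points after embedding (500+
#'   recommended).
#' @param m Embedding dimension (default 10).
#' @param tau Delay in samples (default 1).
#' @param thresholds Optional increasing vector of distance thresholds;
#'   `NULL` for the automatic grid.
#' @param theiler Theiler exclusion window in samples (default `m * tau`).
#' @param n_thresholds Size of the automatic grid.
#' @param c_max Upper bound on `C(r)` for points entering the slope fit.
#' @param min_pairs Minimum pair count for a grid point to enter the fit.
#' @return List of class `cd_result`: `cd`, `scaling_range`
#'   `(r_low, r_high)`, `n_fit_points`, `reliable` (FALSE when fewer than
#'   3 usable grid points), and a `curve` data frame (`r`, `c_r`,
#'   `pairs`).
#' @examples
#' x <- sin(2 * pi * seq(0, 60, by = 0.06))
#' correlation_dimension(x, m = 10)$cd  # ~ 1: a limit cycle
#' @export
correlation_dimension <- function(x, m = 10, tau = 1, thresholds = NULL,
                                  theiler = m * tau, n_thresholds = 24,
                                  c_max = 0.2, min_pairs = 10) {
  x <- as.numeric(x)
  if (stats::sd(x) == 0)
    stop("degenerate (constant) series", call. = FALSE)
  emb <- delay_embed(x, m, tau)
  if (nrow(emb) < 100)
    stop("need at least 100 embedded vectors", call. = FALSE)

  if (is.null(thresholds)) {
    q <- pair_distance_quantiles(emb, probs = c(0.001, 0.5), theiler = theiler)
    if (q[1] <= 0) q[1] <- q[2] * 1e-3
    thresholds <- exp(seq(log(q[1]), log(q[2]), length.out = n_thresholds))
  }
  thresholds <- sort(thresholds)

  res <- .corr_integral_counts(t(emb), thresholds, as.integer(theiler))
  c_r <- res$counts / res$npairs
  curve <- data.frame(r = thresholds, c_r = c_r, pairs = res$counts)

  sel <- res$counts >= min_pairs & c_r <= c_max & c_r > 0
  reliable <- sum(sel) >= 3
  if (!reliable) {
    # fall back to the most permissive usable set
    sel <- res$counts >= min_pairs & c_r > 0
    reliable <- FALSE
  }
  if (sum(sel) < 2)
    stop("too few threshold points with enough pairs for a fit", call. = FALSE)
  lx <- log(thresholds[sel]); ly <- log(c_r[sel])
  fit <- stats::lm.fit(cbind(1, lx), ly)
  structure(
    list(cd = unname(fit$coefficients[2]),
         scaling_range = range(thresholds[sel]),
         n_fit_points = sum(sel),
         reliable = reliable || sum(res$counts >= min_pairs & c_r <= c_max & c_r > 0) >= 3,
         m = m, tau = tau, theiler = theiler,
         curve = curve),
    class = "cd_result")
}

# Quantiles of the pairwise embedded distance distribution, estimated on
# a bounded random sample of pairs (keeps the grid choice O(n)).
pair_distance_quantiles <- function(emb, probs, theiler,
                                    n_sample = 20000L, seed = 17L) {
  n <- nrow(emb)
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(seed)
  i <- sample.int(n, n_sample, replace = TRUE)
  j <- sample.int(n, n_sample, replace = TRUE)
  keep <- abs(i - j) > theiler
  i <- i[keep]; j <- j[keep]
  d <- sqrt(rowSums((emb[i, , drop = FALSE] - emb[j, , drop = FALSE])^2))
  stats::quantile(d, probs, names = FALSE)
}

#' Shannon entropy of recurrence diagonal line lengths
#'
#' Builds the recurrence plot of the delay-embedded series at a single
#' threshold (default `sqrt(m)` times the series SD, the convention of
#' standard HRV software), collects all maximal diagonal line segments
#' of length at least `lmin` from the off-diagonal triangle beyond the
#' Theiler window, and returns the Shannon entropy (bits) of the line
#' length distribution:
#' \deqn{SE = -\sum_\ell p(\ell) \log_2 p(\ell), \quad
#'       p(\ell) = \frac{n_\ell}{\sum_k n_k}.}
#'
#' @param x Numeric series (>= 200 points after embedding).
#' @param m Embedding dimension (default 10).
#' @param tau Delay in samples (default 1).
#' @param threshold Recurrence radius; default `sqrt(m) * sd(x)`.
#' @param lmin Shortest line length counted (default 2).
#' @param theiler Theiler exclusion window (default `m * tau`).
#' @return List of class `se_result`: `se` (bits; `NA` with
#'   `defined = FALSE` when no lines are found), `n_lines`, `histogram`
#'   (data frame `length`, `count`), plus the parameters used.
#' @export
shannon_entropy <- function(x, m = 10, tau = 1,
                            threshold = sqrt(m) * stats::sd(x),
                            lmin = 2, theiler = m * tau) {
  x <- as.numeric(x)
  if (stats::sd(x) == 0)
    stop("degenerate (constant) series", call. = FALSE)
  emb <- delay_embed(x, m, tau)
  if (nrow(emb) < 200)
    stop("need at least 200 embedded vectors", call. = FALSE)
  lens <- .recurrence_diag_lengths(t(emb), threshold, as.integer(theiler),
                                   as.integer(lmin))
  if (!length(lens)) {
    return(structure(
      list(se = NA_real_, defined = FALSE, n_lines = 0L,
           histogram = data.frame(length = integer(0), count = integer(0)),
           m = m, tau = tau, threshold = threshold, lmin = lmin),
      class = "se_result"))
  }
  tab <- table(lens)
  hist <- data.frame(length = as.integer(names(tab)),
                     count = as.integer(tab))
  structure(
    list(se = line_length_entropy(hist$count), defined = TRUE,
         n_lines = length(lens), histogram = hist,
         m = m, tau = tau, threshold = threshold, lmin = lmin),
    class = "se_result")
}

#' Shannon entropy (bits) of a line-length histogram
#'
#' @param counts Non-negative counts per observed line length.
#' @return Entropy in bits; 0 for a histogram concentrated on one length,
#'   `log2(k)` for a uniform histogram over `k` lengths.
#' @examples
#' line_length_entropy(rep(5, 8))  # 3 bits
#' @export
line_length_entropy <- function(counts) {
  counts <- counts[counts > 0]
  if (!length(counts)) return(NA_real_)
  p <- counts / sum(counts)
  -sum(p * log2(p))
}
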