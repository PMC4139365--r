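#' Single-component cosinor rhythm analysis
#'
#' Fits \eqn{y(t) = M + A \cos(2\pi (t - \phi)/P)} by least squares via
#' the standard linearization \eqn{y = M + \beta_1 \cos(\omega t) +
#' \beta_2 \sin(\omega t)}, with \eqn{A = \sqrt{\beta_1^2 + \beta_2^2}}
#' and the acrophase \eqn{\phi} recovered by `atan2`. Rhythmicity is
#' tested with the zero-amplitude F test (2 numerator degrees of
#' freedom): a metric is called rhythmic when `p_rhythm < 0.05`.
#'
#' The period is fixed (24 h by default) so the test has a determinate
#' null distribution; `fit_period = TRUE` additionally profiles the
#' period over `period_range` and reports the least-squares optimum, but
#' the rhythmicity decision still uses the fixed period.
#'
#' @param times Sampling times in clock hours (need not be sorted; >= 6
#'   points spanning at least one period).
#' @param values Metric values at `times`.
#' @param period Fixed period in hours.
#' @param fit_period If `TRUE`, also report the profiled best-fit period.
#' @param period_range Search range for the profiled period, hours.
#' @return List of class `cosinor_fit`: `mesor`, `amplitude`,
#'   `acrophase` (clock hours in `[0, period)`), `period`, `p_rhythm`,
#'   `rhythmic` (p < 0.05), `rss`, `n`, and `period_est` when profiled.
#' @examples
#' t <- seq(0, 23, by = 3)
#' y <- 10 + 3 * cos(2 * pi * (t - 8) / 24)
#' cosinor_fit(t, y)[c("mesor", "amplitude", "acrophase")]
#' @export
cosinor_fit <- function(times, values, period = 24,
                        fit_period = FALSE, period_range = c(20, 28)) {
  stopifnot(length(times) == length(values), period > 0)
  ok <- is.finite(times) & is.finite(values)
  times <- times[ok]; values <- values[ok]
  n <- length(times)
  if (n < 6) stop("need at least 6 time points", call. = FALSE)
  if (length(unique(round(times %% period, 9))) < 3)
    stop("degenerate design: need at least 3 distinct clock times",
         call. = FALSE)

  fit <- cosinor_ls(times, values, period)
  rss0 <- sum((values - mean(values))^2)
  df2 <- n - 3
  if (fit$rss <= .Machine$double.eps * rss0 || rss0 == 0) {
    p <- if (fit$amplitude > sqrt(.Machine$double.eps) * max(1, abs(fit$mesor)))
      0 else 1
  } else {
    f <- ((rss0 - fit$rss) / 2) / (fit$rss / df2)
    p <- stats::pf(f, 2, df2, lower.tail = FALSE)
  }

  out <- list(mesor = fit$mesor, amplitude = fit$amplitude,
              acrophase = fit$acrophase, period = period,
              p_rhythm = p, rhythmic = p < 0.05,
              rss = fit$rss, n = n)
  if (fit_period) {
    opt <- stats::optimize(function(P) cosinor_ls(times, values, P)$rss,
                           interval = period_range)
    out$period_est <- opt$minimum
  }
  structure(out, class = "cosinor_fit")
}

# Linearized least-squares cosinor at a fixed period.
cosinor_ls <- function(times, values, period) {
  w <- 2 * pi / period
  X <- cbind(1, cos(w * times), sin(w * times))
  qrx <- qr(X)
  if (qrx$rank < 3)
    stop("degenerate design: cosinor design matrix is rank deficient",
         call. = FALSE)
  beta <- qr.coef(qrx, values)
  res <- values - X %*% beta
  amplitude <- sqrt(beta[2]^2 + beta[3]^2)
  acrophase <- (atan2(beta[3], beta[2]) / w) %% period
  list(mesor = unname(beta[1]), amplitude = unname(amplitude),
       acrophase = unname(acrophase), rss = sum(res^2))
}

#' @export
print.cosinor_fit <- function(x, ...) {
  cat(sprintf(
    "<cosinor_fit> mesor %.4g, amplitude %.4g, acrophase %.2f h (period %g h)\n",
    x$mesor, x$amplitude, x$acrophase, x$period))
  cat(sprintf("  zero-amplitude test: p = %.4g -> %s\n", x$p_rhythm,
              if (x$rhythmic) "rhythmic" else "not rhythmic"))
  invisible(x)
}

#' Morning-minus-night delta of a windowed metric
#'
#' The morning value is the mean of the 3-h bins covering 6 AM–noon
#' (`[6,9)` and `[9,12)`), the night value the mean of the bins covering
#' midnight–6 AM; the delta is their exact difference. This is the
#' summary used to quantify the morning rise of heart rate and of each
#' HRV metric.
#'
#' @param window_means Either a numeric vector of 8 per-3-h-bin means in
#'   clock order (`[0,3), [3,6), ..., [21,24)`), or a data frame with
#'   columns `start_clock_h` and `value`.
#' @return List of class `delta_metric`: `morning_mean`, `night_mean`,
#'   `delta`.
#' @examples
#' delta_metric(c(80, 82, 90, 94, 88, 86, 84, 82))$delta
#' @export
delta_metric <- function(window_means) {
  if (is.data.frame(window_means)) {
    stopifnot(all(c("start_clock_h", "value") %in% names(window_means)))
    sc <- window_means$start_clock_h
    v <- window_means$value
  } else {
    v <- as.numeric(window_means)
    if (length(v) != 8)
      stop("expected 8 per-3-h-bin means", call. = FALSE)
    sc <- seq(0, 21, by = 3)
  }
  night <- v[sc >= 0 & sc < 6]
  morning <- v[sc >= 6 & sc < 12]
  if (length(night) < 1 || length(morning) < 1)
    stop("bins covering [0,6) and [6,12) are required", call. = FALSE)
  structure(
    list(morning_mean = mean(morning), night_mean = mean(night),
         delta = mean(morning) - mean(night)),
    class = "delta_metric")
}

#' Compare a metric across groups
#'
#' Unpaired two-sample t test (pooled variance) for two groups, one-way
#' ANOVA for three or more; per-group mean and SEM are always reported.
#'
#' @param groups Named (or unnamed) list of numeric vectors, one per
#'   group, each with at least 2 values.
#' @return List of class `group_comparison`: `method` (`"t"` or
#'   `"anova"`), `statistic`, `dof`, `p_value`, and a `summary` data
#'   frame (`group`, `n`, `mean`, `sem`).
#' @examples
#' group_compare(list(a = c(1, 2, 3), b = c(4, 5, 6)))$p_value
#' @export
group_compare <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2)
  groups <- lapply(groups, function(g) as.numeric(g[is.finite(g)]))
  if (any(lengths(groups) < 2))
    stop("each group needs at least 2 values", call. = FALSE)
  nm <- names(groups)
  if (is.null(nm) || any(!nzchar(nm)))
    nm <- paste0("group", seq_along(groups))
  summ <- data.frame(
    group = nm,
    n = lengths(groups),
    mean = vapply(groups, mean, 0.0),
    sem = vapply(groups, function(g) stats::sd(g) / sqrt(length(g)), 0.0),
    row.names = NULL)

  if (length(groups) == 2) {
    tt <- stats::t.test(groups[[1]], groups[[2]], var.equal = TRUE)
    out <- list(method = "t", statistic = unname(tt$statistic),
                dof = unname(tt$parameter), p_value = tt$p.value,
                summary = summ)
  } else {
    val <- unlist(groups, use.names = FALSE)
    grp <- factor(rep(nm, lengths(groups)))
    av <- stats::aov(val ~ grp)
    tab <- summary(av)[[1]]
    out <- list(method = "anova", statistic = tab[["F value"]][1],
                dof = tab[["Df"]], p_value = tab[["Pr(>F)"]][1],
                summary = summ)
  }
  structure(out, class = "group_comparison")
}

#' Left-ventricular fractional shortening
#'
#' Echocardiographic index of systolic function:
#' \deqn{FS = \frac{LVEDD - LVESD}{LVEDD} \times 100.}
#'
#' @param lvedd Left-ventricular end-diastolic diameter (any length
#'   unit, consistent with `lvesd`).
#' @param lvesd Left-ventricular end-systolic diameter; must satisfy
#'   `0 < lvesd < lvedd`.
#' @return Fractional shortening in percent.
#' @examples
#' fractional_shortening(50, 25)  # 50%
#' @export
fractional_shortening <- function(lvedd, lvesd) {
  stopifnot(length(lvedd) == length(lvesd))
  if (any(lvesd <= 0) || any(lvedd <= lvesd))
    stop("need 0 < lvesd < lvedd", call. = FALSE)
  (lvedd - lvesd) / lvedd * 100
}
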