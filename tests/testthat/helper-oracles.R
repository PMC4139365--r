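# Brute-force reference implementations used as independent oracles for
# the compiled nonlinear kernels, plus small fixture builders. These stay
# deliberately naive (full distance matrices, explicit loops).

ref_corr_integral <- function(x, m, tau, r, theiler) {
  emb <- delay_embed(x, m, tau)
  D <- as.matrix(stats::dist(emb))
  keep <- upper.tri(D) & (col(D) - row(D) > theiler)
  d <- D[keep]
  list(counts = vapply(r, function(ri) sum(d <= ri), 0.0),
       npairs = sum(keep))
}

ref_diag_lengths <- function(x, m, tau, r, theiler, lmin = 2) {
  emb <- delay_embed(x, m, tau)
  n <- nrow(emb)
  D <- as.matrix(stats::dist(emb))
  lens <- integer(0)
  for (off in seq(theiler + 1, n - 1)) {
    hits <- D[cbind(seq_len(n - off), seq_len(n - off) + off)] < r
    rl <- rle(hits)
    lens <- c(lens, rl$lengths[rl$values & rl$lengths >= lmin])
  }
  sort(lens)
}

ref_entropy_bits <- function(lens) {
  p <- table(lens) / length(lens)
  -sum(p * log2(p))
}

# A strictly-increasing random beat stream on the digitization grid.
random_stream <- function(n, seed, labels = c("N", "V", "A", "X"),
                          p = c(0.9, 0.05, 0.03, 0.02)) {
  set.seed(seed)
  rr <- stats::runif(n, 0.4, 1.2)
  time_s <- round(cumsum(rr) * 125) / 125
  time_s <- time_s[!duplicated(time_s)]
  beat_stream(time_s, sample(labels, length(time_s), TRUE, p), id = "fuzz")
}

# Fast all-N stream at a constant rate (bpm) for a given duration.
constant_stream <- function(duration_h, bpm = 100, start_clock_h = 0) {
  rr <- 60 / bpm
  t <- seq(rr, duration_h * 3600, by = rr)
  beat_stream(round(t * 125) / 125, rep("N", length(t)),
              id = "const", start_clock_h = start_clock_h,
              duration_s = duration_h * 3600)
}
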