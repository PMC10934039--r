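# Shared fixtures and independent oracles for the test suite.

# Beat train that samples a prescribed RR(t) curve exactly at beat onsets
# (no IPFM integration): t_{k+1} = t_k + RR(t_k)/1000, so the resulting
# interval sequence equals RR evaluated at its own onsets.
beats_from_rr_curve <- function(rr_fun, t_end, t0 = 0) {
  t <- t0
  out <- t0
  while (t < t_end) {
    t <- t + rr_fun(t) / 1000
    out <- c(out, t)
  }
  out
}

# Build an hrv_trend object directly from per-frame values (bypasses the
# spectral stage; used to test the paradigm averaging rules in isolation).
make_trend <- function(t, lf, hf, lfhf = NULL, hr = 60) {
  n <- length(t)
  recycle <- function(v) rep_len(v, n)
  if (is.null(lfhf)) lfhf <- ifelse(recycle(hf) > 0, recycle(lf) / recycle(hf), NA)
  structure(data.frame(t = t, lf = recycle(lf), hf = recycle(hf),
                       lfhf = recycle(lfhf), hr = recycle(hr)),
            class = c("hrv_trend", "data.frame"),
            window_s = 30, step_s = 2, order = 16)
}

# Brute-force digram-redundancy oracle: explicit 10x10 pair tally.
rng_index_oracle <- function(digits) {
  n <- length(digits)
  nij <- matrix(0L, 10, 10)
  for (k in seq_len(n - 1)) {
    i <- digits[k] + 1L
    j <- digits[k + 1L] + 1L
    nij[i, j] <- nij[i, j] + 1L
  }
  ni <- rowSums(nij)
  num <- sum(ifelse(nij > 0, nij * log(nij), 0))
  den <- sum(ifelse(ni > 0, ni * log(ni), 0))
  if (den == 0) 0 else num / den
}

# Exact sample moments: rows of `target` become the group mean, unit
# covariance by construction (used for closed-form discriminant checks).
unit_cov_group <- function(mu, n = 4) {
  stopifnot(n == 4)
  base <- matrix(c(1, 1, 1, -1, -1, 1, -1, -1), 4, 2, byrow = TRUE) * sqrt(3) / 2
  if (length(mu) == 1) base <- base[, 1, drop = FALSE]
  sweep(base[, seq_along(mu), drop = FALSE], 2, mu, `+`)
}
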