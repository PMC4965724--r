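# Independent oracles used across the suite: direct-summation MAV, unbanded
# DTW dynamic programming in plain R, and small random-input generators.

# Direct per-window mean of absolute values, summing the window index set
# i = -N+1..N explicitly for every instance.
mav_oracle <- function(x, rate, step_s, N) {
  x <- as.matrix(x)
  n <- nrow(x)
  m <- floor((n / rate) / step_s)
  step_samples <- round(rate * step_s)
  out <- matrix(NA_real_, m, ncol(x))
  for (k in seq_len(m)) {
    idx <- (k * step_samples - N + 1):(k * step_samples + N)
    idx <- idx[idx >= 1 & idx <= n]
    out[k, ] <- colMeans(abs(x[idx, , drop = FALSE]))
  }
  out
}

# Modified lexical word cost, written independently of the package.
mld_oracle <- function(a, b) {
  d <- abs(a - b)
  sum(ifelse(d == 0, 0, d - 1))
}

# Full (unbanded) DTW dynamic program over word sequences.
dtw_oracle <- function(a, b) {
  na <- nrow(a); nb <- nrow(b)
  D <- matrix(Inf, na + 1, nb + 1)
  D[1, 1] <- 0
  for (i in 1:na) {
    for (j in 1:nb) {
      cost <- mld_oracle(a[i, ], b[j, ])
      D[i + 1, j + 1] <- cost + min(D[i, j], D[i, j + 1], D[i + 1, j])
    }
  }
  D[na + 1, nb + 1]
}

# Random word sequence: `len` words over an alphabet of size n.
random_words <- function(len, n = 5) {
  matrix(sample(0:(n - 1), len * 8, replace = TRUE), len, 8)
}

# Small fabricated acc_summary for detector unit tests.
fake_acc_summary <- function(stat, dt = 0.05) {
  structure(list(time = seq_along(stat) * dt, stat = stat,
                 median = stats::median(stat), dt = dt),
            class = "acc_summary")
}

# Small fabricated emg_run (short duration) for I/O round trips.
fake_run <- function(n_emg = 2000, n_acc = 149, seed = 1) {
  set.seed(seed)
  emg <- matrix(rnorm(n_emg * 8), n_emg, 8)
  acc <- matrix(rnorm(n_acc * 6), n_acc, 6)
  structure(
    list(emg = emg, acc = acc, emg_rate = 2000, acc_rate = 148.1,
         duration = n_emg / 2000, group = "hammer", group_no = 1L,
         truth = data.frame(code = c("NR", "HG"), onset = c(0, 0.5),
                            offset = c(0.5, 1)),
         seed = seed),
    class = "emg_run"
  )
}
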