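# Independent oracles and small fixtures used across the suite.

# Exact two-tailed rank-sum p by enumerating every assignment of the pooled
# observations to the two groups (independent of the package's code path:
# works on raw values, sums mid-ranks per subset).
oracle_ranksum_p <- function(a, b) {
  pooled <- c(a, b)
  r <- rank(pooled)
  nA <- length(a)
  idx <- utils::combn(length(pooled), nA)
  ws <- apply(idx, 2, function(i) sum(r[i]))
  w_obs <- sum(r[seq_len(nA)])
  lo <- mean(ws <= w_obs + 1e-9)
  hi <- mean(ws >= w_obs - 1e-9)
  min(1, 2 * min(lo, hi))
}

# Brute-force BH step-up: k* = max{i : p_(i) <= i * alpha / m}; reject all
# p <= p_(k*).
oracle_bh_reject <- function(p, alpha = 0.05) {
  m <- length(p)
  ps <- sort(p)
  ok <- which(ps <= seq_len(m) * alpha / m)
  if (!length(ok)) return(rep(FALSE, length(p)))
  p <= ps[max(ok)] + 1e-15
}

# Single-channel recording holding a test tone or arbitrary samples.
tone_recording <- function(freq_hz, dur_s = 10, rate_hz = 250, amp = 1) {
  t <- seq(0, dur_s, by = 1 / rate_hz)
  eeg_recording(matrix(amp * sin(2 * pi * freq_hz * t), 1), rate_hz, "Cz")
}

rms <- function(x) sqrt(mean(x^2))

# RMS over the central part of a signal, away from filter edges.
rms_mid <- function(x, trim = 500) rms(x[(trim + 1):(length(x) - trim)])

table1_path <- function() {
  system.file("extdata", "subject_visits_table1.tsv", package = "passivelp")
}

# Epoch array of iid standard normal noise.
noise_epochs <- function(n, n_ch = 2, n_t = 10) {
  array(stats::rnorm(n * n_ch * n_t), dim = c(n, n_ch, n_t))
}
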