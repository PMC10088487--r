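#' Speech envelope signal
#'
#' The slow amplitude modulation of a speech waveform, resampled onto the
#' EEG sampling grid. After [preprocess_envelope] it is dimensionless
#' (band-passed and standardized under the same contract as the EEG).
#'
#' @param values numeric vector of envelope samples.
#' @param rate_hz sampling rate (must match the paired EEG, default 250).
#' @return object of class `envelope_signal`.
#' @export
envelope_signal <- function(values, rate_hz = 250) {
  structure(list(values = as.numeric(values), rate_hz = rate_hz),
            class = "envelope_signal")
}

#' @export
print.envelope_signal <- function(x, ...) {
  cat(sprintf("<envelope_signal> %d samples @ %g Hz (%.2f s)\n",
              length(x$values), x$rate_hz, length(x$values) / x$rate_hz))
  invisible(x)
}

# Magnitude of the analytic signal (Hilbert envelope) via the FFT.
analytic_magnitude <- function(x) {
  n <- length(x)
  h <- stats::fft(x)
  m <- numeric(n)
  if (n %% 2 == 0) {
    m[1] <- 1; m[2:(n / 2)] <- 2; m[n / 2 + 1] <- 1
  } else {
    m[1] <- 1; m[2:((n + 1) / 2)] <- 2
  }
  Mod(stats::fft(h * m, inverse = TRUE)) / n
}

#' Compute the speech envelope of an audio signal
#'
#' Binaural input is averaged to mono; the envelope is the magnitude of the
#' analytic signal, low-pass filtered (anti-aliasing) and linearly
#' interpolated onto the EEG sampling grid, then band-pass filtered and
#' standardized under the same preprocessing contract as the EEG. With
#' `raw_audio = TRUE` the rectification step is skipped and the raw waveform
#' itself is resampled and filtered (an alternate convention for the
#' cross-correlation input).
#'
#' @param audio an [audio_signal].
#' @param cfg a [preprocess_config] supplying the band and the output rate.
#' @param raw_audio use the raw waveform instead of its envelope.
#' @return an [envelope_signal] at `cfg$rate_hz`; the attribute
#'   `raw_envelope` holds the envelope before band-pass and standardization.
#' @export
compute_envelope <- function(audio, cfg = preprocess_config(), raw_audio = FALSE) {
  mono <- colMeans(audio$data)
  if (all(mono == 0)) stop("silent (all-zero) audio: envelope has zero variance")
  env_hi <- if (raw_audio) mono else analytic_magnitude(mono)
  # anti-alias before decimating to the EEG rate
  lp <- signal::butter(4, min(40, 0.4 * cfg$rate_hz) / (audio$rate_hz / 2),
                       type = "low")
  env_hi <- filtfilt_pad(lp$b, lp$a, env_hi)
  n_out <- floor(length(mono) / audio$rate_hz * cfg$rate_hz)
  t_out <- (seq_len(n_out) - 1) / cfg$rate_hz
  t_in <- (seq_along(mono) - 1) / audio$rate_hz
  env <- stats::approx(t_in, env_hi, xout = t_out, rule = 2)$y
  out <- preprocess_envelope(envelope_signal(env, cfg$rate_hz), cfg)
  attr(out, "raw_envelope") <- env
  out
}

#' Band-pass and standardize an envelope
#'
#' Applies the same 2-15 Hz band-pass and zero-mean/unit-variance scaling
#' used for the EEG, so envelope and EEG live on a common scale before
#' cross-correlation.
#'
#' @param env an [envelope_signal].
#' @param cfg a [preprocess_config].
#' @return an [envelope_signal].
#' @export
preprocess_envelope <- function(env, cfg = preprocess_config(rate_hz = env$rate_hz)) {
  flt <- signal::butter(4, c(cfg$band_low_hz, cfg$band_high_hz) / (env$rate_hz / 2),
                        type = "pass")
  v <- filtfilt_pad(flt$b, flt$a, env$values)
  s <- stats::sd(v)
  if (!is.finite(s) || s == 0) stop("envelope has zero variance")
  envelope_signal((v - mean(v)) / s, env$rate_hz)
}

#' Cut an EEG/envelope pair into non-overlapping segments
#'
#' Splits both signals into aligned, non-overlapping segments of `seg_s`
#' seconds (the trailing remainder is dropped). Segments touching any
#' artifact-masked EEG sample are excluded; the count is kept in the
#' `excluded` element.
#'
#' @param rec preprocessed [eeg_recording].
#' @param env matching [envelope_signal] (same rate; lengths are truncated
#'   to the shorter of the two).
#' @param seg_s segment length in seconds (default 2).
#' @return object of class `segment_set`: list with `eeg` (segments x
#'   channels x samples), `env` (segments x samples), `rate_hz`, `channels`,
#'   `excluded`.
#' @export
segment_pairs <- function(rec, env, seg_s = 2) {
  if (abs(rec$rate_hz - env$rate_hz) > 1e-9)
    stop("EEG and envelope sampling rates differ")
  n <- min(n_samples(rec), length(env$values))
  len <- round(seg_s * rec$rate_hz)
  n_seg <- floor(n / len)
  if (n_seg < 1) stop("record shorter than one segment")
  keep <- logical(n_seg)
  for (k in seq_len(n_seg))
    keep[k] <- !any(rec$artifact_mask[((k - 1) * len + 1):(k * len)])
  idx <- which(keep)
  eeg <- array(0, dim = c(length(idx), nrow(rec$data), len))
  envm <- matrix(0, length(idx), len)
  for (q in seq_along(idx)) {
    k <- idx[q]
    cols <- ((k - 1) * len + 1):(k * len)
    eeg[q, , ] <- rec$data[, cols, drop = FALSE]
    envm[q, ] <- env$values[cols]
  }
  structure(list(eeg = eeg, env = envm, rate_hz = rec$rate_hz,
                 channels = rec$channel_labels,
                 excluded = n_seg - length(idx)),
            class = "segment_set")
}

# Center and scale matrix rows to zero mean / unit variance (sample sd).
# Zero-variance rows come back as NA.
row_standardize <- function(M) {
  M <- M - rowMeans(M)
  s <- sqrt(rowSums(M^2) / (ncol(M) - 1))
  s[s == 0] <- NA
  M / s
}

lag_samples <- function(max_lag_ms, rate_hz) 0:round(max_lag_ms / 1000 * rate_hz)

#' Segment-averaged cross-correlation between EEG and envelope
#'
#' For each channel and each non-negative lag L (EEG delayed relative to the
#' envelope, 0..`max_lag_ms` in sample steps), computes the Pearson
#' correlation within each segment between the envelope and the EEG shifted
#' by L, and averages the correlations across segments. Zero-variance
#' segments are skipped (counted in the `skipped` attribute).
#'
#' @param segments a [segment_pairs] result.
#' @param max_lag_ms maximum lag in ms (default 500, i.e. 126 lags at 250 Hz).
#' @return channels x lags matrix in `[-1, 1]` with attribute `lags_ms`.
#' @export
xcorr_statistic <- function(segments, max_lag_ms = 500) {
  lags <- lag_samples(max_lag_ms, segments$rate_hz)
  n_seg <- dim(segments$eeg)[1]
  if (n_seg < 1) stop("need at least one segment")
  n_ch <- dim(segments$eeg)[2]
  len <- dim(segments$eeg)[3]
  stat <- matrix(NA_real_, n_ch, length(lags),
                 dimnames = list(segments$channels, NULL))
  skipped <- 0L
  for (li in seq_along(lags)) {
    l <- lags[li]
    m <- len - l
    E0 <- row_standardize(segments$env[, seq_len(m), drop = FALSE])
    for (ch in seq_len(n_ch)) {
      G0 <- row_standardize(matrix(segments$eeg[, ch, (l + 1):len], n_seg, m))
      r <- rowSums(E0 * G0) / (m - 1)
      skipped <- skipped + sum(is.na(r))
      stat[ch, li] <- mean(r, na.rm = TRUE)
    }
  }
  structure(stat, lags_ms = lags * 1000 / segments$rate_hz, skipped = skipped)
}

# Pairwise correlation stack: C[(i-1)*n + j, (li-1)*n_ch + ch] =
# corr(envelope segment i, EEG segment j of channel ch, at lag index li).
pairwise_xcorr_matrix <- function(segments, lags) {
  n_seg <- dim(segments$eeg)[1]
  n_ch <- dim(segments$eeg)[2]
  len <- dim(segments$eeg)[3]
  C <- matrix(0, n_seg * n_seg, n_ch * length(lags))
  for (li in seq_along(lags)) {
    l <- lags[li]
    m <- len - l
    E0 <- row_standardize(segments$env[, seq_len(m), drop = FALSE])
    for (ch in seq_len(n_ch)) {
      G0 <- row_standardize(matrix(segments$eeg[, ch, (l + 1):len], n_seg, m))
      C[, (li - 1) * n_ch + ch] <- as.vector(tcrossprod(E0, G0) / (m - 1))
    }
  }
  C
}

#' Shuffle-based null distribution of the cross-correlation statistic
#'
#' Re-pairs EEG and envelope segments under random permutations (the identity
#' pairing, which would reproduce the observed statistic, is excluded and
#' re-drawn) and recomputes the segment-averaged cross-correlation for every
#' permutation, channel and lag. Seeded and reproducible.
#'
#' @param segments a [segment_pairs] result with at least 3 segments.
#' @param n_shuffles number of permutations (default 10000; fewer than 100
#'   triggers a warning about unstable tails).
#' @param seed integer seed for the permutation stream.
#' @param max_lag_ms maximum lag in ms.
#' @return object of class `null_distribution`: `draws` is an
#'   `n_shuffles x (channels * lags)` matrix (cells ordered lag-major, matching
#'   `as.vector` of the channels x lags statistic), with `n_channels`,
#'   `channels`, `lags_ms` elements.
#' @export
shuffle_null <- function(segments, n_shuffles = 10000, seed = NULL,
                         max_lag_ms = 500) {
  n_seg <- dim(segments$eeg)[1]
  if (n_seg < 3)
    stop("need at least 3 segments for a non-degenerate permutation null")
  if (n_shuffles < 100)
    warning("fewer than 100 shuffles: empirical tail will be unstable")
  lags <- lag_samples(max_lag_ms, segments$rate_hz)
  C <- pairwise_xcorr_matrix(segments, lags)
  if (anyNA(C)) {
    warning(sum(is.na(C)), " zero-variance segment correlations set to 0 in the null")
    C[is.na(C)] <- 0
  }
  perms <- with_seed(seed, {
    vapply(seq_len(n_shuffles), function(s) {
      p <- sample.int(n_seg)
      while (all(p == seq_len(n_seg))) p <- sample.int(n_seg)
      p
    }, integer(n_seg))
  })
  # statistic under permutation p: mean_i C[(i-1)*n+p[i], cell]
  rows <- (seq_len(n_seg) - 1L) * n_seg + perms     # n_seg x n_shuffles
  P <- Matrix::sparseMatrix(i = rep(seq_len(n_shuffles), each = n_seg),
                            j = as.vector(rows), x = 1 / n_seg,
                            dims = c(n_shuffles, n_seg * n_seg))
  draws <- as.matrix(P %*% C)
  structure(list(draws = draws, n_channels = dim(segments$eeg)[2],
                 channels = segments$channels,
                 lags_ms = lags * 1000 / segments$rate_hz),
            class = "null_distribution")
}

#' Empirical significance of the cross-correlation statistic
#'
#' Two-tailed empirical p-value per (channel, lag):
#' `p = (1 + #\{shuffles: |null| >= |observed|\}) / (n_shuffles + 1)`,
#' followed by BH-FDR correction across lags within each channel (or
#' globally).
#'
#' @param obs channels x lags statistic from [xcorr_statistic].
#' @param null matching [shuffle_null] result.
#' @param alpha FDR level.
#' @param scope correction scope, see [bh_fdr_mask].
#' @return list with `p_values` (channels x lags) and `mask` (logical
#'   channels x lags significance map).
#' @export
empirical_significance <- function(obs, null, alpha = 0.05,
                                   scope = c("within_channel", "global")) {
  scope <- match.arg(scope)
  n_ch <- nrow(obs); n_lag <- ncol(obs)
  draws <- null$draws
  if (ncol(draws) != n_ch * n_lag)
    stop("null distribution shape does not match the observed statistic")
  ns <- nrow(draws)
  obs_vec <- abs(as.vector(obs))   # lag-major, matches the null layout
  cnt <- colSums(abs(draws) >= rep(obs_vec, each = ns))
  p <- matrix((1 + cnt) / (ns + 1), n_ch, n_lag, dimnames = dimnames(obs))
  list(p_values = p, mask = bh_fdr_mask(p, alpha, scope))
}

#' Full natural-speech-envelope tracking analysis of one trial
#'
#' Segments the preprocessed EEG and envelope, computes the segment-averaged
#' cross-correlation over lags 0..`max_lag_ms`, builds the shuffle null, and
#' derives empirical p-values and the FDR significance mask.
#'
#' @param rec preprocessed [eeg_recording].
#' @param env preprocessed [envelope_signal] on the same grid.
#' @param seg_s segment length (s).
#' @param max_lag_ms maximum lag (ms).
#' @param n_shuffles,seed permutation-null parameters, see [shuffle_null].
#' @param alpha,scope significance parameters, see [empirical_significance].
#' @return list with `statistic`, `null`, `p_values`, `mask`, `map` (a
#'   lag-axis [frequency_map] of the 0/1 mask), `segments_used`, `excluded`.
#' @export
nse_analysis <- function(rec, env, seg_s = 2, max_lag_ms = 500,
                         n_shuffles = 10000, seed = NULL, alpha = 0.05,
                         scope = c("within_channel", "global")) {
  scope <- match.arg(scope)
  segs <- segment_pairs(rec, env, seg_s)
  stat <- xcorr_statistic(segs, max_lag_ms)
  null <- shuffle_null(segs, n_shuffles, seed, max_lag_ms)
  sig <- empirical_significance(stat, null, alpha, scope)
  map <- frequency_map(unclass(sig$mask) * 1, points_ms = attr(stat, "lags_ms"),
                       channels = rec$channel_labels, axis = "lag",
                       level = "trial", chance_level = alpha / ncol(stat))
  list(statistic = stat, null = null, p_values = sig$p_values,
       mask = sig$mask, map = map,
       segments_used = dim(segs$eeg)[1], excluded = segs$excluded)
}
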