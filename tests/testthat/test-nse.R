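test_that("envelope of a pure tone is constant before band-pass filtering", {
  t <- seq(0, 5, by = 1 / 8000)
  tone <- audio_signal(0.5 * sin(2 * pi * 1000 * t), 8000)
  env <- compute_envelope(tone, preprocess_config(rate_hz = 250))
  raw <- attr(env, "raw_envelope")
  mid <- raw[100:(length(raw) - 100)]
  expect_lt((max(mid) - min(mid)) / mean(mid), 0.01)
})

test_that("envelope of an amplitude-modulated tone peaks at the modulation rate", {
  t <- seq(0, 5, by = 1 / 8000)
  am <- audio_signal(sin(2 * pi * 1000 * t) * (1 + 0.8 * sin(2 * pi * 4 * t)),
                     8000)
  env <- compute_envelope(am, preprocess_config(rate_hz = 250))
  v <- env$values
  sp <- Mod(fft(v))^2
  f <- (seq_along(v) - 1) * 250 / length(v)
  keep <- f > 0.5 & f < 125
  expect_equal(f[keep][which.max(sp[keep])], 4, tolerance = 0.1)
})

test_that("binaural input with identical channels equals the mono envelope", {
  t <- seq(0, 2, by = 1 / 8000)
  w <- sin(2 * pi * 500 * t) * (1 + 0.5 * sin(2 * pi * 3 * t))
  mono <- compute_envelope(audio_signal(w, 8000),
                           preprocess_config(rate_hz = 250))
  stereo <- compute_envelope(audio_signal(rbind(w, w), 8000),
                             preprocess_config(rate_hz = 250))
  expect_equal(mono$values, stereo$values)
})

test_that("silent audio raises a zero-variance error", {
  expect_error(compute_envelope(audio_signal(rep(0, 8000), 8000),
                                preprocess_config(rate_hz = 250)),
               "zero variance|silent")
})

test_that("segmentation yields non-overlapping 2 s pairs and drops remainders", {
  set.seed(40)
  rec <- eeg_recording(matrix(rnorm(2 * 148 * 250), 2), 250, c("Cz", "Pz"))
  env <- envelope_signal(rnorm(148 * 250), 250)
  segs <- segment_pairs(rec, env)
  expect_equal(dim(segs$eeg), c(74, 2, 500))
  expect_equal(dim(segs$env), c(74, 500))
  short <- eeg_recording(matrix(rnorm(975), 1), 250, "Cz")  # 3.9 s
  s2 <- segment_pairs(short, envelope_signal(rnorm(975), 250))
  expect_equal(dim(s2$eeg)[1], 1)
  masked <- apply_artifact_mask(rec, c(0, 2))
  s3 <- segment_pairs(masked, env)
  expect_equal(dim(s3$eeg)[1], 73)
  expect_equal(s3$excluded, 1)
  tiny <- eeg_recording(matrix(rnorm(100), 1), 250, "Cz")
  expect_error(segment_pairs(tiny, envelope_signal(rnorm(100), 250)),
               "shorter than one segment")
})

test_that("cross-correlation statistic finds exact and delayed copies", {
  set.seed(41)
  env <- envelope_signal(rnorm(2000), 250)
  same <- eeg_recording(matrix(env$values, 1), 250, "Cz")
  st <- xcorr_statistic(segment_pairs(same, env))
  expect_equal(unname(st[1, 1]), 1)
  lagn <- 25  # 100 ms
  delayed <- eeg_recording(matrix(c(rep(0, lagn),
                                    env$values[1:(2000 - lagn)]), 1), 250, "Cz")
  st2 <- xcorr_statistic(segment_pairs(delayed, env))
  expect_equal(attr(st2, "lags_ms")[which.max(st2[1, ])], 100)
  expect_true(all(abs(st2) <= 1 + 1e-12))
})

test_that("independent white noise keeps the mean correlation small", {
  set.seed(42)
  rec <- eeg_recording(matrix(rnorm(120 * 250), 1), 250, "Cz")  # 60 segments
  env <- envelope_signal(rnorm(120 * 250), 250)
  st <- xcorr_statistic(segment_pairs(rec, env))
  expect_lt(max(abs(st)), 0.2)
})

test_that("shuffle null is seeded, reproducible, and excludes the identity", {
  set.seed(43)
  n <- 3 * 500
  env <- envelope_signal(rnorm(n), 250)
  rec <- eeg_recording(matrix(env$values, 1), 250, "Cz")  # EEG == envelope
  segs <- segment_pairs(rec, env)
  null1 <- shuffle_null(segs, n_shuffles = 300, seed = 7)
  null2 <- shuffle_null(segs, n_shuffles = 300, seed = 7)
  expect_identical(null1$draws, null2$draws)
  null3 <- shuffle_null(segs, n_shuffles = 300, seed = 8)
  expect_false(identical(null1$draws, null3$draws))
  # identity pairing would give statistic exactly 1 at lag 0; it is excluded
  expect_lt(max(null1$draws[, 1]), 1 - 1e-8)
  expect_error(shuffle_null(segment_pairs(
    eeg_recording(matrix(rnorm(1000), 1), 250, "Cz"),
    envelope_signal(rnorm(1000), 250)), 100, seed = 1),
    "at least 3 segments")
  expect_warning(shuffle_null(segs, n_shuffles = 50, seed = 1), "unstable")
})

test_that("null draws of unrelated noise center on zero", {
  set.seed(44)
  rec <- eeg_recording(matrix(rnorm(60 * 500), 1), 250, "Cz")
  env <- envelope_signal(rnorm(60 * 500), 250)
  null <- shuffle_null(segment_pairs(rec, env), n_shuffles = 2000, seed = 9)
  means <- colMeans(null$draws)
  # conditionally on the data the permutation mean sits at the off-diagonal
  # average, which for 60 independent 500-sample segments is within a few
  # thousandths of zero
  expect_lt(max(abs(means)), 0.005)
  expect_lt(abs(mean(means)), 5e-4)
})

test_that("empirical p-values follow the +1-corrected two-tailed formula", {
  draws <- matrix(seq(-0.5, 0.5, length.out = 9999), 9999, 2)
  null <- structure(list(draws = draws, n_channels = 1,
                         channels = "Cz", lags_ms = c(0, 4)),
                    class = "null_distribution")
  obs <- matrix(c(0.9, 0), 1, 2)   # beats every draw; ties with none
  sig <- empirical_significance(obs, null)
  expect_equal(sig$p_values[1, 1], 1 / 10000)
  expect_equal(sig$p_values[1, 2], (1 + sum(abs(draws[, 2]) >= 0)) / 10000)
  expect_true(all(sig$p_values > 0 & sig$p_values <= 1))
})

test_that("empirical p-values are super-uniform under the shuffle null", {
  set.seed(45)
  rec <- eeg_recording(matrix(rnorm(40 * 500), 1), 250, "Cz")
  env <- envelope_signal(rnorm(40 * 500), 250)
  segs <- segment_pairs(rec, env)
  st <- xcorr_statistic(segs, max_lag_ms = 100)
  null <- shuffle_null(segs, n_shuffles = 400, seed = 10, max_lag_ms = 100)
  p <- empirical_significance(st, null)$p_values
  for (x in c(0.05, 0.1, 0.25, 0.5))
    expect_lte(mean(p <= x), x + 2 * sqrt(x * (1 - x) / length(p)) + 0.05)
})

test_that("the statistic and its significance are scale invariant", {
  set.seed(46)
  cfg <- synth_config(duration_s = 24, n_channels = 2)
  d <- generate_dataset(cfg, seed = 47)
  rec <- preprocess(d$eeg)
  env <- preprocess_envelope(d$envelope)
  base <- nse_analysis(rec, env, n_shuffles = 300, seed = 11)
  rec2 <- rec; rec2$data[1, ] <- 3.7 * rec2$data[1, ]
  env2 <- env; env2$values <- 2.2 * env2$values
  scaled <- nse_analysis(rec2, env2, n_shuffles = 300, seed = 11)
  expect_equal(unclass(scaled$statistic), unclass(base$statistic),
               tolerance = 1e-12)
  expect_equal(scaled$p_values, base$p_values)
  expect_identical(unclass(scaled$mask), unclass(base$mask))
})
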