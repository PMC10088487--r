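test_that("generators are pure functions of configuration and seed", {
  cfg <- synth_config(duration_s = 12, n_channels = 3)
  a1 <- generate_annotation(cfg, 77)
  a2 <- generate_annotation(cfg, 77)
  expect_identical(a1$intervals, a2$intervals)
  expect_false(identical(generate_annotation(cfg, 78)$intervals, a1$intervals))
  e1 <- generate_envelope(a1, cfg, 5)
  e2 <- generate_envelope(a1, cfg, 5)
  expect_identical(e1$envelope$values, e2$envelope$values)
  expect_identical(e1$audio$data, e2$audio$data)
  r1 <- generate_eeg(a1, e1$envelope, cfg, 6)
  r2 <- generate_eeg(a1, e1$envelope, cfg, 6)
  expect_identical(r1$data, r2$data)
})

test_that("phoneme durations follow the truncated model and fill the record", {
  cfg <- synth_config(duration_s = 148)
  annot <- generate_annotation(cfg, 80)
  durs <- annot$intervals$end_s - annot$intervals$start_s
  expect_true(all(durs >= 0.030 - 1e-12 & durs <= 0.320 + 1e-12))
  # expected count ~ 148 / 0.0795 ~ 1862
  expect_gt(nrow(annot$intervals), 1862 * 0.9)
  expect_lt(nrow(annot$intervals), 1862 * 1.1)
  expect_equal(mean(durs), 0.0795, tolerance = 0.05)
  # contiguous tiling from zero
  expect_equal(annot$intervals$start_s[1], 0)
  expect_equal(annot$intervals$start_s[-1],
               annot$intervals$end_s[-nrow(annot$intervals)])
  # class mixture follows the configured probabilities
  freq <- table(factor(annot$intervals$class, c("A", "F", "N", "P", "V")))
  probs <- c(163, 264, 147, 355, 617) / 1546
  expect_lt(max(abs(freq / sum(freq) - probs)), 0.05)
})

test_that("the synthetic envelope is non-negative and renders to audio", {
  cfg <- synth_config(duration_s = 10, audio_rate_hz = 8000)
  annot <- generate_annotation(cfg, 81)
  ea <- generate_envelope(annot, cfg, 82)
  expect_true(all(ea$envelope$values >= -1e-12))
  expect_true(max(abs(ea$audio$data)) <= 0.9 + 1e-9)
  silent_cfg <- synth_config(duration_s = 10, audio_rate_hz = 8000,
                             class_levels = c(A = 0, F = 0, N = 0, P = 0, V = 0))
  silent <- generate_envelope(annot, silent_cfg, 82)
  expect_equal(max(abs(silent$audio$data)), 0)
})

test_that("the rendered audio round-trips through the envelope extractor", {
  cfg <- synth_config(duration_s = 30, n_channels = 2, audio_rate_hz = 8000)
  d <- generate_dataset(cfg, seed = 83)
  recovered <- compute_envelope(d$audio, preprocess_config())
  reference <- preprocess_envelope(d$envelope)
  n <- min(length(recovered$values), length(reference$values))
  expect_gt(cor(recovered$values[1:n], reference$values[1:n]), 0.9)
})

test_that("noise-only EEG has unit variance per channel and a ground-truth mask", {
  cfg <- synth_config(duration_s = 20, n_channels = 4,
                      artifacts = list(count = 2, duration_s = 0.5,
                                       amplitude = 20))
  annot <- generate_annotation(cfg, 84)
  rec <- generate_eeg(annot, NULL, cfg, 85)
  expect_equal(dim(rec$data), c(4, 5000))
  truth <- attr(rec, "truth")
  expect_equal(nrow(truth$artifact_intervals), 2)
  expect_true(any(rec$artifact_mask))
  clean <- rec$data[, !rec$artifact_mask]
  expect_true(all(abs(apply(clean, 1, sd) - 1) < 0.1))
})

test_that("detection frequency increases with injected effect amplitude", {
  freqs <- vapply(c(0, 2), function(amp) {
    cfg <- synth_config(duration_s = 60, n_channels = 2,
                        class_effects = if (amp > 0)
                          list(list(class = "V", amplitude = amp,
                                    latency_ms = 120, duration_ms = 60,
                                    channels = "Fp1")) else list())
    d <- generate_dataset(cfg, seed = 86)
    rec <- preprocess(d$eeg)
    pr <- pair_map(rec, d$annotation, c("P", "V"))
    win <- seq(round(100 / 4), round(200 / 4))
    mean(pr$mask[1, win])
  }, 0)
  expect_gt(freqs[2], freqs[1])
  expect_gt(freqs[2], 0.2)
})
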