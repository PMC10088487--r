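test_that("epochs are cut at round(onset * rate) with a 125-sample window", {
  rec <- eeg_recording(matrix(seq_len(300), 1), 250, "Cz")
  an <- phoneme_annotation(data.frame(start_s = 0.1, end_s = 0.18,
                                      phoneme_label = "T"))
  es <- extract_epochs(rec, an)
  expect_equal(dim(es$P$epochs), c(1, 1, 125))
  # 1-based samples 26..150 (0-based 25..149)
  expect_equal(es$P$epochs[1, 1, 1], 26)
  expect_equal(es$P$epochs[1, 1, 125], 150)
  expect_equal(es$P$onset_samples, 26)
})

test_that("epochs that overrun the record end are dropped and counted", {
  rec <- eeg_recording(matrix(rnorm(250), 1), 250, "Cz")  # 1 s record
  an <- phoneme_annotation(data.frame(start_s = c(0.1, 0.7),
                                      end_s = c(0.2, 0.8),
                                      phoneme_label = c("T", "T")))
  es <- extract_epochs(rec, an)
  expect_equal(dim(es$P$epochs)[1], 1)
  dc <- attr(es, "drop_counts")
  expect_equal(unname(dc["boundary"]), 1L)
  expect_equal(unname(dc["kept"]), 1L)
})

test_that("epochs touching masked artifact samples are excluded at the exact rate", {
  # 10,000 phonemes; exactly 413 (4.13%) have their windows inside masked spans
  n <- 10000
  rate <- 250
  starts <- (seq_len(n) - 1) * 0.7 + 0.05
  n_samp <- (n * 0.7 + 2) * rate
  set.seed(30)
  rec <- eeg_recording(matrix(rnorm(n_samp), 1, n_samp), rate, "Cz")
  an <- phoneme_annotation(data.frame(start_s = starts, end_s = starts + 0.06,
                                      phoneme_label = rep("T", n)))
  masked <- seq(7, by = 24, length.out = 413)  # phoneme indices to poison
  ivals <- cbind(starts[masked] - 0.02, starts[masked] + 0.02)
  rec <- apply_artifact_mask(rec, ivals)
  es <- extract_epochs(rec, an)
  dc <- attr(es, "drop_counts")
  expect_equal(unname(dc["artifact"]), 413L)
  expect_equal(unname(dc["artifact"]) / n, 0.0413)
  expect_equal(unname(dc["kept"]), n - 413L)
})

test_that("amplitude rejection removes epochs exceeding the threshold", {
  ep <- noise_epochs(20, 2, 50)
  ep[ep > 3] <- 0
  ep[3, 1, 10] <- 11     # one offending sample
  es <- structure(list(class_label = "V", epochs = ep,
                       onset_samples = seq_len(20), rate_hz = 250,
                       channels = c("Cz", "Pz")), class = "epoch_set")
  out <- reject_epochs(es, 10)
  expect_equal(dim(out$epochs)[1], 19)
  expect_equal(unname(attr(out, "rejection")["rejected"]), 1L)
  all_ok <- reject_epochs(structure(list(class_label = "V",
                                         epochs = pmin(pmax(ep, -10), 10),
                                         onset_samples = seq_len(20),
                                         rate_hz = 250,
                                         channels = c("Cz", "Pz")),
                                    class = "epoch_set"), 10)
  expect_equal(dim(all_ok$epochs)[1], 20)
})

test_that("standard-normal epochs are almost never rejected at 10 SD", {
  set.seed(20)
  ep <- noise_epochs(2000, 4, 125)
  es <- structure(list(class_label = "V", epochs = ep,
                       onset_samples = seq_len(2000), rate_hz = 250,
                       channels = montage_labels(4)), class = "epoch_set")
  out <- reject_epochs(es, 10)
  expect_lt(unname(attr(out, "rejection")["fraction"]), 0.01)
})

test_that("rank-sum p-values match hand-checked exact cases", {
  A <- array(c(1, 2, 3), dim = c(3, 1, 1))
  B <- array(c(4, 5, 6), dim = c(3, 1, 1))
  expect_equal(ranksum_pvalues(A, B)[1, 1], 0.1)
  expect_equal(ranksum_pvalues(A, A)[1, 1], 1)  # identical multisets
  expect_error(ranksum_pvalues(A, array(1, dim = c(1, 1, 1))),
               "at least 2 epochs")
})

test_that("rank-sum p-values match the enumeration oracle for group sizes <= 6", {
  set.seed(21)
  for (nA in 2:6) for (nB in 2:6) {
    for (rep in 1:5) {
      a <- sample.int(5, nA, replace = TRUE)  # integer data: ties guaranteed
      b <- sample.int(5, nB, replace = TRUE)
      p_pkg <- ranksum_pvalues(array(a, dim = c(nA, 1, 1)),
                               array(b, dim = c(nB, 1, 1)))[1, 1]
      expect_equal(p_pkg, oracle_ranksum_p(a, b), tolerance = 1e-12,
                   info = sprintf("nA=%d nB=%d rep=%d", nA, nB, rep))
    }
  }
})

test_that("large-sample rank-sum p-values are uniform under the null", {
  set.seed(22)
  A <- noise_epochs(40, 1, 10000)
  B <- noise_epochs(40, 1, 10000)
  p <- ranksum_pvalues(A, B)[1, ]
  grid <- seq(0.05, 0.95, by = 0.05)
  ecdf_err <- max(abs(vapply(grid, function(g) mean(p <= g), 0) - grid))
  expect_lt(ecdf_err, 0.02)
})

test_that("BH mask follows the step-up rule", {
  p <- matrix(c(0.01, 0.02, 0.04, 0.5), 1)
  expect_identical(as.vector(bh_fdr_mask(p, 0.05)),
                   c(TRUE, TRUE, FALSE, FALSE))
  expect_false(any(bh_fdr_mask(matrix(1, 2, 5))))
  expect_true(bh_fdr_mask(matrix(0.04, 1, 1))[1, 1])  # m = 1: uncorrected
  expect_error(bh_fdr_mask(matrix(c(0, 0.5), 1)), "0, 1")
})

test_that("BH mask equals the brute-force step-up oracle on random p-vectors", {
  set.seed(23)
  for (i in 1:200) {
    m <- sample(c(5, 20, 125), 1)
    p <- matrix(runif(m)^sample(c(1, 2, 3), 1), 1)
    expect_identical(as.vector(bh_fdr_mask(p, 0.05)),
                     unname(oracle_bh_reject(p[1, ], 0.05)))
  }
})

test_that("global-scope BH is no more permissive than within-channel under the null", {
  set.seed(24)
  rej_within <- 0; rej_global <- 0
  for (i in 1:300) {
    p <- matrix(runif(8 * 50), 8)
    rej_within <- rej_within + sum(bh_fdr_mask(p, scope = "within_channel"))
    rej_global <- rej_global + sum(bh_fdr_mask(p, scope = "global"))
  }
  expect_lte(rej_global, rej_within)
})

test_that("pair maps require two distinct phoneme classes", {
  cfg <- synth_config(duration_s = 10, n_channels = 2)
  d <- generate_dataset(cfg, seed = 25)
  rec <- preprocess(d$eeg)
  expect_error(pair_map(rec, d$annotation, c("A", "A")), "distinct")
  expect_error(pair_map(rec, d$annotation, c("A", "Q")), "unknown")
})

test_that("pair-mask averaging needs exactly the 10 distinct pairs", {
  mk <- function(pair, val) {
    mask <- matrix(val, 2, 5)
    structure(list(pair = pair, p_values = matrix(0.5, 2, 5),
                   mask = structure(mask, alpha = 0.05, scope = "within_channel"),
                   correction_scope = "within_channel", alpha = 0.05,
                   n_epochs = c(3, 3), rate_hz = 250,
                   channels = c("Cz", "Pz")), class = "pair_result")
  }
  pairs <- combn(c("A", "F", "N", "P", "V"), 2)
  prs <- lapply(seq_len(10), function(k) mk(pairs[, k], k <= 3))
  fm <- average_pair_maps(prs)
  expect_true(all(fm == 0.3))
  expect_identical(attr(fm, "level"), "trial")
  all_true <- lapply(seq_len(10), function(k) mk(pairs[, k], TRUE))
  expect_true(all(average_pair_maps(all_true) == 1))
  expect_error(average_pair_maps(prs[1:9]), "10")
  expect_error(average_pair_maps(c(prs[1:9], prs[9])), "distinct pairs")
})

test_that("profiles average over the orthogonal axis and keep the chance level", {
  m <- frequency_map(matrix(0.2, 37, 125), (0:124) * 4, montage_labels(37))
  expect_true(all(abs(temporal_profile(m) - 0.2) < 1e-15))
  expect_true(all(abs(spatial_profile(m) - 0.2) < 1e-15))
  vals <- matrix(0, 37, 125); vals[5, 10] <- 1
  m2 <- frequency_map(vals, (0:124) * 4, montage_labels(37))
  tp <- temporal_profile(m2)
  expect_equal(unname(tp[10]), 1 / 37)
  expect_equal(sum(tp), 1 / 37)
  expect_equal(attr(tp, "chance_level"), 0.05 / 125)
})

test_that("subinterval summary respects the 4 ms grid and default bins", {
  m <- frequency_map(matrix(0.5, 3, 125), (0:124) * 4, c("F3", "F4", "Cz"))
  s <- subinterval_summary(m)
  expect_equal(dim(s), c(3, 5))
  expect_true(all(s == 0.5))
  expect_identical(colnames(s)[1], "0-80")
  # first bin covers samples 0..20 -> 21 timepoints
  vals <- matrix(0, 1, 125); vals[1, 1:21] <- 1
  m2 <- frequency_map(vals, (0:124) * 4, "Cz")
  s2 <- subinterval_summary(m2)
  expect_equal(unname(s2[1, ]), c(1, 0, 0, 0, 0))
  expect_error(subinterval_summary(m, list(c(0, 81), c(85, 500))), "grid")
  expect_error(subinterval_summary(m, list(c(0, 80), c(80, 500))), "overlap")
  expect_error(subinterval_summary(m, list(c(0, 80), c(100, 500))), "cover")
})

test_that("an injected early effect maximizes the first subinterval", {
  vals <- matrix(0, 2, 125)
  vals[2, 8:15] <- 1    # 28-56 ms
  m <- frequency_map(vals, (0:124) * 4, c("Cz", "Pz"))
  s <- subinterval_summary(m)
  expect_equal(unname(which.max(s[2, ])), 1L)
})
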