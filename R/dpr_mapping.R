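#' Extract onset-locked epochs per phoneme class
#'
#' Cuts the (preprocessed) record into fixed-length segments beginning at
#' each phoneme onset (`onset sample = round(start_s * rate) + 1`, 1-based)
#' and groups them by phoneme class. Because phonemes are much shorter than
#' the analysis window, epochs overlap freely. An epoch is dropped if its
#' window extends past the record end or touches any artifact-masked sample;
#' phonemes with an unmapped label are skipped. Dropped epochs are counted in
#' the `drop_counts` attribute (`kept`, `boundary`, `artifact`, `unmapped`).
#'
#' @param rec a preprocessed [eeg_recording].
#' @param annot a [phoneme_annotation].
#' @param window_ms epoch length in ms (default 500, i.e. 125 samples at
#'   250 Hz).
#' @return named list of `epoch_set` objects (one per class present), each a
#'   list with `class_label`, `epochs` (n x channels x samples array),
#'   `onset_samples`, `rate_hz`, `channels`.
#' @export
extract_epochs <- function(rec, annot, window_ms = 500) {
  win <- round(window_ms / 1000 * rec$rate_hz)
  ns <- n_samples(rec)
  iv <- annot$intervals
  onset <- round(iv$start_s * rec$rate_hz) + 1L
  unmapped <- is.na(iv$class)
  boundary <- !unmapped & (onset + win - 1L > ns | onset < 1L)
  # cumulative mask count gives O(1) "any masked sample in window" lookups
  cm <- c(0, cumsum(rec$artifact_mask))
  artifact <- !unmapped & !boundary &
    (cm[pmin(onset + win, ns + 1L)] - cm[pmax(onset, 1L)] > 0)
  keep <- !unmapped & !boundary & !artifact
  sets <- list()
  for (cl in intersect(PHONEME_CLASSES, unique(iv$class[keep]))) {
    idx <- which(keep & iv$class == cl)
    ep <- array(0, dim = c(length(idx), nrow(rec$data), win))
    for (k in seq_along(idx))
      ep[k, , ] <- rec$data[, onset[idx[k]]:(onset[idx[k]] + win - 1L), drop = FALSE]
    sets[[cl]] <- structure(
      list(class_label = cl, epochs = ep, onset_samples = onset[idx],
           rate_hz = rec$rate_hz, channels = rec$channel_labels),
      class = "epoch_set")
  }
  structure(sets,
            drop_counts = c(kept = sum(keep), boundary = sum(boundary),
                            artifact = sum(artifact), unmapped = sum(unmapped)))
}

#' Reject epochs by amplitude
#'
#' Removes any epoch containing a sample whose absolute amplitude exceeds
#' `sd_threshold`. The input channels are assumed standardized to unit
#' variance, so the threshold is expressed in standard deviations. The
#' fraction rejected is recorded in the `rejection` attribute.
#'
#' @param epoch_sets list of `epoch_set`s from [extract_epochs] (a single
#'   `epoch_set` is also accepted).
#' @param sd_threshold rejection threshold (default 10 SD).
#' @return epoch sets with offending epochs removed.
#' @export
reject_epochs <- function(epoch_sets, sd_threshold = 10) {
  single <- inherits(epoch_sets, "epoch_set")
  if (single) epoch_sets <- list(epoch_sets)
  total <- 0L; rejected <- 0L
  out <- lapply(epoch_sets, function(es) {
    n <- dim(es$epochs)[1]
    if (n == 0) return(es)
    peak <- apply(abs(es$epochs), 1, max)
    keep <- peak <= sd_threshold
    total <<- total + n; rejected <<- rejected + sum(!keep)
    es$epochs <- es$epochs[keep, , , drop = FALSE]
    es$onset_samples <- es$onset_samples[keep]
    es
  })
  if (!single) names(out) <- names(epoch_sets)
  structure(if (single) out[[1]] else out,
            rejection = c(total = total, rejected = rejected,
                          fraction = if (total) rejected / total else 0))
}

epochs_array <- function(x) {
  if (inherits(x, "epoch_set")) x$epochs
  else if (is.array(x) && length(dim(x)) == 3) x
  else stop("expected an epoch_set or an n x channels x samples array")
}

#' Mass-univariate two-tailed Wilcoxon rank-sum p-values
#'
#' At every (channel, timepoint), compares the across-epoch amplitude
#' distributions of two phoneme classes with the two-tailed Wilcoxon
#' rank-sum (Mann-Whitney) test. For group sizes of at most 8 the exact
#' permutation distribution of the rank sum is enumerated (valid under
#' ties); for larger groups the normal approximation with tie and continuity
#' correction is used. Cells where all amplitudes are identical get p = 1.
#'
#' @param epochs_a,epochs_b `epoch_set`s or n x channels x samples arrays
#'   with matching channel/sample dimensions and at least 2 epochs each.
#' @param exact_max largest group size for which the exact distribution is
#'   enumerated.
#' @return channels x samples matrix of p-values in (0, 1].
#' @export
ranksum_pvalues <- function(epochs_a, epochs_b, exact_max = 8) {
  A <- epochs_array(epochs_a); B <- epochs_array(epochs_b)
  if (!all(dim(A)[2:3] == dim(B)[2:3]))
    stop("epoch sets have mismatched channel/sample dimensions")
  nA <- dim(A)[1]; nB <- dim(B)[1]
  if (nA < 2 || nB < 2) stop("each class needs at least 2 epochs")
  n_ch <- dim(A)[2]; n_t <- dim(A)[3]
  N <- nA + nB
  exact <- max(nA, nB) <= exact_max
  comb <- if (exact) utils::combn(N, nA) else NULL
  p <- matrix(1, n_ch, n_t)
  for (ch in seq_len(n_ch)) {
    X <- rbind(matrix(A[, ch, ], nA, n_t), matrix(B[, ch, ], nB, n_t))
    R <- apply(X, 2, rank)
    W <- colSums(R[seq_len(nA), , drop = FALSE])
    if (exact) {
      for (j in seq_len(n_t))
        p[ch, j] <- ranksum_exact_p(R[, j], nA, comb, W[j])
    } else {
      mu <- nA * (N + 1) / 2
      base_var <- nA * nB * (N + 1) / 12
      sigma2 <- rep(base_var, n_t)
      dup <- which(apply(X, 2, anyDuplicated) > 0)
      for (j in dup) {
        tt <- rle(sort(X[, j]))$lengths
        sigma2[j] <- nA * nB / 12 * ((N + 1) - sum(tt^3 - tt) / (N * (N - 1)))
      }
      z <- (abs(W - mu) - 0.5) / sqrt(sigma2)
      pj <- 2 * stats::pnorm(-z)
      pj[sigma2 <= 0] <- 1
      p[ch, ] <- pmin(pj, 1)
    }
  }
  p
}

# Exact two-tailed rank-sum p from the permutation distribution of the rank
# sum over all assignments of nA of the N (tie-adjusted) ranks to group A.
ranksum_exact_p <- function(ranks, nA, comb, w_obs) {
  ws <- colSums(matrix(ranks[comb], nrow = nA))
  lo <- mean(ws <= w_obs + 1e-9)
  hi <- mean(ws >= w_obs - 1e-9)
  min(1, 2 * min(lo, hi))
}

#' Benjamini-Hochberg FDR significance mask
#'
#' Applies the BH step-up rule at level `alpha` to a channels x points
#' p-value matrix. With `scope = "within_channel"` each channel's points form
#' their own correction family (the primary analysis); with
#' `scope = "global"` a single family spans all cells. Ties at the threshold
#' are all rejected, per the step-up definition.
#'
#' @param p_matrix channels x points matrix of p-values in (0, 1].
#' @param alpha FDR level (default 0.05).
#' @param scope `"within_channel"` or `"global"`.
#' @return logical matrix of the same shape (`TRUE` = significant) with
#'   attributes `alpha` and `scope`.
#' @export
bh_fdr_mask <- function(p_matrix, alpha = 0.05,
                        scope = c("within_channel", "global")) {
  scope <- match.arg(scope)
  p_matrix <- as.matrix(p_matrix)
  if (any(p_matrix <= 0 | p_matrix > 1))
    stop("p-values must lie in (0, 1]")
  mask <- if (scope == "within_channel") {
    t(apply(p_matrix, 1, function(p) stats::p.adjust(p, "BH") <= alpha))
  } else {
    matrix(stats::p.adjust(p_matrix, "BH") <= alpha, nrow(p_matrix))
  }
  dimnames(mask) <- dimnames(p_matrix)
  structure(mask, alpha = alpha, scope = scope)
}

#' Differential response map for one phoneme-class pair
#'
#' Composes epoch extraction, amplitude rejection, the mass-univariate
#' rank-sum stage and BH-FDR masking for a single unordered pair of phoneme
#' classes.
#'
#' @param rec preprocessed [eeg_recording].
#' @param annot [phoneme_annotation].
#' @param pair character vector of two distinct classes, e.g. `c("P", "V")`.
#' @param cfg [preprocess_config] (supplies the rejection threshold).
#' @param window_ms epoch length (ms).
#' @param alpha FDR level.
#' @param scope correction scope, see [bh_fdr_mask].
#' @param epoch_sets optionally, pre-extracted (and rejected) epoch sets, to
#'   avoid re-epoching when mapping all 10 pairs of one trial.
#' @return object of class `pair_result`: list with `pair`, `p_values`,
#'   `mask`, `correction_scope`, `alpha`, `n_epochs`.
#' @export
pair_map <- function(rec, annot, pair, cfg = preprocess_config(rate_hz = rec$rate_hz),
                     window_ms = 500, alpha = 0.05,
                     scope = c("within_channel", "global"), epoch_sets = NULL) {
  scope <- match.arg(scope)
  pair <- as.character(pair)
  if (length(pair) != 2 || pair[1] == pair[2])
    stop("pair must name two distinct phoneme classes")
  if (!all(pair %in% PHONEME_CLASSES))
    stop("unknown phoneme class in pair: ", paste(pair, collapse = ", "))
  if (is.null(epoch_sets)) {
    epoch_sets <- reject_epochs(extract_epochs(rec, annot, window_ms),
                                cfg$epoch_reject_sd)
  }
  if (!all(pair %in% names(epoch_sets)))
    stop("no epochs for class(es): ",
         paste(setdiff(pair, names(epoch_sets)), collapse = ", "))
  a <- epoch_sets[[pair[1]]]; b <- epoch_sets[[pair[2]]]
  p <- ranksum_pvalues(a, b)
  dimnames(p) <- list(a$channels, NULL)
  mask <- bh_fdr_mask(p, alpha, scope)
  structure(list(pair = pair, p_values = p, mask = mask,
                 correction_scope = scope, alpha = alpha,
                 n_epochs = c(dim(a$epochs)[1], dim(b$epochs)[1]),
                 rate_hz = a$rate_hz, channels = a$channels),
            class = "pair_result")
}

#' Average significance masks across all 10 phoneme-class pairs
#'
#' Cell values are the fraction of the C(5,2) = 10 pairwise comparisons that
#' reached significance at each (channel, timepoint); exactly the 10 distinct
#' pairs must be supplied.
#'
#' @param pair_results list of `pair_result`s from [pair_map].
#' @return a trial-level [frequency_map].
#' @export
average_pair_maps <- function(pair_results) {
  if (length(pair_results) != 10)
    stop("expected the 10 distinct class pairs, got ", length(pair_results))
  keys <- vapply(pair_results, function(pr)
    paste(sort(pr$pair), collapse = ""), "")
  expected <- apply(utils::combn(PHONEME_CLASSES, 2), 2, paste, collapse = "")
  if (!setequal(keys, expected) || anyDuplicated(keys))
    stop("pair set must be exactly the 10 distinct pairs of the 5 classes")
  masks <- lapply(pair_results, function(pr) {
    m <- unclass(pr$mask) * 1
    attributes(m) <- list(dim = dim(m))
    m
  })
  vals <- Reduce(`+`, masks) / length(masks)
  rate <- pair_results[[1]]$rate_hz
  frequency_map(vals, points_ms = (seq_len(ncol(vals)) - 1) * 1000 / rate,
                channels = pair_results[[1]]$channels,
                axis = "time", level = "trial",
                chance_level = 0.05 / ncol(vals))
}

#' Temporal and spatial profiles of a frequency map
#'
#' The temporal profile is the mean frequency over channels at each
#' time/lag point; the spatial profile is the mean over points for each
#' channel. Both carry the map's chance level as an attribute.
#'
#' @param freq_map a [frequency_map].
#' @return named numeric vector with attribute `chance_level`.
#' @export
temporal_profile <- function(freq_map) {
  structure(colMeans(unclass(freq_map)),
            points_ms = attr(freq_map, "points_ms"),
            chance_level = attr(freq_map, "chance_level"))
}

#' @rdname temporal_profile
#' @export
spatial_profile <- function(freq_map) {
  structure(rowMeans(unclass(freq_map)),
            chance_level = attr(freq_map, "chance_level"))
}

#' Subinterval summary of a frequency map
#'
#' Averages the map within consecutive time bins. The default bins split the
#' 500 ms analysis window at the boundaries 0-80, 84-148, 152-300, 304-400
#' and 404-500 ms (bounds inclusive on the 4 ms sample grid). Bins must fall
#' on the grid, not overlap, and jointly cover every point of the map.
#'
#' @param freq_map a [frequency_map].
#' @param bins_ms list of `c(lo, hi)` bounds in ms.
#' @return channels x bins matrix of mean frequencies.
#' @export
subinterval_summary <- function(freq_map,
                                bins_ms = list(c(0, 80), c(84, 148), c(152, 300),
                                               c(304, 400), c(404, 500))) {
  pts <- attr(freq_map, "points_ms")
  step <- pts[2] - pts[1]
  member <- lapply(bins_ms, function(b) {
    if (any(round(b / step) * step != b))
      stop("bin bounds must fall on the ", step, " ms sample grid")
    pts >= b[1] - 1e-9 & pts <= b[2] + 1e-9
  })
  cover <- Reduce(`+`, member)
  if (any(cover > 1)) stop("bins overlap on the sample grid")
  if (any(cover == 0)) stop("bins do not cover all map points")
  out <- vapply(member, function(m) rowMeans(unclass(freq_map)[, m, drop = FALSE]),
                numeric(nrow(freq_map)))
  out <- matrix(out, nrow = nrow(freq_map),
                dimnames = list(rownames(freq_map),
                                vapply(bins_ms, function(b)
                                  sprintf("%g-%g", b[1], b[2]), "")))
  out
}

#' Full differential phoneme-class response analysis of one trial
#'
#' Extracts and screens epochs once, maps all 10 class pairs, and averages
#' the masks into a trial-level frequency map.
#'
#' @inheritParams pair_map
#' @return list with `pair_results` (named by pair), `trial_map` (a
#'   [frequency_map]), `drop_counts` and `rejection` bookkeeping.
#' @export
dpr_analysis <- function(rec, annot, cfg = preprocess_config(rate_hz = rec$rate_hz),
                         window_ms = 500, alpha = 0.05,
                         scope = c("within_channel", "global")) {
  scope <- match.arg(scope)
  raw_sets <- extract_epochs(rec, annot, window_ms)
  sets <- reject_epochs(raw_sets, cfg$epoch_reject_sd)
  missing <- setdiff(PHONEME_CLASSES, names(sets))
  if (length(missing))
    stop("no usable epochs for class(es): ", paste(missing, collapse = ", "))
  pairs <- utils::combn(PHONEME_CLASSES, 2)
  prs <- lapply(seq_len(ncol(pairs)), function(k)
    pair_map(rec, annot, pairs[, k], cfg, window_ms, alpha, scope,
             epoch_sets = sets))
  names(prs) <- apply(pairs, 2, paste, collapse = "")
  list(pair_results = prs, trial_map = average_pair_maps(prs),
       drop_counts = attr(raw_sets, "drop_counts"),
       rejection = attr(sets, "rejection"))
}
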