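#' Preprocessing configuration
#'
#' Parameters of the fixed preprocessing cascade applied before both
#' analyses: a 60 Hz notch, a 2-15 Hz band-pass, per-channel standardization
#' to zero mean and unit variance, and amplitude-based epoch rejection at 10
#' standard deviations (in standardized units).
#'
#' @param notch_hz mains frequency to remove (Hz).
#' @param band_low_hz,band_high_hz band-pass corner frequencies (Hz).
#' @param epoch_reject_sd epoch rejection threshold, in standard deviations.
#' @param rate_hz EEG sampling rate (Hz).
#' @return object of class `preprocess_config`.
#' @export
preprocess_config <- function(notch_hz = 60, band_low_hz = 2, band_high_hz = 15,
                              epoch_reject_sd = 10, rate_hz = 250) {
  if (!(band_low_hz > 0 && band_low_hz < band_high_hz &&
        band_high_hz < rate_hz / 2))
    stop("need 0 < band_low_hz < band_high_hz < rate_hz/2")
  if (notch_hz >= rate_hz / 2) stop("notch_hz must be below the Nyquist rate")
  if (epoch_reject_sd <= 0) stop("epoch_reject_sd must be positive")
  structure(list(notch_hz = notch_hz, band_low_hz = band_low_hz,
                 band_high_hz = band_high_hz, epoch_reject_sd = epoch_reject_sd,
                 rate_hz = rate_hz),
            class = "preprocess_config")
}

# Zero-phase (forward-backward) IIR filtering with odd reflection padding at
# both ends to suppress edge transients. Squares the magnitude response, so
# quoted attenuations are per single pass of the underlying design.
filtfilt_pad <- function(b, a, x) {
  n <- length(x)
  pad <- min(n - 1, 3L * max(length(a), length(b)) * 10L)
  if (pad < 1) stop("signal too short to filter")
  left <- 2 * x[1] - x[seq(pad + 1, 2)]
  right <- 2 * x[n] - x[seq(n - 1, n - pad)]
  y <- c(left, x, right)
  y <- as.numeric(signal::filter(b, a, y))
  y <- rev(as.numeric(signal::filter(b, a, rev(y))))
  y[(pad + 1):(pad + n)]
}

apply_channelwise <- function(rec, fun) {
  out <- rec
  for (i in seq_len(nrow(rec$data))) out$data[i, ] <- fun(rec$data[i, ])
  out
}

#' Notch filter (mains removal)
#'
#' Zero-phase 4th-order Butterworth band-stop around `notch_hz` (+- 2 Hz),
#' applied forward and backward so evoked latencies are not shifted.
#'
#' @param rec an [eeg_recording].
#' @param cfg a [preprocess_config].
#' @return filtered [eeg_recording] of the same length.
#' @export
notch_filter <- function(rec, cfg = preprocess_config(rate_hz = rec$rate_hz)) {
  if (rec$rate_hz <= 2 * cfg$notch_hz)
    stop("sampling rate must exceed twice the notch frequency")
  w <- c(cfg$notch_hz - 2, cfg$notch_hz + 2) / (rec$rate_hz / 2)
  flt <- signal::butter(4, w, type = "stop")
  apply_channelwise(rec, function(x) filtfilt_pad(flt$b, flt$a, x))
}

#' Band-pass filter
#'
#' Zero-phase 4th-order Butterworth band-pass between `band_low_hz` and
#' `band_high_hz` (default 2-15 Hz), applied forward and backward.
#'
#' @inheritParams notch_filter
#' @return filtered [eeg_recording] of the same length.
#' @export
bandpass_filter <- function(rec, cfg = preprocess_config(rate_hz = rec$rate_hz)) {
  w <- c(cfg$band_low_hz, cfg$band_high_hz) / (rec$rate_hz / 2)
  flt <- signal::butter(4, w, type = "pass")
  apply_channelwise(rec, function(x) filtfilt_pad(flt$b, flt$a, x))
}

#' Standardize each channel to zero mean and unit variance
#'
#' Mean and standard deviation are estimated over non-artifact samples only,
#' and the resulting affine transform is applied to the whole channel, so
#' masked stretches do not bias the scaling.
#'
#' @param rec an [eeg_recording].
#' @return standardized [eeg_recording] (dimensionless amplitudes).
#' @export
standardize <- function(rec) {
  keep <- !rec$artifact_mask
  if (!any(keep)) stop("no non-artifact samples to standardize over")
  out <- rec
  for (i in seq_len(nrow(rec$data))) {
    x <- rec$data[i, keep]
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0)
      stop("channel ", rec$channel_labels[i],
           " has zero variance over non-artifact samples")
    out$data[i, ] <- (rec$data[i, ] - mean(x)) / s
  }
  out
}

#' Mark artifact intervals on a recording
#'
#' Sets the artifact mask to `TRUE` over the union of the given half-open
#' intervals `[start_s, end_s)`. Samples are never deleted: downstream stages
#' exclude any epoch or segment that touches a masked sample, so annotation
#' times keep their sample alignment.
#'
#' @param rec an [eeg_recording].
#' @param intervals_s two-column matrix or data.frame of (start_s, end_s),
#'   or a numeric vector of length 2.
#' @return [eeg_recording] with an updated artifact mask.
#' @export
apply_artifact_mask <- function(rec, intervals_s) {
  if (is.null(intervals_s) || NROW(intervals_s) == 0) return(rec)
  if (is.null(dim(intervals_s))) intervals_s <- matrix(intervals_s, ncol = 2, byrow = TRUE)
  intervals_s <- as.matrix(intervals_s)
  dur <- duration_s(rec)
  if (any(intervals_s[, 1] < 0) || any(intervals_s[, 2] > dur + 1e-9) ||
      any(intervals_s[, 2] <= intervals_s[, 1]))
    stop("artifact intervals must satisfy 0 <= start < end <= record duration")
  mask <- rec$artifact_mask
  r <- rec$rate_hz
  for (k in seq_len(nrow(intervals_s))) {
    first <- floor(intervals_s[k, 1] * r + 1e-9) + 1
    last <- ceiling(intervals_s[k, 2] * r - 1e-9)
    mask[first:min(last, length(mask))] <- TRUE
  }
  rec$artifact_mask <- mask
  rec
}

#' Read artifact intervals from a two-column seconds table
#'
#' @param path whitespace/tab-delimited file with columns start_s, end_s
#'   (header optional).
#' @return two-column numeric matrix.
#' @export
read_artifact_intervals <- function(path) {
  tab <- utils::read.table(path, header = FALSE, col.names = c("start_s", "end_s"),
                           colClasses = "character")
  if (suppressWarnings(is.na(as.numeric(tab$start_s[1])))) tab <- tab[-1, , drop = FALSE]
  cbind(start_s = as.numeric(tab$start_s), end_s = as.numeric(tab$end_s))
}

#' Trial screening by total artifact duration
#'
#' A trial is retained for analysis only if its total artifact-masked
#' duration does not exceed `max_artifact_s` (default 15 s).
#'
#' @param rec an [eeg_recording] with its artifact mask set.
#' @param max_artifact_s maximum tolerated artifact duration in seconds.
#' @return logical: `TRUE` if the trial is accepted.
#' @export
trial_screen <- function(rec, max_artifact_s = 15) {
  sum(rec$artifact_mask) / rec$rate_hz <= max_artifact_s + 1e-9
}

#' Full preprocessing cascade
#'
#' Notch filter, band-pass filter, then per-channel standardization, with an
#' optional artifact-interval mask applied first (masked samples are excluded
#' from the standardization statistics and from all downstream epochs and
#' segments).
#'
#' @param rec an [eeg_recording].
#' @param cfg a [preprocess_config].
#' @param artifact_intervals_s optional intervals for [apply_artifact_mask].
#' @return preprocessed [eeg_recording].
#' @export
preprocess <- function(rec, cfg = preprocess_config(rate_hz = rec$rate_hz),
                       artifact_intervals_s = NULL) {
  if (!is.null(artifact_intervals_s))
    rec <- apply_artifact_mask(rec, artifact_intervals_s)
  standardize(bandpass_filter(notch_filter(rec, cfg), cfg))
}
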