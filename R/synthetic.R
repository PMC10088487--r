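#' Synthetic dataset configuration
#'
#' Describes a synthetic passive-listening dataset: a phoneme annotation
#' whose durations follow a log-normal model with mean 79.5 ms truncated to
#' 30-320 ms and whose five manner classes occur in the proportions of the
#' narrative stimulus (A 163, F 264, N 147, P 355, V 617); a low-frequency
#' speech envelope (class-dependent per-phoneme loudness, smoothed) with a
#' carrier-modulated audio rendering; and EEG containing band-limited 1/f
#' background noise at unit variance plus optional class-specific evoked
#' components, an envelope-following component at a configurable lag, and
#' artifact bursts.
#'
#' @param duration_s record duration in seconds (default 148, one stimulus
#'   presentation).
#' @param rate_hz EEG sampling rate (default 250).
#' @param n_channels number of EEG channels (default 8; up to 37 labelled
#'   10-20/10-10 positions).
#' @param audio_rate_hz audio sampling rate (default 44100).
#' @param carrier_hz carrier tone for the audio rendering.
#' @param dur_mean_ms,dur_range_ms,dur_sdlog phoneme duration model: target
#'   mean, truncation bounds, and log-scale spread of the log-normal.
#' @param class_probs named class probabilities (normalized internally).
#' @param class_levels named per-class envelope loudness levels.
#' @param class_effects list of evoked-component specs, each a list with
#'   `class`, `amplitude` (SD units), `latency_ms` (bump onset after phoneme
#'   onset), `duration_ms`, `channels` (label or index vector) or
#'   `channel_weights` (length `n_channels`).
#' @param envelope_coupling `NULL`, or a list with `lag_ms` (kernel peak),
#'   `amplitude` (SD units), `duration_ms` (kernel width), and `channels` /
#'   `channel_weights` as above.
#' @param artifacts `NULL`, or a list with `count`, `duration_s`, `amplitude`
#'   (SD units) for random high-amplitude bursts.
#' @return object of class `synth_config`.
#' @export
synth_config <- function(duration_s = 148, rate_hz = 250, n_channels = 8,
                         audio_rate_hz = 44100, carrier_hz = 440,
                         dur_mean_ms = 79.5, dur_range_ms = c(30, 320),
                         dur_sdlog = 0.4,
                         class_probs = c(A = 163, F = 264, N = 147,
                                         P = 355, V = 617),
                         class_levels = c(A = 0.7, F = 0.5, N = 0.6,
                                          P = 0.4, V = 1.0),
                         class_effects = list(),
                         envelope_coupling = NULL,
                         artifacts = NULL) {
  if (duration_s <= 0 || rate_hz <= 0) stop("duration_s and rate_hz must be positive")
  if (!setequal(names(class_probs), PHONEME_CLASSES))
    stop("class_probs must be named by the classes ", paste(PHONEME_CLASSES, collapse = ","))
  if (any(class_probs < 0) || sum(class_probs) <= 0)
    stop("class_probs must be non-negative with positive sum")
  class_probs <- class_probs[PHONEME_CLASSES] / sum(class_probs)
  if (dur_range_ms[1] >= dur_range_ms[2] || dur_mean_ms <= dur_range_ms[1] ||
      dur_mean_ms >= dur_range_ms[2])
    stop("duration model needs lo < mean < hi")
  for (eff in class_effects)
    if ((eff$amplitude %||% 0) < 0) stop("effect amplitudes must be >= 0")
  if (!is.null(envelope_coupling) && (envelope_coupling$amplitude %||% 0) < 0)
    stop("coupling amplitude must be >= 0")
  structure(list(duration_s = duration_s, rate_hz = rate_hz,
                 n_channels = n_channels, audio_rate_hz = audio_rate_hz,
                 carrier_hz = carrier_hz, dur_mean_ms = dur_mean_ms,
                 dur_range_ms = dur_range_ms, dur_sdlog = dur_sdlog,
                 class_probs = class_probs, class_levels = class_levels,
                 class_effects = class_effects,
                 envelope_coupling = envelope_coupling,
                 artifacts = artifacts),
            class = "synth_config")
}

# meanlog of a log-normal with spread sdlog whose truncated mean on [lo, hi]
# equals `target` (all in ms).
trunc_lognorm_meanlog <- function(target, lo, hi, sdlog) {
  tm <- function(mu) {
    num <- exp(mu + sdlog^2 / 2) *
      (stats::pnorm((log(hi) - mu - sdlog^2) / sdlog) -
       stats::pnorm((log(lo) - mu - sdlog^2) / sdlog))
    den <- stats::pnorm((log(hi) - mu) / sdlog) -
      stats::pnorm((log(lo) - mu) / sdlog)
    num / den
  }
  stats::uniroot(function(mu) tm(mu) - target,
                 lower = log(lo), upper = log(hi), tol = 1e-10)$root
}

r_trunc_lognorm <- function(n, meanlog, sdlog, lo, hi) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rlnorm(2 * (n - length(out)) + 10, meanlog, sdlog)
    out <- c(out, x[x >= lo & x <= hi])
  }
  out[seq_len(n)]
}

#' Generate a synthetic phoneme annotation
#'
#' Contiguous phoneme intervals tiling `[0, duration_s]`: durations drawn
#' from the truncated log-normal model, classes drawn per the configured
#' probabilities, and a concrete ARPAbet label drawn uniformly within the
#' class. Deterministic given `(cfg, seed)`.
#'
#' @param cfg a [synth_config].
#' @param seed integer seed.
#' @return a [phoneme_annotation].
#' @export
generate_annotation <- function(cfg, seed = 1) {
  meanlog <- trunc_lognorm_meanlog(cfg$dur_mean_ms, cfg$dur_range_ms[1],
                                   cfg$dur_range_ms[2], cfg$dur_sdlog)
  cmap <- default_class_map()
  with_seed(seed, {
    n_guess <- ceiling(cfg$duration_s * 1000 / cfg$dur_mean_ms * 1.2) + 20
    durs <- r_trunc_lognorm(n_guess, meanlog, cfg$dur_sdlog,
                            cfg$dur_range_ms[1], cfg$dur_range_ms[2]) / 1000
    ends <- cumsum(durs)
    n <- sum(ends <= cfg$duration_s)
    durs <- durs[seq_len(n)]
    classes <- sample(PHONEME_CLASSES, n, replace = TRUE, prob = cfg$class_probs)
    labels <- vapply(classes, function(cl) {
      pool <- names(cmap)[cmap == cl]
      pool[sample.int(length(pool), 1)]
    }, "")
    start <- c(0, cumsum(durs)[-n])
    phoneme_annotation(data.frame(start_s = start, end_s = start + durs,
                                  phoneme_label = labels))
  })
}

expand_channel_weights <- function(spec, channels) {
  if (!is.null(spec$channel_weights)) {
    w <- spec$channel_weights
    if (length(w) != length(channels)) stop("channel_weights length mismatch")
    return(as.numeric(w))
  }
  w <- numeric(length(channels))
  idx <- spec$channels %||% seq_along(channels)
  if (is.character(idx)) idx <- match(idx, channels)
  if (anyNA(idx) || any(idx < 1) || any(idx > length(channels)))
    stop("unknown channels in effect spec")
  w[idx] <- 1
  w
}

half_sine <- function(n_samples) {
  if (n_samples < 1) return(numeric(0))
  sin(pi * (seq_len(n_samples) - 0.5) / n_samples)
}

#' Generate the synthetic envelope and its audio rendering
#'
#' The envelope is a smoothed per-phoneme loudness profile: each phoneme gets
#' a class-dependent level with log-normal jitter, held over its interval and
#' smoothed with a 10 ms Gaussian kernel (non-negative by construction). The
#' audio is a carrier tone amplitude-modulated by this envelope at the audio
#' rate, for end-to-end tests of the audio path.
#'
#' @param annot a [phoneme_annotation].
#' @param cfg a [synth_config].
#' @param seed integer seed.
#' @return list with `envelope` (raw, non-negative [envelope_signal] at the
#'   EEG rate) and `audio` (an [audio_signal]).
#' @export
generate_envelope <- function(annot, cfg, seed = 1) {
  n <- round(cfg$duration_s * cfg$rate_hz)
  iv <- annot$intervals
  with_seed(seed, {
    amp <- cfg$class_levels[iv$class] * stats::rlnorm(nrow(iv), 0, 0.3)
    amp[is.na(amp)] <- mean(cfg$class_levels)
    env <- numeric(n)
    first <- pmin(pmax(floor(iv$start_s * cfg$rate_hz) + 1, 1), n)
    last <- pmin(pmax(ceiling(iv$end_s * cfg$rate_hz), 1), n)
    for (k in seq_len(nrow(iv))) env[first[k]:last[k]] <- amp[k]
    # 10 ms Gaussian smoothing
    sd_samp <- 0.010 * cfg$rate_hz
    kx <- seq(-ceiling(4 * sd_samp), ceiling(4 * sd_samp))
    kern <- exp(-kx^2 / (2 * sd_samp^2)); kern <- kern / sum(kern)
    env <- as.numeric(stats::filter(c(rep(env[1], length(kx)), env,
                                      rep(env[n], length(kx))),
                                    kern, sides = 2))[length(kx) + seq_len(n)]
    n_audio <- round(cfg$duration_s * cfg$audio_rate_hz)
    t_audio <- (seq_len(n_audio) - 1) / cfg$audio_rate_hz
    env_hi <- stats::approx((seq_len(n) - 1) / cfg$rate_hz, env,
                            xout = t_audio, rule = 2)$y
    wave <- sin(2 * pi * cfg$carrier_hz * t_audio) * env_hi
    peak <- max(abs(wave))
    if (peak > 0) wave <- wave / peak * 0.9
    list(envelope = envelope_signal(env, cfg$rate_hz),
         audio = audio_signal(wave, cfg$audio_rate_hz))
  })
}

# Band-limited 1/f-shaped Gaussian noise, standardized to unit variance.
shaped_noise <- function(n, rate_hz, band = c(2, 15)) {
  x <- stats::rnorm(n)
  X <- stats::fft(x)
  f <- c(0, pmin(seq_len(n - 1), n - seq_len(n - 1))) * rate_hz / n
  shape <- ifelse(f > 0, 1 / sqrt(pmax(f, 1)), 0)
  x <- Re(stats::fft(X * shape, inverse = TRUE)) / n
  flt <- signal::butter(4, band / (rate_hz / 2), type = "pass")
  x <- filtfilt_pad(flt$b, flt$a, x)
  (x - mean(x)) / stats::sd(x)
}

#' Generate synthetic EEG with known embedded effects
#'
#' EEG = unit-variance band-limited 1/f noise, plus (per configured class
#' effect) a half-sine evoked bump of the given amplitude added at
#' `latency_ms` after every onset of that phoneme class, plus (if configured)
#' the standardized envelope convolved with a half-sine lag kernel peaking at
#' `lag_ms`, each weighted across channels; plus optional high-amplitude
#' artifact bursts whose ground-truth intervals are returned in the artifact
#' mask and the `truth` attribute. Amplitudes are in SD units of the noise.
#'
#' @param annot a [phoneme_annotation].
#' @param envelope raw [envelope_signal] from [generate_envelope] (may be
#'   `NULL` when no coupling is configured).
#' @param cfg a [synth_config].
#' @param seed integer seed.
#' @return an [eeg_recording]; ground truth in `attr(, "truth")`.
#' @export
generate_eeg <- function(annot, envelope = NULL, cfg = synth_config(), seed = 1) {
  n <- round(cfg$duration_s * cfg$rate_hz)
  channels <- montage_labels(cfg$n_channels)
  with_seed(seed, {
    data <- t(vapply(seq_len(cfg$n_channels),
                     function(i) shaped_noise(n, cfg$rate_hz),
                     numeric(n)))
    onsets <- round(annot$intervals$start_s * cfg$rate_hz) + 1L
    for (eff in cfg$class_effects) {
      w <- expand_channel_weights(eff, channels)
      lat <- round((eff$latency_ms %||% 0) / 1000 * cfg$rate_hz)
      bump <- (eff$amplitude %||% 1) *
        half_sine(max(1, round((eff$duration_ms %||% 60) / 1000 * cfg$rate_hz)))
      hits <- onsets[!is.na(annot$intervals$class) &
                       annot$intervals$class == eff$class]
      comp <- numeric(n)
      for (o in hits) {
        i0 <- o + lat
        i1 <- min(i0 + length(bump) - 1L, n)
        if (i0 <= n && i1 >= i0)
          comp[i0:i1] <- comp[i0:i1] + bump[seq_len(i1 - i0 + 1L)]
      }
      data <- data + outer(w, comp)
    }
    if (!is.null(cfg$envelope_coupling)) {
      if (is.null(envelope)) stop("envelope required for envelope coupling")
      cc <- cfg$envelope_coupling
      w <- expand_channel_weights(cc, channels)
      ev <- envelope$values[seq_len(min(n, length(envelope$values)))]
      ev <- (ev - mean(ev)) / stats::sd(ev)
      dur <- max(2L, round((cc$duration_ms %||% 60) / 1000 * cfg$rate_hz))
      kern <- half_sine(dur)
      lead <- round((dur + 1) / 2)   # peak index within the half-sine
      # causal FIR delays by (lead - 1); shift so the peak sits at lag_ms
      comp0 <- as.numeric(stats::filter(ev, kern, method = "convolution",
                                        sides = 1))
      comp0[is.na(comp0)] <- 0
      extra <- round((cc$lag_ms %||% 0) / 1000 * cfg$rate_hz) + 1L - lead
      comp <- numeric(n)
      src <- seq_len(n) - extra
      ok <- src >= 1 & src <= n
      comp[ok] <- comp0[src[ok]]
      s <- stats::sd(comp)
      if (s > 0) comp <- comp / s * (cc$amplitude %||% 1)
      data <- data + outer(w, comp)
    }
    mask <- rep(FALSE, n)
    art_intervals <- NULL
    if (!is.null(cfg$artifacts) && (cfg$artifacts$count %||% 0) > 0) {
      k <- cfg$artifacts$count
      dur_s <- cfg$artifacts$duration_s %||% 1
      amp <- cfg$artifacts$amplitude %||% 20
      starts <- sort(stats::runif(k, 0, max(0, cfg$duration_s - dur_s)))
      art_intervals <- cbind(start_s = starts, end_s = starts + dur_s)
      for (j in seq_len(k)) {
        i0 <- floor(starts[j] * cfg$rate_hz) + 1L
        i1 <- min(ceiling((starts[j] + dur_s) * cfg$rate_hz), n)
        burst <- amp * matrix(stats::rnorm(nrow(data) * (i1 - i0 + 1L)),
                              nrow(data))
        data[, i0:i1] <- data[, i0:i1] + burst
        mask[i0:i1] <- TRUE
      }
    }
    rec <- eeg_recording(data, cfg$rate_hz, channels, artifact_mask = mask)
    attr(rec, "truth") <- list(class_effects = cfg$class_effects,
                               envelope_coupling = cfg$envelope_coupling,
                               artifact_intervals = art_intervals)
    rec
  })
}

#' Generate a complete synthetic dataset
#'
#' Annotation, envelope + audio, and EEG from one configuration, with
#' sub-seeds derived from `seed` so the whole dataset is a pure function of
#' `(cfg, seed)`.
#'
#' @param cfg a [synth_config].
#' @param seed integer seed.
#' @return list with `annotation`, `envelope`, `audio`, `eeg`.
#' @export
generate_dataset <- function(cfg = synth_config(), seed = 1) {
  annot <- generate_annotation(cfg, seed)
  ea <- generate_envelope(annot, cfg, seed + 1000003L)
  eeg <- generate_eeg(annot, ea$envelope, cfg, seed + 2000003L)
  list(annotation = annot, envelope = ea$envelope, audio = ea$audio, eeg = eeg)
}
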