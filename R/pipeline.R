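#' Run the full analysis of one trial
#'
#' Orchestrates preprocessing and the enabled analyses for a single trial and
#' writes all result artifacts to `out_dir` as delimited tables with metadata
#' headers, plus a JSON log of the exclusion bookkeeping. Inputs may be given
#' as objects or file paths.
#'
#' @param eeg an [eeg_recording] or path readable by [read_eeg].
#' @param annot a [phoneme_annotation] or path (needed for the differential
#'   phoneme-class analysis).
#' @param audio an [audio_signal] / [envelope_signal] or WAV path (needed for
#'   envelope tracking; an `envelope_signal` is assumed raw and is band-passed
#'   and standardized here).
#' @param out_dir output directory (created if missing); `NULL` to skip
#'   writing.
#' @param analyses character subset of `c("dpr", "nse")`.
#' @param cfg a [preprocess_config].
#' @param artifact_intervals_s optional artifact intervals (matrix or path to
#'   a two-column seconds table).
#' @param scope FDR correction scope.
#' @param n_shuffles,seed permutation-null parameters (seed required for nse).
#' @param max_artifact_s trial-screening threshold, see [trial_screen].
#' @return list with elements `accepted`, `dpr`, `nse`, `log` (invisible).
#' @export
run_trial <- function(eeg, annot = NULL, audio = NULL, out_dir = NULL,
                      analyses = c("dpr", "nse"),
                      cfg = preprocess_config(),
                      artifact_intervals_s = NULL,
                      scope = c("within_channel", "global"),
                      n_shuffles = 10000, seed = NULL,
                      max_artifact_s = 15) {
  scope <- match.arg(scope)
  analyses <- match.arg(analyses, several.ok = TRUE)
  if ("nse" %in% analyses && is.null(seed))
    stop("a seed is required when the envelope-tracking analysis is enabled")
  if (is.character(eeg)) eeg <- read_eeg(eeg)
  if (is.character(annot)) annot <- read_phoneme_annotation(annot)
  if (is.character(artifact_intervals_s))
    artifact_intervals_s <- read_artifact_intervals(artifact_intervals_s)
  if (!is.null(artifact_intervals_s))
    eeg <- apply_artifact_mask(eeg, artifact_intervals_s)
  log <- list(rate_hz = eeg$rate_hz, n_channels = nrow(eeg$data),
              duration_s = duration_s(eeg),
              artifact_s = sum(eeg$artifact_mask) / eeg$rate_hz)
  accepted <- trial_screen(eeg, max_artifact_s)
  log$accepted <- accepted
  if (!accepted) {
    log$reason <- sprintf("more than %g s of artifact", max_artifact_s)
    if (!is.null(out_dir)) write_trial_log(log, out_dir)
    return(invisible(list(accepted = FALSE, dpr = NULL, nse = NULL, log = log)))
  }
  rec <- tryCatch(preprocess(eeg, cfg),
                  error = function(e) stop("preprocess: ", conditionMessage(e)))
  out <- list(accepted = TRUE, dpr = NULL, nse = NULL)
  if ("dpr" %in% analyses) {
    if (is.null(annot)) stop("dpr: a phoneme annotation is required")
    out$dpr <- tryCatch(dpr_analysis(rec, annot, cfg, scope = scope),
                        error = function(e) stop("dpr: ", conditionMessage(e)))
    dc <- out$dpr$drop_counts; rj <- out$dpr$rejection
    log$phonemes <- c(annotated = nrow(annot$intervals),
                      kept = unname(dc["kept"] - rj["rejected"]),
                      boundary_dropped = unname(dc["boundary"]),
                      artifact_excluded = unname(dc["artifact"]),
                      unmapped = unname(dc["unmapped"]),
                      amplitude_rejected = unname(rj["rejected"]))
    log$phoneme_exclusion_pct <- c(
      artifact = 100 * unname(dc["artifact"]) / max(1, nrow(annot$intervals)),
      amplitude = 100 * unname(rj["fraction"]))
  }
  if ("nse" %in% analyses) {
    if (is.null(audio)) stop("nse: an audio or envelope input is required")
    env <- if (is.character(audio)) compute_envelope(read_audio_wav(audio), cfg)
      else if (inherits(audio, "audio_signal")) compute_envelope(audio, cfg)
      else if (inherits(audio, "envelope_signal")) preprocess_envelope(audio, cfg)
      else stop("nse: unsupported audio input")
    out$nse <- tryCatch(
      nse_analysis(rec, env, n_shuffles = n_shuffles, seed = seed, scope = scope),
      error = function(e) stop("nse: ", conditionMessage(e)))
    log$nse <- c(segments_used = out$nse$segments_used,
                 segments_excluded = out$nse$excluded,
                 n_shuffles = n_shuffles)
  }
  out$log <- log
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!is.null(out$dpr)) {
      rate <- eeg$rate_hz
      for (nm in names(out$dpr$pair_results)) {
        pr <- out$dpr$pair_results[[nm]]
        m <- frequency_map(unclass(pr$mask) * 1,
                           points_ms = (seq_len(ncol(pr$mask)) - 1) * 1000 / rate,
                           channels = pr$channels, axis = "time", level = "pair",
                           chance_level = pr$alpha / ncol(pr$mask))
        write_map(m, file.path(out_dir, sprintf("dpr_pair_%s.tsv", nm)))
      }
      write_map(out$dpr$trial_map, file.path(out_dir, "dpr_trial_map.tsv"))
      write_profile(temporal_profile(out$dpr$trial_map),
                    file.path(out_dir, "dpr_temporal_profile.tsv"), "time_ms")
      write_profile(spatial_profile(out$dpr$trial_map),
                    file.path(out_dir, "dpr_spatial_profile.tsv"), "channel")
      utils::write.table(
        data.frame(channel = rownames(out$dpr$trial_map),
                   subinterval_summary(out$dpr$trial_map), check.names = FALSE),
        file.path(out_dir, "dpr_subintervals.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
    }
    if (!is.null(out$nse)) {
      write_map(out$nse$map, file.path(out_dir, "nse_mask_map.tsv"))
      stat <- out$nse$statistic
      utils::write.table(
        data.frame(channel = rownames(stat),
                   format(unclass(stat), digits = 17, trim = TRUE),
                   check.names = FALSE),
        file.path(out_dir, "nse_statistic.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
      utils::write.table(
        data.frame(channel = rownames(out$nse$p_values),
                   format(out$nse$p_values, digits = 17, trim = TRUE)),
        file.path(out_dir, "nse_pvalues.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
    }
    write_trial_log(log, out_dir)
  }
  invisible(out)
}

write_profile <- function(prof, path, key) {
  k <- if (key == "time_ms") attr(prof, "points_ms") else names(prof)
  if (is.null(k)) k <- seq_along(prof) - 1
  utils::write.table(
    data.frame(k = k,
               frequency = sprintf("%.17g", as.numeric(prof)),
               chance_level = sprintf("%.17g", attr(prof, "chance_level"))),
    path, sep = "\t", quote = FALSE, row.names = FALSE,
    col.names = c(key, "frequency", "chance_level"))
}

write_trial_log <- function(log, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(log, file.path(out_dir, "trial_log.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Null calibration of the differential phoneme-class response stage
#'
#' Simulates pure-noise data with no class effect - independent standard
#' normal epochs for the five classes, with per-class epoch counts matching
#' the stimulus phoneme distribution - and runs the pairwise rank-sum +
#' within-channel BH-FDR stage. Under this null the expected number of
#' significant ("false-positive") timepoints is about 0.05 per channel, i.e.
#' an overall significant-cell frequency of about 0.0004 for 125 timepoints.
#'
#' @param n_replicates number of replicate noise trials (>= 10).
#' @param seed integer seed.
#' @param n_channels,n_timepoints dimensions of each epoch.
#' @param class_counts named per-class epoch counts; the default is the
#'   narrative stimulus distribution.
#' @param alpha,scope FDR parameters.
#' @return list with `fp_per_channel_mean` (mean significant points per
#'   channel-map), `fp_per_channel_se`, `frequency` (overall significant-cell
#'   fraction), `frequency_se`, `n_channel_maps`, `n_cells`,
#'   `per_map_counts`.
#' @export
calibrate_dpr_null <- function(n_replicates = 20, seed = 1, n_channels = 8,
                               n_timepoints = 125,
                               class_counts = c(A = 163, F = 264, N = 147,
                                                P = 355, V = 617),
                               alpha = 0.05,
                               scope = c("within_channel", "global")) {
  scope <- match.arg(scope)
  if (n_replicates < 10) stop("use at least 10 replicates")
  pairs <- utils::combn(PHONEME_CLASSES, 2)
  counts <- with_seed(seed, {
    unlist(lapply(seq_len(n_replicates), function(r) {
      eps <- lapply(PHONEME_CLASSES, function(cl)
        array(stats::rnorm(class_counts[[cl]] * n_channels * n_timepoints),
              dim = c(class_counts[[cl]], n_channels, n_timepoints)))
      names(eps) <- PHONEME_CLASSES
      unlist(lapply(seq_len(ncol(pairs)), function(k) {
        p <- ranksum_pvalues(eps[[pairs[1, k]]], eps[[pairs[2, k]]])
        rowSums(bh_fdr_mask(p, alpha, scope))
      }))
    }))
  })
  n_maps <- length(counts)
  list(fp_per_channel_mean = mean(counts),
       fp_per_channel_se = stats::sd(counts) / sqrt(n_maps),
       frequency = mean(counts) / n_timepoints,
       frequency_se = stats::sd(counts) / sqrt(n_maps) / n_timepoints,
       n_channel_maps = n_maps,
       n_cells = n_maps * n_timepoints,
       per_map_counts = counts)
}

#' Null calibration of the envelope-tracking stage
#'
#' Simulates noise-only EEG (no envelope coupling) together with an unrelated
#' synthetic envelope, runs segmentation, cross-correlation, the shuffle null
#' and within-channel FDR, and reports the significant-cell frequency, which
#' should sit near the chance level of about 0.0004.
#'
#' @param n_replicates number of replicate noise trials (>= 10).
#' @param seed integer seed.
#' @param n_channels,duration_s size of each simulated trial.
#' @param n_shuffles permutations per replicate.
#' @param alpha,scope FDR parameters.
#' @return list with `frequency`, `frequency_se`, `per_replicate_frequency`,
#'   `n_cells`, `n_replicates`.
#' @export
calibrate_nse_null <- function(n_replicates = 20, seed = 1, n_channels = 8,
                               duration_s = 148, n_shuffles = 10000,
                               alpha = 0.05,
                               scope = c("within_channel", "global")) {
  scope <- match.arg(scope)
  if (n_replicates < 10) stop("use at least 10 replicates")
  cfg <- synth_config(duration_s = duration_s, n_channels = n_channels)
  pcfg <- preprocess_config(rate_hz = cfg$rate_hz)
  freqs <- numeric(n_replicates)
  n_cells <- NA_integer_
  for (r in seq_len(n_replicates)) {
    s <- seed + 7919L * r
    annot <- generate_annotation(cfg, s)
    env <- generate_envelope(annot, cfg, s + 1L)$envelope
    eeg <- generate_eeg(annot, NULL, cfg, s + 2L)  # no coupling configured
    rec <- preprocess(eeg, pcfg)
    res <- nse_analysis(rec, preprocess_envelope(env, pcfg),
                        n_shuffles = n_shuffles, seed = s + 3L,
                        alpha = alpha, scope = scope)
    freqs[r] <- mean(res$mask)
    n_cells <- length(res$mask)
  }
  list(frequency = mean(freqs),
       frequency_se = stats::sd(freqs) / sqrt(n_replicates),
       per_replicate_frequency = freqs,
       n_cells = n_cells, n_replicates = n_replicates)
}

#' Null-calibration experiment for both pipelines
#'
#' Convenience wrapper running [calibrate_dpr_null] and [calibrate_nse_null]
#' and returning their reports side by side.
#'
#' @param n_replicates replicates per pipeline (>= 10).
#' @param seed integer seed.
#' @param analyses subset of `c("dpr", "nse")`.
#' @param ... passed on to the individual calibrators.
#' @return list with elements `dpr` and/or `nse`.
#' @export
run_null_calibration <- function(n_replicates = 20, seed = 1,
                                 analyses = c("dpr", "nse"), ...) {
  analyses <- match.arg(analyses, several.ok = TRUE)
  out <- list()
  if ("dpr" %in% analyses)
    out$dpr <- calibrate_dpr_null(n_replicates, seed, ...)
  if ("nse" %in% analyses)
    out$nse <- calibrate_nse_null(n_replicates, seed, ...)
  out
}

#' Group-level maps by behavioural class and CF/LP category
#'
#' Averages subject maps (already trial-averaged) into group maps for each
#' behavioural class present and for the command-following /
#' language-processing categories, with equal subject weight, and reports the
#' subject and visit counts (n_s, n_v) per group.
#'
#' @param metadata subject/visit metadata (data.frame or TSV path).
#' @param subject_maps named list (subject id -> subject-level
#'   [frequency_map]).
#' @return list with `groups` (named list of group [frequency_map]s),
#'   `counts` (n_s/n_v per group), `categories` (per-subject table).
#' @export
run_group <- function(metadata, subject_maps) {
  if (is.character(metadata)) metadata <- read_subject_metadata(metadata)
  metadata <- validate_subject_metadata(metadata)
  ids <- names(subject_maps)
  missing <- setdiff(ids, metadata$subject_id)
  if (length(missing))
    stop("subjects missing from metadata: ", paste(missing, collapse = ", "))
  cats <- categorize_subjects(metadata)
  cats <- cats[cats$subject_id %in% ids, , drop = FALSE]
  group_members <- list()
  for (cl in intersect(BEHAVIOURAL_CLASSES, metadata$behavioural_class)) {
    m <- unique(metadata$subject_id[metadata$behavioural_class == cl])
    group_members[[cl]] <- intersect(ids, m)
  }
  for (cat in c("CF+", "LP+", "LP-")) {
    m <- cats$subject_id[!cats$is_hc &
                           (cats$cf_status == cat | cats$lp_status == cat)]
    group_members[[cat]] <- intersect(ids, m)
  }
  group_members <- Filter(length, group_members)
  groups <- lapply(group_members, function(m) combine_subjects(subject_maps[m]))
  counts <- data.frame(
    group = names(group_members),
    n_s = vapply(group_members, length, 1L),
    n_v = vapply(names(group_members), function(g) {
      m <- group_members[[g]]
      if (g %in% BEHAVIOURAL_CLASSES)
        sum(metadata$behavioural_class == g & metadata$subject_id %in% m)
      else sum(metadata$subject_id %in% m)
    }, 1L),
    row.names = NULL)
  list(groups = groups, counts = counts, categories = cats)
}
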