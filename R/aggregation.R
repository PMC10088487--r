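check_same_axes <- function(maps) {
  ref_pts <- attr(maps[[1]], "points_ms")
  ref_ch <- rownames(maps[[1]])
  for (m in maps[-1]) {
    if (!isTRUE(all.equal(attr(m, "points_ms"), ref_pts)) ||
        !identical(rownames(m), ref_ch) ||
        !identical(attr(m, "axis"), attr(maps[[1]], "axis")))
      stop("frequency maps have mismatched axes")
  }
}

#' Combine trial maps into a subject map
#'
#' Cellwise arithmetic mean of the trial-level frequency maps of one subject.
#'
#' @param trial_maps list of [frequency_map]s sharing axes.
#' @return a subject-level [frequency_map].
#' @export
combine_trials <- function(trial_maps) {
  if (!length(trial_maps)) stop("no trial maps supplied")
  check_same_axes(trial_maps)
  vals <- Reduce(`+`, lapply(trial_maps, unclass)) / length(trial_maps)
  frequency_map(vals, attr(trial_maps[[1]], "points_ms"),
                rownames(trial_maps[[1]]), axis = attr(trial_maps[[1]], "axis"),
                level = "subject",
                chance_level = attr(trial_maps[[1]], "chance_level"),
                n_v = length(trial_maps))
}

#' Combine subject maps into a group map
#'
#' Cellwise mean across subjects with equal subject weight: each input map
#' must already be trial-averaged, so a subject's weight does not depend on
#' how many trials they contributed. Duplicate subject ids are an error.
#'
#' @param subject_maps named list (by subject id) of subject-level
#'   [frequency_map]s.
#' @return a group-level [frequency_map] with `n_s` (subjects) and `n_v`
#'   (total visits, where recorded) attributes.
#' @export
combine_subjects <- function(subject_maps) {
  if (!length(subject_maps)) stop("no subject maps supplied")
  ids <- names(subject_maps)
  if (is.null(ids) || anyDuplicated(ids) || any(!nzchar(ids)))
    stop("subject_maps must be uniquely named by subject id")
  check_same_axes(subject_maps)
  vals <- Reduce(`+`, lapply(subject_maps, unclass)) / length(subject_maps)
  nv <- vapply(subject_maps, function(m) attr(m, "n_v") %||% NA_integer_,
               integer(1))
  frequency_map(vals, attr(subject_maps[[1]], "points_ms"),
                rownames(subject_maps[[1]]),
                axis = attr(subject_maps[[1]], "axis"), level = "group",
                chance_level = attr(subject_maps[[1]], "chance_level"),
                n_s = length(subject_maps),
                n_v = if (anyNA(nv)) NA_integer_ else sum(nv))
}

#' Categorize one subject by the command-following / language-processing tree
#'
#' A patient subject is CF+ if any visit shows command-following on the EEG
#' or fMRI motor-imagery assay; LP+ if CF+ or if any visit's behavioural
#' class is MCS+ or eMCS (behavioural command-following); otherwise LP-.
#' "not done" contributes no evidence either way. Healthy controls are
#' outside the tree and get `NA` statuses.
#'
#' @param visits data.frame of the subject's visit rows (metadata schema,
#'   see [read_subject_metadata]).
#' @return list with `subject_id`, `cf_status` ("CF+"/"CF-"), `lp_status`
#'   ("LP+"/"LP-"), `basis` (character vector of evidence sources among
#'   "behavioural", "EEG", "fMRI"), `is_hc`, and `per_visit` (data.frame with
#'   per-visit `cf` and `lp` logicals).
#' @export
categorize_subject <- function(visits) {
  visits <- validate_subject_metadata(visits)
  if (nrow(visits) < 1) stop("need at least one visit row")
  if (length(unique(visits$subject_id)) != 1)
    stop("visits must belong to a single subject")
  id <- visits$subject_id[1]
  if (any(visits$behavioural_class == "HC")) {
    return(list(subject_id = id, cf_status = NA_character_,
                lp_status = NA_character_, basis = character(0),
                is_hc = TRUE,
                per_visit = data.frame(visit_index = visits$visit_index,
                                       cf = NA, lp = NA)))
  }
  v_cf <- visits$eeg_cf == "pos" | visits$fmri_cf == "pos"
  v_beh <- visits$behavioural_class %in% c("MCS+", "eMCS")
  v_lp <- v_cf | v_beh
  cf <- any(v_cf); lp <- any(v_lp)
  basis <- c(if (any(v_beh)) "behavioural",
             if (any(visits$eeg_cf == "pos")) "EEG",
             if (any(visits$fmri_cf == "pos")) "fMRI")
  list(subject_id = id,
       cf_status = if (cf) "CF+" else "CF-",
       lp_status = if (lp) "LP+" else "LP-",
       basis = basis %||% character(0), is_hc = FALSE,
       per_visit = data.frame(visit_index = visits$visit_index,
                              cf = v_cf, lp = v_lp))
}

#' Categorize every subject in a metadata table
#'
#' @param metadata metadata data.frame (see [read_subject_metadata]).
#' @return data.frame with one row per subject: `subject_id`, `is_hc`,
#'   `cf_status`, `lp_status`, `basis` (comma-separated), `n_visits`.
#' @export
categorize_subjects <- function(metadata) {
  metadata <- validate_subject_metadata(metadata)
  ids <- unique(metadata$subject_id)
  rows <- lapply(ids, function(id)
    categorize_subject(metadata[metadata$subject_id == id, , drop = FALSE]))
  data.frame(subject_id = ids,
             is_hc = vapply(rows, `[[`, TRUE, "is_hc"),
             cf_status = vapply(rows, `[[`, "", "cf_status"),
             lp_status = vapply(rows, `[[`, "", "lp_status"),
             basis = vapply(rows, function(r) paste(r$basis, collapse = ","), ""),
             n_visits = vapply(rows, function(r) nrow(r$per_visit), 1L))
}

#' Tally CF/LP categories and behavioural classes
#'
#' Subject-level tallies use any-visit evidence (a subject is counted once);
#' visit-level tallies count each visit by its own evidence and behavioural
#' class. Healthy controls are excluded from the CF/LP tallies.
#'
#' @param metadata metadata data.frame (see [read_subject_metadata]).
#' @return list with `subjects` (named counts: n_ps, n_hc, `CF+`, `CF-`,
#'   `LP+`, `LP-`), `visits` (same categories at visit level), and
#'   `behavioural` (data.frame of subject-ever and visit counts per class).
#' @export
count_categories <- function(metadata) {
  metadata <- validate_subject_metadata(metadata)
  cats <- categorize_subjects(metadata)
  ps <- cats[!cats$is_hc, , drop = FALSE]
  ps_meta <- metadata[metadata$behavioural_class != "HC", , drop = FALSE]
  v_cf <- ps_meta$eeg_cf == "pos" | ps_meta$fmri_cf == "pos"
  v_lp <- v_cf | ps_meta$behavioural_class %in% c("MCS+", "eMCS")
  beh_levels <- BEHAVIOURAL_CLASSES
  beh <- data.frame(
    class = beh_levels,
    subjects_ever = vapply(beh_levels, function(cl)
      length(unique(metadata$subject_id[metadata$behavioural_class == cl])), 1L),
    visits = vapply(beh_levels, function(cl)
      sum(metadata$behavioural_class == cl), 1L),
    row.names = NULL)
  list(
    subjects = c(n_ps = nrow(ps), n_hc = sum(cats$is_hc),
                 "CF+" = sum(ps$cf_status == "CF+"),
                 "CF-" = sum(ps$cf_status == "CF-"),
                 "LP+" = sum(ps$lp_status == "LP+"),
                 "LP-" = sum(ps$lp_status == "LP-")),
    visits = c(n_ps = nrow(ps_meta),
               n_hc = sum(metadata$behavioural_class == "HC"),
               "CF+" = sum(v_cf), "CF-" = sum(!v_cf),
               "LP+" = sum(v_lp), "LP-" = sum(!v_lp)),
    behavioural = beh)
}
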