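BEHAVIOURAL_CLASSES <- c("VS/UWS", "MCS-", "MCS+", "eMCS", "HC")
CF_LEVELS <- c("pos", "neg", "not_done")

#' Read a subject/visit metadata table
#'
#' Tab-separated table with columns exactly `subject_id`, `visit_index`,
#' `behavioural_class`, `eeg_cf`, `fmri_cf`. Behavioural classes are the
#' bedside disorders-of-consciousness categories `VS/UWS`, `MCS-`, `MCS+`,
#' `eMCS` plus `HC` for healthy controls; the command-following flags take
#' values `pos`, `neg`, `not_done`. Healthy-control rows must have both
#' command-following flags `not_done` (controls are not tested).
#'
#' @param path TSV file.
#' @return data.frame with validated, typed columns.
#' @export
read_subject_metadata <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("subject_id", "visit_index", "behavioural_class", "eeg_cf", "fmri_cf")
  if (!identical(intersect(req, names(tab)), req))
    stop("metadata table must have columns: ", paste(req, collapse = ", "))
  tab <- tab[req]
  validate_subject_metadata(tab)
}

validate_subject_metadata <- function(tab) {
  tab$subject_id <- as.character(tab$subject_id)
  tab$visit_index <- as.integer(tab$visit_index)
  if (any(is.na(tab$visit_index)) || any(tab$visit_index < 1))
    stop("visit_index must be an integer >= 1")
  bad <- setdiff(unique(tab$behavioural_class), BEHAVIOURAL_CLASSES)
  if (length(bad))
    stop("unknown behavioural class: ", paste(bad, collapse = ", "))
  for (col in c("eeg_cf", "fmri_cf")) {
    bad <- setdiff(unique(tab[[col]]), CF_LEVELS)
    if (length(bad))
      stop("unknown ", col, " value: ", paste(bad, collapse = ", "))
  }
  hc <- tab$behavioural_class == "HC"
  if (any(hc & (tab$eeg_cf != "not_done" | tab$fmri_cf != "not_done")))
    stop("HC rows must have eeg_cf = fmri_cf = not_done")
  if (anyDuplicated(tab[c("subject_id", "visit_index")]))
    stop("duplicate (subject_id, visit_index) rows")
  tab
}
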