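PHONEME_CLASSES <- c("A", "F", "N", "P", "V")

#' Default ARPAbet phoneme-to-class map
#'
#' Maps ARPAbet phoneme labels to the five manner-of-articulation classes:
#' approximants (A), fricatives (F), nasals (N), plosives (P) and vowels (V).
#' The two affricates (CH, JH) straddle the plosive/fricative distinction and
#' are deliberately left out of the default map; pass a custom map to assign
#' them.
#'
#' @return named character vector, `names` = phoneme labels, values = class.
#' @export
default_class_map <- function() {
  c(
    # vowels (incl. diphthongs and r-coloured)
    AA = "V", AE = "V", AH = "V", AO = "V", AW = "V", AY = "V",
    EH = "V", ER = "V", EY = "V", IH = "V", IY = "V",
    OW = "V", OY = "V", UH = "V", UW = "V",
    # plosives
    B = "P", D = "P", G = "P", K = "P", P = "P", T = "P",
    # fricatives
    DH = "F", F = "F", HH = "F", S = "F", SH = "F", TH = "F",
    V = "F", Z = "F", ZH = "F",
    # nasals
    M = "N", N = "N", NG = "N",
    # approximants (liquids and glides)
    L = "A", R = "A", W = "A", Y = "A"
  )
}

#' Read a phoneme-to-class map
#'
#' Tab-separated table with columns `phoneme_label` and `class`; classes must
#' be in `{A, F, N, P, V}`.
#'
#' @param path TSV file.
#' @return named character vector as in [default_class_map].
#' @export
read_class_map <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("phoneme_label", "class") %in% names(tab)))
    stop("class map must have columns phoneme_label, class")
  bad <- setdiff(unique(tab$class), PHONEME_CLASSES)
  if (length(bad)) stop("unknown phoneme classes: ", paste(bad, collapse = ", "))
  stats::setNames(tab$class, tab$phoneme_label)
}

#' Timed phoneme annotation
#'
#' Phoneme intervals (seconds, half-open `[start_s, end_s)`) with their class
#' assignment under a phoneme-to-class map. Intervals are sorted by onset;
#' unsorted input is sorted with a warning. Overlapping and contiguous
#' intervals are permitted. Labels absent from the map get class `NA` and are
#' collected in the `unmapped` element; downstream epoching skips them.
#'
#' @param intervals data.frame with columns `start_s`, `end_s`,
#'   `phoneme_label`.
#' @param class_map named character vector (see [default_class_map]).
#' @return object of class `phoneme_annotation` with elements `intervals`
#'   (columns `start_s`, `end_s`, `phoneme_label`, `class`), `class_map`,
#'   `unmapped`.
#' @export
phoneme_annotation <- function(intervals, class_map = default_class_map()) {
  req <- c("start_s", "end_s", "phoneme_label")
  if (!all(req %in% names(intervals)))
    stop("intervals must have columns ", paste(req, collapse = ", "))
  intervals <- intervals[req]
  intervals$phoneme_label <- as.character(intervals$phoneme_label)
  if (any(intervals$start_s < 0)) stop("negative start_s in annotation")
  if (any(intervals$end_s <= intervals$start_s))
    stop("annotation rows with end_s <= start_s")
  if (is.unsorted(intervals$start_s)) {
    warning("annotation intervals were not sorted by start time; sorting")
    intervals <- intervals[order(intervals$start_s, intervals$end_s), ]
  }
  rownames(intervals) <- NULL
  intervals$class <- unname(class_map[intervals$phoneme_label])
  unmapped <- sort(unique(intervals$phoneme_label[is.na(intervals$class)]))
  structure(list(intervals = intervals, class_map = class_map,
                 unmapped = unmapped),
            class = "phoneme_annotation")
}

#' @export
print.phoneme_annotation <- function(x, ...) {
  cat(sprintf("<phoneme_annotation> %d intervals over %.2f s; classes: %s\n",
              nrow(x$intervals), max(x$intervals$end_s),
              paste(sprintf("%s=%d", PHONEME_CLASSES,
                            tabulate(factor(x$intervals$class, PHONEME_CLASSES),
                                     length(PHONEME_CLASSES))),
                    collapse = " ")))
  if (length(x$unmapped))
    cat("  unmapped labels:", paste(x$unmapped, collapse = ", "), "\n")
  invisible(x)
}

#' Read a phoneme annotation
#'
#' Accepts either a tab-separated table with columns `start_s`, `end_s`,
#' `phoneme_label` (forced-aligner style output) or a Praat TextGrid whose
#' first interval tier holds the phoneme labels (empty-text intervals are
#' treated as silence and skipped).
#'
#' @param path annotation file.
#' @param class_map named phoneme-to-class vector.
#' @param format `"auto"` (by extension/content), `"tsv"` or `"textgrid"`.
#' @return a [phoneme_annotation].
#' @export
read_phoneme_annotation <- function(path, class_map = default_class_map(),
                                    format = c("auto", "tsv", "textgrid")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.textgrid$", path, ignore.case = TRUE)) "textgrid"
    else if (grepl("ooTextFile", paste(readLines(path, n = 2), collapse = " ")))
      "textgrid" else "tsv"
  }
  intervals <- if (format == "textgrid") parse_textgrid(path) else {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    if (!all(c("start_s", "end_s", "phoneme_label") %in% names(tab)))
      stop("annotation table must have columns start_s, end_s, phoneme_label")
    tab
  }
  phoneme_annotation(intervals, class_map)
}

#' Write a phoneme annotation as a TSV table
#'
#' @param annot a [phoneme_annotation].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_phoneme_annotation <- function(annot, path) {
  utils::write.table(
    data.frame(start_s = sprintf("%.6f", annot$intervals$start_s),
               end_s = sprintf("%.6f", annot$intervals$end_s),
               phoneme_label = annot$intervals$phoneme_label),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Minimal Praat TextGrid parser: first interval tier, long text format.
parse_textgrid <- function(path) {
  lines <- readLines(path, warn = FALSE)
  num <- function(l) as.numeric(sub(".*=\\s*", "", l))
  txt <- function(l) gsub("^\\s*text\\s*=\\s*\"|\"\\s*$", "", l)
  xmin <- NULL; xmax <- NULL; lab <- NULL
  in_tier <- FALSE
  for (l in lines) {
    if (grepl("class\\s*=\\s*\"IntervalTier\"", l)) {
      if (in_tier) break  # only the first interval tier
      in_tier <- TRUE
    }
    if (!in_tier) next
    if (grepl("^\\s*xmin\\s*=", l)) xmin <- c(xmin, num(l))
    if (grepl("^\\s*xmax\\s*=", l)) xmax <- c(xmax, num(l))
    if (grepl("^\\s*text\\s*=", l)) lab <- c(lab, txt(l))
  }
  if (is.null(lab)) stop("no interval tier found in TextGrid: ", path)
  # first xmin/xmax pair belongs to the tier itself
  n <- length(lab)
  ints <- data.frame(start_s = utils::tail(xmin, n),
                     end_s = utils::tail(xmax, n),
                     phoneme_label = trimws(lab),
                     stringsAsFactors = FALSE)
  # drop forced-aligner silence / pause markers
  ints[!ints$phoneme_label %in% c("", "sp", "sil", "SIL"), ]
}
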