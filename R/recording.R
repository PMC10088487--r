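#' Multichannel EEG recording
#'
#' Container for a continuous multichannel EEG record: a channels x samples
#' matrix, the sampling rate, 10-20-system channel labels, the reference
#' electrode, and a per-sample logical artifact mask (`TRUE` = contaminated).
#' Sample indices are 1-based; time stamps are in seconds; the sample at
#' index `i` covers time `[(i-1)/rate_hz, i/rate_hz)`.
#'
#' @param data numeric matrix, channels in rows, samples in columns.
#' @param rate_hz sampling rate in samples per second.
#' @param channel_labels character vector, one label per row of `data`.
#' @param reference_label label of the reference electrode (default "FCz").
#' @param artifact_mask logical vector of length `ncol(data)`; defaults to
#'   all `FALSE`.
#' @return an object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, rate_hz, channel_labels = rownames(data),
                          reference_label = "FCz", artifact_mask = NULL) {
  data <- as.matrix(data)
  if (is.null(channel_labels))
    channel_labels <- paste0("ch", seq_len(nrow(data)))
  channel_labels <- as.character(channel_labels)
  if (!is.numeric(rate_hz) || length(rate_hz) != 1 || rate_hz <= 0)
    stop("rate_hz must be a single positive number")
  if (length(channel_labels) != nrow(data))
    stop("channel_labels length (", length(channel_labels),
         ") does not match channel count (", nrow(data), ")")
  if (anyDuplicated(channel_labels))
    stop("duplicate channel labels: ",
         paste(unique(channel_labels[duplicated(channel_labels)]), collapse = ", "))
  if (is.null(artifact_mask)) artifact_mask <- rep(FALSE, ncol(data))
  if (length(artifact_mask) != ncol(data))
    stop("artifact_mask length does not match sample count")
  rownames(data) <- channel_labels
  structure(list(channel_labels = channel_labels,
                 rate_hz = rate_hz,
                 data = data,
                 reference_label = reference_label,
                 artifact_mask = as.logical(artifact_mask)),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s), ref %s\n",
              nrow(x$data), ncol(x$data), x$rate_hz,
              ncol(x$data) / x$rate_hz, x$reference_label))
  cat(sprintf("  channels: %s\n", paste(utils::head(x$channel_labels, 10), collapse = " ")))
  cat(sprintf("  artifact samples: %d (%.2f s)\n",
              sum(x$artifact_mask), sum(x$artifact_mask) / x$rate_hz))
  invisible(x)
}

n_samples <- function(rec) ncol(rec$data)
duration_s <- function(rec) ncol(rec$data) / rec$rate_hz

#' Read an EEG recording
#'
#' Reads either an EDF file (16-bit European Data Format) or the package's
#' plain delimited matrix dialect: a text file with header lines
#' `# rate_hz: <r>`, `# reference: <label>` and `# channels: <tab-separated
#' labels>` followed by one whitespace-delimited row of samples per channel.
#' The artifact mask of a freshly read recording is all `FALSE`.
#'
#' @param path file to read.
#' @param format one of `"auto"` (by extension), `"edf"`, `"matrix"`.
#' @return an [eeg_recording].
#' @export
read_eeg <- function(path, format = c("auto", "edf", "matrix")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "matrix"
  if (format == "edf") read_eeg_edf(path) else read_eeg_matrix(path)
}

#' Write an EEG recording
#'
#' Inverse of [read_eeg]. EDF output quantizes each channel to 16 bits over
#' its own physical range; the delimited format is written at full double
#' precision. The artifact mask is not stored in either format.
#'
#' @param rec an [eeg_recording].
#' @param path output file.
#' @param format `"auto"` (by extension), `"edf"` or `"matrix"`.
#' @return `path`, invisibly.
#' @export
write_eeg <- function(rec, path, format = c("auto", "edf", "matrix")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "matrix"
  if (format == "edf") write_eeg_edf(rec, path) else write_eeg_matrix(rec, path)
  invisible(path)
}

read_eeg_matrix <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get_field <- function(key) {
    m <- grep(paste0("^#\\s*", key, ":"), hdr, value = TRUE)
    if (length(m) == 0) return(NULL)
    sub(paste0("^#\\s*", key, ":\\s*"), "", m[1])
  }
  rate <- get_field("rate_hz")
  if (is.null(rate)) stop("delimited EEG file lacks '# rate_hz:' header: ", path)
  labels <- get_field("channels")
  if (is.null(labels)) stop("delimited EEG file lacks '# channels:' header: ", path)
  labels <- strsplit(labels, "\t", fixed = TRUE)[[1]]
  ref <- get_field("reference") %||% "FCz"
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(trimws(body))]
  if (length(body) != length(labels))
    stop("declared channel count (", length(labels),
         ") does not match data rows (", length(body), ")")
  rows <- lapply(body, function(l) as.numeric(strsplit(trimws(l), "[\t ]+")[[1]]))
  ns <- unique(lengths(rows))
  if (length(ns) != 1) stop("ragged sample rows in ", path)
  data <- do.call(rbind, rows)
  eeg_recording(data, as.numeric(rate), labels, ref)
}

write_eeg_matrix <- function(rec, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# rate_hz: %.10g", rec$rate_hz),
               sprintf("# reference: %s", rec$reference_label),
               paste0("# channels: ", paste(rec$channel_labels, collapse = "\t"))),
             con)
  utils::write.table(format(rec$data, digits = 17, trim = TRUE, scientific = TRUE),
                     con, sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
}

# --- minimal EDF (European Data Format, 16-bit) support -----------------
# Continuous recordings only; every signal shares one sampling rate. The
# whole record is stored as a single EDF data record whose duration is the
# full record length, which keeps the sample count exact for any duration.

edf_pad <- function(s, width) {
  s <- as.character(s)
  if (nchar(s) > width) s <- substr(s, 1, width)
  formatC(s, width = -width, flag = " ")
}

edf_num <- function(x, width = 8) {
  s <- formatC(x, format = "g", digits = 7, width = 1)
  while (nchar(s) > width) {
    s <- formatC(x, format = "g", digits = max(1, 7 - (nchar(s) - width)), width = 1)
    x <- as.numeric(s)
  }
  edf_pad(s, width)
}

write_eeg_edf <- function(rec, path) {
  ns <- length(rec$channel_labels)
  nsamp <- ncol(rec$data)
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s) writeChar(s, con, nchar(s), eos = NULL)
  wr(edf_pad("0", 8))
  wr(edf_pad("X X X X", 80))
  wr(edf_pad(paste0("Startdate 01-JAN-2000 X X ref:", rec$reference_label), 80))
  wr(edf_pad("01.01.00", 8)); wr(edf_pad("00.00.00", 8))
  wr(edf_num(256 * (1 + ns)))
  wr(edf_pad("", 44))
  wr(edf_num(1))                       # one data record
  wr(edf_num(nsamp / rec$rate_hz))     # record duration (s)
  wr(edf_pad(as.character(ns), 4))
  pmin_ <- apply(rec$data, 1, min); pmax_ <- apply(rec$data, 1, max)
  flat <- pmax_ - pmin_ <= 0
  pmin_[flat] <- pmin_[flat] - 1; pmax_[flat] <- pmax_[flat] + 1
  for (lab in rec$channel_labels) wr(edf_pad(lab, 16))
  for (i in seq_len(ns)) wr(edf_pad("AgAgCl electrode", 80))
  for (i in seq_len(ns)) wr(edf_pad("uV", 8))
  for (i in seq_len(ns)) wr(edf_num(pmin_[i]))
  for (i in seq_len(ns)) wr(edf_num(pmax_[i]))
  for (i in seq_len(ns)) wr(edf_num(-32767))
  for (i in seq_len(ns)) wr(edf_num(32767))
  for (i in seq_len(ns)) wr(edf_pad("", 80))
  for (i in seq_len(ns)) wr(edf_num(nsamp))
  for (i in seq_len(ns)) wr(edf_pad("", 32))
  for (i in seq_len(ns)) {
    # re-read the 8-char fields so the stored scaling matches exactly
    lo <- as.numeric(edf_num(pmin_[i])); hi <- as.numeric(edf_num(pmax_[i]))
    dig <- round((rec$data[i, ] - lo) / (hi - lo) * (32767 - (-32767)) + (-32767))
    dig <- pmin(pmax(dig, -32767), 32767)
    writeBin(as.integer(dig), con, size = 2, endian = "little")
  }
}

read_eeg_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) readChar(con, n, useBytes = TRUE)
  rd(8)                                 # version
  rd(80)                                # patient
  rec_field <- rd(80)
  rd(8); rd(8)                          # date, time
  rd(8)                                 # header bytes
  rd(44)
  n_records <- as.numeric(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1) stop("unreadable EDF header (signal count): ", path)
  labels <- trimws(vapply(seq_len(ns), function(i) rd(16), ""))
  if (anyDuplicated(labels))
    stop("duplicate channel labels in EDF file: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  for (i in seq_len(ns)) rd(80)         # transducer
  for (i in seq_len(ns)) rd(8)          # physical dim
  pmin_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  pmax_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmin_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmax_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(80)         # prefiltering
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(32)
  if (any(is.na(spr)) || any(spr < 1)) stop("unreadable EDF header (samples/record)")
  if (is.na(rec_dur) || rec_dur <= 0) stop("EDF file lacks a usable record duration")
  data <- matrix(0, ns, spr[1] * n_records)
  if (length(unique(spr)) != 1)
    stop("EDF signals with differing sampling rates are not supported")
  for (r in seq_len(n_records)) {
    for (i in seq_len(ns)) {
      dig <- readBin(con, "integer", n = spr[i], size = 2, endian = "little")
      phys <- pmin_[i] + (dig - dmin_[i]) * (pmax_[i] - pmin_[i]) / (dmax_[i] - dmin_[i])
      data[i, (r - 1) * spr[i] + seq_len(spr[i])] <- phys
    }
  }
  rate <- spr[1] / rec_dur
  ref <- if (grepl("ref:", rec_field)) sub(".*ref:(\\S+).*", "\\1", rec_field) else "FCz"
  eeg_recording(data, rate, labels, ref)
}
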