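#' Audio signal
#'
#' A 1- or 2-channel audio waveform with its sampling rate. Samples are
#' stored as a channels x samples matrix of doubles in `[-1, 1]`.
#'
#' @param data numeric vector (mono) or channels x samples matrix.
#' @param rate_hz sampling rate in Hz.
#' @return an object of class `audio_signal`.
#' @export
audio_signal <- function(data, rate_hz) {
  if (is.null(dim(data))) data <- matrix(data, nrow = 1)
  data <- as.matrix(data)
  if (!nrow(data) %in% 1:2) stop("audio must have 1 or 2 channels")
  if (!is.numeric(rate_hz) || rate_hz <= 0) stop("rate_hz must be positive")
  structure(list(rate_hz = rate_hz, data = data), class = "audio_signal")
}

#' @export
print.audio_signal <- function(x, ...) {
  cat(sprintf("<audio_signal> %d channel(s), %d samples @ %g Hz (%.2f s)\n",
              nrow(x$data), ncol(x$data), x$rate_hz, ncol(x$data) / x$rate_hz))
  invisible(x)
}

#' Read a WAV file
#'
#' Reads RIFF/WAVE files with 16-bit PCM samples (the format written by
#' [write_audio_wav]). Samples are rescaled to `[-1, 1]`. Binaural files are
#' kept as two channels.
#'
#' @param path WAV file.
#' @return an [audio_signal].
#' @export
read_audio_wav <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  if (readChar(con, 4, useBytes = TRUE) != "RIFF") stop("not a WAV (RIFF) file: ", path)
  readBin(con, "integer", size = 4, endian = "little")
  if (readChar(con, 4, useBytes = TRUE) != "WAVE") stop("not a WAV file: ", path)
  n_chan <- NA_integer_; rate <- NA_real_; bits <- NA_integer_; samples <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", size = 4, endian = "little")
    if (id == "fmt ") {
      fmt <- readBin(con, "integer", n = 2, size = 2, endian = "little")
      if (fmt[1] != 1L) stop("only PCM WAV is supported")
      n_chan <- fmt[2]
      rate <- readBin(con, "integer", size = 4, endian = "little")
      readBin(con, "integer", size = 4, endian = "little")  # byte rate
      readBin(con, "integer", size = 2, endian = "little")  # block align
      bits <- readBin(con, "integer", size = 2, endian = "little")
      if (bits != 16L) stop("only 16-bit PCM WAV is supported")
      if (size > 16) readBin(con, "raw", n = size - 16)
    } else if (id == "data") {
      samples <- readBin(con, "integer", n = size / 2, size = 2, endian = "little")
      break
    } else {
      readBin(con, "raw", n = size + size %% 2)
    }
  }
  if (is.null(samples) || is.na(n_chan)) stop("malformed WAV file: ", path)
  audio_signal(matrix(samples / 32768, nrow = n_chan), rate)
}

#' Write a WAV file (16-bit PCM)
#'
#' @param audio an [audio_signal]; samples are clipped to `[-1, 1]`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_audio_wav <- function(audio, path) {
  data <- pmin(pmax(audio$data, -1), 1)
  dig <- as.integer(round(t(data) * 32767))   # interleaved
  n_chan <- nrow(data)
  con <- file(path, "wb")
  on.exit(close(con))
  data_bytes <- length(dig) * 2L
  writeChar("RIFF", con, 4, eos = NULL)
  writeBin(as.integer(36 + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, 8, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(c(1L, n_chan), con, size = 2, endian = "little")
  writeBin(as.integer(audio$rate_hz), con, size = 4, endian = "little")
  writeBin(as.integer(audio$rate_hz * n_chan * 2), con, size = 4, endian = "little")
  writeBin(c(as.integer(n_chan * 2), 16L), con, size = 2, endian = "little")
  writeChar("data", con, 4, eos = NULL)
  writeBin(data_bytes, con, size = 4, endian = "little")
  writeBin(dig, con, size = 2, endian = "little")
  invisible(path)
}
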