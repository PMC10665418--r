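# Minimal RIFF/WAVE I/O for 16-bit PCM mono audio.
#
# The corpus convention is 16 kHz, 16-bit, mono PCM; no R package for WAV
# handling is assumed, so the canonical 44-byte header is read and written
# directly.

#' Read a 16-bit PCM mono WAV file
#'
#' Parses a RIFF/WAVE file and returns samples scaled to `[-1, 1]`. Only
#' uncompressed 16-bit mono PCM is supported. Files whose sample rate differs
#' from `expected_rate` are either rejected or resampled, per
#' `rate_policy`.
#'
#' @param path Path to a `.wav` file.
#' @param expected_rate Required sample rate in Hz (default 16000).
#' @param rate_policy `"reject"` (default) raises an error on a sample-rate
#'   mismatch; `"resample"` converts to `expected_rate` with
#'   [signal::resample()].
#' @return A list with `samples` (numeric vector in `[-1, 1]`) and
#'   `sample_rate`.
#' @export
read_wav <- function(path, expected_rate = 16000L,
                     rate_policy = c("reject", "resample")) {
  rate_policy <- match.arg(rate_policy)
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  readBin(con, "integer", 1, size = 4, endian = "little") # chunk size
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)

  sample_rate <- NULL
  bits <- NULL
  channels <- NULL
  samples <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- readBin(con, "integer", 2, size = 2, endian = "little")
      audio_format <- fmt[1]
      channels <- fmt[2]
      sample_rate <- readBin(con, "integer", 1, size = 4, endian = "little")
      readBin(con, "integer", 1, size = 4, endian = "little") # byte rate
      readBin(con, "integer", 1, size = 2, endian = "little") # block align
      bits <- readBin(con, "integer", 1, size = 2, endian = "little")
      if (audio_format != 1L) stop("only PCM WAV supported: ", path)
      if (size > 16) readBin(con, "raw", size - 16)
    } else if (identical(id, "data")) {
      n <- size %/% 2L
      samples <- readBin(con, "integer", n, size = 2, signed = TRUE,
                         endian = "little")
      break
    } else {
      readBin(con, "raw", size)
    }
  }
  if (is.null(sample_rate) || is.null(samples))
    stop("malformed WAV (missing fmt/data chunk): ", path)
  if (channels != 1L) stop("only mono WAV supported: ", path)
  if (bits != 16L) stop("only 16-bit PCM supported: ", path)
  x <- samples / 32768
  if (sample_rate != expected_rate) {
    if (rate_policy == "reject")
      stop("sample rate ", sample_rate, " Hz differs from required ",
           expected_rate, " Hz: ", path)
    x <- signal::resample(x, expected_rate, sample_rate)
    sample_rate <- expected_rate
  }
  list(samples = as.numeric(x), sample_rate = as.integer(sample_rate))
}

#' Write a 16-bit PCM mono WAV file
#'
#' @param samples Numeric vector in `[-1, 1]`; values outside are clipped.
#' @param path Output path.
#' @param sample_rate Sample rate in Hz (default 16000).
#' @return `path`, invisibly.
#' @export
write_wav <- function(samples, path, sample_rate = 16000L) {
  x <- pmax(pmin(samples, 1), -1)
  pcm <- as.integer(round(x * 32767))
  n_bytes <- length(pcm) * 2L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")              # PCM
  writeBin(1L, con, size = 2, endian = "little")              # mono
  writeBin(as.integer(sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate) * 2L, con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")              # block align
  writeBin(16L, con, size = 2, endian = "little")             # bits
  writeChar("data", con, eos = NULL)
  writeBin(n_bytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}
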