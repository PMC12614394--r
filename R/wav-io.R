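#' Write a mono waveform as 16-bit PCM WAV
#'
#' Canonical 44-byte RIFF/WAVE header followed by little-endian signed
#' 16-bit samples. Samples are clipped to \[-1, 1\] and scaled by 32767.
#'
#' @param samples Numeric vector in \[-1, 1\].
#' @param rate Sampling rate in Hz.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(samples, rate, path) {
  pcm <- as.integer(round(pmin(pmax(samples, -1), 1) * 32767))
  n <- length(pcm)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + 2 * n), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")            # fmt chunk size
  writeBin(1L, con, size = 2, endian = "little")             # PCM
  writeBin(1L, con, size = 2, endian = "little")             # mono
  writeBin(as.integer(rate), con, size = 4, endian = "little")
  writeBin(as.integer(rate * 2), con, size = 4, endian = "little")  # byte rate
  writeBin(2L, con, size = 2, endian = "little")             # block align
  writeBin(16L, con, size = 2, endian = "little")            # bits per sample
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(2 * n), con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a 16-bit PCM mono WAV file
#'
#' Walks the RIFF chunk list to the `fmt ` and `data` chunks; only
#' uncompressed 16-bit mono audio is supported (the format every simulator
#' in this package writes).
#'
#' @param path WAV file path.
#' @return List with `samples` (numeric in \[-1, 1\]) and `rate` (Hz).
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4)
  readBin(con, "integer", 1, size = 4, endian = "little")
  wave <- readChar(con, 4)
  if (!identical(riff, "RIFF") || !identical(wave, "WAVE")) {
    stop(path, " is not a RIFF/WAVE file", call. = FALSE)
  }
  rate <- NULL; bits <- NULL; channels <- NULL; samples <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (id == "fmt ") {
      fmt <- readBin(con, "integer", 2, size = 2, endian = "little")
      channels <- fmt[2]
      rate <- readBin(con, "integer", 1, size = 4, endian = "little")
      readBin(con, "integer", 1, size = 4, endian = "little")
      readBin(con, "integer", 1, size = 2, endian = "little")
      bits <- readBin(con, "integer", 1, size = 2, endian = "little")
      if (fmt[1] != 1L) stop("only PCM WAV is supported", call. = FALSE)
      skip <- size - 16
      if (skip > 0) readBin(con, "raw", skip)
    } else if (id == "data") {
      samples <- readBin(con, "integer", size / 2, size = 2,
                         signed = TRUE, endian = "little")
      break
    } else {
      readBin(con, "raw", size)
    }
  }
  if (is.null(samples) || is.null(rate)) {
    stop("missing fmt/data chunk in ", path, call. = FALSE)
  }
  if (!identical(channels, 1L) || !identical(bits, 16L)) {
    stop("only 16-bit mono WAV is supported", call. = FALSE)
  }
  list(samples = samples / 32767, rate = rate)
}
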