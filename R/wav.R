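#' Read a mono PCM WAV file
#'
#' Minimal RIFF/WAVE reader for single-channel 16-bit PCM audio, the format
#' produced by [write_wav()] and typical of archival hydrophone recordings
#' after conversion. Samples are returned on the normalized \[-1, 1) scale.
#'
#' @param path Path to a `.wav` file.
#' @return A list with `waveform` (numeric vector in \[-1, 1)) and
#'   `sample_rate` (Hz).
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF/WAVE file: ", path)
  invisible(readBin(con, "integer", 1L, size = 4L, endian = "little"))
  wave <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a RIFF/WAVE file: ", path)
  sample_rate <- NULL
  bits <- NULL
  channels <- NULL
  repeat {
    id <- readChar(con, 4L, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) stop("no data chunk found in ", path)
    size <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- readBin(con, "integer", 2L, size = 2L, endian = "little")
      channels <- fmt[2L]
      sample_rate <- readBin(con, "integer", 1L, size = 4L, endian = "little")
      invisible(readBin(con, "integer", 1L, size = 4L, endian = "little"))
      ba <- readBin(con, "integer", 1L, size = 2L, endian = "little")
      bits <- readBin(con, "integer", 1L, size = 2L, endian = "little")
      extra <- size - 16L
      if (extra > 0L) invisible(readBin(con, "raw", extra))
    } else if (identical(id, "data")) {
      if (is.null(bits)) stop("data chunk before fmt chunk in ", path)
      if (bits != 16L || channels != 1L)
        stop("only mono 16-bit PCM supported (got ", channels, " ch, ", bits, " bit)")
      n <- size %/% 2L
      x <- readBin(con, "integer", n, size = 2L, signed = TRUE, endian = "little")
      return(list(waveform = x / 32768, sample_rate = sample_rate))
    } else {
      invisible(readBin(con, "raw", size + size %% 2L))
    }
  }
}

#' Write a mono PCM WAV file
#'
#' @param waveform Numeric vector on the \[-1, 1\] scale; values are clipped.
#' @param sample_rate Sampling rate in Hz.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(waveform, sample_rate, path) {
  x <- pmin(pmax(waveform, -1), 32767 / 32768)
  pcm <- as.integer(round(x * 32768))
  n_bytes <- length(pcm) * 2L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(36L + n_bytes, con, size = 4L, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4L, endian = "little")
  writeBin(c(1L, 1L), con, size = 2L, endian = "little")        # PCM, mono
  writeBin(as.integer(sample_rate), con, size = 4L, endian = "little")
  writeBin(as.integer(sample_rate) * 2L, con, size = 4L, endian = "little")
  writeBin(c(2L, 16L), con, size = 2L, endian = "little")       # block align, bits
  writeChar("data", con, eos = NULL)
  writeBin(n_bytes, con, size = 4L, endian = "little")
  writeBin(pcm, con, size = 2L, endian = "little")
  invisible(path)
}
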