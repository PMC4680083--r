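# Minimal RIFF/WAVE reader and writer (mono PCM16 or IEEE float32).
# No installed package provides WAV IO, and stimuli only ever use the two
# canonical encodings, so the format is handled directly here.

#' Read a mono WAV file as a waveform
#'
#' Supports uncompressed PCM 16-bit and IEEE float 32-bit, single channel.
#' PCM samples are rescaled to \[-1, 1\].
#'
#' @param path Path to a `.wav` file.
#' @return A [waveform()].
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path, call. = FALSE)
  readBin(con, "integer", 1, 4, endian = "little")   # chunk size
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path, call. = FALSE)

  fmt <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) stop("no data chunk in ", path, call. = FALSE)
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      raw_fmt <- readBin(con, "raw", size)
      fmt <- list(
        audio_format = readBin(raw_fmt[1:2], "integer", 1, 2, signed = FALSE, endian = "little"),
        n_channels   = readBin(raw_fmt[3:4], "integer", 1, 2, signed = FALSE, endian = "little"),
        sample_rate  = readBin(raw_fmt[5:8], "integer", 1, 4, endian = "little"),
        bits         = readBin(raw_fmt[15:16], "integer", 1, 2, signed = FALSE, endian = "little")
      )
    } else if (identical(id, "data")) {
      if (is.null(fmt)) stop("data chunk before fmt chunk in ", path, call. = FALSE)
      if (fmt$n_channels != 1) stop("only mono WAV supported", call. = FALSE)
      samples <- if (fmt$audio_format == 1 && fmt$bits == 16) {
        readBin(con, "integer", size / 2, 2, signed = TRUE, endian = "little") / 32767
      } else if (fmt$audio_format == 3 && fmt$bits == 32) {
        readBin(con, "double", size / 4, 4, endian = "little")
      } else {
        stop("unsupported WAV encoding (need PCM16 or float32)", call. = FALSE)
      }
      return(waveform(samples, fmt$sample_rate))
    } else {
      readBin(con, "raw", size + size %% 2)  # skip unknown chunk (padded)
    }
  }
}

#' Write a waveform to a mono WAV file
#'
#' @param w A [waveform()].
#' @param path Output path.
#' @param bits 16 (PCM) or 32 (IEEE float). Float preserves amplitudes
#'   exactly; PCM16 clips outside \[-1, 1\].
#' @return `path`, invisibly.
#' @export
write_wav <- function(w, path, bits = 32) {
  stopifnot(inherits(w, "waveform"), bits %in% c(16, 32))
  n <- length(w$samples)
  bytes_per <- bits / 8
  data_size <- n * bytes_per
  audio_format <- if (bits == 16) 1L else 3L

  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_size), con, 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(audio_format, con, 2, endian = "little")
  writeBin(1L, con, 2, endian = "little")                       # mono
  writeBin(as.integer(w$sample_rate), con, 4, endian = "little")
  writeBin(as.integer(w$sample_rate * bytes_per), con, 4, endian = "little")
  writeBin(as.integer(bytes_per), con, 2, endian = "little")
  writeBin(as.integer(bits), con, 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, 4, endian = "little")
  if (bits == 16) {
    x <- pmax(pmin(w$samples, 1), -1)
    writeBin(as.integer(round(x * 32767)), con, 2, endian = "little")
  } else {
    writeBin(w$samples, con, 4, endian = "little")
  }
  invisible(path)
}
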