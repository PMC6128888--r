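#' Read a PCM WAV file
#'
#' Minimal RIFF/WAVE reader for the acquisition format used throughout this
#' pipeline: linear PCM, 16-bit, mono. Amplitudes are normalized to full
#' scale +/- 1 on read. Files at other sampling rates are rejected with an
#' explicit resample-required message (the pipeline never resamples
#' silently); `allow_resample = TRUE` performs linear-interpolation
#' resampling to 44.1 kHz for convenience from the command line.
#'
#' @param path path to a `.wav` file.
#' @param allow_resample resample non-44.1 kHz input instead of failing.
#' @return An [audio_stream()].
#' @export
read_wav <- function(path, allow_resample = FALSE) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) abort("not a RIFF/WAVE file")
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) abort("not a RIFF/WAVE file")

  fmt <- NULL; data <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- list(
        audio_format = readBin(con, "integer", 1, 2, endian = "little", signed = FALSE),
        channels = readBin(con, "integer", 1, 2, endian = "little", signed = FALSE),
        rate = readBin(con, "integer", 1, 4, endian = "little"),
        byte_rate = readBin(con, "integer", 1, 4, endian = "little"),
        block_align = readBin(con, "integer", 1, 2, endian = "little", signed = FALSE),
        bits = readBin(con, "integer", 1, 2, endian = "little", signed = FALSE)
      )
      if (size > 16) invisible(readBin(con, "raw", size - 16))
    } else if (identical(id, "data")) {
      if (is.null(fmt)) abort("malformed WAV: data chunk before fmt chunk")
      n <- size %/% 2L
      data <- readBin(con, "integer", n, 2, endian = "little", signed = TRUE)
      break
    } else {
      invisible(readBin(con, "raw", size + size %% 2L))
    }
  }
  if (is.null(fmt) || is.null(data)) abort("malformed WAV: missing fmt or data chunk")
  if (fmt$audio_format != 1L || fmt$bits != 16L) {
    abort("only 16-bit linear PCM WAV is supported")
  }
  if (fmt$channels != 1L) abort("only mono WAV is supported")
  x <- data / 32768
  if (fmt$rate != ACU_RATE) {
    if (!allow_resample) {
      abort(sprintf(
        "WAV is %d Hz but the pipeline requires 44100 Hz; pass allow_resample = TRUE or resample externally",
        fmt$rate
      ))
    }
    n_out <- round(length(x) * ACU_RATE / fmt$rate)
    x <- approx(seq_along(x), x, xout = seq(1, length(x), length.out = n_out))$y
  }
  audio_stream(x)
}

#' Write a simulated night to WAV, one epoch at a time
#'
#' Streams a (lazy or materialized) [simulate_night()] object to a 16-bit
#' PCM WAV without ever holding the whole night in memory: a full 7-hour
#' night is about 9 GB of doubles materialized, but only ~10 MB per epoch
#' streamed.
#'
#' @param night a [simulate_night()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_night_wav <- function(night, path) {
  n_total <- night$n_epochs * ACU_EPOCH_SAMPLES
  con <- file(path, "wb")
  on.exit(close(con))
  data_size <- n_total * 2          # can exceed .Machine$integer.max
  w_u32 <- function(x) {            # unsigned 32-bit little-endian
    writeBin(as.raw(c(x %% 256, x %/% 256 %% 256, x %/% 65536 %% 256,
                      x %/% 16777216 %% 256)), con)
  }
  writeChar("RIFF", con, eos = NULL)
  w_u32(36 + data_size)
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")
  writeBin(ACU_RATE, con, size = 4, endian = "little")
  writeBin(ACU_RATE * 2L, con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")
  writeBin(16L, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  w_u32(data_size)
  for (t in seq_len(night$n_epochs)) {
    x <- pmin(1, pmax(-1, night_epoch_audio(night, t)))
    writeBin(as.integer(round(x * 32767)), con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Write a PCM WAV file
#'
#' Writes a mono 16-bit PCM WAV at 44.1 kHz. Samples outside `[-1, 1]` are
#' clipped with a warning.
#'
#' @param audio an [audio_stream()] or numeric vector.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(audio, path) {
  x <- as_audio_samples(audio)
  if (any(abs(x) > 1)) {
    warn("samples outside [-1, 1] clipped on write")
    x <- pmin(1, pmax(-1, x))
  }
  pcm <- as.integer(round(x * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  data_size <- length(pcm) * 2L
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_size), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")        # PCM
  writeBin(1L, con, size = 2, endian = "little")        # mono
  writeBin(ACU_RATE, con, size = 4, endian = "little")
  writeBin(ACU_RATE * 2L, con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")
  writeBin(16L, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(data_size, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}
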