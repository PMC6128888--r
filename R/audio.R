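#' Construct an audio stream
#'
#' A light container for single-channel audio at the fixed acquisition rate
#' of 44.1 kHz. Amplitudes are dimensionless, full scale +/- 1; intensity
#' features downstream are therefore expressed in dB relative to full scale
#' (dBFS).
#'
#' @param samples numeric vector of amplitudes in `[-1, 1]` (values outside
#'   are allowed but flagged when writing WAV).
#' @param rate sampling rate; must be 44100. Other rates are rejected with an
#'   explicit resample-required message rather than silently resampled.
#' @return An object of class `audio_stream`.
#' @export
audio_stream <- function(samples, rate = 44100L) {
  if (length(samples) == 0) abort("audio stream is empty")
  if (!is.numeric(samples)) abort("samples must be numeric")
  if (anyNA(samples) || any(!is.finite(samples))) {
    abort("audio samples must be finite")
  }
  if (rate != ACU_RATE) {
    abort(sprintf(
      "sampling rate is %s but this pipeline requires 44100 Hz; resample the recording first",
      format(rate)
    ))
  }
  structure(
    list(samples = as.numeric(samples), rate = ACU_RATE, channel_count = 1L),
    class = "audio_stream"
  )
}

#' @export
print.audio_stream <- function(x, ...) {
  n <- length(x$samples)
  cat(sprintf("<audio_stream> %d samples (%.2f s) @ %d Hz, mono\n",
              n, n / x$rate, x$rate))
  invisible(x)
}

#' @export
length.audio_stream <- function(x) length(x$samples)

#' Split an audio stream into contiguous 50 ms frames
#'
#' Frames are non-overlapping windows of 2205 samples; a trailing partial
#' frame is discarded so no fabricated audio enters the feature pipeline.
#' The returned matrix holds one frame per column, in temporal order, so a
#' strictly causal consumer can walk the columns left to right.
#'
#' @param audio an [audio_stream()] (or numeric vector at 44.1 kHz).
#' @return A `2205 x n_frames` numeric matrix with class `audio_frames`.
#' @export
#' @examples
#' fr <- stream_frames(audio_stream(rnorm(44100) * 0.01))
#' ncol(fr) # 20 frames in one second
stream_frames <- function(audio) {
  x <- as_audio_samples(audio)
  n_frames <- length(x) %/% ACU_FRAME
  if (n_frames == 0) {
    abort("audio is shorter than one 50 ms frame (2205 samples)")
  }
  m <- matrix(x[seq_len(n_frames * ACU_FRAME)], nrow = ACU_FRAME)
  class(m) <- c("audio_frames", class(m))
  m
}

as_audio_samples <- function(audio) {
  if (inherits(audio, "audio_stream")) return(audio$samples)
  if (is.numeric(audio)) {
    if (length(audio) == 0) abort("audio stream is empty")
    return(as.numeric(audio))
  }
  abort("expected an audio_stream or numeric vector")
}

#' Group frames into 30 s epochs
#'
#' Epoch `t` (1-based, matching sleep-scoring convention) contains frames
#' `600 * (t - 1) .. 600 * t - 1` (0-based frame indices). A final incomplete
#' epoch is discarded.
#'
#' @param frames a frame matrix from [stream_frames()].
#' @return A list of `2205 x 600` matrices, one per epoch; names are epoch
#'   indices.
#' @export
frames_to_epochs <- function(frames) {
  if (!is.matrix(frames) || nrow(frames) != ACU_FRAME) {
    abort("frames must be a 2205-row matrix from stream_frames()")
  }
  n_epochs <- ncol(frames) %/% ACU_FRAMES_PER_EPOCH
  if (n_epochs == 0) return(setNames(list(), character()))
  out <- lapply(seq_len(n_epochs), function(t) {
    cols <- (t - 1L) * ACU_FRAMES_PER_EPOCH + seq_len(ACU_FRAMES_PER_EPOCH)
    frames[, cols, drop = FALSE]
  })
  setNames(out, as.character(seq_len(n_epochs)))
}

#' Align two energy envelopes by cross-correlation
#'
#' Finds the lag (on the common 10 ms grid) that maximizes the normalized
#' cross-correlation between two intensity envelopes; used to synchronize an
#' audio recording with a reference intensity channel. A positive lag means
#' `b` lags (is delayed relative to) `a`.
#'
#' @param envelope_a,envelope_b numeric energy series sampled every 10 ms.
#' @param max_lag_s maximum |lag| searched, in seconds.
#' @return A one-row tibble with `lag_s` (multiple of 0.01) and `correlation`.
#' @export
align_by_crosscorrelation <- function(envelope_a, envelope_b, max_lag_s = 30) {
  a <- as.numeric(envelope_a); b <- as.numeric(envelope_b)
  grid <- 0.01
  if (length(a) < 200 || length(b) < 200) {
    abort("both envelopes must cover at least 2 s (200 samples at 10 ms)")
  }
  if (sd(a) == 0 || sd(b) == 0) {
    abort("undefined alignment: an envelope has zero variance")
  }
  max_lag <- floor(max_lag_s / grid)
  if (max_lag >= min(length(a), length(b))) {
    abort("max_lag_s exceeds the envelope length")
  }
  lags <- seq.int(-max_lag, max_lag)
  cors <- vapply(lags, function(k) {
    if (k >= 0) {
      ia <- seq_len(min(length(a) - 0, length(b) - k))
      x <- a[ia]; y <- b[ia + k]
    } else {
      ib <- seq_len(min(length(b), length(a) + k))
      x <- a[ib - k]; y <- b[ib]
    }
    if (length(x) < 2 || sd(x) == 0 || sd(y) == 0) return(-Inf)
    cor(x, y)
  }, numeric(1))
  best <- which.max(cors)
  tibble(lag_s = lags[best] * grid, correlation = cors[best])
}

#' Per-frame energy envelope on a 10 ms grid
#'
#' Helper for alignment and debugging exports: mean squared amplitude over
#' consecutive 10 ms windows (441 samples).
#'
#' @param audio an [audio_stream()] or numeric vector.
#' @return A tibble with `time_s` and `energy`.
#' @export
energy_envelope <- function(audio) {
  x <- as_audio_samples(audio)
  win <- 441L
  n <- length(x) %/% win
  e <- colMeans(matrix(x[seq_len(n * win)]^2, nrow = win))
  tibble(time_s = (seq_len(n) - 1L) * 0.01, energy = e)
}
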