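#' Update the background-noise profile from one epoch
#'
#' Tracks the stationary background-noise spectrum at 30 s epoch resolution.
#' The epoch's lowest-energy frames (default lowest 20%) are taken as
#' noise-only; their mean power spectrum is blended exponentially with the
#' previous profile (per bin: weight 0.9 on the past when the level falls,
#' 0.7 when it rises), so the profile follows drifts and level steps in the
#' room noise while ignoring breathing and movement sounds. Tracking is
#' strictly causal: only the current and past epochs ever contribute.
#'
#' @param epoch a `2205 x 600` frame matrix (one epoch) from
#'   [frames_to_epochs()], or any `2205 x m` frame matrix.
#' @param previous the previous `noise_profile`, or `NULL` for the first
#'   epoch.
#' @param config an [acusleep_config()]; the `enhancement` block is used.
#' @return An object of class `noise_profile`: per-bin magnitude estimate of
#'   the background noise on the analysis grid.
#' @export
update_noise_profile <- function(epoch, previous = NULL,
                                 config = acusleep_config()) {
  en <- config$enhancement
  spec <- epoch_spectra(epoch, en$window)
  profile_from_spectra(spec$P, spec$sp, previous, en,
                       frame_power = colMeans(epoch^2))
}

profile_from_spectra <- function(P, sp, previous, en, frame_power) {
  n_keep <- max(1L, floor(ncol(P) * en$noise_quantile))
  idx <- order(frame_power)[seq_len(n_keep)]
  est <- sqrt(rowMeans(P[, idx, drop = FALSE]))
  epoch_idx <- if (is.null(previous)) 1L else previous$last_update_epoch + 1L
  # asymmetric exponential blend: rising noise is tracked faster than
  # falling noise (standard practice for background trackers; the
  # low-energy quantile already keeps sound events out of the estimate)
  mag <- if (is.null(previous)) est else {
    w <- ifelse(est > previous$magnitude, en$blend_up, en$blend)
    w * previous$magnitude + (1 - w) * est
  }
  structure(
    list(magnitude = mag, window = sp$L, last_update_epoch = epoch_idx,
         adaptation_weight = en$blend,
         floor_db = power_to_db(mean(frame_power[idx]), ACU_LOGE_FLOOR)),
    class = "noise_profile"
  )
}

#' @export
print.noise_profile <- function(x, ...) {
  cat(sprintf("<noise_profile> %d bins, epoch %d, floor %.1f dBFS\n",
              length(x$magnitude), x$last_update_epoch, x$floor_db))
  invisible(x)
}

# Spectral gain: over-subtraction spectral subtraction in the Wiener family.
# G^2 = max(1 - alpha * N^2 / P, gf^2), applied to power spectra.
wiener_gain_sq <- function(P, noise_sq, en) {
  gf2 <- 10^(en$floor_db / 10)
  pmax(1 - en$oversubtraction * noise_sq / (P + 1e-30), gf2)
}

#' Enhance one 50 ms frame
#'
#' Applies the per-bin spectral-subtraction gain derived from the tracked
#' noise profile to a single frame and reconstructs the time signal. The
#' full 2205-point spectrum is used for reconstruction (phase preserved);
#' the noise profile, estimated on the analysis grid, is interpolated onto
#' the frame's frequency grid with the appropriate window-energy scaling.
#'
#' @param frame numeric vector of 2205 samples (one column of a frame
#'   matrix).
#' @param profile a `noise_profile` from [update_noise_profile()].
#' @param config an [acusleep_config()].
#' @return The enhanced frame: numeric vector of length 2205.
#' @export
enhance_frame <- function(frame, profile, config = acusleep_config()) {
  if (length(frame) != ACU_FRAME) abort("frame must have 2205 samples")
  if (!inherits(profile, "noise_profile")) {
    abort("profile must be initialized with update_noise_profile()")
  }
  en <- config$enhancement
  sp <- spectral_setup(profile$window)
  L <- ACU_FRAME
  X <- fft(frame)
  nb <- L %/% 2L + 1L
  freqs <- (seq_len(nb) - 1L) * ACU_RATE / L
  # rectangular-window PSD scaling: |X_rect(L)|^2 ~ L * PSD vs Hann sum(w^2)
  scale <- sqrt(L / sp$wsq)
  nmag <- approx(sp$freqs, profile$magnitude, xout = freqs, rule = 2)$y * scale
  P <- Mod(X[seq_len(nb)])^2
  G <- sqrt(wiener_gain_sq(P, nmag^2, en))
  # mirror onto the conjugate half (L = 2205 is odd: no Nyquist bin)
  Gfull <- if (L %% 2L == 0L) c(G, rev(G[2:(nb - 1L)])) else c(G, rev(G[2:nb]))
  Re(fft(X * Gfull, inverse = TRUE)) / L
}

#' Enhance a whole epoch of frames
#'
#' Vectorized counterpart of [enhance_frame()] for a `2205 x m` frame
#' matrix, updating nothing: the supplied profile is used as-is.
#'
#' @inheritParams enhance_frame
#' @param epoch `2205 x m` frame matrix.
#' @return Enhanced `2205 x m` frame matrix.
#' @export
enhance_epoch <- function(epoch, profile, config = acusleep_config()) {
  apply(epoch, 2, enhance_frame, profile = profile, config = config)
}

#' Event-to-background signal-to-noise ratio of an epoch
#'
#' `10 log10` of the ratio between mean frame power inside events and mean
#' frame power of background frames, as marked by a per-frame mask.
#' Supports the diagnostic relationship between recording SNR and staging
#' performance.
#'
#' @param epoch `2205 x m` frame matrix (raw, un-enhanced audio).
#' @param event_mask logical vector, length `m`: `TRUE` for event frames.
#' @return SNR in dB.
#' @export
estimate_epoch_snr <- function(epoch, event_mask) {
  if (length(event_mask) != ncol(epoch)) {
    abort("event_mask length must equal the number of frames")
  }
  if (all(event_mask) || !any(event_mask)) {
    abort("event_mask must mark at least one event and one background frame")
  }
  p <- colMeans(epoch^2)
  10 * log10(mean(p[event_mask]) / mean(p[!event_mask]))
}
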