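#' Breathing periodicity via autocorrelation
#'
#' Autocorrelation of the mean-removed inhalation probability curve of one
#' epoch, normalized so the zero-lag value is 1 (per-lag estimates use the
#' unbiased `1/(n-k)` scaling, so an exactly periodic curve scores 1 at its
#' period). The first local peak at lag >= 1 s summarizes breathing
#' periodicity: prominent and sharp in regular NREM breathing, lower in
#' REM, near-absent in wake. The lag search is bounded to the physiologic
#' breathing range (periods up to 10 s, i.e. rates down to 6 breaths/min):
#' beyond it, an isolated pair of sounds can masquerade as a "period".
#'
#' @param curves probability curves of one epoch ([detect_events()] output
#'   or the equivalent 4-column matrix).
#' @param max_lag_s longest lag examined (default 10 s).
#' @return A list with `acf` (tibble: `lag_s`, `acf`), `peak_lag_s`,
#'   `peak_height` (both `NA` when undefined) and `constant` (`TRUE` when
#'   the curve had zero variance).
#' @export
breathing_autocorrelation <- function(curves, max_lag_s = 10) {
  ac <- breath_acf(curves_matrix(curves)[, "inhale"], max_lag_s)
  max_lag <- length(ac$values) - 1L
  list(
    acf = tibble(lag_s = (0:max_lag) * 0.05, acf = ac$values),
    peak_lag_s = ac$peak_lag_s, peak_height = ac$peak_height,
    constant = ac$constant
  )
}

# internal: inhalation curve -> unbiased normalized ACF + first local peak
breath_acf <- function(x, max_lag_s = 10) {
  n <- length(x)
  max_lag <- min(n - 1L, round(max_lag_s / 0.05))
  lags <- 0:max_lag
  if (var(x) < 1e-18) {
    return(list(values = c(1, rep(NA_real_, max_lag)),
                peak_lag_s = NA_real_, peak_height = NA_real_,
                constant = TRUE))
  }
  xc <- x - mean(x)
  # raw autocovariances via FFT, then unbiased scaling per lag
  npad <- nextn(2L * n, 2)
  sp <- fft(c(xc, numeric(npad - n)))
  r <- Re(fft(sp * Conj(sp), inverse = TRUE))[seq_len(max_lag + 1L)] / npad
  acf_u <- (r / (n - lags)) / (r[1] / n)
  acf_u <- pmin(1, pmax(-1, acf_u))

  k0 <- round(1 / 0.05)   # peaks searched at lag >= 1 s
  peak_lag <- NA_real_; peak_height <- NA_real_
  if (max_lag > k0 + 1L) {
    for (k in seq.int(k0 + 1L, max_lag)) {  # 0-based lag k -> acf_u[k + 1]
      lo <- max(1L, k - 2L); hi <- min(max_lag, k + 2L)
      neigh <- acf_u[setdiff(seq.int(lo, hi), k) + 1L]
      # a genuine periodicity peak is positive; plateau ripple is not
      if (acf_u[k + 1L] > 0 && acf_u[k + 1L] > max(neigh)) {
        peak_lag <- k * 0.05
        peak_height <- acf_u[k + 1L]
        break
      }
    }
  }
  list(values = acf_u, peak_lag_s = peak_lag, peak_height = peak_height,
       constant = FALSE)
}

#' Segment probability curves into breath events
#'
#' Maximal runs of frames whose most probable class is inhalation
#' (respectively exhalation) with probability at or above the threshold
#' become breath events; runs shorter than `config$features$min_run` frames
#' (150 ms by default) are discarded as detector noise.
#'
#' @param curves probability curves of one epoch.
#' @param threshold minimum class probability inside a run (default from
#'   config, 0.5).
#' @param frame_intensity optional per-frame intensity (dBFS) used to fill
#'   each event's `mean_intensity`; `NA` otherwise.
#' @param config an [acusleep_config()].
#' @return A tibble of events: `kind`, `onset_frame`, `offset_frame`
#'   (0-based, inclusive), `duration_s`, `mean_intensity`.
#' @export
segment_breath_events <- function(curves, threshold = NULL,
                                  frame_intensity = NULL,
                                  config = acusleep_config()) {
  threshold <- threshold %||% config$features$breath_threshold
  if (threshold <= 0 || threshold >= 1) abort("threshold must be in (0, 1)")
  cm <- curves_matrix(curves)
  cls <- max.col(cm, ties.method = "first")
  events <- list()
  for (ki in 1:2) {            # 1 = inhale, 2 = exhale
    act <- cls == ki & cm[, ki] >= threshold
    ev <- runs_from_mask(act, config$features$min_run)
    if (ev$n) {
      events[[length(events) + 1L]] <- list(
        kind = rep(EVENT_CLASSES[ki], ev$n),
        onset_frame = ev$onset_frame, offset_frame = ev$offset_frame
      )
    }
  }
  if (!length(events)) {
    return(new_tibble(list(kind = character(), onset_frame = integer(),
                           offset_frame = integer(), duration_s = numeric(),
                           mean_intensity = numeric()), nrow = 0L))
  }
  kind <- unlist(lapply(events, `[[`, "kind"))
  onset <- unlist(lapply(events, `[[`, "onset_frame"))
  offset <- unlist(lapply(events, `[[`, "offset_frame"))
  o <- order(onset)
  kind <- kind[o]; onset <- onset[o]; offset <- offset[o]
  mi <- if (is.null(frame_intensity)) rep(NA_real_, length(onset)) else {
    vapply(seq_along(onset), function(i) {
      power_to_db(mean(10^(frame_intensity[(onset[i]:offset[i]) + 1L] / 10)))
    }, numeric(1))
  }
  new_tibble(list(
    kind = kind, onset_frame = onset, offset_frame = offset,
    duration_s = (offset - onset + 1L) * 0.05, mean_intensity = mi
  ), nrow = length(onset))
}

# logical mask -> 0-based inclusive runs of length >= min_run
# (plain list for speed; hot path allocates these hundreds of times)
runs_from_mask <- function(mask, min_run = 1L) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_run
  list(onset_frame = starts[keep] - 1L, offset_frame = ends[keep] - 1L,
       n = sum(keep))
}
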