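# The 67-feature epoch vector: five families computed from enhanced audio,
# the four probability curves, the tracked noise profile, subject metadata
# and the epoch index. Undefined statistics (no events in the epoch) take
# the reserved sentinel and are replaced by training-set medians when a
# cascade is fitted.

or_sentinel <- function(x) {
  x <- suppressWarnings(as.numeric(x))
  ifelse(is.na(x) | !is.finite(x), ACU_SENTINEL, x)
}

db_mean <- function(db) power_to_db(mean(10^(db / 10)))

#' Within-breathing features (33 values)
#'
#' Breath-event counts, duration and intensity statistics, the
#' inhale:exhale intensity ratio (linear amplitude ratio derived from the
#' dB difference of mean intensities), and spectral summaries of the
#' breath-active frames.
#'
#' @param epoch `2205 x 600` enhanced frame matrix.
#' @param curves probability curves of the epoch.
#' @param events breath events from [segment_breath_events()].
#' @param config an [acusleep_config()].
#' @return A named numeric vector of length 33.
#' @export
within_breathing_features <- function(epoch, curves, events,
                                      config = acusleep_config()) {
  spec <- epoch_spectra(epoch, config$enhancement$window)
  ff <- frame_features_from_spectra(spec$P, spec$win, spec$sp)
  f_within(ff, curves_matrix(curves), events)
}

f_within <- function(ff, cm, events) {
  m <- nrow(cm)
  in_ev <- events[events$kind == "inhale", , drop = FALSE]
  ex_ev <- events[events$kind == "exhale", , drop = FALSE]

  ev_frames <- function(ev) {
    if (!nrow(ev)) return(integer())
    unlist(lapply(seq_len(nrow(ev)), function(i) {
      (ev$onset_frame[i]:ev$offset_frame[i]) + 1L
    }))
  }
  ev_int <- function(ev) {
    if (!nrow(ev)) return(numeric())
    vapply(seq_len(nrow(ev)), function(i) {
      db_mean(ff[(ev$onset_frame[i]:ev$offset_frame[i]) + 1L, "log_energy"])
    }, numeric(1))
  }

  in_int <- ev_int(in_ev); ex_int <- ev_int(ex_ev)
  br_idx <- sort(unique(c(ev_frames(in_ev), ev_frames(ex_ev))))
  br <- ff[br_idx, , drop = FALSE]

  ratio <- if (length(in_int) && length(ex_int)) {
    10^((db_mean(in_int) - db_mean(ex_int)) / 20)
  } else NA_real_

  vals <- c(
    in_count = nrow(in_ev), ex_count = nrow(ex_ev),
    in_dur_mean = mean(in_ev$duration_s), in_dur_sd = sd(in_ev$duration_s),
    in_dur_max = suppressWarnings(max(in_ev$duration_s)),
    ex_dur_mean = mean(ex_ev$duration_s), ex_dur_sd = sd(ex_ev$duration_s),
    ex_dur_max = suppressWarnings(max(ex_ev$duration_s)),
    in_int_mean = mean(in_int), in_int_sd = sd(in_int),
    ex_int_mean = mean(ex_int), ex_int_sd = sd(ex_int),
    in_ex_int_ratio = ratio,
    br_centroid_mean = mean(br[, "spectral_centroid"]),
    br_centroid_sd = sd(br[, "spectral_centroid"]),
    br_entropy_mean = mean(br[, "spectral_entropy"]),
    br_entropy_sd = sd(br[, "spectral_entropy"]),
    br_rolloff_mean = mean(br[, "spectral_rolloff"]),
    br_rolloff_sd = sd(br[, "spectral_rolloff"]),
    br_band1_mean = mean(br[, "band1"]), br_band2_mean = mean(br[, "band2"]),
    br_band3_mean = mean(br[, "band3"]), br_band4_mean = mean(br[, "band4"]),
    br_zcr_mean = mean(br[, "zcr"]), br_zcr_sd = sd(br[, "zcr"]),
    br_cep1_mean = mean(br[, "cep1"]), br_cep2_mean = mean(br[, "cep2"]),
    br_cep3_mean = mean(br[, "cep3"]), br_cep4_mean = mean(br[, "cep4"]),
    br_cep5_mean = mean(br[, "cep5"]), br_cep6_mean = mean(br[, "cep6"]),
    br_harmonic_frac = if (length(br_idx)) {
      mean(br[, "spectral_entropy"] < 0.6)
    } else NA_real_,
    breath_duty_cycle = length(br_idx) / m
  )
  out <- or_sentinel(vals)
  # counts and the duty cycle are always defined, even with zero events
  out[c(1, 2)] <- c(nrow(in_ev), nrow(ex_ev))
  out[33] <- length(br_idx) / m
  names(out) <- registry_names$within_breathing
  out
}

#' Between-breathing features (12 values)
#'
#' Respiratory-cycle statistics: inter-breath intervals (inhale onset to
#' inhale onset), breathing-curve autocorrelation peak, dominant breathing
#' frequency from the inhalation-curve periodogram, regularity ratio,
#' duty-cycle variability across thirds of the epoch, inhale-to-exhale
#' onset intervals, and the fraction of the epoch with detectable
#' breathing.
#'
#' @inheritParams within_breathing_features
#' @return A named numeric vector of length 12.
#' @export
between_breathing_features <- function(curves, events,
                                       config = acusleep_config()) {
  f_between(curves_matrix(curves), events)
}

f_between <- function(cm, events) {
  m <- nrow(cm)
  in_on <- events$onset_frame[events$kind == "inhale"]
  ex_on <- events$onset_frame[events$kind == "exhale"]

  ibi <- if (length(in_on) >= 2) diff(sort(in_on)) * 0.05 else numeric()
  ibi_mean <- mean(ibi); ibi_sd <- sd(ibi)
  ibi_cv <- if (length(ibi) >= 2 && ibi_mean > 0) ibi_sd / ibi_mean else NA_real_

  ac <- breath_acf(cm[, "inhale"])

  # periodogram of the mean-removed inhalation curve (zero-padded)
  x <- cm[, "inhale"] - mean(cm[, "inhale"])
  npad <- max(2048L, nextn(m, 2))
  px <- Mod(fft(c(x, numeric(npad - m))))^2 * 2 / m^2
  freqs <- (seq_len(npad) - 1L) * 20 / npad
  sel <- which(freqs >= 0.05 & freqs <= 2)
  if (length(sel) && var(x) > 1e-18) {
    i0 <- sel[which.max(px[sel])]
    dom_f <- freqs[i0]; dom_mag <- px[i0]
  } else {
    dom_f <- NA_real_; dom_mag <- NA_real_
  }

  reg <- if (!is.na(ac$peak_height)) {
    k <- round(ac$peak_lag_s / 0.05)
    ac$values[k + 1L] * (m - k) / m   # biased first-peak / zero-lag ratio
  } else NA_real_

  br_mask <- logical(m)
  if (nrow(events)) {
    for (i in seq_len(nrow(events))) {
      br_mask[(events$onset_frame[i]:events$offset_frame[i]) + 1L] <- TRUE
    }
  }
  thirds <- split(br_mask, rep(1:3, each = ceiling(m / 3))[seq_len(m)])
  duty_var <- sd(vapply(thirds, mean, numeric(1)))

  iei <- vapply(in_on, function(o) {
    nxt <- ex_on[ex_on > o]
    if (length(nxt)) (nxt[1] - o) * 0.05 else NA_real_
  }, numeric(1))
  iei <- iei[!is.na(iei)]

  sec_bins <- split(br_mask, rep(seq_len(ceiling(m / 20)), each = 20)[seq_len(m)])
  detect_frac <- mean(vapply(sec_bins, any, logical(1)))

  out <- or_sentinel(c(
    ibi_mean = ibi_mean, ibi_sd = ibi_sd, ibi_cv = ibi_cv,
    acf_peak_height = ac$peak_height, acf_peak_lag = ac$peak_lag_s,
    dom_breath_freq = dom_f, dom_breath_mag = dom_mag,
    regularity_ratio = reg, duty_cycle_var = duty_var,
    in_ex_interval_mean = mean(iei), in_ex_interval_sd = sd(iei),
    breath_detect_frac = detect_frac
  ))
  out[12] <- detect_frac
  names(out) <- registry_names$between_breathing
  out
}

#' Body-movement features (10 values)
#'
#' Movement-event counts, durations, intensities, the movement-free
#' structure of the epoch, and the night-level recency of the last
#' movement (capped at one epoch).
#'
#' @inheritParams within_breathing_features
#' @param frame_intensity optional per-frame intensity (dBFS); derived from
#'   the enhanced audio by the night pipeline.
#' @param prev_gap frames elapsed since the last movement event at the
#'   start of this epoch (night state; 600 = saturated).
#' @return A named numeric vector of length 10.
#' @export
body_movement_features <- function(curves, frame_intensity = NULL,
                                   prev_gap = 600L,
                                   config = acusleep_config()) {
  f_movement(curves_matrix(curves), frame_intensity, prev_gap,
             config$features)
}

f_movement <- function(cm, intensity_db, prev_gap, fcfg) {
  m <- nrow(cm)
  cls <- max.col(cm, ties.method = "first")
  mask <- cls == 3L & cm[, 3L] >= fcfg$breath_threshold
  ev <- runs_from_mask(mask, fcfg$min_run)
  bm_frames <- which(mask)
  dur <- (ev$offset_frame - ev$onset_frame + 1L) * 0.05
  ints <- if (!is.null(intensity_db) && length(bm_frames)) {
    intensity_db[bm_frames]
  } else numeric()

  since <- if (ev$n) {
    min(m - 1L - max(ev$offset_frame), 600L)
  } else min(prev_gap + m, 600L)
  free_runs <- runs_from_mask(!mask, 1L)
  free_max <- if (free_runs$n) {
    max(free_runs$offset_frame - free_runs$onset_frame + 1L)
  } else 0L
  half <- sum(ev$onset_frame < m / 2) - sum(ev$onset_frame >= m / 2)

  out <- or_sentinel(c(
    bm_count = ev$n, bm_frac = length(bm_frames) / m,
    bm_dur_mean = mean(dur), bm_dur_max = suppressWarnings(max(dur)),
    bm_int_mean = db_mean(ints), bm_int_max = suppressWarnings(max(ints)),
    bm_frames_since_last = since, bm_p_mean = mean(cm[, 3L]),
    bm_free_run_max = free_max, bm_half_diff = half
  ))
  out[c(1, 2, 9, 10)] <- c(ev$n, length(bm_frames) / m, free_max, half)
  names(out) <- registry_names$body_movement
  out
}

#' Background-noise features (8 values)
#'
#' "Other sound" transient events (frames classified as other sounds and
#' louder than the noise floor by 6 dB), the raw noise-floor level and its
#' change since the previous epoch, and the transient rate over the
#' trailing five epochs. The first epoch's delta is defined as 0.
#'
#' @inheritParams body_movement_features
#' @param epoch `2205 x 600` raw frame matrix (noise floor is a property of
#'   the un-enhanced signal).
#' @param profile optional `noise_profile`; used for the floor when the raw
#'   epoch is not supplied.
#' @param state optional night state list with `prev_floor` and `os_counts`
#'   (counts of the preceding <= 4 epochs).
#' @return A named numeric vector of length 8.
#' @export
background_noise_features <- function(epoch = NULL, curves, profile = NULL,
                                      state = NULL,
                                      config = acusleep_config()) {
  floor_db <- if (!is.null(epoch)) {
    p <- colMeans(epoch^2)
    power_to_db(mean(sort(p)[seq_len(max(1, floor(length(p) * 0.2)))]),
                ACU_LOGE_FLOOR)
  } else if (!is.null(profile)) profile$floor_db else ACU_LOGE_FLOOR
  spec <- if (!is.null(epoch)) epoch_spectra(epoch, config$enhancement$window) else NULL
  ff <- if (!is.null(spec)) {
    frame_features_from_spectra(spec$P, spec$win, spec$sp)
  } else NULL
  f_noise(curves_matrix(curves), ff, floor_db, state, config$features)
}

f_noise <- function(cm, ff, floor_db, state, fcfg) {
  m <- nrow(cm)
  cls <- max.col(cm, ties.method = "first")
  loud <- if (!is.null(ff)) ff[, "log_energy"] >= floor_db + 6 else rep(FALSE, m)
  mask <- cls == 4L & cm[, 4L] >= fcfg$breath_threshold & loud
  ev <- runs_from_mask(mask, fcfg$min_run)
  os_frames <- which(mask)

  ints <- if (!is.null(ff) && length(os_frames)) ff[os_frames, "log_energy"] else numeric()
  cent <- if (!is.null(ff) && length(os_frames)) ff[os_frames, "spectral_centroid"] else numeric()

  prev_counts <- if (!is.null(state)) state$os_counts else integer()
  recent <- c(tail(prev_counts, 4L), ev$n)
  rate <- sum(recent) / (length(recent) * 0.5)   # events per minute

  delta <- if (!is.null(state) && !is.null(state$prev_floor)) {
    floor_db - state$prev_floor
  } else 0

  vals <- c(
    os_count = ev$n, os_frac = length(os_frames) / m,
    os_int_mean = if (length(ints)) db_mean(ints) else ACU_DB_FLOOR,
    os_int_max = if (length(ints)) max(ints) else ACU_DB_FLOOR,
    noise_floor_db = floor_db, noise_floor_delta = delta,
    os_centroid_mean = if (length(cent)) mean(cent) else 0,
    transient_rate = rate
  )
  out <- or_sentinel(vals)
  names(out) <- registry_names$background_noise
  out
}

#' Personalization features (4 values)
#'
#' Anthropometric calibration plus the chronicity of the recording: age
#' (years), gender code (0/1), BMI (kg/m^2) and the 1-based epoch index.
#' Missing metadata is an error; there are no silent defaults.
#'
#' @param meta a list or one-row data frame with `age`, `gender`, `bmi`.
#' @param t 1-based epoch index.
#' @return A named numeric vector of length 4.
#' @export
personalization_features <- function(meta, t) {
  for (fld in c("age", "gender", "bmi")) {
    v <- meta[[fld]]
    if (is.null(v) || length(v) != 1 || is.na(v)) {
      abort(sprintf("subject metadata field '%s' is missing", fld))
    }
  }
  if (meta$age <= 0) abort("age must be positive")
  if (meta$bmi <= 0) abort("bmi must be positive")
  if (!meta$gender %in% c(0, 1)) abort("gender must be coded 0 or 1")
  if (t < 1) abort("epoch index t is 1-based")
  c(age = as.numeric(meta$age), gender = as.numeric(meta$gender),
    bmi = as.numeric(meta$bmi), epoch_index = as.numeric(t))
}

#' Full 67-feature vector of one epoch
#'
#' Concatenates the five families in registry order. All values are finite
#' (undefined statistics carry the documented sentinel until imputed at
#' model-fit time).
#'
#' @param epoch `2205 x 600` enhanced frame matrix of epoch `t`.
#' @param curves probability curves of the epoch.
#' @param profile the `noise_profile` after updating on this epoch.
#' @param meta subject metadata (`age`, `gender`, `bmi`).
#' @param t 1-based epoch index.
#' @param state optional night state (movement recency, noise-floor history,
#'   transient counts); `NULL` gives first-epoch semantics.
#' @param config an [acusleep_config()].
#' @return A one-row tibble with 67 feature columns in registry order, with
#'   the updated night state in attribute `"state"`.
#' @export
extract_epoch_features <- function(epoch, curves, profile, meta, t,
                                   state = NULL, config = acusleep_config()) {
  spec <- epoch_spectra(epoch, config$enhancement$window)
  ff <- frame_features_from_spectra(spec$P, spec$win, spec$sp)
  cm <- curves_matrix(curves)
  events <- segment_breath_events(cm, frame_intensity = ff[, "log_energy"],
                                  config = config)
  floor_db <- if (!is.null(profile)) profile$floor_db else ACU_LOGE_FLOOR
  row <- assemble_epoch_features(ff, cm, events, floor_db, meta, t, state,
                                 config)
  st <- attr(row, "state")
  out <- as_tibble(as.list(row))
  attr(out, "state") <- st
  out
}

# shared by extract_epoch_features and the night engine
assemble_epoch_features <- function(ff, cm, events, floor_db, meta, t,
                                    state, config) {
  fcfg <- config$features
  prev_gap <- if (!is.null(state)) state$bm_gap else 600L
  v <- c(
    f_within(ff, cm, events),
    f_between(cm, events),
    f_movement(cm, ff[, "log_energy"], prev_gap, fcfg),
    f_noise(cm, ff, floor_db, state, fcfg),
    personalization_features(meta, t)
  )
  # updated night state
  cls <- max.col(cm, ties.method = "first")
  mask <- cls == 3L & cm[, 3L] >= fcfg$breath_threshold
  ev <- runs_from_mask(mask, fcfg$min_run)
  new_gap <- if (ev$n) {
    min(nrow(cm) - 1L - max(ev$offset_frame), 600L)
  } else min(prev_gap + nrow(cm), 600L)
  prev_counts <- if (!is.null(state)) state$os_counts else integer()
  os_count <- v[["os_count"]]
  attr(v, "state") <- list(
    bm_gap = new_gap,
    prev_floor = floor_db,
    os_counts = c(tail(prev_counts, 4L), os_count)
  )
  v
}
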