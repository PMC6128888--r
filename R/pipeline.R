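# Night-level driver: streams epochs through noise tracking, enhancement,
# event detection and feature extraction in one causal pass. Accepts
# either materialized audio or a lazy simulated night, so multi-hour
# recordings never need to sit in memory at once.

night_source <- function(x) {
  chunk_from_samples <- function(samples) {
    function(ts) {
      if (length(ts) == 1L || all(diff(ts) == 1L)) {
        i0 <- (ts[1] - 1) * ACU_EPOCH_SAMPLES
        return(matrix(samples[(i0 + 1):(i0 + length(ts) * ACU_EPOCH_SAMPLES)],
                      nrow = ACU_FRAME))
      }
      out <- matrix(0, ACU_FRAME, ACU_FRAMES_PER_EPOCH * length(ts))
      for (j in seq_along(ts)) {
        i0 <- (ts[j] - 1) * ACU_EPOCH_SAMPLES
        out[, (j - 1L) * ACU_FRAMES_PER_EPOCH +
              seq_len(ACU_FRAMES_PER_EPOCH)] <-
          samples[(i0 + 1):(i0 + ACU_EPOCH_SAMPLES)]
      }
      out
    }
  }
  if (inherits(x, "simulated_night")) {
    if (!is.null(x$audio)) {
      samples <- x$audio$samples
      return(list(
        n_epochs = length(samples) %/% ACU_EPOCH_SAMPLES,
        get_chunk = chunk_from_samples(samples),
        meta = x$meta
      ))
    }
    return(list(
      n_epochs = x$n_epochs,
      get_chunk = function(ts) night_epoch_chunk(x, ts),
      meta = x$meta
    ))
  }
  samples <- as_audio_samples(x)
  n <- length(samples) %/% ACU_EPOCH_SAMPLES
  if (n == 0) abort("audio is shorter than one 30 s epoch")
  list(n_epochs = n, get_chunk = chunk_from_samples(samples), meta = NULL)
}

#' Extract the per-epoch feature matrix of a night
#'
#' Runs the causal processing chain over a whole night: per-epoch
#' background-noise tracking and spectral-subtraction enhancement, the
#' four-curve event detector, breath/movement segmentation, and the
#' 67-feature epoch vector. Features of epoch `t` depend only on epochs
#' `<= t`.
#'
#' @param x an [audio_stream()], numeric sample vector, or a
#'   [simulate_night()] object (lazy or materialized).
#' @param detector a trained [train_detector()] model (or `NULL` for the
#'   uniform prior -- features then carry little information).
#' @param meta subject metadata list (`age`, `gender`, `bmi`); taken from a
#'   simulated night automatically.
#' @param config an [acusleep_config()].
#' @param epochs epochs to process (default all). History state still
#'   advances only over the processed epochs, in order.
#' @param return_curves also return the probability curves of every
#'   processed epoch (attribute `"curves"`: list of 600 x 4 matrices).
#' @return A tibble with `epoch` plus the 67 registry feature columns;
#'   attribute `"registry"` holds the registry hash.
#' @export
extract_night_features <- function(x, detector = NULL, meta = NULL,
                                   config = acusleep_config(),
                                   epochs = NULL, return_curves = FALSE) {
  src <- night_source(x)
  meta <- meta %||% src$meta
  if (is.null(meta)) abort("subject metadata is required (age, gender, bmi)")
  epochs <- epochs %||% seq_len(src$n_epochs)
  en <- config$enhancement

  profile <- NULL
  state <- NULL
  rows <- vector("list", length(epochs))
  curves_out <- if (return_curves) vector("list", length(epochs)) else NULL
  fpe <- ACU_FRAMES_PER_EPOCH

  # epochs are processed in chunks so the FFT, the per-frame features and
  # the detector forward pass are batched; noise tracking stays a strictly
  # causal per-epoch recursion inside each chunk
  chunk_size <- 8L
  chunks <- split(seq_along(epochs),
                  ceiling(seq_along(epochs) / chunk_size))
  for (ch in chunks) {
    frames <- src$get_chunk(epochs[ch])
    spec <- epoch_spectra(frames, en$window)
    fp <- frame_power_from_spectra(spec$P, spec$sp)
    PE <- spec$P
    floors <- numeric(length(ch))
    for (j in seq_along(ch)) {
      cols <- (j - 1L) * fpe + seq_len(fpe)
      profile <- profile_from_spectra(spec$P[, cols, drop = FALSE], spec$sp,
                                      profile, en, fp[cols])
      floors[j] <- profile$floor_db
      PE[, cols] <- spec$P[, cols] *
        wiener_gain_sq(spec$P[, cols, drop = FALSE], profile$magnitude^2, en)
    }
    ff_all <- frame_features_from_spectra(PE, spec$win, spec$sp)
    cm_all <- curves_from_features(ff_all, detector)
    for (j in seq_along(ch)) {
      i <- ch[j]
      t <- epochs[i]
      rws <- (j - 1L) * fpe + seq_len(fpe)
      ff <- ff_all[rws, , drop = FALSE]
      cm <- cm_all[rws, , drop = FALSE]
      events <- segment_breath_events(cm, frame_intensity = ff[, "log_energy"],
                                      config = config)
      v <- assemble_epoch_features(ff, cm, events, floors[j], meta, t,
                                   state, config)
      state <- attr(v, "state")
      attr(v, "state") <- NULL
      rows[[i]] <- v
      if (return_curves) curves_out[[i]] <- cm
    }
  }
  X <- do.call(rbind, rows)
  out <- as_tibble(as.data.frame(X))
  out <- bind_cols(tibble(epoch = epochs), out)
  attr(out, "registry") <- registry_hash()
  if (return_curves) {
    names(curves_out) <- as.character(epochs)
    attr(out, "curves") <- curves_out
  }
  out
}

#' Stage a night of audio
#'
#' The full estimation chain: features, real-time cascade scores, offline
#' re-scoring, labels and the eight-parameter sleep report (computed from
#' the offline hypnogram, or the real-time one with
#' `realtime_only = TRUE`).
#'
#' @param x audio or simulated night (see [extract_night_features()]).
#' @param detector a trained [train_detector()] model.
#' @param cascades a [train_cascades()] fit.
#' @param meta subject metadata (`age`, `gender`, `bmi`).
#' @param config an [acusleep_config()].
#' @param realtime_only skip the offline pass.
#' @return A list of class `staged_night`: `scores` (tibble with `epoch`,
#'   `rt_pW`, `rt_pR`, `rt_pN`, `rt_label` and offline counterparts),
#'   `report` (a `sleep_report`), `features`, and provenance hashes.
#' @export
stage_night <- function(x, detector, cascades, meta = NULL,
                        config = acusleep_config(), realtime_only = FALSE) {
  feats <- extract_night_features(x, detector, meta, config)
  rt <- classify_night_realtime(feats, cascades$realtime)
  scores <- tibble(
    epoch = rt$epoch, rt_pW = rt$p_W, rt_pR = rt$p_R, rt_pN = rt$p_N,
    rt_label = rt$label
  )
  final <- rt$label
  if (!realtime_only) {
    off <- classify_night_offline(rt, cascades$offline)
    scores$off_pW <- off$p_W; scores$off_pR <- off$p_R
    scores$off_pN <- off$p_N; scores$off_label <- off$label
    final <- off$label
  }
  structure(
    list(
      scores = scores,
      report = compute_report(hypnogram(final), config),
      features = feats,
      realtime_only = realtime_only,
      config_hash = config_hash(config),
      registry = registry_hash()
    ),
    class = "staged_night"
  )
}

#' @export
print.staged_night <- function(x, ...) {
  tab <- table(factor(
    if (x$realtime_only) x$scores$rt_label else x$scores$off_label,
    levels = STAGES
  ))
  cat(sprintf("<staged_night> %d epochs | W %d / R %d / N %d (%s pass)\n",
              nrow(x$scores), tab["W"], tab["R"], tab["N"],
              if (x$realtime_only) "real-time" else "offline"))
  print(x$report)
  invisible(x)
}

#' Collect labeled detector-training frames from simulated nights
#'
#' Samples epochs across simulated nights, runs the causal
#' enhancement/feature chain, and pairs each frame's acoustic features
#' with its ground-truth event label, balanced across the four classes.
#'
#' @param nights list of [simulate_night()] objects.
#' @param config an [acusleep_config()].
#' @param epochs_per_night epochs sampled per night.
#' @param frames_per_class frames kept per class after pooling.
#' @return A tibble of frame features plus `label`, ready for
#'   [train_detector()].
#' @export
collect_detector_frames <- function(nights, config = acusleep_config(),
                                    epochs_per_night = 30L,
                                    frames_per_class = 5000L) {
  en <- config$enhancement
  set.seed(derive_seed(config$seed, 53L))
  pool_x <- list(); pool_y <- list()
  for (night in nights) {
    T <- night$n_epochs
    eps <- sort(sample.int(T, min(epochs_per_night, T)))
    src <- night_source(night)
    profile <- NULL
    for (t in eps) {
      ep <- src$get_chunk(t)
      spec <- epoch_spectra(ep, en$window)
      raw_power <- frame_power_from_spectra(spec$P, spec$sp)
      profile <- profile_from_spectra(spec$P, spec$sp, profile, en, raw_power)
      G2 <- wiener_gain_sq(spec$P, profile$magnitude^2, en)
      ff <- frame_features_from_spectra(spec$P * G2, spec$win, spec$sp)
      labs <- night$frame_labels[(t - 1) * ACU_FRAMES_PER_EPOCH +
                                   seq_len(ACU_FRAMES_PER_EPOCH)]
      pool_x[[length(pool_x) + 1L]] <- ff
      pool_y[[length(pool_y) + 1L]] <- as.character(labs)
    }
  }
  X <- do.call(rbind, pool_x)
  y <- unlist(pool_y)
  keep <- unlist(lapply(EVENT_CLASSES, function(cl) {
    idx <- which(y == cl)
    if (length(idx) > frames_per_class) {
      idx <- sample(idx, frames_per_class)
    }
    idx
  }))
  keep <- sort(keep)
  out <- as_tibble(as.data.frame(X[keep, , drop = FALSE]))
  out$label <- y[keep]
  out
}

#' Export probability curves as a tidy table
#'
#' Runs detection over (a subset of) a night and returns the four curves
#' in long-night form, one row per 50 ms frame.
#'
#' @inheritParams extract_night_features
#' @return A tibble: `epoch`, `frame`, `night_time_s`, `p_in`, `p_ex`,
#'   `p_bm`, `p_os`.
#' @export
detect_night_curves <- function(x, detector, config = acusleep_config(),
                                epochs = NULL) {
  feats <- extract_night_features(x, detector,
                                  meta = list(age = 40, gender = 0, bmi = 25),
                                  config = config, epochs = epochs,
                                  return_curves = TRUE)
  curves <- attr(feats, "curves")
  bind_rows(purrr::imap(curves, function(cm, ep) {
    ep <- as.integer(ep)
    tibble(
      epoch = ep, frame = seq_len(nrow(cm)) - 1L,
      night_time_s = (ep - 1) * 30 + (seq_len(nrow(cm)) - 1L) * 0.05,
      p_in = cm[, 1], p_ex = cm[, 2], p_bm = cm[, 3], p_os = cm[, 4]
    )
  }))
}
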