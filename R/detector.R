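FRAME_FEATURE_NAMES <- c(
  "log_energy", "spectral_entropy", "spectral_centroid", "spectral_rolloff",
  "zcr", paste0("band", 1:4), paste0("cep", 1:8)
)

#' Per-frame acoustic features
#'
#' Computes the fixed 17-feature acoustic description of each 50 ms frame:
#' log energy (dB), normalized spectral entropy, spectral centroid and 95%
#' roll-off (Hz), zero-crossing rate, four band-energy ratios
#' (50-300, 300-1000, 1000-2000, 2000-8000 Hz) and cepstral coefficients
#' 1-8 (DCT of 24 log-spaced log band energies). All-zero (digitally silent)
#' frames map to a defined vector: log energy at the -100 dB floor, entropy
#' at its maximum of 1, remaining features 0.
#'
#' @param frames a `2205 x m` frame matrix (typically enhanced audio), or a
#'   single frame vector.
#' @param config an [acusleep_config()].
#' @return A tibble with `m` rows and the 17 feature columns.
#' @export
frame_acoustic_features <- function(frames, config = acusleep_config()) {
  if (is.null(dim(frames))) frames <- matrix(frames, ncol = 1)
  spec <- epoch_spectra(frames, config$enhancement$window)
  as_tibble(frame_features_from_spectra(spec$P, spec$win, spec$sp))
}

# Internal vectorized path; P = power spectra (nb x m), win = windowed rows.
# Returns an m x 17 matrix.
frame_features_from_spectra <- function(P, win, sp) {
  m <- ncol(P)
  tot <- colSums(P)
  silent <- tot <= 1e-20

  frame_pow <- frame_power_from_spectra(P, sp)
  log_energy <- power_to_db(frame_pow, ACU_LOGE_FLOOR)

  safe_tot <- ifelse(silent, 1, tot)
  Pn <- sweep(P, 2, safe_tot, "/")
  entropy <- -colSums(Pn * log(Pn + 1e-15)) / log(nrow(P))
  centroid <- colSums(P * sp$freqs) / safe_tot

  # roll-off from 64 log-spaced bands via a triangular cumulator
  B <- sp$ro_bands %*% P
  cum <- sp$ro_cum %*% B
  k <- colSums(sweep(cum, 2, 0.95 * colSums(B), "<")) + 1L
  rolloff <- sp$ro_upper[pmin(k, length(sp$ro_upper))]

  # zero-crossing rate from the central half of the analysis window
  L <- nrow(win)
  zcr <- zcr_fast(win[(L %/% 4 + 1L):(3L * L %/% 4), , drop = FALSE])

  bands <- sp$band_mat %*% P
  band_ratio <- sweep(bands, 2, safe_tot, "/")

  CB <- sp$cep_bands %*% P
  ceps <- sp$dct %*% log(CB + 1e-12)

  out <- cbind(log_energy, entropy, centroid, rolloff, zcr,
               t(band_ratio), t(ceps))
  colnames(out) <- FRAME_FEATURE_NAMES
  if (any(silent)) {
    out[silent, ] <- 0
    out[silent, "log_energy"] <- ACU_LOGE_FLOOR
    out[silent, "spectral_entropy"] <- 1
  }
  out
}

# zcr via apply(diff) is slow for big m; vectorized variant used by the
# night engine
zcr_fast <- function(win) {
  sgn <- win > 0
  colMeans(abs(sgn[-1, , drop = FALSE] - sgn[-nrow(sgn), , drop = FALSE]))
}

#' Train the frame-level sound-event detector
#'
#' Fits the four-class frame classifier (inhalation / exhalation /
#' body-movement / other sounds) on labeled frame features. A single
#' normalized four-class model plays the role of the parallel
#' breathing and body-movement detectors: its softmax outputs are the four
#' probability curves consumed downstream. Features are z-scored with
#' training-set statistics stored in the model; training is reproducible
#' from the seed.
#'
#' @param data a data frame with the 17 frame-feature columns (see
#'   [frame_acoustic_features()]) and a `label` column with values from
#'   `c("inhale", "exhale", "body_movement", "other")` (at least two classes
#'   present).
#' @param config an [acusleep_config()]; the `detector` block sets the
#'   architecture and optimizer.
#' @return An object of class `event_detector`.
#' @export
train_detector <- function(data, config = acusleep_config()) {
  if (!"label" %in% names(data)) abort("data must contain a 'label' column")
  labs <- factor(as.character(data$label),
                 levels = intersect(EVENT_CLASSES, unique(as.character(data$label))))
  if (nlevels(labs) < 2) {
    abort("detector training needs at least two event classes")
  }
  x <- as.matrix(data[, FRAME_FEATURE_NAMES])
  de <- config$detector
  seed <- derive_seed(config$seed, 11L)
  set.seed(seed)
  n <- nrow(x)
  val_idx <- if (de$val_frac > 0 && n >= 10) {
    sample.int(n, max(1L, floor(n * de$val_frac)))
  } else NULL
  freq <- table(labs)
  cw <- as.numeric(sum(freq) / (nlevels(labs) * freq))
  fit <- mlp_fit(x, labs, hidden = de$hidden, class_weights = cw,
                 val_idx = val_idx, max_iter = de$max_iter,
                 learn_rate = de$learn_rate, patience = de$patience,
                 l2 = de$l2, seed = seed)
  acc <- if (!is.null(val_idx)) {
    pred <- fit$classes[max.col(mlp_predict(fit, x[val_idx, , drop = FALSE]))]
    mean(pred == as.character(labs[val_idx]))
  } else NA_real_
  structure(
    list(mlp = fit, classes = fit$classes, holdout_accuracy = acc,
         n_frames = n, seed = seed, version = "1",
         config = config$detector),
    class = "event_detector"
  )
}

#' Predict frame labels from a detector
#'
#' Hard labels (argmax of the four probability curves) for a table of
#' frame features.
#'
#' @param model an `event_detector`.
#' @param data a data frame with the 17 frame-feature columns.
#' @return Character vector of predicted classes.
#' @export
predict_frame_labels <- function(model, data) {
  P <- mlp_predict(model$mlp, as.matrix(data[, FRAME_FEATURE_NAMES]))
  colnames(P)[max.col(P, ties.method = "first")]
}

#' @export
print.event_detector <- function(x, ...) {
  cat(sprintf(
    "<event_detector> classes: %s | %d training frames | held-out accuracy %s\n",
    paste(x$classes, collapse = "/"), x$n_frames,
    ifelse(is.na(x$holdout_accuracy), "NA",
           sprintf("%.3f", x$holdout_accuracy))
  ))
  invisible(x)
}

#' Detect breathing and movement events in one epoch
#'
#' Runs the frame detector over a (noise-suppressed) epoch and returns the
#' four probability curves at 50 ms resolution: inhalation, exhalation,
#' body movement and other sounds. Each frame's quadruple sums to one.
#' Digitally silent frames are mapped deterministically to "other".
#' Inference is causal: each frame's probabilities depend on that frame
#' only.
#'
#' @param epoch a `2205 x 600` enhanced frame matrix (a `2205 x m` matrix is
#'   accepted for partial epochs).
#' @param model an [train_detector()] fit, or `NULL` for the untrained
#'   uniform prior (every frame gets probability 1/4 per class).
#' @param config an [acusleep_config()].
#' @return A tibble with columns `frame` (0-based), `p_in`, `p_ex`, `p_bm`,
#'   `p_os`.
#' @export
detect_events <- function(epoch, model = NULL, config = acusleep_config()) {
  spec <- epoch_spectra(epoch, config$enhancement$window)
  ff <- frame_features_from_spectra(spec$P, spec$win, spec$sp)
  curves_tibble(curves_from_features(ff, model))
}

# feature matrix (m x 17) -> m x 4 probability matrix, columns in
# EVENT_CLASSES order
curves_from_features <- function(ff, model) {
  m <- nrow(ff)
  out <- matrix(0.25, m, 4, dimnames = list(NULL, EVENT_CLASSES))
  if (!is.null(model)) {
    if (!inherits(model, "event_detector")) {
      abort("model must be an event_detector (or NULL for the uniform prior)")
    }
    P <- mlp_predict(model$mlp, ff)
    out[, colnames(P)] <- P
    missing <- setdiff(EVENT_CLASSES, colnames(P))
    if (length(missing)) out[, missing] <- 0
    out <- out / rowSums(out)
  }
  silent <- ff[, "log_energy"] <= ACU_LOGE_FLOOR + 1e-9
  if (any(silent)) {
    out[silent, ] <- rep(c(0, 0, 0, 1), each = sum(silent))
  }
  out
}

curves_tibble <- function(cm) {
  new_tibble(list(
    frame = seq_len(nrow(cm)) - 1L,
    p_in = unname(cm[, "inhale"]), p_ex = unname(cm[, "exhale"]),
    p_bm = unname(cm[, "body_movement"]), p_os = unname(cm[, "other"])
  ), class = "event_curves")
}

# accept either the tibble form or a bare matrix with the four columns
curves_matrix <- function(curves) {
  if (is.matrix(curves)) {
    stopifnot(ncol(curves) == 4)
    colnames(curves) <- EVENT_CLASSES
    return(curves)
  }
  cm <- cbind(curves$p_in, curves$p_ex, curves$p_bm, curves$p_os)
  colnames(cm) <- EVENT_CLASSES
  cm
}
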