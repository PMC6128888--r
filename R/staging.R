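# Cascaded sleep-stage classifiers.
#
# Real-time cascade C(r): six periods over the epoch index t. Period 1
# (t <= 5) is the constant-Wake rule; periods 2..6 are feedforward networks
# over the concatenated feature vectors of the current epoch and its
# lookback window (5 / 20 / 50 / 100 / 200 epochs, hidden units
# 100 / 400 / 1000 / 1000 / 1000). The offline cascade C(o) runs backward
# over the real-time score sequence with lookahead windows
# (5 / 20 / 50 / 100 / 200, hidden units 20 / 50 / 100 / 200 / 200);
# epochs with T - 5 <= t keep their real-time scores.

RT_LOOKBACK <- c(5L, 20L, 50L, 100L, 200L)
OFF_LOOKAHEAD <- c(5L, 20L, 50L, 100L, 200L)

#' Real-time cascade period of an epoch
#'
#' Piecewise mapping from the 1-based epoch index to the cascade period:
#' `t <= 5` is period 1, `5 < t <= 20` period 2, `20 < t <= 50` period 3,
#' `50 < t <= 100` period 4, `100 < t <= 200` period 5, `200 < t` period 6.
#'
#' @param t 1-based epoch index (vectorized).
#' @return Integer period(s) in 1..6.
#' @export
select_period_realtime <- function(t) {
  if (any(t < 1)) abort("epoch index t is 1-based")
  findInterval(t, c(-Inf, 5, 20, 50, 100, 200), left.open = TRUE)
}

#' Offline cascade period of an epoch
#'
#' For a night of `T` epochs: `T - 5 <= t` is period 1 (real-time scores
#' kept), `T - 20 <= t < T - 5` period 2, down to `0 < t < T - 200`
#' period 6. Equivalently the smallest period whose window reaches `t`,
#' which also degrades gracefully for nights shorter than 200 epochs.
#'
#' @param t 1-based epoch index (vectorized).
#' @param T total number of epochs in the night.
#' @return Integer period(s) in 1..6.
#' @export
select_period_offline <- function(t, T) {
  if (any(t < 1) || any(t > T)) abort("epoch index t must be in 1..T")
  findInterval(T - t, c(-Inf, 5, 20, 50, 100, 200), left.open = TRUE)
}

#' Input vector of a real-time sub-classifier
#'
#' Concatenation of the 67-feature epoch vectors for epochs
#' `t - k, ..., t` (current epoch included), length `67 * (k + 1)`.
#' Z-scoring with training statistics happens inside the fitted
#' sub-classifier.
#'
#' @param X feature matrix (epochs x 67), rows 1..T in epoch order.
#' @param t 1-based epoch index.
#' @param lookback window length `k`.
#' @return Numeric vector of length `67 * (k + 1)`.
#' @export
build_realtime_input <- function(X, t, lookback) {
  X <- feature_matrix(X)
  if (t - lookback < 1) {
    abort(sprintf("epoch %d has no %d-epoch history", t, lookback))
  }
  as.numeric(t(X[(t - lookback):t, , drop = FALSE]))
}

# rows = epochs in the period, windowed inputs stacked; used by training
# and night-level inference. ts must all satisfy ts - k >= 1.
stack_windows <- function(X, ts, k) {
  d <- ncol(X)
  out <- matrix(0, length(ts), d * (k + 1L))
  for (j in 0:k) {
    out[, j * d + seq_len(d)] <- X[ts - k + j, , drop = FALSE]
  }
  out
}

feature_matrix <- function(X) {
  if (is.matrix(X)) return(X)
  nm <- feature_registry()$name
  if (!all(nm %in% names(X))) {
    abort("feature table lacks registry columns; see feature_registry()")
  }
  as.matrix(X[, nm])
}

#' Score one epoch with the real-time cascade
#'
#' Strictly causal: epochs 1..5 are Wake with probability 1 by rule; later
#' epochs are scored by their period's sub-classifier from the features of
#' the lookback window.
#'
#' @param X feature matrix or tibble (epochs x 67) covering at least
#'   epochs 1..t.
#' @param t 1-based epoch index.
#' @param cascade a trained `realtime_cascade` (from [train_cascades()]).
#' @return A one-row tibble `p_W`, `p_R`, `p_N`.
#' @export
classify_epoch_realtime <- function(X, t, cascade) {
  scores <- classify_night_realtime(X, cascade, epochs = t)
  scores[1, c("p_W", "p_R", "p_N")]
}

#' Score a night with the real-time cascade
#'
#' @param X feature matrix or tibble (epochs x 67) for epochs 1..T.
#' @param cascade a trained `realtime_cascade`.
#' @param epochs epochs to score (default all).
#' @return A tibble with `epoch`, `p_W`, `p_R`, `p_N`, `label`.
#' @export
classify_night_realtime <- function(X, cascade, epochs = NULL) {
  check_cascade(cascade, "realtime_cascade")
  Xm <- impute_features(feature_matrix(X), cascade$medians)
  T <- nrow(Xm)
  epochs <- epochs %||% seq_len(T)
  S <- matrix(0, length(epochs), 3, dimnames = list(NULL, STAGES))
  per <- select_period_realtime(epochs)
  S[per == 1L, "W"] <- 1
  for (p in sort(unique(per[per > 1L]))) {
    ts <- epochs[per == p]
    sub <- cascade_submodel(cascade, p)
    k <- RT_LOOKBACK[sub$period_used - 1L]
    S[per == p, ] <- predict_scores(sub$fit, stack_windows(Xm, ts, k))
  }
  tibble(epoch = epochs, p_W = S[, "W"], p_R = S[, "R"], p_N = S[, "N"],
         label = scores_to_label(S))
}

#' Re-score a night with the offline cascade
#'
#' Runs backward over the completed night's real-time scores. Epochs with
#' `T - 5 <= t` keep their real-time scores; earlier epochs are re-scored
#' by their period's sub-classifier fed the flattened real-time score
#' triplets of epochs `t .. t + k` plus the epoch index. Nights shorter
#' than 6 epochs keep all real-time scores.
#'
#' @param realtime_scores tibble from [classify_night_realtime()] (or a
#'   T x 3 matrix of W/R/N scores).
#' @param cascade a trained `offline_cascade`.
#' @return A tibble with `epoch`, `p_W`, `p_R`, `p_N`, `label`.
#' @export
classify_night_offline <- function(realtime_scores, cascade) {
  check_cascade(cascade, "offline_cascade")
  R <- rt_score_matrix(realtime_scores)
  T <- nrow(R)
  S <- R
  if (T >= 6) {
    per <- select_period_offline(seq_len(T), T)
    for (p in sort(unique(per[per > 1L]), decreasing = FALSE)) {
      ts <- which(per == p)
      sub <- cascade_submodel(cascade, p)
      k <- OFF_LOOKAHEAD[sub$period_used - 1L]
      inp <- cbind(stack_windows_forward(R, ts, k), ts)
      # backward in time, as the cascade is defined
      ord <- order(ts, decreasing = TRUE)
      S[ts[ord], ] <- predict_scores(sub$fit, inp[ord, , drop = FALSE])
    }
  }
  tibble(epoch = seq_len(T), p_W = S[, "W"], p_R = S[, "R"], p_N = S[, "N"],
         label = scores_to_label(S))
}

stack_windows_forward <- function(R, ts, k) {
  d <- ncol(R)
  out <- matrix(0, length(ts), d * (k + 1L))
  for (j in 0:k) {
    out[, j * d + seq_len(d)] <- R[ts + j, , drop = FALSE]
  }
  out
}

rt_score_matrix <- function(realtime_scores) {
  if (is.matrix(realtime_scores)) {
    stopifnot(ncol(realtime_scores) == 3)
    colnames(realtime_scores) <- STAGES
    return(realtime_scores)
  }
  R <- cbind(realtime_scores$p_W, realtime_scores$p_R, realtime_scores$p_N)
  colnames(R) <- STAGES
  R
}

#' Convert stage scores to labels
#'
#' Argmax of the (W, R, N) scores; exact ties resolve by the fixed priority
#' N > R > W (sleep over wake, the rarer sleep stage over wake).
#'
#' @param scores a tibble or matrix with `p_W`, `p_R`, `p_N` columns (or
#'   W/R/N).
#' @return Character vector of labels in `c("W", "R", "N")`.
#' @export
scores_to_label <- function(scores) {
  S <- if (is.matrix(scores)) scores else rt_score_matrix(scores)
  pri <- S[, c("N", "R", "W"), drop = FALSE]
  c("N", "R", "W")[max.col(pri, ties.method = "first")]
}

# sub-classifier probabilities mapped onto the full W/R/N columns (a
# sub-classifier trained where a stage never occurred emits 0 for it)
predict_scores <- function(fit, X) {
  P <- mlp_predict(fit, X)
  out <- matrix(0, nrow(P), 3, dimnames = list(NULL, STAGES))
  out[, colnames(P)] <- P
  out
}

check_cascade <- function(cascade, cls) {
  if (!inherits(cascade, cls) || is.null(cascade$models)) {
    abort(sprintf("expected a trained %s from train_cascades()", cls))
  }
}

# period -> fitted sub-model; untrained periods fall back to the largest
# trained shorter-window period when the cascade was built with
# allow_missing_periods = TRUE
cascade_submodel <- function(cascade, p) {
  for (q in seq(p, 2L)) {
    fit <- cascade$models[[q - 1L]]
    if (!is.null(fit)) return(list(fit = fit, period_used = q))
  }
  abort("cascade has no trained sub-classifier applicable to this period")
}

impute_features <- function(Xm, medians) {
  sent <- Xm == ACU_SENTINEL
  if (any(sent)) {
    idx <- which(sent, arr.ind = TRUE)
    Xm[sent] <- medians[idx[, 2]]
  }
  Xm
}

#' Cascade architecture self-description
#'
#' The period boundaries, window lengths and hidden-unit counts of both
#' cascades as configured, for inspection and configuration self-tests.
#'
#' @param config an [acusleep_config()].
#' @return A tibble with one row per (cascade, period).
#' @export
cascade_structure <- function(config = acusleep_config()) {
  st <- config$staging
  bind_rows(
    tibble(
      cascade = "realtime", period = 1:6,
      window = c(0L, st$rt_lookback), hidden = c(0L, st$rt_hidden),
      rule = c("constant Wake",
               sprintf("%d < t <= %d", c(5L, 20L, 50L, 100L),
                       c(20L, 50L, 100L, 200L)), "200 < t")
    ),
    tibble(
      cascade = "offline", period = 1:6,
      window = c(0L, st$off_lookahead), hidden = c(0L, st$off_hidden),
      rule = c("T - 5 <= t (real-time kept)",
               sprintf("T - %d <= t < T - %d", c(20L, 50L, 100L, 200L),
                       c(5L, 20L, 50L, 100L)), "0 < t < T - 200")
    )
  )
}
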