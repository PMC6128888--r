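#' Tidy an event detector
#'
#' One row per event class with its training prevalence in the fitted
#' model's frame set.
#'
#' @param x an `event_detector`.
#' @param ... unused.
#' @return A tibble.
#' @export
tidy.event_detector <- function(x, ...) {
  tibble(class = x$classes)
}

#' Glance at an event detector
#'
#' @param x an `event_detector`.
#' @param ... unused.
#' @return A one-row tibble with fit summaries.
#' @export
glance.event_detector <- function(x, ...) {
  tibble(
    n_frames = x$n_frames, hidden = x$mlp$hidden,
    holdout_accuracy = x$holdout_accuracy,
    final_loss = x$mlp$loss, iterations = length(x$mlp$trace),
    seed = x$seed
  )
}

#' Tidy a cascade pair
#'
#' One row per (cascade, period) with window length, hidden units and
#' whether the sub-classifier is trained.
#'
#' @param x an `mss_cascades` object from [train_cascades()].
#' @param ... unused.
#' @return A tibble.
#' @export
tidy.mss_cascades <- function(x, ...) {
  bind_rows(
    tibble(cascade = "realtime", period = 1:6,
           window = c(0L, x$realtime$lookback),
           hidden = c(0L, x$realtime$hidden),
           trained = c(TRUE, !vapply(x$realtime$models, is.null, logical(1)))),
    tibble(cascade = "offline", period = 1:6,
           window = c(0L, x$offline$lookahead),
           hidden = c(0L, x$offline$hidden),
           trained = c(TRUE, !vapply(x$offline$models, is.null, logical(1))))
  )
}

#' Glance at a cascade pair
#'
#' @param x an `mss_cascades` object.
#' @param ... unused.
#' @return A one-row tibble with development-set accuracy of both passes.
#' @export
glance.mss_cascades <- function(x, ...) {
  tibble(
    dev_accuracy_realtime = unname(x$dev_accuracy["realtime"]),
    dev_accuracy_offline = unname(x$dev_accuracy["offline"]),
    n_dev_nights = length(x$dev_ids),
    registry = x$registry, seed = x$seed
  )
}

#' Tidy a sleep report
#'
#' Long form: one row per parameter with value and unit.
#'
#' @param x a `sleep_report`.
#' @param ... unused.
#' @return A tibble with `parameter`, `value`, `unit`.
#' @export
tidy.sleep_report <- function(x, ...) {
  tibble(
    parameter = c("TST", "SL", "SE", "WASO", "RL", "RP", "NP", "RC"),
    value = c(x$tst_min, x$sl_min, x$se_pct, x$waso_min, x$rl_min,
              x$rp_pct, x$np_pct, x$rc_count),
    unit = c("min", "min", "%", "min", "min", "%", "%", "cycles")
  )
}

#' @export
tidy.confusion_matrix <- function(x, ...) {
  d <- as_tibble(expand.grid(ref = rownames(x), est = colnames(x),
                             stringsAsFactors = FALSE))
  d$count <- as.vector(unclass(x))
  d$row_pct <- as.vector(per_class_rates(x))
  d
}
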