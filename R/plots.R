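#' Plot a hypnogram
#'
#' Standard step plot of the stage sequence, wake on top.
#'
#' @param object a [hypnogram()].
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.hypnogram <- function(object, ...) {
  d <- mutate(object,
              level = c(W = 3, R = 2, N = 1)[as.character(.data$stage)],
              time_h = (.data$epoch - 1) / 120)
  ggplot(d, aes(x = .data$time_h, y = .data$level)) +
    geom_step() +
    scale_y_continuous(breaks = 1:3, labels = c("NREM", "REM", "Wake"),
                       limits = c(0.8, 3.2)) +
    labs(x = "Time (h)", y = NULL, title = "Hypnogram") +
    theme_minimal()
}

#' Plot event probability curves
#'
#' The four per-frame likelihood curves of one epoch (inhalation,
#' exhalation, body movement, other sounds).
#'
#' @param object an `event_curves` tibble from [detect_events()].
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.event_curves <- function(object, ...) {
  d <- tidyr::pivot_longer(as_tibble(object), c("p_in", "p_ex", "p_bm", "p_os"),
                           names_to = "curve", values_to = "p")
  d$curve <- factor(d$curve, levels = c("p_in", "p_ex", "p_bm", "p_os"),
                    labels = c("Inhale", "Exhale", "Body movement", "Other"))
  ggplot(d, aes(x = .data$frame * 0.05, y = .data$p)) +
    geom_line() +
    facet_wrap(~curve, ncol = 1) +
    labs(x = "Time in epoch (s)", y = "Likelihood") +
    theme_minimal()
}

#' Plot staged-night scores
#'
#' Real-time and (when present) offline stage probability scores across
#' the night.
#'
#' @param object a `staged_night` from [stage_night()].
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.staged_night <- function(object, ...) {
  s <- object$scores
  long <- list(tibble(pass = "real-time", epoch = s$epoch,
                      W = s$rt_pW, R = s$rt_pR, N = s$rt_pN))
  if (!object$realtime_only) {
    long[[2]] <- tibble(pass = "offline", epoch = s$epoch,
                        W = s$off_pW, R = s$off_pR, N = s$off_pN)
  }
  d <- tidyr::pivot_longer(bind_rows(long), c("W", "R", "N"),
                           names_to = "stage", values_to = "p")
  ggplot(d, aes(x = .data$epoch / 120, y = .data$p, colour = .data$stage)) +
    geom_line() +
    facet_wrap(~pass, ncol = 1) +
    labs(x = "Time (h)", y = "Stage probability", colour = "Stage") +
    theme_minimal()
}

#' Confusion-matrix heat map
#'
#' Row-normalized percentages with counts overlaid.
#'
#' @param cm a [confusion_matrix()].
#' @return A ggplot object.
#' @export
plot_confusion <- function(cm) {
  r <- per_class_rates(cm)
  d <- as_tibble(expand.grid(ref = rownames(cm), est = colnames(cm)))
  d$count <- as.vector(cm)
  d$pct <- as.vector(r)
  ggplot(d, aes(x = .data$est, y = .data$ref, fill = .data$pct)) +
    geom_tile() +
    geom_text(aes(label = sprintf("%d\n(%.1f%%)", .data$count, .data$pct))) +
    scale_fill_gradient(low = "white", high = "steelblue") +
    labs(x = "Estimated", y = "Reference", fill = "% of row") +
    theme_minimal()
}

#' Bland-Altman plot
#'
#' Differences against means with bias and 95% limits of agreement.
#'
#' @param x,y paired measurements (reference, estimate).
#' @param label optional axis label for the measured quantity.
#' @return A ggplot object.
#' @export
plot_bland_altman <- function(x, y, label = "measurement") {
  ba <- bland_altman(x, y)
  d <- tibble(m = (x + y) / 2, d = y - x)
  ggplot(d, aes(x = .data$m, y = .data$d)) +
    geom_point() +
    geom_hline(yintercept = ba$bias) +
    geom_hline(yintercept = c(ba$lower_loa, ba$upper_loa), linetype = 2) +
    labs(x = sprintf("Mean of methods (%s)", label),
         y = "Difference (estimate - reference)") +
    theme_minimal()
}
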