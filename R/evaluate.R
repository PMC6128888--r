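#' Epoch-by-epoch confusion matrix
#'
#' 3 x 3 counts of reference (rows, e.g. PSG) versus estimated (columns)
#' stage labels at 30 s epoch resolution.
#'
#' @param ref,est hypnograms (or label vectors) of equal length.
#' @return An integer matrix with W/R/N dimnames (`ref` x `est`).
#' @export
confusion_matrix <- function(ref, est) {
  r <- stage_vector(ref); e <- stage_vector(est)
  if (length(r) != length(e)) {
    abort("reference and estimate cover different numbers of epochs")
  }
  m <- table(factor(r, levels = STAGES), factor(e, levels = STAGES))
  cm <- matrix(as.integer(m), 3, 3, dimnames = list(ref = STAGES, est = STAGES))
  class(cm) <- c("confusion_matrix", class(cm))
  cm
}

as_cm <- function(cm) {
  if (!is.matrix(cm) || nrow(cm) != ncol(cm)) {
    abort("expected a square confusion matrix")
  }
  cm
}

#' Overall percent agreement
#'
#' `100 * trace / total` of a confusion matrix.
#'
#' @param cm a confusion matrix (any square size; 2- or 3-class here).
#' @return Percent agreement.
#' @export
accuracy <- function(cm) {
  cm <- as_cm(cm)
  tot <- sum(cm)
  if (tot == 0) abort("empty confusion matrix")
  100 * sum(diag(cm)) / tot
}

#' Cohen's kappa
#'
#' Chance-corrected agreement `(p_o - p_e) / (1 - p_e)` with the expected
#' agreement from the row/column marginal products. Returns `NA` with a
#' warning when `p_e == 1` (both raters degenerate on one class).
#'
#' @param cm a confusion matrix.
#' @return Kappa in `[-1, 1]`, or `NA` when undefined.
#' @export
cohens_kappa <- function(cm) {
  cm <- as_cm(cm)
  tot <- sum(cm)
  if (tot == 0) abort("empty confusion matrix")
  po <- sum(diag(cm)) / tot
  pe <- sum(rowSums(cm) * colSums(cm)) / tot^2
  if (abs(1 - pe) < 1e-12) {
    warn("kappa undefined: expected agreement is 1")
    return(NA_real_)
  }
  (po - pe) / (1 - pe)
}

#' Collapse three stages to sleep/wake
#'
#' Merges R and N into a single sleep class `S`. Works on hypnograms,
#' label vectors and confusion matrices (counts are additive).
#'
#' @param x a hypnogram, label vector, or 3 x 3 confusion matrix.
#' @return Two-class labels (`W`/`S`) or a 2 x 2 confusion matrix.
#' @export
collapse_sleep_wake <- function(x) {
  if (is.matrix(x)) {
    cm <- as_cm(x)
    g <- c(W = "W", R = "S", N = "S")[rownames(cm)]
    out <- rowsum(t(rowsum(cm, g)), g)
    out <- out[c("W", "S"), c("W", "S")]
    dimnames(out) <- list(ref = c("W", "S"), est = c("W", "S"))
    class(out) <- c("confusion_matrix", class(out))
    return(out)
  }
  ifelse(stage_vector(x) == "W", "W", "S")
}

#' Row-normalized class rates
#'
#' Each reference row of the confusion matrix expressed as percentages of
#' the row total (the diagonal is per-class recall). Full precision is
#' returned; display rounding to one decimal is the caller's choice.
#' Rows with zero total are `NA`.
#'
#' @param cm a confusion matrix.
#' @return A numeric matrix of percentages with the same dimnames.
#' @export
per_class_rates <- function(cm) {
  cm <- as_cm(cm)
  rs <- rowSums(cm)
  out <- sweep(cm, 1, ifelse(rs > 0, rs, NA), "/") * 100
  matrix(as.numeric(out), nrow(cm), ncol(cm), dimnames = dimnames(cm))
}

#' Lin's concordance correlation coefficient
#'
#' Agreement of paired continuous measurements against the identity line:
#' `2 cov(x, y) / (var(x) + var(y) + (mean(x) - mean(y))^2)`, with
#' population (1/n) moment estimators.
#'
#' @param x,y numeric vectors of equal length (n >= 2).
#' @return The concordance correlation coefficient.
#' @export
concordance_correlation <- function(x, y) {
  if (length(x) != length(y)) abort("x and y lengths differ")
  n <- length(x)
  if (n < 2) abort("need at least two pairs")
  if (var(x) == 0 && var(y) == 0 && mean(x) == mean(y)) return(1)
  mx <- mean(x); my <- mean(y)
  sxy <- mean((x - mx) * (y - my))
  sx2 <- mean((x - mx)^2); sy2 <- mean((y - my)^2)
  2 * sxy / (sx2 + sy2 + (mx - my)^2)
}

#' Bland-Altman limits of agreement
#'
#' Bias (mean of `y - x`) and the 95% limits `bias +/- 1.96 sd(y - x)`.
#'
#' @param x,y numeric vectors of equal length (n >= 2).
#' @return A one-row tibble: `bias`, `lower_loa`, `upper_loa`, `sd_diff`,
#'   `n`.
#' @export
bland_altman <- function(x, y) {
  if (length(x) != length(y)) abort("x and y lengths differ")
  if (length(x) < 2) abort("need at least two pairs")
  d <- y - x
  b <- mean(d); s <- sd(d)
  tibble(bias = b, lower_loa = b - 1.96 * s, upper_loa = b + 1.96 * s,
         sd_diff = s, n = length(d))
}

#' Agreement summary between two sets of hypnograms
#'
#' Epoch-by-epoch agreement between reference and estimated staging, as a
#' pooled confusion matrix (all epochs together) and, when several
#' subjects are supplied, per-subject accuracy/kappa means. The
#' aggregation used is labeled in the output.
#'
#' @param ref,est a hypnogram each, or lists of hypnograms (one per
#'   subject).
#' @return A list with `pooled` (3-class and 2-class matrices plus
#'   accuracy/kappa) and, for multiple subjects, `per_subject` (tibble) and
#'   `subject_mean`.
#' @export
agreement_summary <- function(ref, est) {
  if (!is.list(ref) || is.data.frame(ref)) ref <- list(ref)
  if (!is.list(est) || is.data.frame(est)) est <- list(est)
  if (length(ref) != length(est)) abort("ref and est subject counts differ")
  cms <- purrr::map2(ref, est, confusion_matrix)
  pooled3 <- Reduce("+", cms)
  class(pooled3) <- c("confusion_matrix", "matrix", "array")
  pooled2 <- collapse_sleep_wake(pooled3)
  out <- list(pooled = list(
    cm3 = pooled3, cm2 = pooled2,
    accuracy3 = accuracy(pooled3), kappa3 = cohens_kappa(pooled3),
    accuracy2 = accuracy(pooled2), kappa2 = cohens_kappa(pooled2),
    aggregation = "pooled epochs"
  ))
  if (length(cms) > 1) {
    per <- purrr::imap(cms, function(cm, i) {
      tibble(subject = i, accuracy3 = accuracy(cm),
             kappa3 = cohens_kappa(cm),
             accuracy2 = accuracy(collapse_sleep_wake(cm)),
             kappa2 = cohens_kappa(collapse_sleep_wake(cm)))
    })
    out$per_subject <- bind_rows(per)
    out$subject_mean <- dplyr::summarise(
      out$per_subject,
      across(c("accuracy3", "kappa3", "accuracy2", "kappa2"),
             list(mean = mean, sd = sd))
    )
    out$aggregation <- "per-subject mean of epoch-by-epoch agreement"
  }
  out
}
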