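#' Train the real-time and offline staging cascades
#'
#' Fits both cascades on a corpus of design nights. Subjects are split
#' 80/20 into training and development sets at the subject level (never at
#' the epoch level); each real-time sub-classifier is trained on its
#' period's epochs pooled across training nights with
#' inverse-class-frequency weights and early stopping on the development
#' loss. The offline sub-classifiers are then trained on the score
#' sequences the fitted real-time cascade produces for the same nights.
#' All randomness derives from `config$seed`.
#'
#' @param nights a list; each element has `features` (tibble or matrix,
#'   epochs x 67 in registry order) and `hypnogram` (a [hypnogram()] or
#'   character vector of W/R/N labels, same length).
#' @param config an [acusleep_config()]; the `staging` block sets windows,
#'   hidden-unit counts and the optimizer.
#' @return A list with class `mss_cascades`: `realtime` (class
#'   `realtime_cascade`), `offline` (class `offline_cascade`), the shared
#'   imputation medians, dev-set accuracy, and the feature-registry hash.
#' @export
train_cascades <- function(nights, config = acusleep_config()) {
  st <- config$staging
  if (length(nights) < 5) {
    abort("at least 5 design nights are required for a subject-level split")
  }
  feats <- lapply(nights, function(n) feature_matrix(n$features))
  labs <- lapply(nights, function(n) stage_vector(n$hypnogram))
  for (i in seq_along(nights)) {
    if (nrow(feats[[i]]) != length(labs[[i]])) {
      abort(sprintf("night %d: features and hypnogram lengths differ", i))
    }
  }
  all_lab <- unlist(labs)
  missing_cls <- setdiff(STAGES, unique(all_lab))
  if (length(missing_cls)) {
    abort(sprintf("class %s absent from training labels",
                  paste(missing_cls, collapse = ", ")))
  }

  seed <- derive_seed(config$seed, 23L)
  set.seed(seed)
  n_dev <- max(1L, round(length(nights) * st$dev_frac))
  dev_ids <- sort(sample.int(length(nights), n_dev))
  train_ids <- setdiff(seq_along(nights), dev_ids)

  # sentinel imputation by training-set medians, shared by both cascades
  train_stack <- do.call(rbind, feats[train_ids])
  medians <- apply(train_stack, 2, function(col) {
    ok <- col != ACU_SENTINEL
    if (any(ok)) median(col[ok]) else 0
  })
  feats <- lapply(feats, impute_features, medians = medians)

  freq <- table(factor(all_lab, levels = STAGES))
  class_w <- as.numeric(sum(freq) / (3 * pmax(freq, 1)))
  names(class_w) <- STAGES

  rt_models <- vector("list", 5L)
  for (p in 2:6) {
    k <- st$rt_lookback[p - 1L]
    tr <- period_samples(feats, labs, train_ids, p, k, forward = FALSE)
    dv <- period_samples(feats, labs, dev_ids, p, k, forward = FALSE)
    if (is.null(tr)) {
      if (!st$allow_missing_periods) {
        abort(sprintf(
          "no night is long enough to train real-time period %d (needs epochs beyond %d); use longer nights or allow_missing_periods",
          p, c(5L, 20L, 50L, 100L, 200L)[p - 1L]
        ))
      }
      next
    }
    rt_models[[p - 1L]] <- fit_period(tr, dv, st$rt_hidden[p - 1L], class_w,
                                      st, derive_seed(seed, p))
  }
  realtime <- structure(
    list(models = rt_models, medians = medians, lookback = st$rt_lookback,
         hidden = st$rt_hidden, seed = seed, registry = registry_hash(),
         version = "1"),
    class = "realtime_cascade"
  )

  # offline training consumes the fitted real-time cascade's scores
  rt_scores <- lapply(seq_along(nights), function(i) {
    rt_score_matrix(classify_night_realtime(feats[[i]], realtime))
  })
  off_models <- vector("list", 5L)
  for (p in 2:6) {
    k <- st$off_lookahead[p - 1L]
    tr <- period_samples(rt_scores, labs, train_ids, p, k, forward = TRUE)
    dv <- period_samples(rt_scores, labs, dev_ids, p, k, forward = TRUE)
    if (is.null(tr)) {
      if (!st$allow_missing_periods) {
        abort(sprintf("no night is long enough to train offline period %d", p))
      }
      next
    }
    off_models[[p - 1L]] <- fit_period(tr, dv, st$off_hidden[p - 1L], class_w,
                                       st, derive_seed(seed, 100L + p))
  }
  offline <- structure(
    list(models = off_models, lookahead = st$off_lookahead,
         hidden = st$off_hidden, seed = seed, registry = registry_hash(),
         version = "1"),
    class = "offline_cascade"
  )

  dev_acc <- cascade_dev_accuracy(feats, labs, dev_ids, realtime, offline)
  structure(
    list(realtime = realtime, offline = offline, medians = medians,
         dev_ids = dev_ids, dev_accuracy = dev_acc,
         registry = registry_hash(), config_hash = config_hash(config),
         seed = seed, version = "1"),
    class = "mss_cascades"
  )
}

# pooled windowed design matrix for one period across a set of nights;
# forward = TRUE builds offline (lookahead) inputs from score matrices and
# appends the epoch index
period_samples <- function(mats, labs, ids, p, k, forward) {
  xs <- list(); ys <- list()
  for (i in ids) {
    T <- nrow(mats[[i]])
    ts <- if (forward) {
      which(select_period_offline(seq_len(T), T) == p)
    } else {
      which(select_period_realtime(seq_len(T)) == p)
    }
    if (!length(ts)) next
    X <- if (forward) {
      cbind(stack_windows_forward(mats[[i]], ts, k), ts)
    } else {
      stack_windows(mats[[i]], ts, k)
    }
    xs[[length(xs) + 1L]] <- X
    ys[[length(ys) + 1L]] <- labs[[i]][ts]
  }
  if (!length(xs)) return(NULL)
  list(x = do.call(rbind, xs), y = factor(unlist(ys), levels = STAGES))
}

fit_period <- function(tr, dv, hidden, class_w, st, seed) {
  present <- unique(as.character(tr$y))
  if (length(present) == 1L) {
    return(constant_mlp(STAGES, present, ncol(tr$x)))
  }
  if (!is.null(dv)) {
    x <- rbind(tr$x, dv$x)
    y <- factor(c(as.character(tr$y), as.character(dv$y)), levels = STAGES)
    val_idx <- nrow(tr$x) + seq_len(nrow(dv$x))
  } else {
    x <- tr$x; y <- tr$y; val_idx <- NULL
  }
  mlp_fit(x, y, hidden = hidden, class_weights = class_w[levels(y)],
          val_idx = val_idx, max_iter = st$max_iter,
          learn_rate = st$learn_rate, patience = st$patience, l2 = st$l2,
          seed = seed)
}

cascade_dev_accuracy <- function(feats, labs, dev_ids, realtime, offline) {
  accs <- vapply(dev_ids, function(i) {
    rt <- classify_night_realtime(feats[[i]], realtime)
    off <- classify_night_offline(rt, offline)
    c(mean(rt$label == labs[[i]]), mean(off$label == labs[[i]]))
  }, numeric(2))
  c(realtime = mean(accs[1, ]), offline = mean(accs[2, ]))
}

#' @export
print.mss_cascades <- function(x, ...) {
  cat(sprintf(
    "<mss_cascades> dev accuracy: real-time %.3f, offline %.3f | registry %s\n",
    x$dev_accuracy["realtime"], x$dev_accuracy["offline"],
    substr(x$registry, 1, 8)
  ))
  invisible(x)
}

# Untrained cascades with seeded random weights and identity scaling;
# architectural behavior (periods, causality, pass-through) does not depend
# on training, so tests of those properties use this constructor.
random_cascades <- function(config = acusleep_config(), seed = 1L) {
  st <- config$staging
  mk <- function(d, hidden, s) {
    set.seed(s)
    H <- as.integer(hidden)
    params <- if (H > 0) {
      list(W1 = matrix(rnorm(d * H, sd = 0.05), d, H), b1 = numeric(H),
           W2 = matrix(rnorm(H * 3, sd = 0.5), H, 3), b2 = numeric(3))
    } else {
      list(W2 = matrix(rnorm(d * 3, sd = 0.5), d, 3), b2 = numeric(3))
    }
    structure(list(params = params, hidden = H, classes = STAGES,
                   center = numeric(d), scale = rep(1, d), seed = s,
                   version = "1"),
              class = "acu_mlp")
  }
  rt_models <- lapply(1:5, function(i) {
    mk(67L * (st$rt_lookback[i] + 1L), min(st$rt_hidden[i], 16L),
       derive_seed(seed, i))
  })
  off_models <- lapply(1:5, function(i) {
    mk(3L * (st$off_lookahead[i] + 1L) + 1L, min(st$off_hidden[i], 16L),
       derive_seed(seed, 50L + i))
  })
  list(
    realtime = structure(
      list(models = rt_models, medians = rep(0, 67), lookback = st$rt_lookback,
           hidden = st$rt_hidden, seed = seed, registry = registry_hash(),
           version = "1"),
      class = "realtime_cascade"),
    offline = structure(
      list(models = off_models, lookahead = st$off_lookahead,
           hidden = st$off_hidden, seed = seed, registry = registry_hash(),
           version = "1"),
      class = "offline_cascade")
  )
}
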