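# Shared fixtures, built lazily and cached for the whole test run.
# Everything is generated in code from fixed seeds; nothing is stored on
# disk.

fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(fixture_env[[name]])) fixture_env[[name]] <- builder()
  fixture_env[[name]]
}

# a small lazy simulated night (default 40 epochs)
fix_night <- function(seed = 5, epochs = 40L, materialize = FALSE) {
  key <- sprintf("night_%d_%d_%d", seed, epochs, materialize)
  fixture(key, function() {
    simulate_night(
      acusleep_config(seed = seed, simulator = list(night_epochs = epochs)),
      materialize = materialize
    )
  })
}

# event detector trained on frames from four small nights
fix_detector <- function() {
  fixture("detector", function() {
    cfg <- acusleep_config(seed = 101)
    nights <- lapply(11:14, function(s) {
      simulate_night(
        acusleep_config(seed = s, simulator = list(night_epochs = 60)),
        materialize = FALSE
      )
    })
    frames <- collect_detector_frames(nights, cfg, epochs_per_night = 12)
    list(detector = train_detector(frames, cfg), frames = frames,
         nights = nights)
  })
}

# synthetic feature tables for cascade-level tests that do not need audio:
# stage-dependent means plus noise, in registry order
toy_features <- function(hyp, seed = 1) {
  set.seed(seed)
  labs <- as.character(hyp$stage)
  T <- length(labs)
  mu <- c(W = -3, R = 0, N = 3)[labs]
  X <- matrix(rnorm(T * 67, mean = rep(mu, 67), sd = 0.5), T, 67)
  X[, 67] <- seq_len(T)   # epoch index channel stays honest
  colnames(X) <- feature_registry()$name
  tibble::as_tibble(as.data.frame(X))
}

# sticky Markov stage sequence: stages persist across epochs, as real
# hypnograms do, so lookback/lookahead windows carry signal
toy_hypnogram <- function(T, seed = 1) {
  set.seed(seed)
  lat <- 6L + rpois(1, 4)
  labs <- character(T)
  labs[1:lat] <- "W"
  cur <- "N"
  for (t in (lat + 1):T) {
    if (runif(1) > 0.97) {   # bouts of ~35 epochs, like real stage bouts
      cur <- sample(setdiff(c("N", "R", "W"), cur), 1,
                    prob = c(0.7, 0.3)[seq_len(2)])
    }
    labs[t] <- cur
  }
  hypnogram(labs)
}

toy_design_nights <- function(n_nights = 6L, T = 60L, seed = 1) {
  lapply(seq_len(n_nights), function(i) {
    h <- toy_hypnogram(T, seed = seed + i)
    list(features = toy_features(h, seed = 100 * seed + i), hypnogram = h)
  })
}

# detected curves (600 x 4 matrix) for one synthesized epoch of a stage,
# routed through the causal pipeline (noise tracking + enhancement) the
# detector was trained under
curves_mat_for <- function(det, stage, seed) {
  syn <- synthesize_epoch_audio(stage, acusleep_config(seed = seed))
  cur <- detect_night_curves(audio_stream(as.numeric(syn$epoch)), det)
  cbind(inhale = cur$p_in, exhale = cur$p_ex,
        body_movement = cur$p_bm, other = cur$p_os)
}

# hand-built probability-curve matrix: all "other" unless overridden
flat_curves <- function(m = 600L) {
  cm <- matrix(0, m, 4, dimnames = list(NULL, c("inhale", "exhale",
                                                "body_movement", "other")))
  cm[, 4] <- 1
  cm
}

# place an event (probability 1) of `kind` over 0-based frames
set_curve_run <- function(cm, kind, from, to) {
  cm[(from:to) + 1L, ] <- 0
  cm[(from:to) + 1L, kind] <- 1
  cm
}

# periodic inhale curve: square pulses of `width` frames every `period`
periodic_inhale <- function(m = 600L, period = 80L, width = 10L,
                            exhale_gap = 20L) {
  cm <- flat_curves(m)
  starts <- seq(1L, m - width, by = period)
  for (s in starts) {
    cm <- set_curve_run(cm, "inhale", s - 1L, s + width - 2L)
    ex <- s + exhale_gap
    if (ex + width - 1L <= m) {
      cm <- set_curve_run(cm, "exhale", ex - 1L, ex + width - 2L)
    }
  }
  cm
}
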