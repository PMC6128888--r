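# Night simulator: ground-truth hypnograms, stage-conditioned audio and
# frame-level event labels embodying the physiology the staging system
# exploits -- periodic breathing in NREM, faster and more variable
# breathing in REM without body movement, sparse faint breathing with
# frequent movement in wake, stationary background noise, and occasional
# third-party transients.

sim_config_defaults <- function() {
  list(
    night_epochs = 840L,            # 7 h
    wake_latency_min = c(mean = 15, sd = 5),
    min_latency_min = 3,
    rem_cycle_min = c(mean = 95, sd = 10),
    rem_bout_min = c(mean = 18, sd = 5),
    awakening_rate_per_h = 1.5,
    awakening_min = c(mean = 3, sd = 1.5),
    terminal_wake_min = c(mean = 4, sd = 2),
    terminal_wake_prob = 0.7,
    breath_rate_bpm = list(N = c(mean = 14, sd = 0.5),
                           R = c(mean = 16, sd = 2),
                           W = c(mean = 5, sd = 2)),
    breath_cv = list(N = 0.05, R = 0.25, W = 0.4),
    movement_rate = list(W = 1.5, N = 0.1, R = 0),
    movement_dur_s = c(1.5, 4),
    noise_dbfs = -45,
    breath_snr_db = 15,
    wake_breath_atten_db = 8,
    movement_dbfs = -22,
    transient_rate_per_min = 0.3,
    transient_dbfs = -25,
    inhale_s = c(mean = 1.0, sd = 0.15),
    exhale_s = c(mean = 0.8, sd = 0.15),
    breath_pause_s = 0.3,
    ramp_s = 0.1,
    age_range = c(18, 75),
    bmi_range = c(20, 40)
  )
}

clamp <- function(x, lo, hi) pmin(hi, pmax(lo, x))

#' Simulate a night's hypnogram
#'
#' Semi-Markov stage sequence: an initial wake bout (sleep latency), then
#' alternating NREM and REM bouts with a cycle period drawn around 95 min,
#' brief awakenings carved out of NREM, and an optional terminal wake
#' bout. Fully reproducible from `config$seed`.
#'
#' @param config an [acusleep_config()]; the `simulator` block holds the
#'   distributions.
#' @return A [hypnogram()].
#' @export
simulate_hypnogram <- function(config = acusleep_config()) {
  sc <- config$simulator
  T <- as.integer(sc$night_epochs)
  if (T < 20) abort("night_epochs must be at least 20")
  set.seed(derive_seed(config$seed, 31L))

  lat_ep <- max(6L, round(2 * max(sc$min_latency_min,
                                  rnorm(1, sc$wake_latency_min["mean"],
                                        sc$wake_latency_min["sd"]))))
  stages <- rep("W", lat_ep)
  while (length(stages) < T + 40L) {
    cyc <- round(2 * clamp(rnorm(1, sc$rem_cycle_min["mean"],
                                 sc$rem_cycle_min["sd"]), 70, 130))
    rem <- round(2 * clamp(rnorm(1, sc$rem_bout_min["mean"],
                                 sc$rem_bout_min["sd"]), 8, 30))
    stages <- c(stages, rep("N", cyc - rem), rep("R", rem))
  }
  stages <- stages[seq_len(T)]

  # brief awakenings replace NREM epochs so REM-onset spacing is preserved
  n_aw <- rpois(1, sc$awakening_rate_per_h * T / 120)
  n_idx <- which(stages == "N")
  if (n_aw > 0 && length(n_idx) > 2) {
    for (pos in sample(n_idx, min(n_aw, length(n_idx)))) {
      dur <- max(1L, round(2 * clamp(rnorm(1, sc$awakening_min["mean"],
                                           sc$awakening_min["sd"]), 0.5, 6)))
      span <- pos:min(pos + dur - 1L, T)
      span <- span[stages[span] == "N"]
      stages[span] <- "W"
    }
  }
  if (runif(1) < sc$terminal_wake_prob) {
    m <- max(1L, round(2 * clamp(rnorm(1, sc$terminal_wake_min["mean"],
                                       sc$terminal_wake_min["sd"]), 0.5, 10)))
    stages[seq.int(max(1L, T - m + 1L), T)] <- "W"
  }
  hypnogram(stages)
}

# band-limited unit-RMS noise template via FFT shaping
bandlimited_noise <- function(n, band) {
  npad <- nextn(n, 2)
  x <- rnorm(npad)
  X <- fft(x)
  freqs <- (seq_len(npad) - 1) * (ACU_RATE / npad)
  freqs <- pmin(freqs, ACU_RATE - freqs)
  X[freqs < band[1] | freqs > band[2]] <- 0
  y <- Re(fft(X, inverse = TRUE))[seq_len(n)] / npad
  y / sqrt(mean(y^2))
}

sim_bands <- list(
  inhale = c(300, 2000), exhale = c(200, 1000),
  body_movement = c(100, 8000)
)

TEMPLATE_S <- 4.5

night_templates <- function(n_tpl = 6L) {
  n <- round(TEMPLATE_S * ACU_RATE)
  tpl <- lapply(names(sim_bands), function(k) {
    lapply(seq_len(n_tpl), function(i) bandlimited_noise(n, sim_bands[[k]]))
  })
  names(tpl) <- names(sim_bands)
  tpl$transient <- lapply(seq_len(n_tpl), function(i) {
    lo <- runif(1, 300, 1500)
    bandlimited_noise(n, c(lo, lo * runif(1, 2, 4)))
  })
  tpl
}

# per-epoch event schedule for the whole night (times in night seconds)
night_schedule <- function(stages, sc) {
  n_tpl <- 6L
  kind <- character(); onset_s <- numeric(); dur_s <- numeric()
  dbfs <- numeric()
  add <- function(k, onset, dur, db) {
    kind[length(kind) + 1L] <<- k
    onset_s[length(onset_s) + 1L] <<- onset
    dur_s[length(dur_s) + 1L] <<- dur
    dbfs[length(dbfs) + 1L] <<- db
  }
  breath_dbfs <- sc$noise_dbfs + sc$breath_snr_db
  for (e in seq_along(stages)) {
    s <- stages[e]
    t0 <- (e - 1) * 30
    rb <- sc$breath_rate_bpm[[s]]
    rate <- clamp(rnorm(1, rb["mean"], rb["sd"]), 3, 30)
    period <- 60 / rate
    cv <- sc$breath_cv[[s]]
    amp <- if (s == "W") breath_dbfs - sc$wake_breath_atten_db else breath_dbfs
    t <- runif(1, 0, period)
    while (t < 30) {
      di <- clamp(rnorm(1, sc$inhale_s["mean"], sc$inhale_s["sd"]), 0.4, 1.8)
      de <- clamp(rnorm(1, sc$exhale_s["mean"], sc$exhale_s["sd"]), 0.3, 1.6)
      add("inhale", t0 + t, di, amp + rnorm(1, 0, 1))
      ex_on <- t + di + clamp(rnorm(1, sc$breath_pause_s, 0.05), 0.1, 0.6)
      if (ex_on < 30) add("exhale", t0 + ex_on, de, amp + rnorm(1, 0, 1))
      t <- t + max(0.5 * period, period * (1 + cv * rnorm(1)))
    }
    n_mv <- rpois(1, sc$movement_rate[[s]])
    for (i in seq_len(n_mv)) {
      add("body_movement", t0 + runif(1, 0, 28),
          runif(1, sc$movement_dur_s[1], sc$movement_dur_s[2]),
          sc$movement_dbfs + rnorm(1, 0, 2))
    }
    n_tr <- rpois(1, sc$transient_rate_per_min * 0.5)
    for (i in seq_len(n_tr)) {
      add("transient", t0 + runif(1, 0, 29.5), runif(1, 0.2, 0.4),
          sc$transient_dbfs + rnorm(1, 0, 3))
    }
  }
  n_ev <- length(kind)
  tibble(
    kind = kind, onset_s = onset_s, dur_s = dur_s, dbfs = dbfs,
    tpl = sample.int(n_tpl, n_ev, replace = TRUE),
    tpl_off = runif(n_ev, 0, pmax(0.01, TEMPLATE_S - dur_s - 0.01))
  )
}

# frame labels for the whole night from the schedule (priority: movement
# over breathing over other; transients stay "other")
schedule_frame_labels <- function(schedule, n_epochs) {
  n_frames <- n_epochs * ACU_FRAMES_PER_EPOCH
  lab <- rep.int(4L, n_frames)
  centers <- (seq_len(n_frames) - 0.5) * 0.05
  mark <- function(kind_code, rows) {
    for (i in rows) {
      on <- schedule$onset_s[i]
      j0 <- floor(on / 0.05) + 1L
      j1 <- min(ceiling((on + schedule$dur_s[i]) / 0.05), n_frames)
      jj <- j0:j1
      jj <- jj[centers[jj] >= on & centers[jj] < on + schedule$dur_s[i]]
      lab[jj] <<- kind_code
    }
  }
  mark(1L, which(schedule$kind == "inhale"))
  mark(2L, which(schedule$kind == "exhale"))
  mark(3L, which(schedule$kind == "body_movement"))
  factor(EVENT_CLASSES[lab], levels = EVENT_CLASSES)
}

#' Simulate a full night
#'
#' Generates the hypnogram, subject metadata, the per-frame ground-truth
#' event labels and (optionally materialized) stage-conditioned audio. One
#' night-level seed (`config$seed`) drives everything; per-epoch audio is
#' reconstructed deterministically from the stored schedule, so the lazy
#' and materialized forms are bit-identical.
#'
#' @param config an [acusleep_config()].
#' @param materialize build the full audio vector (`2205 * 600 * T`
#'   samples; about 10.6 MB of doubles per epoch). Set `FALSE` for long
#'   nights and read epochs on demand with [night_epoch_audio()].
#' @return An object of class `simulated_night`: `hypnogram`, `meta`,
#'   `frame_labels`, `schedule`, `n_epochs`, and `audio` (an
#'   [audio_stream()]) when materialized.
#' @export
simulate_night <- function(config = acusleep_config(), materialize = TRUE) {
  sc <- config$simulator
  hyp <- simulate_hypnogram(config)
  stages <- as.character(hyp$stage)
  T <- length(stages)

  set.seed(derive_seed(config$seed, 37L))
  meta <- list(
    age = round(runif(1, sc$age_range[1], sc$age_range[2])),
    gender = sample(0:1, 1),
    bmi = round(runif(1, sc$bmi_range[1], sc$bmi_range[2]), 1)
  )
  templates <- night_templates()
  # double-length pre-scaled template: each epoch reads one contiguous
  # slice at a random offset (cheap, deterministic stationary background)
  bg <- as.numeric(stats::filter(rnorm(2L * ACU_EPOCH_SAMPLES), 0.6,
                                 method = "recursive"))
  bg <- bg / sqrt(mean(bg^2)) * 10^(sc$noise_dbfs / 20)
  shifts <- sample.int(ACU_EPOCH_SAMPLES, T, replace = TRUE)
  schedule <- night_schedule(stages, sc)

  night <- structure(
    list(
      hypnogram = hyp, meta = meta,
      frame_labels = schedule_frame_labels(schedule, T),
      schedule = schedule, templates = templates, bg = bg, shifts = shifts,
      n_epochs = T, noise_dbfs = sc$noise_dbfs, ramp_s = sc$ramp_s,
      seed = config$seed, config_hash = config_hash(config), audio = NULL
    ),
    class = "simulated_night"
  )
  if (materialize) {
    night$audio <- audio_stream(unlist(
      lapply(seq_len(T), function(t) night_epoch_audio(night, t))
    ))
  }
  night
}

#' @export
print.simulated_night <- function(x, ...) {
  tab <- table(x$hypnogram$stage)
  cat(sprintf(
    "<simulated_night> %d epochs (%.1f h) seed %s | W %d / R %d / N %d | audio %s\n",
    x$n_epochs, x$n_epochs / 120, format(x$seed), tab["W"], tab["R"], tab["N"],
    if (is.null(x$audio)) "lazy" else "materialized"
  ))
  invisible(x)
}

#' Audio of one simulated epoch
#'
#' Reconstructs epoch `t`'s 30 s of audio (1,323,000 samples) from the
#' night's stored schedule and templates; deterministic, identical to the
#' corresponding slice of the materialized audio.
#'
#' @param night a [simulate_night()] object.
#' @param t 1-based epoch index.
#' @return Numeric vector of `2205 * 600` samples.
#' @export
night_epoch_audio <- function(night, t) {
  as.numeric(night_epoch_chunk(night, t))
}

# frames matrix (2205 x 600K) for a set of epochs, via the C kernel
night_epoch_chunk <- function(night, ts) {
  if (any(ts < 1) || any(ts > night$n_epochs)) {
    abort("epoch index out of range")
  }
  flat_tpls <- c(night$templates$inhale, night$templates$exhale,
                 night$templates$body_movement, night$templates$transient)
  kind_code <- c(inhale = 0L, exhale = 1L, body_movement = 2L,
                 transient = 3L)
  sched <- night$schedule
  onset <- sched$onset_s; dur <- sched$dur_s
  ev_epoch <- integer(); rows_all <- integer()
  for (j in seq_along(ts)) {
    t0 <- (ts[j] - 1) * 30
    rows <- which(onset < t0 + 30 & onset + dur > t0)
    ev_epoch <- c(ev_epoch, rep(j, length(rows)))
    rows_all <- c(rows_all, rows)
  }
  dur_e <- dur[rows_all]
  ramp <- pmin(night$ramp_s, dur_e / 3)
  synth_chunk_cpp(
    bg = night$bg, sh = as.integer(night$shifts[ts]),
    frame_len = ACU_FRAME, frames_per_epoch = ACU_FRAMES_PER_EPOCH,
    tpls = flat_tpls, ev_epoch = ev_epoch,
    tpl_id = kind_code[sched$kind[rows_all]] * 6L +
      as.integer(sched$tpl[rows_all]),
    tpl_off = as.integer(round(sched$tpl_off[rows_all] * ACU_RATE)),
    n_ev = as.integer(round(dur_e * ACU_RATE)),
    s_ev = as.integer(round((onset[rows_all] - (ts[ev_epoch] - 1) * 30) *
                              ACU_RATE)),
    ramp_n = pmax(1L, as.integer(round(ramp * ACU_RATE))),
    amp = 10^(sched$dbfs[rows_all] / 20)
  )
}

#' Synthesize a single labeled epoch
#'
#' Stand-alone stage-conditioned epoch synthesis (30 s of audio plus the
#' 600 ground-truth frame labels), convenient for unit-scale experiments.
#' Equivalent to one epoch of [simulate_night()] with the same stage.
#'
#' @param stage `"W"`, `"R"` or `"N"`.
#' @param config an [acusleep_config()].
#' @return A list with `epoch` (`2205 x 600` frame matrix), `labels`
#'   (factor, length 600) and `events` (the schedule tibble).
#' @export
synthesize_epoch_audio <- function(stage, config = acusleep_config()) {
  stage <- match.arg(stage, STAGES)
  sc <- config$simulator
  set.seed(derive_seed(config$seed, 41L))
  templates <- night_templates()
  bg <- as.numeric(stats::filter(rnorm(2L * ACU_EPOCH_SAMPLES), 0.6,
                                 method = "recursive"))
  bg <- bg / sqrt(mean(bg^2)) * 10^(sc$noise_dbfs / 20)
  schedule <- night_schedule(stage, sc)
  night <- list(
    schedule = schedule, templates = templates, bg = bg, shifts = 1L,
    n_epochs = 1L, noise_dbfs = sc$noise_dbfs, ramp_s = sc$ramp_s
  )
  list(
    epoch = matrix(night_epoch_audio(night, 1L), nrow = ACU_FRAME),
    labels = schedule_frame_labels(schedule, 1L),
    events = schedule
  )
}
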