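cfg <- acusleep_config(seed = 4)

test_that("frame features honor the silence convention", {
  ff <- frame_acoustic_features(matrix(0, 2205, 3), cfg)
  expect_equal(nrow(ff), 3)
  expect_equal(ff$log_energy, rep(-100, 3))
  expect_equal(ff$spectral_entropy, rep(1, 3))
  expect_equal(ff$spectral_centroid, rep(0, 3))
})

test_that("spectral centroid of a pure tone is recovered", {
  fr <- sin(2 * pi * 440 * (0:2204) / 44100)
  ff <- frame_acoustic_features(fr, cfg)
  expect_lt(abs(ff$spectral_centroid - 440), 20)
})

test_that("white noise has near-maximal spectral entropy", {
  set.seed(8)
  ff <- frame_acoustic_features(matrix(rnorm(2205 * 20, sd = 0.05), 2205), cfg)
  expect_true(all(ff$spectral_entropy >= 0.9))
})

test_that("feature vector is fixed-length and documented", {
  ff <- frame_acoustic_features(rnorm(2205), cfg)
  expect_named(ff, c("log_energy", "spectral_entropy", "spectral_centroid",
                     "spectral_rolloff", "zcr", paste0("band", 1:4),
                     paste0("cep", 1:8)))
})

test_that("detector training contracts hold", {
  fr <- fix_detector()$frames
  expect_error(train_detector(fr[, -ncol(fr)], cfg), "label")
  one_class <- fr[fr$label == "other", ]
  expect_error(train_detector(one_class, cfg), "two event classes")
})

test_that("a separable duplicate-frame training set is fit perfectly", {
  fr <- fix_detector()$frames
  one_each <- do.call(rbind, lapply(split(fr, fr$label), function(d) d[1, ]))
  dup <- one_each[rep(1:4, each = 30), ]
  det <- train_detector(dup, acusleep_config(seed = 2,
                                             detector = list(val_frac = 0)))
  pred <- predict_frame_labels(det, one_each)
  expect_equal(pred, as.character(one_each$label))
})

test_that("trained detector generalizes to held-out frames", {
  d <- fix_detector()
  expect_gte(d$detector$holdout_accuracy, 0.85)
})

test_that("label shuffling destroys detection (permutation control)", {
  fr <- fix_detector()$frames
  # balance classes so chance is exactly 1/4
  n_min <- min(table(fr$label))
  idx <- unlist(lapply(split(seq_len(nrow(fr)), fr$label),
                       function(i) i[seq_len(n_min)]))
  bal <- fr[idx, ]
  set.seed(123)
  bal$label <- sample(bal$label)
  hold <- sample(nrow(bal), 400)
  det <- train_detector(bal[-hold, ],
                        acusleep_config(seed = 3,
                                        detector = list(max_iter = 60L)))
  acc <- mean(predict_frame_labels(det, bal[hold, ]) ==
                as.character(bal$label[hold]))
  expect_lt(abs(acc - 0.25), 0.08)
})

test_that("detector training is reproducible from the seed", {
  fr <- head(fix_detector()$frames, 1500)
  c5 <- acusleep_config(seed = 5, detector = list(max_iter = 40L))
  d1 <- train_detector(fr, c5)
  d2 <- train_detector(fr, c5)
  expect_identical(d1$mlp$params, d2$mlp$params)
})

test_that("untrained prior yields uniform curves; probabilities normalize", {
  syn <- synthesize_epoch_audio("N", acusleep_config(seed = 21))
  cur <- detect_events(syn$epoch, NULL, cfg)
  expect_equal(nrow(cur), 600)
  expect_true(all(abs(cur$p_in + cur$p_ex + cur$p_bm + cur$p_os - 1) < 1e-6))
  loud <- matrix(cur$p_in, ncol = 1)  # uniform everywhere but silent frames
  expect_true(all(cur$p_in %in% c(0, 0.25)))

  det <- fix_detector()$detector
  cur2 <- detect_events(syn$epoch, det, cfg)
  expect_true(all(abs(cur2$p_in + cur2$p_ex + cur2$p_bm + cur2$p_os - 1) < 1e-6))
  expect_true(all(cur2$p_in >= 0 & cur2$p_in <= 1))
})

test_that("silent frames map deterministically to other", {
  ep <- matrix(0, 2205, 10)
  cur <- detect_events(ep, fix_detector()$detector, cfg)
  expect_equal(cur$p_os, rep(1, 10))
})

test_that("detected inhale bursts line up with the simulator's ground truth", {
  det <- fix_detector()$detector
  hits <- vapply(1:4, function(s) {
    syn <- synthesize_epoch_audio("N", acusleep_config(seed = 400 + s))
    cur <- detect_events(syn$epoch, det, cfg)
    cm <- cbind(cur$p_in, cur$p_ex, cur$p_bm, cur$p_os)
    inh <- which(syn$labels == "inhale")
    mean(max.col(cm)[inh] == 1L)
  }, numeric(1))
  expect_gte(mean(hits), 0.8)
})

test_that("movement bursts dominate p_bm where they occur", {
  det <- fix_detector()$detector
  found <- vapply(1:6, function(s) {
    syn <- synthesize_epoch_audio("W", acusleep_config(seed = 500 + s))
    bm <- which(syn$labels == "body_movement")
    if (!length(bm)) return(NA)
    cur <- detect_events(syn$epoch, det, cfg)
    which.max(cur$p_bm) %in% bm
  }, logical(1))
  expect_gte(mean(found, na.rm = TRUE), 0.5)
})

test_that("tidy and glance summarize a detector fit", {
  det <- fix_detector()$detector
  expect_equal(nrow(tidy(det)), length(det$classes))
  g <- glance(det)
  expect_true(all(c("n_frames", "holdout_accuracy", "hidden") %in% names(g)))
})
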