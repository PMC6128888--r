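test_that("real-time period boundaries follow the displayed cascade", {
  expect_equal(select_period_realtime(c(1, 5)), c(1L, 1L))
  expect_equal(select_period_realtime(c(6, 20)), c(2L, 2L))
  expect_equal(select_period_realtime(c(21, 50)), c(3L, 3L))
  expect_equal(select_period_realtime(c(51, 100)), c(4L, 4L))
  expect_equal(select_period_realtime(c(101, 200)), c(5L, 5L))
  expect_equal(select_period_realtime(c(201, 10000)), c(6L, 6L))
  expect_error(select_period_realtime(0), "1-based")
})

test_that("offline period boundaries follow the displayed cascade", {
  T <- 430
  expect_equal(select_period_offline(c(T - 5, T), T), c(1L, 1L))
  expect_equal(select_period_offline(c(T - 20, T - 6), T), c(2L, 2L))
  expect_equal(select_period_offline(c(T - 50, T - 21), T), c(3L, 3L))
  expect_equal(select_period_offline(c(T - 100, T - 51), T), c(4L, 4L))
  expect_equal(select_period_offline(c(T - 200, T - 101), T), c(5L, 5L))
  expect_equal(select_period_offline(c(1, T - 201), T), c(6L, 6L))
  # shorter nights: the window always fits
  expect_equal(select_period_offline(80, 100), 2L)
  expect_equal(select_period_offline(40, 100), 4L)
  expect_error(select_period_offline(0, 100), "1..T")
})

test_that("real-time input windows concatenate the right epochs", {
  X <- toy_features(toy_hypnogram(250, 3), seed = 3)
  v <- build_realtime_input(X, t = 6, lookback = 5)
  expect_length(v, 402)
  Xm <- acusleep:::feature_matrix(X)
  expect_equal(v, as.numeric(t(Xm[1:6, ])))
  expect_length(build_realtime_input(X, 201, 200), 13467)
  expect_error(build_realtime_input(X, 5, 5), "history")

  # causality: epochs after t are irrelevant
  X2 <- X
  X2[10:250, ] <- X2[10:250, ] * 10
  expect_equal(build_realtime_input(X, 9, 5), build_realtime_input(X2, 9, 5))
})

test_that("stage scores map to labels with the N > R > W tie rule", {
  expect_equal(scores_to_label(matrix(c(1, 0, 0), 1,
                                      dimnames = list(NULL, c("W", "R", "N")))),
               "W")
  s <- tibble::tibble(p_W = c(0.2, 0.4, 0.2), p_R = c(0.3, 0.4, 0.4),
                      p_N = c(0.5, 0.2, 0.4))
  expect_equal(scores_to_label(s), c("N", "R", "N"))
})

test_that("epochs 1-5 are Wake with probability one, whatever the audio", {
  casc <- acusleep:::random_cascades(seed = 2)
  X <- toy_features(toy_hypnogram(30, 4), seed = 4)
  for (t in c(1, 3, 5)) {
    s <- classify_epoch_realtime(X, t, casc$realtime)
    expect_equal(as.numeric(s), c(1, 0, 0))
  }
  s6 <- classify_epoch_realtime(X, 6, casc$realtime)
  expect_true(abs(sum(as.numeric(s6)) - 1) < 1e-6)
})

test_that("real-time scoring is strictly causal under feature mutation", {
  casc <- acusleep:::random_cascades(seed = 3)
  X <- toy_features(toy_hypnogram(230, 5), seed = 5)
  base <- classify_night_realtime(X, casc$realtime)
  set.seed(99)
  for (t in sample(6:229, 25)) {
    X2 <- X
    X2[(t + 1):230, seq_len(66)] <- 0   # trash the future (epoch index kept)
    mut <- classify_night_realtime(X2, casc$realtime, epochs = 1:t)
    expect_equal(mut$p_W, base$p_W[1:t], tolerance = 1e-12)
    expect_equal(mut$label, base$label[1:t])
  }
})

test_that("offline pass keeps real-time scores where the equation says so", {
  casc <- acusleep:::random_cascades(seed = 4)
  X <- toy_features(toy_hypnogram(230, 6), seed = 6)
  rt <- classify_night_realtime(X, casc$realtime)
  off <- classify_night_offline(rt, casc$offline)
  keep <- 225:230   # T - 5 <= t
  expect_equal(off$p_W[keep], rt$p_W[keep])
  expect_equal(off$p_R[keep], rt$p_R[keep])
  expect_equal(off$p_N[keep], rt$p_N[keep])
  expect_false(isTRUE(all.equal(off$p_W[1:220], rt$p_W[1:220])))

  # T < 6: everything passes through
  rt5 <- rt[1:5, c("epoch", "p_W", "p_R", "p_N", "label")]
  off5 <- classify_night_offline(rt5, casc$offline)
  expect_equal(off5$p_W, rt5$p_W)
})

test_that("cascade structure matches the published architecture", {
  st <- cascade_structure()
  rt <- st[st$cascade == "realtime", ]
  expect_equal(rt$window, c(0L, 5L, 20L, 50L, 100L, 200L))
  expect_equal(rt$hidden, c(0L, 100L, 400L, 1000L, 1000L, 1000L))
  off <- st[st$cascade == "offline", ]
  expect_equal(off$window, c(0L, 5L, 20L, 50L, 100L, 200L))
  expect_equal(off$hidden, c(0L, 20L, 50L, 100L, 200L, 200L))
})

test_that("training contracts: corpus size, class coverage, short nights", {
  dn <- toy_design_nights(4, 60)
  expect_error(train_cascades(dn), "at least 5")

  dn6 <- toy_design_nights(6, 150, seed = 2)
  cfg <- acusleep_config_reduced(seed = 2)
  expect_error(train_cascades(dn6, cfg), "period 6")

  all_wn <- lapply(1:5, function(i) {
    h <- hypnogram(rep(c("W", "N"), c(10, 50)))
    list(features = toy_features(h, i), hypnogram = h)
  })
  expect_error(train_cascades(all_wn, acusleep_config()), "class R absent")
})

test_that("cascade training is deterministic and labeled with the registry", {
  dn <- toy_design_nights(6, 230, seed = 7)
  cfg <- acusleep_config_reduced(
    seed = 11, staging = list(max_iter = 30L, patience = 5L))
  c1 <- train_cascades(dn, cfg)
  c2 <- train_cascades(dn, cfg)
  expect_identical(
    lapply(c1$realtime$models, function(m) m$params),
    lapply(c2$realtime$models, function(m) m$params)
  )
  expect_identical(c1$registry, acusleep:::registry_hash())
  td <- tidy(c1)
  expect_equal(nrow(td), 12)
  expect_true(all(td$trained))
  expect_true(all(c("dev_accuracy_realtime", "dev_accuracy_offline") %in%
                    names(glance(c1))))
})

test_that("a trained cascade learns toy stage structure end to end", {
  dn <- toy_design_nights(30, 230, seed = 9)
  cfg <- acusleep_config_reduced(seed = 13)
  casc <- train_cascades(dn, cfg)
  expect_true(all(tidy(casc)$trained))
  accs <- vapply(c(77, 78, 79, 80), function(hs) {
    h <- toy_hypnogram(230, seed = hs)
    rt <- classify_night_realtime(toy_features(h, seed = hs), casc$realtime)
    truth <- as.character(h$stage)
    mean(rt$label[6:230] == truth[6:230])
  }, numeric(1))
  # far above the 1/3 chance level on nights the cascade never saw
  expect_gt(mean(accs), 0.7)
  h <- toy_hypnogram(230, seed = 81)
  rt <- classify_night_realtime(toy_features(h, seed = 81), casc$realtime)
  off <- classify_night_offline(rt, casc$offline)
  expect_true(all(abs(rowSums(as.matrix(
    off[, c("p_W", "p_R", "p_N")])) - 1) < 1e-6))
})

test_that("untrained cascade objects are rejected", {
  expect_error(classify_night_realtime(toy_features(toy_hypnogram(30, 1), 1),
                                       structure(list(), class = "realtime_cascade")),
               "train_cascades")
})
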