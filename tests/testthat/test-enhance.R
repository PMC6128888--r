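cfg <- acusleep_config(seed = 9)

white_epoch <- function(sd = 0.01, seed = 1) {
  set.seed(seed)
  matrix(rnorm(2205 * 600, sd = sd), 2205, 600)
}

test_that("noise profile of stationary white noise is flat", {
  prof <- NULL
  for (e in 1:10) prof <- update_noise_profile(white_epoch(seed = e), prof, cfg)
  mag_db <- 20 * log10(prof$magnitude)
  # interior bins (edge bins carry half the power); flat within +/- 3 dB
  interior <- mag_db[5:(length(mag_db) - 5)]
  expect_lt(max(interior) - min(interior), 6)
  expect_lt(max(abs(interior - median(interior))), 3)

  # level agrees with a long-run periodogram oracle of the same process
  sp <- acusleep:::spectral_setup(cfg$enhancement$window)
  set.seed(99)
  oracle <- sqrt(rowMeans(acusleep:::rfft_power(
    matrix(rnorm(512 * 4000, sd = 0.01), 512, 4000) * sp$w
  )))
  # profile uses the lowest-energy quantile, so sits slightly below
  ratio_db <- 20 * log10(median(prof$magnitude[5:250] / oracle[5:250]))
  expect_lt(abs(ratio_db), 3)
})

test_that("digital silence yields a near-zero profile and passes through", {
  silent <- matrix(0, 2205, 600)
  prof <- update_noise_profile(silent, NULL, cfg)
  expect_true(all(prof$magnitude < 1e-12))
  out <- enhance_frame(silent[, 1], prof, cfg)
  expect_identical(out, rep(0, 2205))
})

test_that("profile tracks a step change in noise level", {
  prof <- NULL
  for (e in 1:5) prof <- update_noise_profile(white_epoch(0.005, e), prof, cfg)
  lvl1 <- median(prof$magnitude)
  for (e in 6:10) prof <- update_noise_profile(white_epoch(0.02, e), prof, cfg)
  lvl2 <- median(prof$magnitude)
  # level moved by 12 dB; profile at epoch 10 within 3 dB of the new level
  set.seed(1234)
  target <- update_noise_profile(white_epoch(0.02, 1234), NULL, cfg)
  expect_lt(abs(20 * log10(lvl2 / median(target$magnitude))), 3)
  expect_gt(20 * log10(lvl2 / lvl1), 6)
})

test_that("steady noise frames are suppressed by at least 10 dB", {
  prof <- NULL
  for (e in 1:8) prof <- update_noise_profile(white_epoch(seed = e), prof, cfg)
  set.seed(500)
  reductions <- vapply(1:20, function(i) {
    fr <- rnorm(2205, sd = 0.01)
    out <- enhance_frame(fr, prof, cfg)
    10 * log10(mean(fr^2) / (mean(out^2) + 1e-30))
  }, numeric(1))
  expect_gt(mean(reductions), 10)
})

test_that("a breath burst at +20 dB SNR survives enhancement", {
  prof <- NULL
  for (e in 1:8) prof <- update_noise_profile(white_epoch(seed = e), prof, cfg)
  set.seed(77)
  burst <- sin(2 * pi * 700 * (0:2204) / 44100) *
    (0.5 - 0.5 * cos(2 * pi * (0:2204) / 2204))
  burst <- burst / sqrt(mean(burst^2)) * 0.1   # +20 dB over sd 0.01 noise
  noisy <- burst + rnorm(2205, sd = 0.01)
  out <- enhance_frame(noisy, prof, cfg)
  expect_gt(cor(out, burst), 0.9)
})

test_that("enhancement never amplifies a frame", {
  prof <- NULL
  for (e in 1:5) prof <- update_noise_profile(white_epoch(seed = e), prof, cfg)
  set.seed(3)
  for (i in 1:10) {
    fr <- rnorm(2205, sd = runif(1, 0.001, 0.05))
    out <- enhance_frame(fr, prof, cfg)
    expect_lte(mean(out^2), mean(fr^2) * (1 + 1e-9))
  }
})

test_that("transient sounds 20 dB above the noise lose under 3 dB", {
  prof <- NULL
  for (e in 1:8) prof <- update_noise_profile(white_epoch(seed = e), prof, cfg)
  # 200 ms broadband burst spanning 4 frames, 20 dB above the floor
  set.seed(11)
  tr <- rnorm(8820, sd = 0.1)
  loss_db <- vapply(1:4, function(k) {
    fr <- tr[(k - 1) * 2205 + 1:2205] + rnorm(2205, sd = 0.01)
    out <- enhance_frame(fr, prof, cfg)
    10 * log10(mean(fr^2) / mean(out^2))
  }, numeric(1))
  expect_lt(mean(loss_db), 3)
})

test_that("epoch SNR matches closed forms and the simulator's setting", {
  ep <- matrix(0.001, 2205, 10)
  ep[, 6:10] <- 0.01   # power ratio 100
  mask <- c(rep(FALSE, 5), rep(TRUE, 5))
  expect_equal(estimate_epoch_snr(ep, mask), 20)
  expect_equal(estimate_epoch_snr(cbind(ep[, 1:5], ep[, 1:5]), mask), 0)
  expect_error(estimate_epoch_snr(ep, rep(TRUE, 10)), "background")
  expect_error(estimate_epoch_snr(ep, rep(FALSE, 10)), "event")

  snrs <- vapply(1:10, function(s) {
    syn <- synthesize_epoch_audio("N", acusleep_config(seed = 300 + s))
    estimate_epoch_snr(syn$epoch, syn$labels %in% c("inhale", "exhale"))
  }, numeric(1))
  expect_lt(abs(mean(snrs) - 15), 3)
})
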