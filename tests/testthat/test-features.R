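cfg <- acusleep_config(seed = 12)
meta <- list(age = 40, gender = 1, bmi = 27)

test_that("registry is a frozen 67-feature bijection with family sizes 33/12/10/8/4", {
  reg <- feature_registry()
  expect_equal(nrow(reg), 67)
  expect_equal(anyDuplicated(reg$name), 0)
  expect_equal(reg$index, seq_len(67))
  expect_equal(as.integer(table(reg$family)[c(
    "within_breathing", "between_breathing", "body_movement",
    "background_noise", "personalization"
  )]), c(33L, 12L, 10L, 8L, 4L))
})

test_that("personalization features follow the metadata contract", {
  expect_equal(unname(personalization_features(
    list(age = 18, gender = 0, bmi = 32), t = 1
  )), c(18, 0, 32, 1))
  expect_equal(personalization_features(meta, 7)[["epoch_index"]], 7)
  expect_error(personalization_features(list(age = 18, gender = 0), 1),
               "bmi")
  expect_error(personalization_features(
    list(age = 18, gender = 0, bmi = NA), 1), "bmi")
  expect_error(personalization_features(meta, 0), "1-based")
})

test_that("zero breath events impute durations and zero the counts", {
  ep <- matrix(rnorm(2205 * 600, sd = 0.001), 2205, 600)
  ev <- segment_breath_events(flat_curves(), config = cfg)
  w <- within_breathing_features(ep, flat_curves(), ev, cfg)
  expect_length(w, 33)
  expect_equal(unname(w[c("in_count", "ex_count", "breath_duty_cycle")]),
               c(0, 0, 0))
  expect_equal(unname(w["in_dur_mean"]), -999)
  expect_equal(unname(w["in_ex_int_ratio"]), -999)
})

test_that("equal-intensity inhale/exhale synthesis gives a unit ratio", {
  set.seed(9)
  ep <- matrix(rnorm(2205 * 600, sd = 1e-4), 2205, 600)
  cm <- flat_curves()
  burst <- function(cols) {
    n <- length(cols) * 2205
    matrix(rnorm(n, sd = 0.05), 2205, length(cols))
  }
  for (s in c(50, 200, 350)) {
    cm <- set_curve_run(cm, "inhale", s, s + 19)
    ep[, (s:(s + 19)) + 1] <- burst(s:(s + 19))
    cm <- set_curve_run(cm, "exhale", s + 25, s + 44)
    ep[, ((s + 25):(s + 44)) + 1] <- burst(1:20)
  }
  ev <- segment_breath_events(cm, config = cfg)
  w <- within_breathing_features(ep, cm, ev, cfg)
  expect_lt(abs(w[["in_ex_int_ratio"]] - 1), 0.1)
  expect_equal(unname(w[c("in_count", "ex_count")]), c(3, 3))
})

test_that("metronomic breathing yields exact between-breath statistics", {
  # 0.2 Hz: inhale every 100 frames (5 s)
  cm <- periodic_inhale(m = 600L, period = 100L, width = 20L,
                        exhale_gap = 30L)
  ev <- segment_breath_events(cm, config = cfg)
  b <- between_breathing_features(cm, ev, cfg)
  expect_lt(abs(b[["ibi_mean"]] - 5), 0.1)
  expect_lte(b[["ibi_cv"]], 0.05)
  expect_lt(abs(b[["dom_breath_freq"]] - 0.2), 0.02)
  expect_lt(abs(b[["in_ex_interval_mean"]] - 1.5), 0.06)
})

test_that("a single breath event imputes intervals but keeps detectability", {
  cm <- set_curve_run(flat_curves(), "inhale", 100, 119)
  ev <- segment_breath_events(cm, config = cfg)
  b <- between_breathing_features(cm, ev, cfg)
  expect_equal(unname(b[c("ibi_mean", "ibi_sd", "ibi_cv")]),
               rep(-999, 3))
  expect_gt(b[["breath_detect_frac"]], 0)
})

test_that("movement features: none, and one centered 2 s burst", {
  none <- body_movement_features(flat_curves(), config = cfg)
  expect_equal(unname(none[c("bm_count", "bm_frac", "bm_free_run_max")]),
               c(0, 0, 600))
  expect_equal(unname(none[["bm_frames_since_last"]]), 600)

  cm <- set_curve_run(flat_curves(), "body_movement", 280, 319)  # 2 s
  one <- body_movement_features(cm, config = cfg)
  expect_equal(unname(one[["bm_count"]]), 1)
  expect_equal(unname(one[["bm_frac"]]), 2 / 30)
  expect_equal(unname(one[["bm_dur_max"]]), 2)
})

test_that("background-noise features see a door slam and a level step", {
  # constructed epoch: faint noise + one broadband 300 ms transient at -10 dBFS
  set.seed(14)
  ep <- matrix(rnorm(2205 * 600, sd = 0.003), 2205, 600)
  slam_cols <- 301:306
  ep[, slam_cols] <- rnorm(2205 * 6, sd = 10^(-10 / 20))
  cm <- flat_curves()
  bn <- background_noise_features(ep, cm, config = cfg)
  expect_gte(bn[["os_count"]], 1)
  expect_gte(bn[["os_int_max"]], -15)

  # level step between epochs: delta close to +10 dB
  quiet <- matrix(rnorm(2205 * 600, sd = 0.003), 2205, 600)
  loud <- matrix(rnorm(2205 * 600, sd = 0.003 * 10^(10 / 20)), 2205, 600)
  bn1 <- background_noise_features(quiet, flat_curves(), config = cfg)
  st <- list(prev_floor = bn1[["noise_floor_db"]], os_counts = 0L,
             bm_gap = 600L)
  bn2 <- background_noise_features(loud, flat_curves(), state = st,
                                   config = cfg)
  expect_lt(abs(bn2[["noise_floor_delta"]] - 10), 1.5)
})

test_that("silent epoch over silent history stays at floors", {
  ep <- matrix(0, 2205, 600)
  bn <- background_noise_features(ep, flat_curves(), config = cfg)
  expect_equal(unname(bn[c("os_count", "os_frac")]), c(0, 0))
  expect_equal(unname(bn[["noise_floor_db"]]), -100)
  expect_equal(unname(bn[["noise_floor_delta"]]), 0)
})

test_that("the full epoch vector is 67 long, finite and deterministic", {
  syn <- synthesize_epoch_audio("N", acusleep_config(seed = 33))
  prof <- update_noise_profile(syn$epoch, NULL, cfg)
  cur <- detect_events(syn$epoch, fix_detector()$detector, cfg)
  v1 <- extract_epoch_features(syn$epoch, cur, prof, meta, 3, config = cfg)
  v2 <- extract_epoch_features(syn$epoch, cur, prof, meta, 3, config = cfg)
  expect_equal(ncol(v1), 67)
  expect_identical(names(v1), feature_registry()$name)
  expect_true(all(is.finite(as.numeric(v1[1, ]))))
  expect_identical(as.data.frame(v1), as.data.frame(v2))
})

test_that("a silent epoch still yields a finite feature vector", {
  ep <- matrix(0, 2205, 600)
  prof <- update_noise_profile(ep, NULL, cfg)
  cur <- detect_events(ep, fix_detector()$detector, cfg)
  v <- extract_epoch_features(ep, cur, prof, meta, 1, config = cfg)
  expect_true(all(is.finite(as.numeric(v[1, ]))))
})

test_that("feature matrices round-trip through CSV with their manifest", {
  h <- toy_hypnogram(25, 2)
  f <- toy_features(h, 2)
  f <- dplyr::bind_cols(tibble::tibble(epoch = seq_len(nrow(f))), f)
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_matrix(f, path)
  back <- utils::read.csv(path, check.names = FALSE)
  expect_equal(names(back), names(f))
  man <- jsonlite::read_json(sub("\\.csv$", ".registry.json", path))
  expect_equal(man$registry_hash, acusleep:::registry_hash())
  expect_equal(length(man$families$within_breathing), 33)
})

test_that("REM breathing is more variable than NREM (paired seeds)", {
  det <- fix_detector()$detector
  cvs <- vapply(1:20, function(s) {
    cv_of <- function(stage) {
      cm <- curves_mat_for(det, stage, 700 + s)
      ev <- segment_breath_events(cm, config = cfg)
      between_breathing_features(cm, ev, cfg)[["ibi_cv"]]
    }
    c(cv_of("R"), cv_of("N"))
  }, numeric(2))
  ok <- cvs[, cvs[1, ] > -900 & cvs[2, ] > -900, drop = FALSE]
  expect_gt(median(ok[1, ]), median(ok[2, ]))
})
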