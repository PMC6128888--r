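# The printed validation-set confusion matrices (counts), used as worked
# examples throughout.
cm_offline <- matrix(c(12403, 141, 3156,
                       297, 6738, 2290,
                       3562, 1484, 54322),
                     3, 3, byrow = TRUE,
                     dimnames = list(ref = c("W", "R", "N"),
                                     est = c("W", "R", "N")))
cm_realtime <- matrix(c(11744, 314, 3642,
                        428, 5631, 3248,
                        4393, 2909, 52066),
                      3, 3, byrow = TRUE,
                      dimnames = list(ref = c("W", "R", "N"),
                                      est = c("W", "R", "N")))

test_that("confusion matrices count epoch pairs", {
  ref <- rep(c("W", "R", "N"), each = 10)
  cm <- confusion_matrix(ref, ref)
  expect_equal(diag(cm), c(W = 10L, R = 10L, N = 10L))
  expect_equal(sum(cm), 30)

  cm2 <- confusion_matrix(rep("W", 7), rep("N", 7))
  expect_equal(cm2["W", "N"], 7L)
  expect_equal(sum(cm2), 7)

  a <- sample(c("W", "R", "N"), 60, replace = TRUE)
  b <- sample(c("W", "R", "N"), 60, replace = TRUE)
  expect_equal(unclass(confusion_matrix(a, b)),
               t(unclass(confusion_matrix(b, a))), ignore_attr = TRUE)
  expect_error(confusion_matrix(a, b[1:10]), "different")
})

test_that("accuracy matches the printed offline agreement", {
  expect_equal(accuracy(diag(c(5, 5, 5))), 100)
  expect_equal(accuracy(matrix(c(0, 3, 2, 0), 2)), 0)
  expect_equal(round(accuracy(cm_offline), 1), 87.0)
  expect_equal(round(accuracy(cm_realtime), 1), 82.3)
})

test_that("kappa: perfect, independent, and printed-count cases", {
  expect_equal(cohens_kappa(diag(c(10, 20, 30))), 1)
  # outer-product (statistically independent) counts
  r <- c(30, 20, 50); e <- c(10, 60, 30)
  expect_equal(cohens_kappa(outer(r, e)), 0, tolerance = 1e-12)
  k <- cohens_kappa(cm_offline)
  expect_gt(k, 0.69); expect_lt(k, 0.73)
  expect_warning(kna <- cohens_kappa(matrix(c(9, 0, 0, 0), 2)), "undefined")
  expect_true(is.na(kna))
})

test_that("kappa agrees with an independent implementation", {
  skip_if_not_installed("e1071")
  for (s in 1:5) {
    set.seed(s)
    cm <- matrix(rpois(9, 40), 3)
    expect_equal(cohens_kappa(cm),
                 e1071::classAgreement(cm)$kappa, tolerance = 1e-12)
  }
})

test_that("kappa is 1 iff all mass is diagonal, and permutation-invariant", {
  set.seed(10)
  for (i in 1:20) {
    cm <- matrix(rpois(9, 20), 3, dimnames = dimnames(cm_offline))
    k <- cohens_kappa(cm)
    off <- sum(cm) - sum(diag(cm))
    expect_equal(k == 1, off == 0)
    p <- sample(3)
    expect_equal(cohens_kappa(cm[p, p]), k, tolerance = 1e-12)
  }
})

test_that("sleep/wake collapse merges R and N additively", {
  expect_equal(collapse_sleep_wake(c("W", "R", "N")), c("W", "S", "S"))
  cm2 <- collapse_sleep_wake(cm_offline)
  expect_equal(sum(cm2), sum(cm_offline))
  expect_equal(cm2["S", "S"], 6738 + 2290 + 1484 + 54322)

  # collapsing can only raise accuracy (checked exhaustively on random cms)
  set.seed(11)
  for (i in 1:50) {
    cm <- matrix(rpois(9, 15), 3, dimnames = dimnames(cm_offline))
    expect_gte(accuracy(collapse_sleep_wake(cm)) + 1e-9, accuracy(cm))
  }
})

test_that("row rates reproduce the printed percentages", {
  r <- per_class_rates(cm_realtime)
  expect_equal(round(r["W", ], 1), c(W = 74.8, R = 2.0, N = 23.2))
  r2 <- per_class_rates(cm_offline)
  expect_equal(round(r2["N", ], 1), c(W = 6.0, R = 2.5, N = 91.5))
  expect_equal(unname(rowSums(r2)), rep(100, 3), tolerance = 0.1)
  withzero <- rbind(cm_offline[1:2, ], N = c(0, 0, 0))
  expect_true(all(is.na(per_class_rates(withzero)["N", ])))
})

test_that("concordance correlation matches its closed form", {
  x <- rnorm(50)
  expect_equal(concordance_correlation(x, x), 1)
  x0 <- x - mean(x)
  expect_equal(concordance_correlation(x0, -x0), -1)
  set.seed(13)
  z <- rnorm(1000)
  expect_lt(abs(concordance_correlation(z, z + 1) - 2 / 3), 0.05)
  expect_error(concordance_correlation(z, z[1:10]), "differ")
  expect_error(concordance_correlation(1, 2), "two pairs")
})

test_that("Bland-Altman limits match the analytic construction", {
  x <- rnorm(100)
  ba0 <- bland_altman(x, x)
  expect_equal(as.numeric(ba0[1, 1:3]), c(0, 0, 0))
  ba2 <- bland_altman(x, x + 2)
  expect_equal(as.numeric(ba2[1, 1:3]), c(2, 2, 2))
  set.seed(7)
  y <- x2 <- rnorm(10000)
  y <- x2 + rnorm(10000)
  ba <- bland_altman(x2, y)
  expect_lt(abs(ba$bias), 0.05)
  expect_lt(abs(ba$upper_loa - 1.96), 0.08)
  expect_lt(abs(ba$lower_loa + 1.96), 0.08)
})

test_that("agreement_summary pools epochs and reports per-subject spread", {
  set.seed(5)
  refs <- lapply(1:4, function(i) sample(c("W", "R", "N"), 80, replace = TRUE,
                                         prob = c(0.2, 0.2, 0.6)))
  ests <- lapply(refs, function(r) {
    flip <- runif(80) < 0.15
    r[flip] <- sample(c("W", "R", "N"), sum(flip), replace = TRUE)
    r
  })
  s <- agreement_summary(refs, ests)
  expect_equal(sum(s$pooled$cm3), 320)
  expect_equal(nrow(s$per_subject), 4)
  expect_true(s$pooled$accuracy2 >= s$pooled$accuracy3)
  pooled_acc <- accuracy(Reduce(`+`, Map(confusion_matrix, refs, ests)))
  expect_equal(s$pooled$accuracy3, pooled_acc)
})
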