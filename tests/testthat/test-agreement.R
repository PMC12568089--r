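test_that("per-subject MAE and MAPE follow their definitions", {
  pd <- tibble::tibble(
    subject_id = "S01", t_s = 1:2,
    ref_bpm = c(100, 100), dev_bpm = c(90, 110)
  )
  acc <- accuracy_per_subject(pd)
  expect_equal(acc$per_subject$mae, 10)
  expect_equal(acc$per_subject$mape, 10)

  pd_id <- tibble::tibble(
    subject_id = rep(c("a", "b"), each = 3), t_s = rep(1:3, 2),
    ref_bpm = rep(80, 6), dev_bpm = rep(80, 6)
  )
  acc_id <- accuracy_per_subject(pd_id)
  expect_equal(acc_id$median_mae, 0)
  expect_equal(acc_id$median_mape, 0)

  expect_error(
    accuracy_per_subject(tibble::tibble(
      subject_id = "a", t_s = 1, ref_bpm = 0, dev_bpm = 5
    )),
    "onpositive"
  )
})

test_that("group medians and IQRs follow the declared quantile rule", {
  # hand-computed type-7 quantiles for {2, 4, 9}:
  # median 4; Q1 = 2 + 0.5*(4-2) = 3; Q3 = 4 + 0.5*(9-4) = 6.5; IQR = 3.5
  pd <- dplyr::bind_rows(lapply(seq_along(c(2, 4, 9)), function(i) {
    m <- c(2, 4, 9)[i]
    tibble::tibble(
      subject_id = paste0("S", i), t_s = 1:2,
      ref_bpm = c(100, 100), dev_bpm = c(100 + m, 100 - m)
    )
  }))
  acc <- accuracy_per_subject(pd)
  expect_equal(sort(acc$per_subject$mape), c(2, 4, 9))
  expect_equal(acc$median_mape, 4)
  expect_equal(acc$iqr_mape, 3.5)
})

test_that("condition filtering retains the labelled subset only", {
  pd <- tibble::tibble(
    subject_id = "S01", t_s = 1:4, ref_bpm = rep(100, 4),
    dev_bpm = c(110, 90, 105, 95),
    state = factor(c("steady", "steady", "transition", "transition"),
      levels = c("steady", "transition")),
    transition_id = c(NA, NA, 1L, 2L)
  )
  expect_equal(accuracy_per_subject(pd, condition = "steady")$median_mape, 10)
  expect_equal(accuracy_per_subject(pd, condition = "transition")$median_mape, 5)
  expect_equal(accuracy_per_subject(pd, transition_id = 1)$median_mape, 5)
  expect_error(
    accuracy_per_subject(pd[, 1:4], condition = "steady"),
    "no state labels"
  )
})

test_that("Lin's CCC matches the moment formula and its conventions", {
  expect_equal(lin_ccc(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(lin_ccc(c(1, 2, 3), c(2, 3, 4)), 2 / 3)
  expect_lt(lin_ccc(c(1, 2, 3), c(5, 4, 3)), 0)
  expect_message(v <- lin_ccc(rep(2, 3), rep(2, 3)), "convention")
  expect_equal(v, 1)
  expect_equal(lin_ccc(rep(2, 3), rep(5, 3)), 0)

  # independent oracle: direct sample-moment evaluation on random draws
  set.seed(4)
  x <- rnorm(30, 100, 12)
  y <- 0.8 * x + rnorm(30, 15, 6)
  expected <- 2 * cov(x, y) / (var(x) + var(y) + (mean(x) - mean(y))^2)
  expect_equal(lin_ccc(x, y), expected, tolerance = 1e-12)
})

test_that("rm_ccc reduces to Lin's CCC on single-observation data", {
  set.seed(11)
  for (rep in 1:20) {
    n <- sample(8:20, 1)
    x <- rnorm(n, 90, 12)
    y <- x * runif(1, 0.7, 1.2) + rnorm(n, runif(1, -5, 5), 4)
    pd <- tibble::tibble(
      subject_id = sprintf("S%02d", seq_len(n)), t_s = 1,
      ref_bpm = x, dev_bpm = y
    )
    expect_equal(rm_ccc(pd, n_boot = 0)$estimate, lin_ccc(x, y),
      tolerance = 1e-6)
  }
})

test_that("rm_ccc hits the degenerate and shift limits", {
  pd <- toy_paired(4, 20, bias = 0, sd = 0, seed = 2)
  expect_equal(rm_ccc(pd, n_boot = 0)$estimate, 1) # dev = ref exactly

  shifted <- pd
  shifted$dev_bpm <- shifted$ref_bpm + 500
  expect_lt(rm_ccc(shifted, n_boot = 0)$estimate, 0.01)

  one <- pd[pd$subject_id == "S01", ]
  expect_warning(r1 <- rm_ccc(one, n_boot = 0), "single subject")
  expect_equal(r1$estimate, lin_ccc(one$ref_bpm, one$dev_bpm))
})

test_that("rm_ccc bootstrap CI brackets the estimate", {
  pd <- toy_paired(8, 15, bias = 1, sd = 4, seed = 3)
  r <- rm_ccc(pd, n_boot = 40, seed = 5)
  expect_true(r$ci[1] <= r$estimate && r$estimate <= r$ci[2])
  expect_true(all(abs(c(r$estimate, r$ci)) <= 1))
  r2 <- rm_ccc(pd, n_boot = 40, seed = 5)
  expect_identical(r, r2) # seeded bootstrap is reproducible
})

test_that("rm_spearman captures monotone association on ranks", {
  set.seed(21)
  pd <- toy_paired(5, 25, bias = 0, sd = 0, seed = 4)
  pd$dev_bpm <- exp(pd$ref_bpm / 40) # strictly increasing transform
  expect_equal(rm_spearman(pd, n_boot = 0)$estimate, 1)

  rev <- toy_paired(5, 25, bias = 0, sd = 0, seed = 5)
  rev$dev_bpm <- -rev$ref_bpm
  expect_equal(rm_spearman(rev, n_boot = 0)$estimate, -1)

  # independent streams: near-zero estimate across seeds
  ests <- vapply(1:20, function(s) {
    set.seed(s)
    pd0 <- tibble::tibble(
      subject_id = rep(sprintf("S%02d", 1:8), each = 120),
      t_s = rep(1:120, 8),
      ref_bpm = rnorm(960, 100, 10), dev_bpm = rnorm(960, 100, 10)
    )
    rm_spearman(pd0, n_boot = 0)$estimate
  }, 0)
  expect_lt(max(abs(ests)), 0.1)

  cst <- toy_paired(3, 10, seed = 6)
  cst$dev_bpm <- 100
  expect_error(rm_spearman(cst, n_boot = 0), "constant")
})

test_that("mixed-model Bland-Altman recovers degenerate and exact cases", {
  pd <- toy_paired(4, 10, bias = 0, sd = 0, seed = 7)
  ba0 <- lmm_bland_altman(pd)
  expect_equal(ba0$bias, 0)
  expect_equal(c(ba0$loa_lower, ba0$loa_upper), c(0, 0))
  expect_equal(ba0$bias_p, 1)

  pd$dev_bpm <- pd$ref_bpm + 3 # all differences exactly 3
  ba3 <- lmm_bland_altman(pd)
  expect_equal(ba3$bias, 3)
  expect_equal(c(ba3$loa_lower, ba3$loa_upper), c(3, 3))
  expect_equal(ba3$bias_p, 0)
})

test_that("mixed-model Bland-Altman partitions subject and residual spread", {
  set.seed(12)
  n_sub <- 24
  d <- unlist(lapply(seq_len(n_sub), function(i) {
    2 + rnorm(1, 0, 1) + rnorm(100, 0, 3)
  }))
  pd <- tibble::tibble(
    subject_id = rep(sprintf("S%02d", seq_len(n_sub)), each = 100),
    t_s = rep(seq_len(100), n_sub),
    ref_bpm = 90, dev_bpm = 90 + d
  )
  ba <- lmm_bland_altman(pd)
  expect_lt(abs(ba$bias - 2), 3 * sqrt(1 / 24 + 9 / 2400))
  half <- (ba$loa_upper - ba$loa_lower) / 2
  expect_lt(abs(half - 1.96 * sqrt(10)) / (1.96 * sqrt(10)), 0.10)
  expect_lt(ba$bias_p, 0.001)
  # LoA symmetric about the bias by construction
  expect_equal(ba$loa_upper - ba$bias, ba$bias - ba$loa_lower)
})

test_that("zero subject variance reduces to pooled limits with a warning", {
  set.seed(13)
  pd <- tibble::tibble(
    subject_id = rep(c("a", "b", "c", "d"), each = 50),
    t_s = rep(1:50, 4), ref_bpm = 100,
    dev_bpm = 100 + rnorm(200, 0, 2) # no subject-level component
  )
  expect_warning(ba <- lmm_bland_altman(pd), "boundary")
  expect_equal(ba$sigma_u, 0)
  expect_lt(abs((ba$loa_upper - ba$loa_lower) / 2 - 1.96 * sd(
    pd$dev_bpm - pd$ref_bpm
  )), 0.2)
})

test_that("adding a constant to both streams leaves shift-invariant metrics", {
  pd <- toy_paired(6, 30, bias = 1.5, sd = 4, seed = 9)
  pd_shift <- pd
  pd_shift$ref_bpm <- pd$ref_bpm + 25
  pd_shift$dev_bpm <- pd$dev_bpm + 25

  a <- accuracy_per_subject(pd)
  b <- accuracy_per_subject(pd_shift)
  expect_equal(a$median_mae, b$median_mae)
  expect_gt(a$median_mape, b$median_mape) # denominator grows

  ba_a <- suppressWarnings(lmm_bland_altman(pd))
  ba_b <- suppressWarnings(lmm_bland_altman(pd_shift))
  expect_equal(ba_a$bias, ba_b$bias, tolerance = 1e-8)
  expect_equal(ba_a$loa_upper - ba_a$loa_lower,
    ba_b$loa_upper - ba_b$loa_lower, tolerance = 1e-8)

  expect_equal(rm_spearman(pd, n_boot = 0)$estimate,
    rm_spearman(pd_shift, n_boot = 0)$estimate, tolerance = 1e-10)
})

test_that("threshold verdicts apply the printed cut-points", {
  acc_good <- accuracy_per_subject(toy_paired(5, 20, bias = 0, sd = 2,
    seed = 10))
  v <- classify_thresholds(acc_good, 0.77)
  expect_equal(v$cc_band, "strong")
  expect_false(v$cc_acceptable)

  expect_equal(classify_thresholds(acc_good, 0.5)$cc_band, "weak")
  expect_equal(classify_thresholds(acc_good, 0.6)$cc_band, "moderate")
  expect_true(classify_thresholds(acc_good, 0.80)$cc_acceptable)
  expect_true(v$mape_acceptable)

  # boundary: median MAPE of exactly 10% is acceptable
  pd10 <- tibble::tibble(
    subject_id = rep(c("a", "b", "c", "d", "e"), each = 2),
    t_s = rep(1:2, 5), ref_bpm = 100,
    dev_bpm = rep(c(110, 90), 5)
  )
  acc10 <- accuracy_per_subject(pd10)
  acc10$median_mae <- 11 # force the MAE clause off
  expect_true(classify_thresholds(acc10, 0.9)$mape_acceptable)
})
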