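test_that("noise-free reference settles on the phase targets", {
  p <- build_default_protocol()
  sp <- subject_params(resting_hr = 70, hrv_sd = 0, tau = 20,
    orthostatic_amp = 0)
  ref <- simulate_reference_hr(p, sp, seed = 1)
  expect_equal(nrow(ref), 1200)
  expect_equal(ref$t_s, 0:1199)

  # at onset + 5 tau the trajectory is within 1% of the step size
  targets <- sp$phase_targets[as.character(p$phases$load)]
  onsets <- p$phases$onset_s
  for (k in 2:6) {
    step <- abs(targets[k] - targets[k - 1])
    if (step == 0) next
    t_check <- onsets[k] + 5 * sp$tau
    hr_at <- ref$hr_bpm[ref$t_s == t_check]
    expect_lt(abs(hr_at - targets[k]), 0.011 * step)
  }

  # near-zero tau: HR tracks the target almost immediately
  sp_fast <- subject_params(resting_hr = 70, hrv_sd = 0, tau = 1e-3,
    orthostatic_amp = 0)
  ref_fast <- simulate_reference_hr(p, sp_fast, seed = 1)
  expect_equal(
    ref_fast$hr_bpm,
    unname(targets[findInterval(ref_fast$t_s, onsets)]),
    tolerance = 1e-6
  )
})

test_that("orthostatic pulse adds a decaying peak at the sit-stand onset", {
  p <- build_default_protocol()
  sp0 <- subject_params(hrv_sd = 0, orthostatic_amp = 0)
  sp1 <- subject_params(hrv_sd = 0, orthostatic_amp = 10, orthostatic_tau = 20)
  d <- simulate_reference_hr(p, sp1, 1)$hr_bpm -
    simulate_reference_hr(p, sp0, 1)$hr_bpm
  expect_equal(d[180 + 1], 10) # t = 180, 0-based indexing into t_s
  expect_equal(d[180 + 20 + 1], 10 * exp(-1), tolerance = 1e-8)
  expect_true(all(d[1:180] == 0))
})

test_that("reference simulation is deterministic given the seed", {
  p <- build_default_protocol()
  sp <- subject_params()
  a <- simulate_reference_hr(p, sp, seed = 42)
  b <- simulate_reference_hr(p, sp, seed = 42)
  expect_identical(a, b)
  c <- simulate_reference_hr(p, sp, seed = 43)
  expect_false(isTRUE(all.equal(a$hr_bpm, c$hr_bpm)))
})

test_that("AR(1) noise has the requested stationary SD", {
  p <- build_default_protocol()
  sp0 <- subject_params(hrv_sd = 0)
  sp1 <- subject_params(hrv_sd = 3)
  noise <- simulate_reference_hr(p, sp1, seed = 9)$hr_bpm -
    simulate_reference_hr(p, sp0, seed = 9)$hr_bpm
  expect_lt(abs(sd(noise) - 3) / 3, 0.10)
  # and the lag-1 autocorrelation reflects phi = 0.8
  expect_gt(cor(noise[-1], noise[-length(noise)]), 0.6)
})

test_that("zero-error device on a 1 s schedule reproduces the reference", {
  p <- build_default_protocol()
  ref <- simulate_reference_hr(p, subject_params(), seed = 2)
  tw <- derive_transitions(p)
  em <- device_error_model(schedule = schedule_fixed(1), lag_window = 1)
  dev <- simulate_device(ref, em, tw, seed = 3)
  expect_equal(dev$t_s, ref$t_s)
  expect_equal(dev$hr_bpm, ref$hr_bpm)
})

test_that("bias shifts the trailing mean and dropout empties the stream", {
  p <- build_default_protocol()
  ref <- simulate_reference_hr(p, subject_params(hrv_sd = 0), seed = 2)
  em_b <- device_error_model(schedule = schedule_fixed(1), lag_window = 1,
    bias = 5)
  dev_b <- simulate_device(ref, em_b, seed = 3)
  expect_equal(dev_b$hr_bpm, ref$hr_bpm + 5)

  em_d <- device_error_model(dropout_p = 1)
  expect_error(device_error_model(dropout_p = 1.2), "\\[0, 1\\]")
  expect_equal(nrow(simulate_device(ref, em_d, seed = 3)), 0)

  empty <- ref[0, ]
  expect_equal(nrow(simulate_device(empty, em_b, seed = 1)), 0)
})

test_that("trailing-mean lag smooths the reported signal", {
  p <- build_default_protocol()
  ref <- simulate_reference_hr(p, subject_params(hrv_sd = 0), seed = 2)
  em <- device_error_model(schedule = schedule_fixed(1), lag_window = 10)
  dev <- simulate_device(ref, em, seed = 3)
  t_check <- 400
  expected <- mean(ref$hr_bpm[ref$t_s > t_check - 10 & ref$t_s <= t_check])
  expect_equal(dev$hr_bpm[dev$t_s == t_check], expected)
})

test_that("jittered schedules hit the target mean reporting interval", {
  p <- build_default_protocol()
  ref <- simulate_reference_hr(p, subject_params(), seed = 2)
  em <- device_error_model(schedule = schedule_jittered(1, 110, 10),
    lag_window = 10)
  counts <- vapply(1:5, function(s) {
    nrow(simulate_device(ref, em, seed = s))
  }, 0L)
  expect_lt(abs(mean(counts) - 120) / 120, 0.2)
  gaps <- diff(simulate_device(ref, em, seed = 1)$t_s)
  expect_true(all(gaps >= 1 & gaps <= 110))
})

test_that("motion-window noise inflation only affects transitions", {
  p <- build_default_protocol()
  tw <- derive_transitions(p)
  ref <- simulate_reference_hr(p, subject_params(hrv_sd = 0), seed = 2)
  em <- device_error_model(schedule = schedule_fixed(1), lag_window = 1,
    noise_sd_steady = 1, noise_sd_motion = 12)
  dev <- simulate_device(ref, em, tw, seed = 4)
  err <- dev$hr_bpm - ref$hr_bpm[match(dev$t_s, ref$t_s)]
  lab <- label_timestamps(dev$t_s, tw)
  expect_gt(sd(err[lab$state == "transition"]),
    3 * sd(err[lab$state == "steady"]))
})

test_that("cohort generation is reproducible and correctly sized", {
  profiles <- default_device_profiles()[c("chest_1s", "wrist_60s")]
  coh <- generate_cohort(3, profiles, seed = 5)
  expect_equal(nrow(coh$reference), 3 * 1200)
  expect_equal(names(coh$devices), names(profiles))
  expect_equal(length(coh$subject_params), 3)

  coh2 <- generate_cohort(3, profiles, seed = 5)
  expect_identical(coh$reference, coh2$reference)
  expect_identical(coh$devices, coh2$devices)

  # different seed: same schedule structure, different noise realizations
  coh3 <- generate_cohort(3, profiles, seed = 6)
  expect_false(isTRUE(all.equal(coh$reference$hr_bpm, coh3$reference$hr_bpm)))

  expect_error(generate_cohort(0), ">= 1")
})

test_that("adding a device profile never perturbs existing series", {
  p1 <- default_device_profiles()[c("chest_1s")]
  p2 <- default_device_profiles()[c("chest_1s", "wrist_1_3s")]
  a <- generate_cohort(2, p1, seed = 8)
  b <- generate_cohort(2, p2, seed = 8)
  expect_identical(a$reference, b$reference)
  expect_identical(a$devices$chest_1s, b$devices$chest_1s)
})

test_that("cohort CSV export is byte-identical for identical inputs", {
  coh <- generate_cohort(2, default_device_profiles()["chest_1s"], seed = 3)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_cohort_csv(coh, d1)
  write_cohort_csv(generate_cohort(2, default_device_profiles()["chest_1s"],
    seed = 3), d2)
  for (f in list.files(d1)) {
    expect_identical(
      readLines(file.path(d1, f)), readLines(file.path(d2, f))
    )
  }
  # and the CSVs round-trip through the reader
  streams <- read_hr_csv(d1)
  ref_back <- streams[streams$device_id == "reference", ]
  expect_equal(nrow(ref_back), nrow(coh$reference))
  expect_equal(ref_back$hr_bpm, round(coh$reference$hr_bpm, 6))
})

test_that("ISO 8601 timestamps convert to seconds from protocol start", {
  f <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(
    subject_id = "S01", device_id = "d",
    timestamp = c("2025-01-01T10:00:00Z", "2025-01-01T10:00:05.7Z"),
    hr_bpm = c(70, 71)
  ), f, row.names = FALSE)
  out <- read_hr_csv(f, protocol_start = "2025-01-01T10:00:00Z")
  expect_equal(out$t_s, c(0, 5)) # sub-second input floored
})
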