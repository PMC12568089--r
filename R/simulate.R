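#' Physiological parameters of one simulated subject
#'
#' Parameters of the generative heart-rate model: a first-order relaxation
#' towards a load-specific target, an exponentially decaying orthostatic
#' pulse at the sit-to-stand onset, and stationary AR(1) heart-rate
#' variability.
#'
#' @param resting_hr Resting (sitting) heart rate, bpm; must lie in
#'   `[40, 120]`.
#' @param phase_targets Named numeric vector mapping load levels to
#'   steady-state target heart rates (bpm); must be nondecreasing in load
#'   order.
#' @param tau First-order response time constant, seconds (> 0). Typical
#'   heart-rate on-kinetics for light-to-moderate exercise are 20-45 s.
#' @param orthostatic_amp Amplitude (bpm) of the transient peak added at the
#'   sit-to-stand transition.
#' @param orthostatic_tau Decay time constant (s) of that peak.
#' @param hrv_sd Stationary standard deviation (bpm) of the AR(1)
#'   heart-rate-variability noise.
#' @param hrv_phi AR(1) coefficient in `[0, 1)`.
#'
#' @return A `subject_params` list.
#' @export
subject_params <- function(resting_hr = 70,
                           phase_targets = c(
                             sit = resting_hr,
                             stand = resting_hr + 8,
                             walk4 = resting_hr + 28,
                             walk6 = resting_hr + 42,
                             walk6_incline = resting_hr + 53
                           ),
                           tau = 35,
                           orthostatic_amp = 12,
                           orthostatic_tau = 20,
                           hrv_sd = 2.5,
                           hrv_phi = 0.8) {
  if (resting_hr < 40 || resting_hr > 120) {
    stop("resting_hr must lie in [40, 120] bpm", call. = FALSE)
  }
  if (tau <= 0) stop("tau must be positive", call. = FALSE)
  if (hrv_phi < 0 || hrv_phi >= 1) {
    stop("hrv_phi must lie in [0, 1)", call. = FALSE)
  }
  if (is.unsorted(phase_targets)) {
    stop("phase_targets must be nondecreasing in load level", call. = FALSE)
  }
  structure(
    list(
      resting_hr = resting_hr, phase_targets = phase_targets, tau = tau,
      orthostatic_amp = orthostatic_amp, orthostatic_tau = orthostatic_tau,
      hrv_sd = hrv_sd, hrv_phi = hrv_phi
    ),
    class = "subject_params"
  )
}

#' Draw subject parameters from the cohort population model
#'
#' Resting heart rate is Normal(70, 8^2) bpm truncated to `[50, 95]`; the
#' steady-state increments between consecutive load levels are drawn
#' independently from truncated normals so targets are nondecreasing; the
#' response time constant, orthostatic amplitude and HRV level vary
#' moderately between subjects.
#'
#' @param seed Integer seed; the draw is fully determined by it.
#' @return A [subject_params()] object.
#' @export
draw_subject_params <- function(seed) {
  set.seed(seed)
  rtnorm <- function(mu, sd, lo, hi) min(hi, max(lo, rnorm(1, mu, sd)))
  resting <- rtnorm(70, 8, 50, 95)
  inc_stand <- rtnorm(8, 2, 2, 16)
  inc_walk4 <- rtnorm(20, 4, 6, 34)
  inc_walk6 <- rtnorm(14, 3, 4, 26)
  inc_incline <- rtnorm(11, 3, 3, 22)
  subject_params(
    resting_hr = resting,
    phase_targets = c(
      sit = resting,
      stand = resting + inc_stand,
      walk4 = resting + inc_stand + inc_walk4,
      walk6 = resting + inc_stand + inc_walk4 + inc_walk6,
      walk6_incline = resting + inc_stand + inc_walk4 + inc_walk6 + inc_incline
    ),
    tau = rtnorm(35, 6, 18, 55),
    orthostatic_amp = rtnorm(12, 3, 4, 20),
    orthostatic_tau = 20,
    hrv_sd = rtnorm(2.5, 0.5, 1, 4),
    hrv_phi = 0.8
  )
}

phase_target_trace <- function(protocol, sp, times) {
  loads <- as.character(protocol$phases$load)
  miss <- setdiff(loads, names(sp$phase_targets))
  if (length(miss) > 0) {
    stop(
      "phase_targets missing load level(s): ", paste(miss, collapse = ", "),
      call. = FALSE
    )
  }
  idx <- findInterval(times, protocol$phases$onset_s)
  unname(sp$phase_targets[loads[idx]])
}

#' Simulate a 1 Hz reference heart-rate series
#'
#' Generates the ground-truth heart-rate trajectory of one subject over the
#' protocol at 1 Hz (integer seconds `0 .. duration - 1`). The deterministic
#' part follows the first-order relaxation
#' `dHR/dt = (target(phase) - HR) / tau` integrated exactly between samples,
#' plus an additive orthostatic pulse
#' `orthostatic_amp * exp(-(t - t1) / orthostatic_tau)` starting at the first
#' sit-to-stand phase change `t1` (omitted when the protocol has none).
#' Stationary AR(1) noise with coefficient `hrv_phi` and stationary SD
#' `hrv_sd` is added on top. The series is fully determined by `seed`.
#'
#' @inheritParams protocol_duration
#' @param sp A [subject_params()] object.
#' @param seed Integer seed for the noise stream.
#' @param subject_id,device_id Labels stored in the output.
#'
#' @return A heart-rate series: a tibble with columns `subject_id`,
#'   `device_id`, `t_s`, `hr_bpm`, timestamps strictly increasing.
#' @export
simulate_reference_hr <- function(protocol, sp, seed,
                                  subject_id = "S01",
                                  device_id = "reference") {
  stopifnot(inherits(protocol, "hr_protocol"), inherits(sp, "subject_params"))
  if (sp$tau <= 0) stop("tau must be positive", call. = FALSE)
  dur <- protocol_duration(protocol)
  t <- seq(protocol$start_time, protocol$start_time + dur - 1)
  target <- phase_target_trace(protocol, sp, t)

  hr <- numeric(length(t))
  a <- exp(-1 / sp$tau)
  hr[1] <- target[1]
  for (i in seq_along(t)[-1]) {
    hr[i] <- target[i] + (hr[i - 1] - target[i]) * a
  }

  # orthostatic peak at the first sit -> stand boundary, if present
  loads <- as.character(protocol$phases$load)
  b <- which(loads[-length(loads)] == "sit" & loads[-1] == "stand")
  if (length(b) > 0 && sp$orthostatic_amp > 0) {
    t1 <- protocol$phases$end_s[b[1]]
    after <- t >= t1
    hr[after] <- hr[after] +
      sp$orthostatic_amp * exp(-(t[after] - t1) / sp$orthostatic_tau)
  }

  if (sp$hrv_sd > 0) {
    set.seed(seed)
    innov_sd <- sp$hrv_sd * sqrt(1 - sp$hrv_phi^2)
    e <- numeric(length(t))
    e[1] <- rnorm(1, 0, sp$hrv_sd)
    innov <- rnorm(length(t) - 1, 0, innov_sd)
    for (i in seq_along(t)[-1]) e[i] <- sp$hrv_phi * e[i - 1] + innov[i - 1]
    hr <- hr + e
  }

  hr <- pmin(pmax(hr, 25), 245) # physiological clamp
  tibble::tibble(
    subject_id = subject_id, device_id = device_id,
    t_s = t, hr_bpm = hr
  )
}

#' Observation model of one simulated device
#'
#' Describes how a wearable corrupts the reference heart rate: a reporting
#' schedule, trailing-mean smoothing (`lag_window`), additive bias, Gaussian
#' read noise whose SD is inflated inside transition windows, per-sample
#' dropout, burst dropout, and optional integer rounding.
#'
#' @param schedule One of `schedule_fixed()`, `schedule_jittered()`,
#'   `schedule_minute()`.
#' @param lag_window Trailing smoothing span, seconds (>= 1); each report at
#'   time `t` is the mean of reference samples in `(t - lag_window, t]`.
#' @param bias Additive bias, bpm.
#' @param noise_sd_steady,noise_sd_motion Read-noise SD (bpm) outside and
#'   inside transition windows; `noise_sd_motion >= noise_sd_steady >= 0`.
#' @param dropout_p Probability in `[0, 1]` that a scheduled sample is
#'   dropped.
#' @param burst_rate Expected number of dropout bursts per 1000 s.
#' @param burst_mean_len Mean burst length, seconds (exponential).
#' @param round_to_integer Round reported bpm to integers?
#'
#' @return A `device_error_model` list.
#' @export
device_error_model <- function(schedule = schedule_fixed(1),
                               lag_window = 1,
                               bias = 0,
                               noise_sd_steady = 0,
                               noise_sd_motion = noise_sd_steady,
                               dropout_p = 0,
                               burst_rate = 0,
                               burst_mean_len = 0,
                               round_to_integer = FALSE) {
  if (noise_sd_steady < 0 || noise_sd_motion < noise_sd_steady) {
    stop("need noise_sd_motion >= noise_sd_steady >= 0", call. = FALSE)
  }
  if (dropout_p < 0 || dropout_p > 1) {
    stop("dropout_p must lie in [0, 1]", call. = FALSE)
  }
  if (lag_window < 1) stop("lag_window must be >= 1 s", call. = FALSE)
  structure(
    list(
      schedule = schedule, lag_window = lag_window, bias = bias,
      noise_sd_steady = noise_sd_steady, noise_sd_motion = noise_sd_motion,
      dropout_p = dropout_p, burst_rate = burst_rate,
      burst_mean_len = burst_mean_len, round_to_integer = round_to_integer
    ),
    class = "device_error_model"
  )
}

#' Device reporting schedules
#'
#' `schedule_fixed(interval)` reports every `interval` seconds starting at
#' the first reference timestamp. `schedule_jittered(min, max, mean)` draws
#' integer inter-report gaps from a shifted log-normal calibrated so the mean
#' gap is about `mean`, clamped to `[min, max]`. `schedule_minute()` is
#' shorthand for a fixed 60 s schedule.
#'
#' @param interval Fixed reporting interval, seconds (>= 1).
#' @param min,max,mean Gap range and average for the jittered schedule.
#' @return A `device_schedule` list.
#' @export
schedule_fixed <- function(interval = 1) {
  stopifnot(interval >= 1)
  structure(list(type = "fixed", interval = interval), class = "device_schedule")
}

#' @rdname schedule_fixed
#' @export
schedule_jittered <- function(min = 1, max = 110, mean = 10) {
  stopifnot(min >= 1, max >= min, mean >= min, mean <= max)
  structure(
    list(type = "jittered", min = min, max = max, mean = mean),
    class = "device_schedule"
  )
}

#' @rdname schedule_fixed
#' @export
schedule_minute <- function() {
  structure(list(type = "fixed", interval = 60), class = "device_schedule")
}

realize_schedule <- function(schedule, t0, t_end) {
  if (schedule$type == "fixed") {
    return(seq(t0, t_end, by = schedule$interval))
  }
  # shifted log-normal gaps: gap = min + X, E[X] targeted at mean - min
  sigma <- 0.9
  mu <- log(max(schedule$mean - schedule$min, 0.5)) - sigma^2 / 2
  times <- numeric(0)
  t <- t0
  span <- t_end - t0
  n_guess <- max(16L, ceiling(2.5 * span / schedule$mean))
  repeat {
    gaps <- schedule$min + stats::rlnorm(n_guess, mu, sigma)
    gaps <- pmin(pmax(round(gaps), schedule$min), schedule$max)
    t_new <- t + cumsum(gaps)
    times <- c(times, t_new)
    t <- times[length(times)]
    if (t > t_end) break
  }
  times[times <= t_end]
}

#' Simulate a device stream from a reference series
#'
#' Realizes the device's reporting schedule over the reference span, then for
#' each scheduled report time `t` emits the mean of the reference over
#' `(t - lag_window, t]` plus bias plus Gaussian noise whose SD is
#' `noise_sd_motion` when `t` lies in a transition window and
#' `noise_sd_steady` otherwise. Scheduled samples are dropped independently
#' with probability `dropout_p` and during burst-dropout intervals; values
#' are optionally rounded to integer bpm. Deterministic given `seed`.
#'
#' @param ref A 1 Hz reference series from [simulate_reference_hr()] (one
#'   subject).
#' @param em A [device_error_model()].
#' @param tw Transition windows from [derive_transitions()] (used to switch
#'   the noise level); may be `NULL` for steady noise throughout.
#' @param seed Integer seed.
#' @param device_id Label stored in the output.
#'
#' @return A heart-rate series tibble (possibly zero rows under heavy
#'   dropout).
#' @export
simulate_device <- function(ref, em, tw = NULL, seed = 1,
                            device_id = "device") {
  stopifnot(inherits(em, "device_error_model"))
  if (nrow(ref) == 0) {
    return(tibble::tibble(
      subject_id = character(0), device_id = character(0),
      t_s = numeric(0), hr_bpm = numeric(0)
    ))
  }
  set.seed(seed)
  t0 <- min(ref$t_s)
  t_end <- max(ref$t_s)
  times <- realize_schedule(em$schedule, t0, t_end)

  rt <- ref$t_s
  cs <- cumsum(ref$hr_bpm)
  lo <- findInterval(times - em$lag_window, rt)
  hi <- findInterval(times, rt)
  n_in <- hi - lo
  keep <- n_in > 0
  times <- times[keep]
  lo <- lo[keep]
  hi <- hi[keep]
  n_in <- n_in[keep]
  vals <- (cs[hi] - ifelse(lo == 0, 0, cs[pmax(lo, 1)])) / n_in

  in_motion <- rep(FALSE, length(times))
  if (!is.null(tw) && nrow(tw) > 0) {
    for (k in seq_len(nrow(tw))) {
      in_motion <- in_motion | (times >= tw$start_s[k] & times <= tw$end_s[k])
    }
  }
  sds <- ifelse(in_motion, em$noise_sd_motion, em$noise_sd_steady)
  vals <- vals + em$bias
  if (any(sds > 0)) vals <- vals + rnorm(length(vals), 0, sds)

  drop <- runif(length(times)) < em$dropout_p
  if (em$burst_rate > 0 && em$burst_mean_len > 0) {
    span <- t_end - t0 + 1
    n_bursts <- rpois(1, em$burst_rate * span / 1000)
    if (n_bursts > 0) {
      starts <- runif(n_bursts, t0, t_end)
      lens <- rexp(n_bursts, 1 / em$burst_mean_len)
      for (k in seq_len(n_bursts)) {
        drop <- drop | (times >= starts[k] & times <= starts[k] + lens[k])
      }
    }
  }
  times <- times[!drop]
  vals <- vals[!drop]
  if (em$round_to_integer) vals <- round(vals)
  vals <- pmin(pmax(vals, 25), 245)

  tibble::tibble(
    subject_id = ref$subject_id[1], device_id = device_id,
    t_s = times, hr_bpm = vals
  )
}

#' Default device observation profiles
#'
#' Six stylized profiles spanning the reporting behaviours found in
#' commercial and research wearables: a 1 s chest-strap-like device with
#' small noise; a 1-3 s jittered wrist device; an irregular ~10 s wrist
#' device (gaps 1-110 s); a 60 s-reporting wrist device with conservative
#' motion rejection; a 1 s wrist device with heavy motion noise; and a
#' second irregular ~10 s wrist device (gaps 1-90 s) with positive bias.
#' All wrist profiles have `noise_sd_motion` well above `noise_sd_steady`,
#' emulating motion-artefact-inflated error during transitions.
#'
#' @return A named list of [device_error_model()] objects.
#' @export
default_device_profiles <- function() {
  list(
    chest_1s = device_error_model(
      schedule = schedule_fixed(1), lag_window = 5, bias = -0.3,
      noise_sd_steady = 1.2, noise_sd_motion = 2.0,
      dropout_p = 0, round_to_integer = TRUE
    ),
    wrist_1_3s = device_error_model(
      schedule = schedule_jittered(1, 3, 2), lag_window = 8, bias = 0.5,
      noise_sd_steady = 3.5, noise_sd_motion = 7.5,
      dropout_p = 0.05, round_to_integer = TRUE
    ),
    wrist_irregular_10s = device_error_model(
      schedule = schedule_jittered(1, 110, 10), lag_window = 10, bias = 2,
      noise_sd_steady = 3, noise_sd_motion = 8,
      dropout_p = 0.02, round_to_integer = TRUE
    ),
    wrist_60s = device_error_model(
      schedule = schedule_minute(), lag_window = 60, bias = -0.5,
      noise_sd_steady = 4, noise_sd_motion = 10,
      dropout_p = 0.1, burst_rate = 0.5, burst_mean_len = 60,
      round_to_integer = TRUE
    ),
    wrist_1s = device_error_model(
      schedule = schedule_fixed(1), lag_window = 10, bias = -0.4,
      noise_sd_steady = 5, noise_sd_motion = 11,
      dropout_p = 0.08, round_to_integer = TRUE
    ),
    wrist_irregular_10s_b = device_error_model(
      schedule = schedule_jittered(1, 90, 10), lag_window = 10, bias = 3.5,
      noise_sd_steady = 4.5, noise_sd_motion = 10,
      dropout_p = 0.1, round_to_integer = TRUE
    )
  )
}

child_seed <- function(seed, i, j = 0) {
  as.integer((as.double(seed) %% 2147483647 + i * 15485863 + j * 32452843) %%
    2147483647)
}

#' Generate a synthetic validation cohort
#'
#' Draws per-subject physiology from the population model, simulates one
#' 1 Hz reference series per subject and one device stream per (subject,
#' device-profile) pair. All randomness flows from the single root `seed`
#' through per-(subject, device) derived streams, so adding a device profile
#' never perturbs the reference or the other devices.
#'
#' @param n_subjects Number of subjects (>= 1); default 24.
#' @param profiles Named list of [device_error_model()] objects; defaults to
#'   [default_device_profiles()].
#' @param seed Integer root seed.
#' @inheritParams protocol_duration
#' @param pre_span,post_span Transition spans (s) used for motion-noise
#'   switching, as in [derive_transitions()].
#'
#' @return An `hr_cohort` list: `protocol`, `transitions`, `reference`
#'   (tibble of all subjects' reference samples), `devices` (named list of
#'   tibbles, one per profile), `subject_params`, `seed`.
#' @examples
#' coh <- generate_cohort(2, default_device_profiles()["chest_1s"], seed = 7)
#' nrow(coh$reference) # 2 subjects x 1200 s
#' @export
generate_cohort <- function(n_subjects = 24,
                            profiles = default_device_profiles(),
                            seed = 1,
                            protocol = build_default_protocol(),
                            pre_span = 10, post_span = 60) {
  if (n_subjects < 1) stop("n_subjects must be >= 1", call. = FALSE)
  if (length(profiles) > 0 &&
    (is.null(names(profiles)) || any(names(profiles) == ""))) {
    stop("profiles must be a named list", call. = FALSE)
  }
  tw <- derive_transitions(protocol, pre_span, post_span)
  ids <- sprintf("S%02d", seq_len(n_subjects))
  sps <- lapply(seq_len(n_subjects), function(i) {
    draw_subject_params(child_seed(seed, i, 0))
  })
  names(sps) <- ids
  reference <- dplyr::bind_rows(lapply(seq_len(n_subjects), function(i) {
    simulate_reference_hr(
      protocol, sps[[i]],
      seed = child_seed(seed, i, 1),
      subject_id = ids[i]
    )
  }))
  devices <- lapply(seq_along(profiles), function(j) {
    dplyr::bind_rows(lapply(seq_len(n_subjects), function(i) {
      ref_i <- reference[reference$subject_id == ids[i], ]
      simulate_device(
        ref_i, profiles[[j]], tw,
        seed = child_seed(seed, i, j + 1),
        device_id = names(profiles)[j]
      )
    }))
  })
  names(devices) <- names(profiles)
  structure(
    list(
      protocol = protocol, transitions = tw, reference = reference,
      devices = devices, subject_params = sps, seed = seed
    ),
    class = "hr_cohort"
  )
}

#' @export
print.hr_cohort <- function(x, ...) {
  cat(sprintf(
    "<hr_cohort> %d subjects, %d device profiles, seed %d\n",
    length(unique(x$reference$subject_id)), length(x$devices), x$seed
  ))
  cat(
    " reference samples:", nrow(x$reference), "| device samples:",
    paste(sprintf("%s=%d", names(x$devices), vapply(x$devices, nrow, 0L)),
      collapse = " "
    ), "\n"
  )
  invisible(x)
}

#' Write a cohort to CSV files plus a JSON manifest
#'
#' One CSV per stream (columns `subject_id`, `device_id`, `t_s`, `hr_bpm`)
#' named `<device_id>.csv`, plus `manifest.json` recording the seed, profile
#' parameters and subject draws. Output is byte-identical for identical
#' inputs.
#'
#' @param cohort An `hr_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort_csv <- function(cohort, dir) {
  stopifnot(inherits(cohort, "hr_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  emit <- function(df, name) {
    df <- as.data.frame(df)
    df$hr_bpm <- round(df$hr_bpm, 6)
    utils::write.csv(df, file.path(dir, paste0(name, ".csv")),
      row.names = FALSE
    )
  }
  emit(cohort$reference, "reference")
  for (nm in names(cohort$devices)) emit(cohort$devices[[nm]], nm)
  manifest <- list(
    seed = cohort$seed,
    n_subjects = length(unique(cohort$reference$subject_id)),
    devices = names(cohort$devices),
    subject_params = lapply(cohort$subject_params, function(sp) {
      list(
        resting_hr = sp$resting_hr,
        phase_targets = as.list(sp$phase_targets),
        tau = sp$tau, orthostatic_amp = sp$orthostatic_amp,
        orthostatic_tau = sp$orthostatic_tau,
        hrv_sd = sp$hrv_sd, hrv_phi = sp$hrv_phi
      )
    })
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(dir)
}

#' Read heart-rate series from a CSV file or directory
#'
#' Accepts the CSV layout written by [write_cohort_csv()]: columns
#' `subject_id`, `device_id`, `t_s` (seconds from protocol start) and
#' `hr_bpm`. A `timestamp` column in ISO 8601 may be supplied instead of
#' `t_s`; it is converted to integer seconds from `protocol_start`
#' (sub-second input is floored).
#'
#' @param path A CSV file, or a directory whose `*.csv` files are all read
#'   and row-bound.
#' @param protocol_start Optional ISO 8601 time of protocol start, required
#'   when timestamps are ISO 8601.
#' @return A tibble with columns `subject_id`, `device_id`, `t_s`, `hr_bpm`.
#' @export
read_hr_csv <- function(path, protocol_start = NULL) {
  files <- if (dir.exists(path)) {
    list.files(path, pattern = "\\.csv$", full.names = TRUE)
  } else {
    path
  }
  out <- dplyr::bind_rows(lapply(files, function(f) {
    df <- utils::read.csv(f, stringsAsFactors = FALSE)
    if (!"t_s" %in% names(df)) {
      if (!"timestamp" %in% names(df)) {
        stop("need a 't_s' or 'timestamp' column in ", f, call. = FALSE)
      }
      if (is.null(protocol_start)) {
        stop("ISO 8601 timestamps need 'protocol_start'", call. = FALSE)
      }
      parse_iso <- function(x) {
        as.numeric(strptime(sub("Z$", "", x), "%Y-%m-%dT%H:%M:%OS",
          tz = "UTC"
        ))
      }
      df$t_s <- floor(parse_iso(df$timestamp) - parse_iso(protocol_start))
    }
    tibble::tibble(
      subject_id = as.character(df$subject_id),
      device_id = as.character(df$device_id),
      t_s = as.numeric(df$t_s),
      hr_bpm = as.numeric(df$hr_bpm)
    )
  }))
  dplyr::arrange(out, .data$device_id, .data$subject_id, .data$t_s)
}
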