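RESOLUTIONS <- c("per_second", "trailing_10s", "sync_60s")

#' Configuration for a full validation run
#'
#' Bundles every choice the end-to-end pipeline needs: the input source
#' (simulation or a CSV directory), the protocol, the device set, the
#' pairing resolutions, the conditions to analyse, the significance level,
#' bootstrap size and seed. Transition-level analyses are only defined at
#' the per-second and trailing-window resolutions; requesting them with
#' only the synchronized 60 s resolution is a configuration error, since
#' that averaging interval cannot resolve a 70 s transient window.
#'
#' @param input `"simulate"` or `"csv"`.
#' @param n_subjects Cohort size when simulating (default 24).
#' @param profiles Named list of [device_error_model()]s when simulating.
#' @param csv_dir Directory of stream CSVs when `input = "csv"`.
#' @param protocol An [hr_protocol()].
#' @param resolutions Subset of `per_second`, `trailing_10s`, `sync_60s`.
#' @param reference_id Device id of the reference stream.
#' @param conditions Subset of `full`, `steady`, `transition`,
#'   `per_transition`.
#' @param alpha Significance level (default 0.05).
#' @param n_boot Bootstrap resamples for correlation CIs (default 200).
#' @param seed Root seed.
#' @param min_pair_ratio Low-coverage exclusion threshold, see
#'   [exclude_low_coverage_devices()] (default 0.25; 0 disables).
#' @param pre_span,post_span Transition window spans, seconds.
#' @param out_dir Optional output directory for tables, manifest and
#'   figures.
#' @param make_plots Write figure files when `out_dir` is set?
#' @return A validated `hr_run_config` list.
#' @export
validation_config <- function(input = c("simulate", "csv"),
                              n_subjects = 24,
                              profiles = default_device_profiles(),
                              csv_dir = NULL,
                              protocol = build_default_protocol(),
                              resolutions = RESOLUTIONS,
                              reference_id = "reference",
                              conditions = c(
                                "full", "steady", "transition",
                                "per_transition"
                              ),
                              alpha = 0.05,
                              n_boot = 200,
                              seed = 1,
                              min_pair_ratio = 0.25,
                              pre_span = 10,
                              post_span = 60,
                              out_dir = NULL,
                              make_plots = !is.null(out_dir)) {
  input <- match.arg(input)
  resolutions <- match.arg(resolutions, RESOLUTIONS, several.ok = TRUE)
  conditions <- match.arg(
    conditions, c("full", "steady", "transition", "per_transition"),
    several.ok = TRUE
  )
  if (input == "csv" && is.null(csv_dir)) {
    stop("input = 'csv' needs csv_dir", call. = FALSE)
  }
  wants_transients <- any(c("steady", "transition", "per_transition") %in%
    conditions)
  if (wants_transients &&
    !any(c("per_second", "trailing_10s") %in% resolutions)) {
    stop(
      "transition/steady analyses require the per_second or trailing_10s ",
      "resolution; they are not defined at sync_60s",
      call. = FALSE
    )
  }
  structure(
    list(
      input = input, n_subjects = n_subjects, profiles = profiles,
      csv_dir = csv_dir, protocol = protocol, resolutions = resolutions,
      reference_id = reference_id, conditions = conditions, alpha = alpha,
      n_boot = n_boot, seed = seed, min_pair_ratio = min_pair_ratio,
      pre_span = pre_span, post_span = post_span, out_dir = out_dir,
      make_plots = make_plots
    ),
    class = "hr_run_config"
  )
}

#' Build a run configuration from a YAML file
#'
#' Recognized keys mirror the arguments of [validation_config()]; the
#' protocol may be given inline (`protocol: {phases: [...]}`), as a file
#' path (`protocol_file`), or omitted for the default.
#'
#' @param path YAML config path.
#' @return An `hr_run_config`.
#' @export
validation_config_from_yaml <- function(path) {
  doc <- yaml::read_yaml(path)
  args <- doc[intersect(names(doc), c(
    "input", "n_subjects", "csv_dir", "resolutions", "reference_id",
    "conditions", "alpha", "n_boot", "seed", "min_pair_ratio",
    "pre_span", "post_span", "out_dir"
  ))]
  if (!is.null(doc$protocol_file)) {
    args$protocol <- read_protocol(doc$protocol_file)
  } else if (!is.null(doc$protocol)) {
    ph <- dplyr::bind_rows(lapply(doc$protocol$phases, tibble::as_tibble))
    args$protocol <- hr_protocol(ph, start_time = doc$protocol$start_time %||% 0)
  }
  do.call(validation_config, args)
}

#' Exclude devices with too few pairs at a resolution
#'
#' A device whose pair count falls below `min_pair_ratio` times the median
#' pair count across devices at the same resolution is excluded from that
#' resolution's statistics (a device reporting once per minute, say, cannot
#' be meaningfully validated second-by-second). `min_pair_ratio = 0`
#' disables the rule.
#'
#' @param pair_counts Named integer vector of pair counts per device.
#' @param min_pair_ratio Proportion of the median below which a device is
#'   excluded (default 0.25).
#' @return A list `keep` (device ids), `excluded` (device ids), `log`
#'   (character vector of audit messages).
#' @export
exclude_low_coverage_devices <- function(pair_counts, min_pair_ratio = 0.25) {
  stopifnot(!is.null(names(pair_counts)))
  if (min_pair_ratio <= 0) {
    return(list(
      keep = names(pair_counts), excluded = character(0),
      log = character(0)
    ))
  }
  cutoff <- min_pair_ratio * median(pair_counts)
  excluded <- names(pair_counts)[pair_counts < cutoff]
  if (length(excluded) == length(pair_counts)) {
    stop(
      "all devices fall below the coverage cutoff (",
      round(cutoff), " pairs); check the inputs",
      call. = FALSE
    )
  }
  log <- sprintf(
    "excluded %s: %d pairs < cutoff %.0f (%.2f x median %d)",
    excluded, pair_counts[excluded], cutoff, min_pair_ratio,
    round(median(pair_counts))
  )
  list(
    keep = setdiff(names(pair_counts), excluded),
    excluded = excluded, log = log
  )
}

pair_at <- function(resolution, ref, dev, tw) {
  switch(resolution,
    per_second = pair_per_second(ref, dev, tw = tw),
    trailing_10s = pair_trailing_window(ref, dev, window = 10, tw = tw),
    sync_60s = pair_synchronized_windows(ref, dev, window = 60),
    stop("unknown resolution: ", resolution, call. = FALSE)
  )
}

#' Run the full validation pipeline
#'
#' Orchestrates the end-to-end analysis: obtain the cohort (simulate, or
#' read CSVs), derive transition windows, build paired datasets per device
#' and resolution, apply the low-coverage exclusion, then compute
#' missingness, per-participant accuracy, agreement statistics and
#' threshold verdicts for the full protocol; steady/transition and
#' per-transition accuracy with condition tests at the fine resolutions;
#' and pairwise device comparisons of per-subject MAPE per resolution.
#' When `cfg$out_dir` is set, writes a results table CSV, comparison-matrix
#' CSVs, a machine-readable JSON manifest and (optionally) Bland-Altman and
#' condition boxplot figures.
#'
#' @param cfg An [validation_config()] object.
#' @return An `hr_validation` bundle: `config`, `transitions`, `paired`
#'   (nested list resolution -> device), `results` (tidy tibble of the
#'   headline statistics), `conditions`, `per_transition`, `comparisons`,
#'   `condition_tests`, `verdicts`, `missingness`, `excluded`, `log`,
#'   `manifest`.
#' @export
run_validation <- function(cfg) {
  stopifnot(inherits(cfg, "hr_run_config"))
  log <- character(0)
  note <- function(...) {
    msg <- sprintf(...)
    log <<- c(log, msg)
    message(msg)
  }

  if (cfg$input == "simulate") {
    cohort <- generate_cohort(
      n_subjects = cfg$n_subjects, profiles = cfg$profiles, seed = cfg$seed,
      protocol = cfg$protocol, pre_span = cfg$pre_span,
      post_span = cfg$post_span
    )
    reference <- cohort$reference
    devices <- cohort$devices
  } else {
    streams <- read_hr_csv(cfg$csv_dir)
    if (!cfg$reference_id %in% streams$device_id) {
      stop("reference device '", cfg$reference_id, "' not found in inputs",
        call. = FALSE
      )
    }
    reference <- streams[streams$device_id == cfg$reference_id, ]
    devices <- split(
      streams[streams$device_id != cfg$reference_id, ],
      streams$device_id[streams$device_id != cfg$reference_id]
    )
  }
  tw <- derive_transitions(cfg$protocol, cfg$pre_span, cfg$post_span)
  note("pipeline start: %d devices, %d transition windows",
    length(devices), nrow(tw))

  ref_subjects <- unique(reference$subject_id)
  devices <- Filter(function(d) {
    ok <- nrow(d) > 0 && any(d$subject_id %in% ref_subjects)
    if (!ok) note("device with no valid subjects skipped")
    ok
  }, devices)
  if (length(devices) == 0) stop("no usable device streams", call. = FALSE)

  paired <- list()
  excluded <- list()
  missingness <- list()
  results <- list()
  verdicts <- list()
  cond_acc <- list()
  per_transition <- list()
  comparisons <- list()
  condition_tests <- list()

  for (res in cfg$resolutions) {
    pd_res <- lapply(names(devices), function(dv) {
      pair_at(res, reference, devices[[dv]], tw)
    })
    names(pd_res) <- names(devices)

    counts <- vapply(pd_res, nrow, 0L)
    excl <- exclude_low_coverage_devices(counts, cfg$min_pair_ratio)
    for (m in excl$log) note("[%s] %s", res, m)
    excluded[[res]] <- excl$excluded
    pd_res <- pd_res[excl$keep]
    paired[[res]] <- pd_res

    mape_by_device <- list()
    for (dv in names(pd_res)) {
      pd <- pd_res[[dv]]
      valid <- unique(devices[[dv]]$subject_id)
      missingness[[paste(res, dv)]] <- compute_missingness(
        reference, pd,
        valid_subjects = intersect(valid, ref_subjects)
      )
      acc <- accuracy_per_subject(pd)
      agr <- agreement_summary(pd, n_boot = cfg$n_boot, seed = cfg$seed)
      verdicts[[paste(res, dv)]] <- c(
        list(resolution = res, device_id = dv),
        classify_thresholds(acc, agr)
      )
      mape_by_device[[dv]] <- setNames(
        acc$per_subject$mape, acc$per_subject$subject_id
      )
      ba <- agr$bland_altman
      results[[paste(res, dv)]] <- tibble::tibble(
        resolution = res, device_id = dv,
        n_pairs = nrow(pd),
        n_subjects = acc$n_subjects,
        missingness_pct =
          missingness[[paste(res, dv)]]$fraction_missing * 100,
        rmccc = agr$rmccc$estimate,
        rmccc_lo = agr$rmccc$ci[1], rmccc_hi = agr$rmccc$ci[2],
        bias = ba$bias, bias_p = ba$bias_p,
        loa_lower = ba$loa_lower, loa_upper = ba$loa_upper,
        median_mape = acc$median_mape, iqr_mape = acc$iqr_mape,
        median_mae = acc$median_mae, iqr_mae = acc$iqr_mae
      )

      if (res %in% c("per_second", "trailing_10s") &&
        any(c("steady", "transition") %in% cfg$conditions)) {
        acc_s <- tryCatch(accuracy_per_subject(pd, condition = "steady"),
          error = function(e) NULL
        )
        acc_t <- tryCatch(accuracy_per_subject(pd, condition = "transition"),
          error = function(e) NULL
        )
        cond_acc[[paste(res, dv)]] <- list(steady = acc_s, transition = acc_t)
        if (!is.null(acc_s) && !is.null(acc_t)) {
          p <- tryCatch(
            suppressMessages(condition_test(
              setNames(acc_s$per_subject$mape, acc_s$per_subject$subject_id),
              setNames(acc_t$per_subject$mape, acc_t$per_subject$subject_id)
            )),
            error = function(e) NA_real_
          )
          condition_tests[[paste(res, dv)]] <- tibble::tibble(
            resolution = res, device_id = dv, p_value = p,
            median_mape_steady = acc_s$median_mape,
            median_mape_transition = acc_t$median_mape
          )
        }
      }
      if (res %in% c("per_second", "trailing_10s") &&
        "per_transition" %in% cfg$conditions) {
        per_transition[[paste(res, dv)]] <- dplyr::bind_rows(lapply(
          tw$transition_id,
          function(k) {
            a <- tryCatch(accuracy_per_subject(pd, transition_id = k),
              error = function(e) NULL
            )
            if (is.null(a)) return(NULL)
            tibble::tibble(
              resolution = res, device_id = dv, transition_id = k,
              n_subjects = a$n_subjects,
              median_mape = a$median_mape, iqr_mape = a$iqr_mape
            )
          }
        ))
      }
    }
    if (length(mape_by_device) >= 2) {
      comparisons[[res]] <- pairwise_device_tests(
        mape_by_device,
        alpha = cfg$alpha
      )
    }
  }

  results <- dplyr::bind_rows(results)
  missingness <- dplyr::bind_rows(missingness)
  condition_tests <- dplyr::bind_rows(condition_tests)
  per_transition <- dplyr::bind_rows(per_transition)

  manifest <- list(
    seed = cfg$seed,
    input = cfg$input,
    n_subjects = length(ref_subjects),
    reference_id = cfg$reference_id,
    devices = names(devices),
    resolutions = cfg$resolutions,
    n_transitions = nrow(tw),
    transitions = as.data.frame(tw),
    alpha = cfg$alpha,
    excluded = excluded,
    results = as.data.frame(results),
    missingness = as.data.frame(missingness),
    condition_tests = as.data.frame(condition_tests),
    per_transition = as.data.frame(per_transition),
    comparisons = lapply(comparisons, function(cm) {
      list(
        alpha_adjusted = cm$alpha_adjusted,
        n_comparisons = cm$n_comparisons,
        p_values = as.data.frame(cm$p_values)
      )
    })
  )

  bundle <- structure(
    list(
      config = cfg, transitions = tw, paired = paired, results = results,
      conditions = cond_acc, per_transition = per_transition,
      comparisons = comparisons, condition_tests = condition_tests,
      verdicts = verdicts, missingness = missingness, excluded = excluded,
      log = log, manifest = manifest
    ),
    class = "hr_validation"
  )

  if (!is.null(cfg$out_dir)) write_validation_outputs(bundle)
  bundle
}

#' @export
print.hr_validation <- function(x, ...) {
  cat(sprintf(
    "<hr_validation> %d devices x %d resolutions, seed %d\n",
    length(unique(x$results$device_id)), length(x$config$resolutions),
    x$config$seed
  ))
  print(x$results[, c(
    "resolution", "device_id", "n_pairs", "missingness_pct", "rmccc",
    "bias", "loa_lower", "loa_upper", "median_mape"
  )])
  invisible(x)
}

write_validation_outputs <- function(bundle) {
  cfg <- bundle$config
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(
    as.data.frame(bundle$results),
    file.path(cfg$out_dir, "results.csv"),
    row.names = FALSE
  )
  utils::write.csv(
    as.data.frame(bundle$missingness),
    file.path(cfg$out_dir, "missingness.csv"),
    row.names = FALSE
  )
  write_transitions(bundle$transitions, file.path(cfg$out_dir, "transitions.csv"))
  for (res in names(bundle$comparisons)) {
    write_comparison_csv(
      bundle$comparisons[[res]],
      file.path(cfg$out_dir, paste0("comparisons_", res, ".csv"))
    )
  }
  if (nrow(bundle$condition_tests) > 0) {
    utils::write.csv(
      as.data.frame(bundle$condition_tests),
      file.path(cfg$out_dir, "condition_tests.csv"),
      row.names = FALSE
    )
  }
  jsonlite::write_json(
    bundle$manifest, file.path(cfg$out_dir, "manifest.json"),
    auto_unbox = TRUE, digits = 10, pretty = TRUE, na = "null"
  )
  if (isTRUE(cfg$make_plots)) {
    for (res in names(bundle$paired)) {
      for (dv in names(bundle$paired[[res]])) {
        f <- file.path(cfg$out_dir, sprintf("bland_altman_%s_%s.png", res, dv))
        tryCatch(
          ggplot2::ggsave(
            f,
            plot_bland_altman(bundle$paired[[res]][[dv]]),
            width = 6, height = 4, dpi = 120
          ),
          error = function(e) NULL
        )
      }
    }
    if (length(bundle$conditions) > 0) {
      tryCatch(
        ggplot2::ggsave(
          file.path(cfg$out_dir, "condition_mape.png"),
          plot_condition_mape(bundle),
          width = 7, height = 4.5, dpi = 120
        ),
        error = function(e) NULL
      )
    }
  }
  invisible(cfg$out_dir)
}
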