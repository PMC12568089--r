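filter_condition <- function(pd, condition = NULL, transition_id = NULL) {
  if (is.null(condition) && is.null(transition_id)) return(pd)
  if (!"state" %in% names(pd)) {
    stop("paired dataset carries no state labels; cannot filter by condition",
      call. = FALSE
    )
  }
  if (!is.null(condition)) {
    condition <- match.arg(condition, c("steady", "transition"))
    pd <- pd[pd$state == condition, ]
  }
  if (!is.null(transition_id)) {
    pd <- pd[!is.na(pd$transition_id) & pd$transition_id == transition_id, ]
  }
  pd
}

#' Per-participant accuracy: MAE and MAPE with group summaries
#'
#' Computes, separately for each participant, the mean absolute error
#' `MAE = mean(|dev - ref|)` (bpm) and mean absolute percentage error
#' `MAPE = mean(|dev - ref| / ref) * 100` over that participant's pairs,
#' then summarises across participants as median and interquartile range.
#' Every retained participant contributes equally to the group summaries,
#' regardless of how many pairs they have. Participants left with zero pairs
#' after condition filtering are omitted (with a message).
#'
#' @param pd A paired dataset (tibble with `subject_id`, `ref_bpm`,
#'   `dev_bpm`, optionally `state`, `transition_id`).
#' @param condition Optional `"steady"` or `"transition"` filter.
#' @param transition_id Optional transition id filter (1..K).
#' @param quantile_type Quantile rule for median/IQR, passed to
#'   [stats::quantile()] (default 7, linear interpolation).
#'
#' @return An `hr_accuracy` list: `per_subject` (tibble with `subject_id`,
#'   `n`, `mae`, `mape`), `median_mae`, `iqr_mae`, `median_mape`,
#'   `iqr_mape`, `n_subjects`, `condition`.
#' @export
accuracy_per_subject <- function(pd, condition = NULL, transition_id = NULL,
                                 quantile_type = 7) {
  pd <- filter_condition(pd, condition, transition_id)
  if (nrow(pd) == 0) stop("no pairs left after filtering", call. = FALSE)
  if (any(pd$ref_bpm <= 0)) {
    stop("nonpositive reference heart rate; MAPE undefined", call. = FALSE)
  }
  per <- dplyr::summarise(
    dplyr::group_by(pd, .data$subject_id),
    n = dplyr::n(),
    mae = mean(abs(.data$dev_bpm - .data$ref_bpm)),
    mape = mean(abs(.data$dev_bpm - .data$ref_bpm) / .data$ref_bpm) * 100,
    .groups = "drop"
  )
  q <- function(x, p) unname(quantile(x, p, type = quantile_type))
  structure(
    list(
      per_subject = per,
      median_mae = q(per$mae, 0.5),
      iqr_mae = q(per$mae, 0.75) - q(per$mae, 0.25),
      median_mape = q(per$mape, 0.5),
      iqr_mape = q(per$mape, 0.75) - q(per$mape, 0.25),
      n_subjects = nrow(per),
      condition = if (is.null(condition)) "full" else condition
    ),
    class = "hr_accuracy"
  )
}

#' @export
print.hr_accuracy <- function(x, ...) {
  cat(sprintf(
    "<hr_accuracy> %d subjects (%s): median MAPE %.2f%% (IQR %.2f), median MAE %.2f bpm (IQR %.2f)\n",
    x$n_subjects, x$condition, x$median_mape, x$iqr_mape,
    x$median_mae, x$iqr_mae
  ))
  invisible(x)
}

#' Lin's concordance correlation coefficient
#'
#' Classical moment form `2 * s_xy / (s_x^2 + s_y^2 + (mean(x) - mean(y))^2)`
#' with sample (n - 1) moments. Penalizes both poor correlation and
#' location/scale shift between two measurement methods.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return The concordance coefficient in `[-1, 1]`. With both variances
#'   zero the value is 1 when the means agree (degenerate perfect
#'   agreement) and 0 otherwise.
#' @examples
#' lin_ccc(c(1, 2, 3), c(2, 3, 4)) # 2/3
#' @export
lin_ccc <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  sx <- var(x)
  sy <- var(y)
  if (sx == 0 && sy == 0) {
    if (isTRUE(all.equal(mean(x), mean(y)))) {
      message("both variances zero with equal means; CCC = 1 by convention")
      return(1)
    }
    return(0)
  }
  sxy <- stats::cov(x, y)
  2 * sxy / (sx + sy + (mean(x) - mean(y))^2)
}

pd_long <- function(pd) {
  tibble::tibble(
    subject_id = rep(pd$subject_id, 2),
    pair_id = rep(seq_len(nrow(pd)), 2),
    method = rep(c("ref", "dev"), each = nrow(pd)),
    value = c(pd$ref_bpm, pd$dev_bpm)
  )
}

rmccc_point <- function(long) {
  # one random intercept per subject and one per paired observation: the
  # subject term absorbs between-subject level differences, the pair term
  # the heart-rate trajectory shared by both methods at each timestamp,
  # so only method disagreement is left in the residual. With a single
  # pair per subject the two terms coincide and the subject term is
  # dropped (unidentifiable); the estimator then equals Lin's CCC.
  single <- max(table(long$subject_id)) <= 2
  form <- if (single) {
    value ~ method + (1 | pair_id)
  } else {
    value ~ method + (1 | subject_id) + (1 | pair_id)
  }
  fit <- suppressMessages(suppressWarnings(lme4::lmer(
    form,
    data = long, REML = TRUE,
    control = lme4::lmerControl(
      check.conv.singular = "ignore",
      calc.derivs = FALSE
    )
  )))
  vc <- as.data.frame(lme4::VarCorr(fit))
  sigma_b2 <- sum(vc$vcov[vc$grp != "Residual"])
  sigma_e2 <- vc$vcov[vc$grp == "Residual"]
  d <- lme4::fixef(fit)[["methodref"]]
  sigma_b2 / (sigma_b2 + sigma_e2 + d^2 / 2)
}

boot_ci <- function(pd, statistic, n_boot, seed, conf = 0.95) {
  if (n_boot < 1) return(c(NA_real_, NA_real_))
  subjects <- unique(pd$subject_id)
  set.seed(seed)
  reps <- vapply(seq_len(n_boot), function(b) {
    take <- sample(subjects, length(subjects), replace = TRUE)
    boot <- dplyr::bind_rows(lapply(seq_along(take), function(k) {
      rows <- pd[pd$subject_id == take[k], ]
      rows$subject_id <- sprintf("B%03d", k) # resampled copies are distinct
      rows
    }))
    tryCatch(statistic(boot), error = function(e) NA_real_)
  }, numeric(1))
  a <- (1 - conf) / 2
  unname(quantile(reps, c(a, 1 - a), na.rm = TRUE, names = FALSE))
}

#' Repeated-measures concordance correlation (variance components)
#'
#' Estimates overall concordance between device and reference while
#' accounting for repeated observations per subject. The stacked long data
#' (one row per measurement, `method` in {ref, dev}) is fit by REML with a
#' fixed method effect, a random intercept per subject and a random
#' intercept per paired observation, so the heart-rate trajectory shared by
#' both methods at each timestamp counts as agreement rather than noise.
#' The concordance is
#' `(sigma_u^2 + sigma_p^2) / (sigma_u^2 + sigma_p^2 + sigma_e^2 + d^2 / 2)`
#' with `sigma_u^2` the subject variance, `sigma_p^2` the pair variance,
#' `sigma_e^2` the residual (method-disagreement) variance and `d` the
#' fixed method difference. With one pair per subject the estimator equals
#' Lin's classical CCC. The 95% CI is a subject-level bootstrap
#' (percentile, seeded).
#'
#' @inheritParams accuracy_per_subject
#' @param n_boot Bootstrap resamples for the CI (default 1000; 0 skips the
#'   CI).
#' @param seed Seed for the bootstrap.
#' @param conf Confidence level (default 0.95).
#' @return A list `estimate`, `ci` (length-2), `n_pairs`, `n_subjects`.
#' @export
rm_ccc <- function(pd, n_boot = 1000, seed = 1, conf = 0.95) {
  stopifnot(all(c("subject_id", "ref_bpm", "dev_bpm") %in% names(pd)))
  subjects <- unique(pd$subject_id)
  if (length(subjects) < 2) {
    warning("single subject; falling back to Lin's CCC", call. = FALSE)
    est <- lin_ccc(pd$ref_bpm, pd$dev_bpm)
    return(list(
      estimate = est, ci = c(NA_real_, NA_real_),
      n_pairs = nrow(pd), n_subjects = length(subjects)
    ))
  }
  if (isTRUE(all.equal(pd$ref_bpm, pd$dev_bpm))) {
    # degenerate perfect agreement: zero residual breaks the REML fit
    return(list(
      estimate = 1, ci = c(1, 1), n_pairs = nrow(pd),
      n_subjects = length(subjects)
    ))
  }
  est <- rmccc_point(pd_long(pd))
  ci <- boot_ci(pd, function(b) rmccc_point(pd_long(b)), n_boot, seed, conf)
  list(
    estimate = est, ci = ci, n_pairs = nrow(pd),
    n_subjects = length(subjects)
  )
}

rm_slope_corr <- function(subject, x, y) {
  # repeated-measures correlation: common within-subject slope after
  # removing subject means (sequential ANOVA, measure fitted last)
  f <- stats::lm(y ~ factor(subject) + x)
  f0 <- stats::lm(y ~ factor(subject))
  ss_e <- stats::deviance(f)
  ss_x <- stats::deviance(f0) - ss_e # sequential SS with the measure last
  if (ss_x + ss_e == 0) {
    stop("no within-subject variation; correlation undefined", call. = FALSE)
  }
  sign(stats::coef(f)[["x"]]) * sqrt(ss_x / (ss_x + ss_e))
}

#' Repeated-measures Spearman correlation
#'
#' Ranks each variable across the pooled sample, then applies the
#' repeated-measures correlation (subject-centred ANCOVA common-slope
#' correlation) to the ranks, so monotone association is measured while
#' between-subject level differences are absorbed by subject intercepts.
#' CI by subject-level bootstrap.
#'
#' @inheritParams rm_ccc
#' @return A list `estimate`, `ci`, `n_pairs`, `n_subjects`.
#' @export
rm_spearman <- function(pd, n_boot = 1000, seed = 1, conf = 0.95) {
  stopifnot(all(c("subject_id", "ref_bpm", "dev_bpm") %in% names(pd)))
  if (var(pd$ref_bpm) == 0 || var(pd$dev_bpm) == 0) {
    stop("constant variable; rank correlation undefined", call. = FALSE)
  }
  point <- function(b) {
    rm_slope_corr(b$subject_id, rank(b$ref_bpm), rank(b$dev_bpm))
  }
  est <- point(pd)
  ci <- boot_ci(pd, point, n_boot, seed, conf)
  list(
    estimate = est, ci = ci, n_pairs = nrow(pd),
    n_subjects = length(unique(pd$subject_id))
  )
}

#' Bland-Altman analysis via a linear mixed-effects model
#'
#' Models the paired differences `d = dev - ref` as
#' `d_ij = mu + u_i + e_ij` with a random intercept `u_i` per subject
#' (REML). The mean bias is `mu_hat`, tested against zero by a Wald test,
#' and the 95% limits of agreement are
#' `mu_hat +/- 1.96 * sqrt(sigma_u^2 + sigma_e^2)`, i.e. the interval
#' expected to cover 95% of individual differences across subjects and
#' repeats. When the subject variance is estimated at the boundary (0) the
#' model reduces to ordinary limits of agreement on the pooled SD and a
#' warning is raised.
#'
#' @inheritParams accuracy_per_subject
#' @return A list `bias`, `bias_p`, `loa_lower`, `loa_upper`, `sigma_u`,
#'   `sigma_e`, `n_pairs`, `n_subjects`.
#' @export
lmm_bland_altman <- function(pd) {
  stopifnot(all(c("subject_id", "ref_bpm", "dev_bpm") %in% names(pd)))
  d <- pd$dev_bpm - pd$ref_bpm
  subjects <- unique(pd$subject_id)
  sdd <- stats::sd(d)
  if (!is.finite(sdd) || sdd == 0) {
    # degenerate: constant differences carry no variance to partition
    mu <- mean(d)
    return(list(
      bias = mu, bias_p = if (abs(mu) < 1e-12) 1 else 0,
      loa_lower = mu, loa_upper = mu, sigma_u = 0, sigma_e = 0,
      n_pairs = nrow(pd), n_subjects = length(subjects)
    ))
  }
  if (length(subjects) < 2) {
    warning("single subject; ordinary Bland-Altman on the pooled SD",
      call. = FALSE
    )
    mu <- mean(d)
    tt <- stats::t.test(d)
    return(list(
      bias = mu, bias_p = tt$p.value,
      loa_lower = mu - 1.96 * sdd, loa_upper = mu + 1.96 * sdd,
      sigma_u = 0, sigma_e = sdd,
      n_pairs = nrow(pd), n_subjects = length(subjects)
    ))
  }
  dat <- tibble::tibble(d = d, subject_id = pd$subject_id)
  fit <- suppressMessages(lme4::lmer(
    d ~ 1 + (1 | subject_id),
    data = dat, REML = TRUE,
    control = lme4::lmerControl(check.conv.singular = "ignore")
  ))
  vc <- as.data.frame(lme4::VarCorr(fit))
  sigma_u2 <- vc$vcov[vc$grp == "subject_id"]
  sigma_e2 <- vc$vcov[vc$grp == "Residual"]
  if (sigma_u2 <= 0) {
    warning(
      "subject variance estimated at boundary 0; limits of agreement reduce to the pooled SD",
      call. = FALSE
    )
  }
  mu <- lme4::fixef(fit)[[1]]
  se <- sqrt(as.numeric(stats::vcov(fit)[1, 1]))
  z <- if (se > 0) mu / se else sign(mu) * Inf
  half <- 1.96 * sqrt(sigma_u2 + sigma_e2)
  list(
    bias = mu,
    bias_p = 2 * pnorm(-abs(z)),
    loa_lower = mu - half,
    loa_upper = mu + half,
    sigma_u = sqrt(sigma_u2),
    sigma_e = sqrt(sigma_e2),
    n_pairs = nrow(pd),
    n_subjects = length(subjects)
  )
}

#' Full agreement summary for one paired dataset
#'
#' Convenience wrapper computing the repeated-measures concordance,
#' repeated-measures Spearman correlation and mixed-model Bland-Altman
#' statistics on one paired dataset.
#'
#' @inheritParams rm_ccc
#' @return An `hr_agreement` list with elements `rmccc`, `rm_spearman`,
#'   `bland_altman`, `n_pairs`, `n_subjects`, `device_id`, `resolution`.
#' @export
agreement_summary <- function(pd, n_boot = 1000, seed = 1) {
  structure(
    list(
      rmccc = rm_ccc(pd, n_boot = n_boot, seed = seed),
      rm_spearman = rm_spearman(pd, n_boot = n_boot, seed = seed),
      bland_altman = lmm_bland_altman(pd),
      n_pairs = nrow(pd),
      n_subjects = length(unique(pd$subject_id)),
      device_id = attr(pd, "device_id") %||% "device",
      resolution = attr(pd, "resolution") %||% NA_character_
    ),
    class = "hr_agreement"
  )
}

#' @export
print.hr_agreement <- function(x, ...) {
  ba <- x$bland_altman
  cat(sprintf(
    "<hr_agreement> %s @ %s: %d pairs / %d subjects\n  rmCCC %.3f (%.3f, %.3f) | rmSCC %.3f | bias %.2f bpm (LoA %.2f, %.2f), p=%.3g\n",
    x$device_id, x$resolution, x$n_pairs, x$n_subjects,
    x$rmccc$estimate, x$rmccc$ci[1], x$rmccc$ci[2],
    x$rm_spearman$estimate, ba$bias, ba$loa_lower, ba$loa_upper, ba$bias_p
  ))
  invisible(x)
}

#' Interpret accuracy and agreement against standard thresholds
#'
#' Accuracy is acceptable when the median MAPE is at most 10% or the median
#' MAE at most 5 bpm (readout-error standard for cardiac monitors:
#' whichever bound is more permissive applies). Correlation strength bands:
#' weak (CC <= 0.5), moderate (0.5 < CC < 0.7), strong (CC >= 0.7); the
#' stricter acceptability boundary is CC >= 0.80.
#'
#' @param acc An `hr_accuracy` summary.
#' @param agr An `hr_agreement` summary (or a number, taken as the
#'   concordance estimate) computed on the same dataset.
#' @return A list `mape_acceptable`, `cc_band`, `cc_acceptable`, `cc`,
#'   `median_mape`, `median_mae`.
#' @export
classify_thresholds <- function(acc, agr) {
  stopifnot(inherits(acc, "hr_accuracy"))
  cc <- if (is.numeric(agr)) agr else agr$rmccc$estimate
  band <- if (cc <= 0.5) "weak" else if (cc < 0.7) "moderate" else "strong"
  list(
    mape_acceptable = acc$median_mape <= 10 || acc$median_mae <= 5,
    cc_band = band,
    cc_acceptable = cc >= 0.80,
    cc = cc,
    median_mape = acc$median_mape,
    median_mae = acc$median_mae
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
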