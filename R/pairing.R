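new_paired <- function(pairs, resolution, device_id, reference_id) {
  structure(
    pairs,
    resolution = resolution, device_id = device_id,
    reference_id = reference_id,
    class = c("hr_paired", class(pairs))
  )
}

#' @export
print.hr_paired <- function(x, ...) {
  cat(sprintf(
    "<hr_paired> %s: %s vs %s, %d pairs, %d subjects\n",
    attr(x, "resolution"), attr(x, "device_id"), attr(x, "reference_id"),
    nrow(x), length(unique(x$subject_id))
  ))
  NextMethod()
}

attach_state <- function(pairs, tw) {
  if (is.null(tw)) return(pairs)
  lab <- label_timestamps(pairs$t_s, tw)
  pairs$state <- lab$state
  pairs$transition_id <- lab$transition_id
  pairs
}

check_streams <- function(ref, dev) {
  need <- c("subject_id", "t_s", "hr_bpm")
  stopifnot(all(need %in% names(ref)), all(need %in% names(dev)))
}

#' Pair reference and device streams second-by-second
#'
#' Retains only timestamps (at 1 s resolution) where both the reference and
#' the device reported a value, matched within subject; no averaging is
#' applied and unmatched timestamps are dropped (pairwise deletion).
#'
#' @param ref,dev Heart-rate series tibbles (`subject_id`, `device_id`,
#'   `t_s`, `hr_bpm`), possibly spanning several subjects.
#' @param tw Optional transition windows; when supplied, each pair is
#'   labelled `steady`/`transition` at its reference timestamp.
#'
#' @return An `hr_paired` tibble with columns `subject_id`, `t_s`,
#'   `ref_bpm`, `dev_bpm` (plus `state`, `transition_id` when `tw` is
#'   given), attribute `resolution = "per_second"`.
#' @export
pair_per_second <- function(ref, dev, tw = NULL) {
  check_streams(ref, dev)
  r <- tibble::tibble(
    subject_id = ref$subject_id, t_s = floor(ref$t_s), ref_bpm = ref$hr_bpm
  )
  d <- tibble::tibble(
    subject_id = dev$subject_id, t_s = floor(dev$t_s), dev_bpm = dev$hr_bpm
  )
  pairs <- dplyr::inner_join(r, d, by = c("subject_id", "t_s"))
  if (nrow(pairs) == 0) {
    warning("no overlapping timestamps; empty paired dataset", call. = FALSE)
  }
  pairs <- dplyr::arrange(pairs, .data$subject_id, .data$t_s)
  new_paired(
    attach_state(pairs, tw), "per_second",
    device_id = if (nrow(dev) > 0) dev$device_id[1] else "device",
    reference_id = if (nrow(ref) > 0) ref$device_id[1] else "reference"
  )
}

trailing_means <- function(ref_t, dev_t, dev_hr, window) {
  ord <- order(dev_t)
  dev_t <- dev_t[ord]
  cs <- cumsum(dev_hr[ord])
  lo <- findInterval(ref_t - window, dev_t) # excludes samples <= t - window
  hi <- findInterval(ref_t, dev_t) # includes samples <= t
  n_in <- hi - lo
  m <- rep(NA_real_, length(ref_t))
  ok <- n_in > 0
  m[ok] <- (cs[hi[ok]] - ifelse(lo[ok] == 0, 0, cs[pmax(lo[ok], 1)])) /
    n_in[ok]
  m
}

#' Pair via trailing-window averaging of the device stream
#'
#' For each reference timestamp `t`, the device value is the mean of all
#' device samples in the half-open window `(t - window, t]`; the reference
#' value is untouched. A pair is emitted only when at least one device
#' sample falls in the window, otherwise the timestamp is pairwise-deleted.
#'
#' @inheritParams pair_per_second
#' @param window Trailing window length in seconds (default 10, > 0).
#' @return An `hr_paired` tibble, attribute `resolution = "trailing_10s"`.
#' @export
pair_trailing_window <- function(ref, dev, window = 10, tw = NULL) {
  check_streams(ref, dev)
  stopifnot(window > 0)
  pairs <- dplyr::bind_rows(lapply(
    split(ref, ref$subject_id),
    function(r) {
      d <- dev[dev$subject_id == r$subject_id[1], ]
      if (nrow(d) == 0) return(NULL)
      m <- trailing_means(r$t_s, d$t_s, d$hr_bpm, window)
      keep <- !is.na(m)
      tibble::tibble(
        subject_id = r$subject_id[keep], t_s = r$t_s[keep],
        ref_bpm = r$hr_bpm[keep], dev_bpm = m[keep]
      )
    }
  ))
  if (nrow(pairs) == 0) {
    warning("no pairable timestamps; empty paired dataset", call. = FALSE)
    pairs <- tibble::tibble(
      subject_id = character(0), t_s = numeric(0),
      ref_bpm = numeric(0), dev_bpm = numeric(0)
    )
  }
  pairs <- dplyr::arrange(pairs, .data$subject_id, .data$t_s)
  new_paired(
    attach_state(pairs, tw), "trailing_10s",
    device_id = if (nrow(dev) > 0) dev$device_id[1] else "device",
    reference_id = if (nrow(ref) > 0) ref$device_id[1] else "reference"
  )
}

#' Pair via synchronized fixed windows averaged on both sides
#'
#' The protocol span is partitioned into consecutive `[k*window,
#' (k+1)*window)` bins anchored at t = 0; each bin contributes one pair of
#' (mean reference, mean device) values, and a bin is dropped whenever
#' either side has no samples in it (pairwise deletion). The recorded
#' timestamp is the bin start. Synchronized pairs carry no steady/transition
#' state: the window is too coarse to isolate transient intervals.
#'
#' @inheritParams pair_per_second
#' @param window Bin width in seconds (default 60, > 0).
#' @return An `hr_paired` tibble, attribute `resolution = "sync_60s"`.
#' @export
pair_synchronized_windows <- function(ref, dev, window = 60) {
  check_streams(ref, dev)
  stopifnot(window > 0)
  bin_means <- function(s, col) {
    s$bin <- floor(s$t_s / window)
    out <- dplyr::summarise(
      dplyr::group_by(s, .data$subject_id, .data$bin),
      v = mean(.data$hr_bpm), .groups = "drop"
    )
    names(out)[names(out) == "v"] <- col
    out
  }
  pairs <- dplyr::inner_join(
    bin_means(ref, "ref_bpm"), bin_means(dev, "dev_bpm"),
    by = c("subject_id", "bin")
  )
  pairs <- tibble::tibble(
    subject_id = pairs$subject_id, t_s = pairs$bin * window,
    ref_bpm = pairs$ref_bpm, dev_bpm = pairs$dev_bpm
  )
  if (nrow(pairs) == 0) {
    warning("no pairable bins; empty paired dataset", call. = FALSE)
  }
  pairs <- dplyr::arrange(pairs, .data$subject_id, .data$t_s)
  new_paired(
    pairs, "sync_60s",
    device_id = if (nrow(dev) > 0) dev$device_id[1] else "device",
    reference_id = if (nrow(ref) > 0) ref$device_id[1] else "reference"
  )
}

#' Missing-data accounting for a paired dataset
#'
#' The fraction of expected reference-aligned data points the device failed
#' to supply: `1 - n_paired / n_expected`, where `n_expected` counts the
#' reference timestamps (for per-second and trailing-window pairing) or the
#' reference-occupied bins (for synchronized windows) across the subjects
#' with a valid recording for the device.
#'
#' @param ref The reference series the pairing was built from.
#' @param paired An `hr_paired` dataset.
#' @param valid_subjects Optional character vector restricting the
#'   accounting to subjects with a valid device recording; defaults to all
#'   subjects in `ref`.
#' @param window Bin width used when `paired` is at `sync_60s` resolution.
#' @return A tibble row with `device_id`, `resolution`, `n_expected`,
#'   `n_paired`, `fraction_missing`.
#' @export
compute_missingness <- function(ref, paired, valid_subjects = NULL,
                                window = 60) {
  stopifnot(inherits(paired, "hr_paired"))
  if (is.null(valid_subjects)) valid_subjects <- unique(ref$subject_id)
  r <- ref[ref$subject_id %in% valid_subjects, ]
  res <- attr(paired, "resolution")
  n_expected <- if (res == "sync_60s") {
    nrow(unique(tibble::tibble(
      subject_id = r$subject_id, bin = floor(r$t_s / window)
    )))
  } else {
    nrow(r)
  }
  if (n_expected == 0) {
    stop("no expected reference samples; missingness undefined", call. = FALSE)
  }
  n_paired <- sum(paired$subject_id %in% valid_subjects)
  tibble::tibble(
    device_id = attr(paired, "device_id"),
    resolution = res,
    n_expected = n_expected,
    n_paired = n_paired,
    fraction_missing = 1 - n_paired / n_expected
  )
}

#' Write a paired dataset as tidy CSV
#'
#' Columns: `subject_id`, `t_s`, `ref_bpm`, `dev_bpm` and, when present,
#' `state`, `transition_id`.
#'
#' @param paired An `hr_paired` dataset.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_paired_csv <- function(paired, path) {
  stopifnot(inherits(paired, "hr_paired"))
  utils::write.csv(as.data.frame(paired), path, row.names = FALSE)
  invisible(path)
}
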