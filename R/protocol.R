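#' Construct a phased activity protocol
#'
#' A protocol is an ordered, contiguous sequence of activity phases, each with
#' a name, a duration in seconds and an ordinal load level. Time is measured
#' in integer seconds from protocol start (`start_time`, default 0), so phase
#' boundaries fall at the cumulative sums of the durations.
#'
#' @param phases A data frame with columns `name` (character), `duration_s`
#'   (positive number of seconds) and `load` (character or factor; coerced to
#'   an ordered factor in order of first appearance unless already ordered).
#' @param start_time Protocol start in seconds (reference zero).
#'
#' @return An object of class `hr_protocol`: a list with elements `phases`
#'   (tibble with `name`, `duration_s`, `load`, `onset_s`, `end_s`) and
#'   `start_time`.
#' @seealso [build_default_protocol()], [derive_transitions()]
#' @export
hr_protocol <- function(phases, start_time = 0) {
  phases <- tibble::as_tibble(phases)
  stopifnot(all(c("name", "duration_s", "load") %in% names(phases)))
  if (nrow(phases) < 1) {
    stop("a protocol needs at least one phase", call. = FALSE)
  }
  if (any(!is.finite(phases$duration_s)) || any(phases$duration_s <= 0)) {
    stop("phase durations must be strictly positive", call. = FALSE)
  }
  if (!is.ordered(phases$load)) {
    lv <- unique(as.character(phases$load))
    phases$load <- factor(as.character(phases$load), levels = lv, ordered = TRUE)
  }
  phases$end_s <- start_time + cumsum(phases$duration_s)
  phases$onset_s <- phases$end_s - phases$duration_s
  phases <- phases[, c("name", "duration_s", "load", "onset_s", "end_s")]
  structure(
    list(phases = phases, start_time = start_time),
    class = "hr_protocol"
  )
}

#' @export
print.hr_protocol <- function(x, ...) {
  cat(sprintf(
    "<hr_protocol> %d phases, %g s total (start %g s)\n",
    nrow(x$phases), protocol_duration(x), x$start_time
  ))
  print(x$phases)
  invisible(x)
}

#' Total protocol duration in seconds
#'
#' @param protocol An [hr_protocol()] object.
#' @return Total duration (sum of phase durations), in seconds.
#' @export
protocol_duration <- function(protocol) {
  stopifnot(inherits(protocol, "hr_protocol"))
  sum(protocol$phases$duration_s)
}

#' Phase-change times of a protocol
#'
#' The internal phase boundaries, i.e. the onsets of every phase after the
#' first. These are the candidate transition onsets.
#'
#' @inheritParams protocol_duration
#' @return Numeric vector of boundary times in seconds (empty for a
#'   single-phase protocol).
#' @export
phase_change_times <- function(protocol) {
  stopifnot(inherits(protocol, "hr_protocol"))
  if (nrow(protocol$phases) < 2) return(numeric(0))
  protocol$phases$onset_s[-1]
}

#' The default six-phase treadmill protocol
#'
#' A 20 min protocol of sequential activity phases: sitting on a chair
#' (3 min), standing still (3 min), treadmill walking at 4 km/h (4 min), at
#' 6 km/h (4 min), at 6 km/h with a 5% incline (4 min), and a final standing
#' phase (2 min) after an abrupt treadmill stop. Load levels are ordered
#' sit < stand < walk4 < walk6 < walk6_incline; the final phase reuses the
#' `stand` level.
#'
#' @return An [hr_protocol()] with 6 phases totalling 1200 s and phase
#'   boundaries at 180, 360, 600, 840 and 1080 s.
#' @examples
#' p <- build_default_protocol()
#' protocol_duration(p) # 1200
#' phase_change_times(p) # 180 360 600 840 1080
#' @export
build_default_protocol <- function() {
  lv <- c("sit", "stand", "walk4", "walk6", "walk6_incline")
  hr_protocol(tibble::tibble(
    name = c(
      "sit", "stand", "walk_4kmh", "walk_6kmh",
      "walk_6kmh_5pct", "stand_recovery"
    ),
    duration_s = c(180, 180, 240, 240, 240, 120),
    load = factor(
      c("sit", "stand", "walk4", "walk6", "walk6_incline", "stand"),
      levels = lv, ordered = TRUE
    )
  ))
}

#' Derive transition windows around phase changes
#'
#' Each internal phase boundary of the protocol defines a transient-state
#' window running from `pre_span` seconds before the boundary ("onset") to
#' `post_span` seconds after it. Windows are closed on both ends and clipped
#' to the protocol span. Onsets come from the predefined protocol timing and
#' are identical for every subject; no event detection from the heart-rate
#' signal is performed.
#'
#' @inheritParams protocol_duration
#' @param pre_span Seconds before each onset included in the window
#'   (default 10).
#' @param post_span Seconds after each onset included in the window
#'   (default 60).
#'
#' @return An `hr_transitions` object: a tibble with columns `transition_id`,
#'   `onset_s`, `start_s`, `end_s`, sorted by onset, with attributes
#'   `pre_span`, `post_span` and `protocol_duration`. A single-phase protocol
#'   yields zero rows.
#' @examples
#' derive_transitions(build_default_protocol())
#' @export
derive_transitions <- function(protocol, pre_span = 10, post_span = 60) {
  stopifnot(inherits(protocol, "hr_protocol"))
  if (pre_span < 0 || post_span < 0) {
    stop("pre_span and post_span must be nonnegative", call. = FALSE)
  }
  onsets <- phase_change_times(protocol)
  dur <- protocol_duration(protocol)
  tw <- tibble::tibble(
    transition_id = seq_along(onsets),
    onset_s = onsets,
    start_s = pmax(protocol$start_time, onsets - pre_span),
    end_s = pmin(protocol$start_time + dur, onsets + post_span)
  )
  structure(
    tw,
    pre_span = pre_span, post_span = post_span,
    protocol_duration = dur,
    class = c("hr_transitions", class(tw))
  )
}

#' Label timestamps as steady-state or transition
#'
#' Assigns each timestamp to a condition: `transition` (with the id of the
#' window it falls in) if it lies inside any transition window, otherwise
#' `steady`. Window bounds are closed on both ends, so a timestamp exactly at
#' a window edge is in-window. Should windows ever overlap (only possible for
#' unusually long spans), a timestamp is assigned to the earlier-onset window
#' and a warning is raised; the labels always partition the input.
#'
#' @param timestamps Numeric vector of times in seconds from protocol start.
#' @param tw An `hr_transitions` object from [derive_transitions()].
#'
#' @return A tibble with columns `t_s`, `state` (factor with levels
#'   `steady`, `transition`) and `transition_id` (integer, `NA` for steady
#'   samples).
#' @examples
#' tw <- derive_transitions(build_default_protocol())
#' label_timestamps(c(200, 300, 240), tw)
#' @export
label_timestamps <- function(timestamps, tw) {
  stopifnot(inherits(tw, "hr_transitions"))
  id <- rep(NA_integer_, length(timestamps))
  if (nrow(tw) > 1 && any(tw$end_s[-nrow(tw)] >= tw$start_s[-1])) {
    warning("overlapping transition windows; earlier onset wins", call. = FALSE)
  }
  # later windows first so earlier onsets overwrite on overlap
  for (k in rev(seq_len(nrow(tw)))) {
    inside <- timestamps >= tw$start_s[k] & timestamps <= tw$end_s[k]
    id[inside] <- tw$transition_id[k]
  }
  tibble::tibble(
    t_s = timestamps,
    state = factor(
      ifelse(is.na(id), "steady", "transition"),
      levels = c("steady", "transition")
    ),
    transition_id = id
  )
}

#' Read or write a protocol as YAML or JSON
#'
#' The on-disk form is an ordered list of `{name, duration_s, load}` records
#' (plus an optional top-level `start_time`). Format is inferred from the
#' file extension (`.yaml`/`.yml` or `.json`).
#'
#' @param path File path.
#' @return `read_protocol()` returns an [hr_protocol()];
#'   `write_protocol()` returns `path` invisibly.
#' @export
read_protocol <- function(path) {
  doc <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  start_time <- 0
  phases <- doc
  if (!is.null(names(doc)) && "phases" %in% names(doc)) {
    phases <- doc$phases
    if (!is.null(doc$start_time)) start_time <- doc$start_time
  }
  if (!is.data.frame(phases)) {
    phases <- dplyr::bind_rows(lapply(phases, tibble::as_tibble))
  }
  hr_protocol(phases, start_time = start_time)
}

#' @rdname read_protocol
#' @inheritParams protocol_duration
#' @export
write_protocol <- function(protocol, path) {
  stopifnot(inherits(protocol, "hr_protocol"))
  ph <- protocol$phases[, c("name", "duration_s", "load")]
  ph$load <- as.character(ph$load)
  doc <- list(
    start_time = protocol$start_time,
    phases = lapply(seq_len(nrow(ph)), function(i) as.list(ph[i, ]))
  )
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(doc, path)
  }
  invisible(path)
}

#' Export transition windows as CSV
#'
#' @param tw An `hr_transitions` object.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_transitions <- function(tw, path) {
  stopifnot(inherits(tw, "hr_transitions"))
  utils::write.csv(
    as.data.frame(tw)[, c("transition_id", "onset_s", "start_s", "end_s")],
    path,
    row.names = FALSE
  )
  invisible(path)
}
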