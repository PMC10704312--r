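#' Prospective window specification
#'
#' @param durations Strictly increasing window lengths in minutes
#'   (default 15, 30, 60, 120).
#' @return Validated integer vector of class `"window_spec"`.
#' @export
window_spec <- function(durations = c(15, 30, 60, 120)) {
  if (length(durations) == 0L || any(durations <= 0) ||
      any(diff(durations) <= 0)) {
    stop("window durations must be strictly increasing and positive",
         call. = FALSE)
  }
  structure(as.integer(durations), class = "window_spec")
}

#' Count intensity minutes in a prospective window after a trigger
#'
#' The window comprises the `duration` clock minutes whose first minute
#' starts at the first minute boundary strictly after the trigger (the
#' minute already in progress when the prompt fires is excluded, so
#' pre-trigger movement is never counted). Minutes absent from the series
#' or classified `MISSING` reduce coverage.
#'
#' @param minutes Classified minute series for one participant
#'   (`minute_start`, `intensity`).
#' @param trigger_time Trigger timestamp (POSIXct or numeric seconds).
#' @param duration Window length in minutes.
#' @return A list with `lpa`, `mvpa`, `sed` minute counts, `coverage`
#'   (fraction of the window with a non-missing class) and `n_missing`.
#' @export
extract_window <- function(minutes, trigger_time, duration) {
  first <- (floor(as.numeric(trigger_time) / 60) + 1) * 60
  starts <- first + 60 * (seq_len(duration) - 1)
  idx <- match(starts, as.numeric(minutes$minute_start))
  cls <- as.character(minutes$intensity[idx])
  cls[is.na(cls)] <- "MISSING"
  n_miss <- sum(cls == "MISSING")
  list(lpa = sum(cls == "LPA"), mvpa = sum(cls == "MVPA"),
       sed = sum(cls == "SED"),
       coverage = 1 - n_miss / duration, n_missing = n_miss)
}

#' Dichotomize an activity count
#'
#' Recodes minute counts into the any-activity indicator used by the
#' logistic hurdle part: 1 if at least one active minute, else 0.
#'
#' @param count Non-negative count vector (`NA` passed through).
#' @return Integer 0/1 vector.
#' @export
dichotomize <- function(count) {
  if (any(count < 0, na.rm = TRUE)) stop("counts must be >= 0", call. = FALSE)
  as.integer(count >= 1)
}

#' Link answered prompts to subsequent activity windows
#'
#' Joins each completed EMA response to the participant's classified minute
#' series and computes, for every window duration, the LPA, MVPA and TPA
#' (= LPA + MVPA) minute totals, the any-activity indicators, and the
#' window coverage. Windows whose coverage falls below `coverage_min` get
#' missing outcomes (`NA`) for that duration.
#'
#' @param responses Completed, validated EMA rows (needs `participant_id`,
#'   `trigger_time` and the item score columns).
#' @param minutes Classified minute series (`participant_id`,
#'   `minute_start`, `intensity`).
#' @param windows A [window_spec()].
#' @param coverage_min Minimum window coverage to keep an outcome
#'   (default 1.0 — any missing minute drops that window's outcome).
#' @return data.frame with one row per response: ids, trigger time, item
#'   scores, and per window `d` the columns `lpa_d`, `mvpa_d`, `tpa_d`,
#'   `any_lpa_d`, `any_mvpa_d`, `any_tpa_d`, `coverage_d`.
#' @export
build_dataset <- function(responses, minutes, windows = window_spec(),
                          coverage_min = 1.0) {
  miss <- setdiff(unique(responses$participant_id),
                  unique(minutes$participant_id))
  if (length(miss) > 0L) {
    stop("no accelerometer data for participant(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (!"intensity" %in% names(minutes)) {
    stop("minute series must be classified first (see classify_minutes_df)",
         call. = FALSE)
  }
  by_pid <- split(minutes, minutes$participant_id)
  out <- responses
  for (d in windows) {
    lpa <- mvpa <- integer(nrow(responses))
    cov <- numeric(nrow(responses))
    for (i in seq_len(nrow(responses))) {
      w <- extract_window(by_pid[[responses$participant_id[i]]],
                          responses$trigger_time[i], d)
      lpa[i] <- w$lpa; mvpa[i] <- w$mvpa; cov[i] <- w$coverage
    }
    low <- cov < coverage_min
    lpa[low] <- NA_integer_
    mvpa[low] <- NA_integer_
    out[[paste0("lpa_", d)]] <- lpa
    out[[paste0("mvpa_", d)]] <- mvpa
    out[[paste0("tpa_", d)]] <- lpa + mvpa
    out[[paste0("any_lpa_", d)]] <- dichotomize(lpa)
    out[[paste0("any_mvpa_", d)]] <- dichotomize(mvpa)
    out[[paste0("any_tpa_", d)]] <- dichotomize(lpa + mvpa)
    out[[paste0("coverage_", d)]] <- cov
  }
  out
}

#' Descriptive summary of one activity outcome
#'
#' Reproduces the descriptive shape used for activity distributions:
#' mean (SD), median (range), quartiles, and the percentage of
#' observations with zero active minutes.
#'
#' @param dataset Output of [build_dataset()].
#' @param window Window duration in minutes.
#' @param intensity `"lpa"`, `"mvpa"` or `"tpa"`.
#' @return A one-row data.frame with `intensity`, `window`, `mean`, `sd`,
#'   `median`, `min`, `max`, `q1`, `q3`, `pct_zero`, `n`.
#' @export
pa_descriptives <- function(dataset, window, intensity = c("lpa", "mvpa",
                                                           "tpa")) {
  intensity <- match.arg(intensity)
  v <- dataset[[paste0(intensity, "_", window)]]
  v <- v[!is.na(v)]
  q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  data.frame(
    intensity = intensity, window = window,
    mean = round(mean(v), 1), sd = round(stats::sd(v), 1),
    median = round(q[2], 1), min = min(v), max = max(v),
    q1 = round(q[1], 1), q3 = round(q[3], 1),
    pct_zero = round(100 * mean(v == 0), 1), n = length(v)
  )
}
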