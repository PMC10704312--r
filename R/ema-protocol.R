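#' Lay out the daily prompting frames
#'
#' Builds the schedule of one-hour frames in which time-based EMA prompts
#' are randomly triggered. The default design places 6 frames of 60 minutes
#' between 09:00 and 22:00. Because the study's exact frame intervals are a
#' configuration of the sampling app, the default layout spaces the frames
#' evenly: the first frame opens the day window, the last closes it, and the
#' gaps between consecutive frames are equal
#' (6 x 60 min in a 780-min window leaves 420 min over 5 gaps, i.e. 84-min
#' gaps and 144-min spacing of frame starts). An explicit list of frame
#' start times overrides the layout.
#'
#' @param day_start,day_end Day window bounds as minutes since midnight
#'   (defaults 540 = 09:00 and 1320 = 22:00).
#' @param n_frames Number of frames per day (default 6).
#' @param frame_duration Frame length in minutes (default 60).
#' @param frame_starts Optional explicit frame start times (minutes since
#'   midnight), overriding the even layout.
#' @return data.frame with `frame` (index), `start_min`, `end_min`.
#' @export
build_frames <- function(day_start = 540, day_end = 1320, n_frames = 6,
                         frame_duration = 60, frame_starts = NULL) {
  window <- day_end - day_start
  if (n_frames * frame_duration > window) {
    stop("frames do not fit inside the day window", call. = FALSE)
  }
  if (is.null(frame_starts)) {
    frame_starts <- if (n_frames == 1L) {
      day_start
    } else {
      day_start + (seq_len(n_frames) - 1) * (window - frame_duration) /
        (n_frames - 1)
    }
  }
  if (length(frame_starts) != n_frames) {
    stop("frame_starts must have length n_frames", call. = FALSE)
  }
  fr <- data.frame(frame = seq_len(n_frames),
                   start_min = frame_starts,
                   end_min = frame_starts + frame_duration)
  if (any(fr$start_min < day_start) || any(fr$end_min > day_end)) {
    stop("frames fall outside the day window", call. = FALSE)
  }
  if (n_frames > 1L && any(diff(fr$start_min) < frame_duration)) {
    stop("frames overlap", call. = FALSE)
  }
  fr
}

#' Draw a random trigger time within a frame
#'
#' The trigger is uniform over the frame; reminder times are fixed at +5 and
#' +10 minutes and the questionnaire expires 20 minutes after the trigger.
#'
#' @param start_min,end_min Frame bounds in minutes since midnight.
#' @param n Number of draws.
#' @param reminder_offsets Reminder offsets in minutes (default `c(5, 10)`).
#' @param expiry_min Expiry offset in minutes (default 20).
#' @return data.frame with `trigger_min`, `reminder1_min`, `reminder2_min`,
#'   `expiry_min`.
#' @export
draw_trigger <- function(start_min, end_min, n = 1L,
                         reminder_offsets = c(5, 10), expiry_min = 20) {
  tr <- stats::runif(n, start_min, end_min)
  data.frame(trigger_min = tr,
             reminder1_min = tr + reminder_offsets[1],
             reminder2_min = tr + reminder_offsets[2],
             expiry_min = tr + expiry_min)
}

#' Flag invalid triggers in a delivered prompt log
#'
#' A delivered prompt is invalid if it falls outside every scheduled frame,
#' or if it is a surplus prompt — every prompt after the `n_frames`-th of a
#' participant-day, in time order. Invalid prompts are excluded from all
#' downstream analysis.
#'
#' @param prompts data.frame with `participant_id`, `date` (Date or
#'   day index), `trigger_min` (minutes since midnight).
#' @param frames Frame schedule from [build_frames()].
#' @return The input with logical columns `in_frame`, `surplus`, `invalid`.
#' @export
validate_triggers <- function(prompts, frames) {
  in_frame <- vapply(prompts$trigger_min, function(t) {
    any(t >= frames$start_min & t <= frames$end_min)
  }, logical(1))
  key <- interaction(prompts$participant_id, prompts$date, drop = TRUE)
  ord <- order(key, prompts$trigger_min)
  rank_in_day <- integer(nrow(prompts))
  rank_in_day[ord] <- stats::ave(seq_along(ord), key[ord],
                                 FUN = seq_along)
  surplus <- rank_in_day > nrow(frames)
  prompts$in_frame <- in_frame
  prompts$surplus <- surplus
  prompts$invalid <- !in_frame | surplus
  prompts
}

#' Compliance filter on completed prompts
#'
#' Retains participants who completed at least a minimum fraction of the
#' scheduled prompts; the threshold is `ceiling(min_fraction * scheduled)`,
#' so one-third of 42 scheduled prompts gives a threshold of 14.
#'
#' @param completed Named vector (or data.frame with `participant_id`,
#'   `n_completed`) of completed-questionnaire counts per participant.
#' @param min_fraction Minimum completed fraction (default 1/3).
#' @param scheduled Number of scheduled prompts per participant (default 42).
#' @return A list with `threshold` and `retained` (participant identifiers).
#' @export
compliance_filter <- function(completed, min_fraction = 1 / 3,
                              scheduled = 42) {
  if (is.data.frame(completed)) {
    counts <- stats::setNames(completed$n_completed, completed$participant_id)
  } else {
    counts <- completed
  }
  threshold <- ceiling(min_fraction * scheduled)
  list(threshold = threshold,
       retained = names(counts)[counts >= threshold])
}

#' Protocol-level descriptive statistics
#'
#' Computes the completion rate among valid delivered triggers, the mean
#' number of completed questionnaires per participant, and
#' median/quartile summaries of response latency and completion duration.
#' Percentages are reported to 2 decimals and means to 1 decimal.
#'
#' @param n_completed Number of completed questionnaires.
#' @param n_valid Number of valid delivered triggers.
#' @param n_participants Number of analysed participants.
#' @param latency_min Optional vector of response latencies (minutes).
#' @param duration_min Optional vector of completion durations (minutes).
#' @return A list with `completion_rate_pct`, `mean_completed_per_participant`
#'   and (when data supplied) `latency` / `duration` median and quartiles.
#' @export
protocol_descriptives <- function(n_completed, n_valid, n_participants,
                                  latency_min = NULL, duration_min = NULL) {
  if (n_valid == 0L) stop("no valid triggers; rate undefined", call. = FALSE)
  qsum <- function(v) {
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
    list(median = round(q[2], 2), q1 = round(q[1], 2), q3 = round(q[3], 2))
  }
  out <- list(
    n_completed = n_completed,
    n_valid = n_valid,
    completion_rate_pct = round(100 * n_completed / n_valid, 2),
    mean_completed_per_participant = round(n_completed / n_participants, 1)
  )
  if (!is.null(latency_min)) out$latency <- qsum(latency_min)
  if (!is.null(duration_min)) out$duration <- qsum(duration_min)
  out
}
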