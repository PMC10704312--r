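#' Intensity cut points on the minute-level ENMO scale
#'
#' ENMO cut points (in mg) separating sedentary, light (LPA) and
#' moderate-to-vigorous (MVPA) activity minutes for wrist-worn
#' accelerometry in older adults. The defaults are 57 mg (sedentary
#' maximum) and 104 mg (MVPA minimum); boundary values follow the
#' inclusive inequalities, i.e. exactly 57 mg is sedentary and exactly
#' 104 mg is MVPA.
#'
#' @param sedentary_max Upper ENMO bound (mg) of the sedentary class.
#' @param mvpa_min Lower ENMO bound (mg) of the MVPA class.
#' @return An object of class `"cut_points"`.
#' @export
cut_points <- function(sedentary_max = 57, mvpa_min = 104) {
  if (!(sedentary_max > 0 && mvpa_min > sedentary_max)) {
    stop("require 0 < sedentary_max < mvpa_min", call. = FALSE)
  }
  structure(list(sedentary_max = sedentary_max, mvpa_min = mvpa_min),
            class = "cut_points")
}

#' Per-sample ENMO from raw triaxial acceleration
#'
#' Computes the Euclidean norm minus one of each (x, y, z) sample,
#' clamps negative values to zero, and scales to milligravitational
#' units: \eqn{\mathrm{ENMO} = \max(0, \sqrt{x^2+y^2+z^2} - 1) \times 1000}.
#' A sample at rest with gravity on one axis gives exactly 0 mg.
#'
#' @param x,y,z Numeric vectors of acceleration in g.
#' @return Numeric vector of ENMO values in mg.
#' @export
compute_enmo <- function(x, y, z) {
  bad <- !is.finite(x) | !is.finite(y) | !is.finite(z)
  if (any(bad)) {
    stop("non-finite acceleration at sample index ",
         paste(utils::head(which(bad), 5L), collapse = ", "), call. = FALSE)
  }
  pmax(0, sqrt(x^2 + y^2 + z^2) - 1) * 1000
}

#' Aggregate a finer series into clock-aligned epochs
#'
#' Averages values into epochs of `epoch_s` seconds aligned to wall-clock
#' boundaries (the epoch containing time t starts at
#' `floor(t / epoch_s) * epoch_s`). Epochs inside the covered span that
#' contain no samples are returned with `NA`, never silently as zero.
#'
#' @param time Numeric seconds (or POSIXct) of each value.
#' @param value Numeric vector (e.g. per-sample or 1-s ENMO).
#' @param epoch_s Target epoch length in seconds (e.g. 1 or 60).
#' @return A data.frame with `epoch_start` (same class as `time`) and
#'   `value` (mean of contained values, `NA` for empty epochs), covering
#'   every epoch from the first to the last observed.
#' @export
aggregate_epochs <- function(time, value, epoch_s) {
  if (length(time) != length(value)) stop("length mismatch", call. = FALSE)
  if (length(time) == 0L) stop("empty series", call. = FALSE)
  tt <- as.numeric(time)
  if (is.unsorted(tt)) stop("timestamps must be non-decreasing", call. = FALSE)
  keep <- !is.na(value)           # missing source epochs carry no information
  if (!any(keep)) stop("no non-missing values to aggregate", call. = FALSE)
  tt <- tt[keep]
  value <- value[keep]
  start <- floor(tt / epoch_s) * epoch_s
  grid <- seq(min(start), max(start), by = epoch_s)
  idx <- match(start, grid)
  means <- rep(NA_real_, length(grid))
  agg <- rowsum(value, idx) / tabulate(idx, nbins = length(grid))[sort(unique(idx))]
  means[sort(unique(idx))] <- agg[, 1L]
  epoch_start <- if (inherits(time, "POSIXct")) {
    as.POSIXct(grid, origin = "1970-01-01", tz = attr(time, "tzone") %||% "UTC")
  } else grid
  data.frame(epoch_start = epoch_start, value = means)
}

#' Classify minute ENMO into intensity categories
#'
#' @param enmo_mg Numeric vector of minute-level ENMO (mg); `NA` allowed.
#' @param cuts A [cut_points()] object.
#' @return Factor with levels `SED`, `LPA`, `MVPA`, `MISSING`.
#' @export
classify_minute <- function(enmo_mg, cuts = cut_points()) {
  if (any(enmo_mg < 0, na.rm = TRUE)) {
    stop("minute ENMO must be non-negative", call. = FALSE)
  }
  out <- rep("MISSING", length(enmo_mg))
  out[!is.na(enmo_mg) & enmo_mg <= cuts$sedentary_max] <- "SED"
  out[!is.na(enmo_mg) & enmo_mg > cuts$sedentary_max &
        enmo_mg < cuts$mvpa_min] <- "LPA"
  out[!is.na(enmo_mg) & enmo_mg >= cuts$mvpa_min] <- "MVPA"
  factor(out, levels = c("SED", "LPA", "MVPA", "MISSING"))
}

#' Raw samples to classified minute series
#'
#' Full accelerometer processing chain: per-sample ENMO, mean over 1-second
#' epochs, mean over 1-minute epochs, then intensity classification. Minutes
#' without any data are kept with `NA` ENMO and class `MISSING`.
#'
#' @param raw data.frame with columns `participant_id`, `timestamp`
#'   (POSIXct or numeric seconds), `x_g`, `y_g`, `z_g`.
#' @param cuts A [cut_points()] object.
#' @return data.frame with `participant_id`, `minute_start`, `enmo_mg`,
#'   `intensity` — the canonical minute series.
#' @export
process_raw_signal <- function(raw, cuts = cut_points()) {
  need <- c("participant_id", "timestamp", "x_g", "y_g", "z_g")
  if (!all(need %in% names(raw))) {
    stop("raw data must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  parts <- split(raw, raw$participant_id)
  out <- lapply(names(parts), function(pid) {
    b <- parts[[pid]]
    if (is.unsorted(as.numeric(b$timestamp))) {
      stop("timestamps not increasing for participant ", pid, call. = FALSE)
    }
    enmo <- compute_enmo(b$x_g, b$y_g, b$z_g)
    sec <- aggregate_epochs(b$timestamp, enmo, 1)
    minute <- aggregate_epochs(sec$epoch_start, sec$value, 60)
    data.frame(participant_id = pid,
               minute_start = minute$epoch_start,
               enmo_mg = minute$value)
  })
  res <- do.call(rbind, out)
  res$intensity <- classify_minute(res$enmo_mg, cuts)
  rownames(res) <- NULL
  res
}

#' Attach intensity classes to a minute-level ENMO table
#'
#' @param minutes data.frame with `participant_id`, `minute_start`,
#'   `enmo_mg` (as written by the simulator or an external pipeline).
#' @param cuts A [cut_points()] object.
#' @return The input with an `intensity` factor column added.
#' @export
classify_minutes_df <- function(minutes, cuts = cut_points()) {
  minutes$intensity <- classify_minute(minutes$enmo_mg, cuts)
  minutes
}
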