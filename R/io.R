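#' Read and write the pipeline's plain-text data files
#'
#' The pipeline exchanges four CSV schemas: raw samples
#' (`participant_id`, `timestamp` ISO-8601, `x_g`, `y_g`, `z_g`), minute
#' series (`participant_id`, `minute_start`, `enmo_mg` and optionally
#' `intensity`), EMA logs (`participant_id`, `trigger_time`, `status`,
#' `latency_min`, and the item columns), and the linked-observation table
#' produced by [build_dataset()]. Timestamps are written in UTC.
#'
#' @param x data.frame to write.
#' @param path File path.
#' @return `read_*` return data.frames with timestamp columns parsed to
#'   POSIXct (UTC); `write_*` return `path` invisibly.
#' @name pipeline_io
NULL

ts_out <- function(t) format(t, "%Y-%m-%dT%H:%M:%OS3", tz = "UTC")
ts_in <- function(s) as.POSIXct(s, format = "%Y-%m-%dT%H:%M:%OS", tz = "UTC")

#' @rdname pipeline_io
#' @export
write_raw_csv <- function(x, path) {
  x$timestamp <- ts_out(as.POSIXct(x$timestamp, origin = "1970-01-01",
                                   tz = "UTC"))
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_raw_csv <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  x$timestamp <- ts_in(x$timestamp)
  x
}

#' @rdname pipeline_io
#' @export
write_minutes_csv <- function(x, path) {
  x$minute_start <- ts_out(x$minute_start)
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_minutes_csv <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  x$minute_start <- ts_in(x$minute_start)
  if ("intensity" %in% names(x)) {
    x$intensity <- factor(x$intensity,
                          levels = c("SED", "LPA", "MVPA", "MISSING"))
  }
  x
}

#' @rdname pipeline_io
#' @export
write_ema_csv <- function(x, path) {
  x$trigger_time <- ts_out(x$trigger_time)
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_ema_csv <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  x$trigger_time <- ts_in(x$trigger_time)
  x
}

#' Serialize a fitted model or ground truth to JSON
#'
#' @param fit An `"eh_glmm"` fit (for `write_fit_json`) or any list of
#'   ground-truth values (for `write_ground_truth_json`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  out <- list(
    family = fit$family$family, truncated = fit$family$truncated,
    coefficients = as.list(fit$coefficients),
    se = as.list(fit$se), vcov = unclass(fit$vcov),
    sigma_u = fit$sigma_u, theta = fit$theta, sigma_res = fit$sigma_res,
    logLik = fit$logLik, AIC = fit$AIC, n_obs = fit$n_obs,
    n_clusters = fit$n_clusters, converged = fit$converged,
    nAGQ = fit$nAGQ
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_fit_json
#' @export
write_ground_truth_json <- function(fit, path) {
  drop_cfg <- function(x) {
    if (is.list(x)) lapply(x[setdiff(names(x), "config")], drop_cfg) else x
  }
  jsonlite::write_json(drop_cfg(fit), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Load a study configuration from a YAML file
#'
#' Reads a key-value configuration (study scale, frames, items, hurdle
#' ground truth, cut points, windows, coverage threshold, quadrature
#' nodes, seed) and returns the corresponding [sim_config()] plus analysis
#' settings. Any key omitted from the file keeps its default.
#'
#' @param path YAML file path.
#' @return A list with elements `sim` (a [sim_config()]), `cuts`
#'   (a [cut_points()]), `windows` (a [window_spec()]), `coverage_min`,
#'   and `nAGQ`.
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim_args <- y[intersect(names(y),
                          names(formals(sim_config)))]
  if (!is.null(y$items)) {
    sim_args$items <- as.data.frame(do.call(rbind, lapply(y$items, as.data.frame)))
  }
  if (!is.null(y$hurdle)) sim_args$hurdle <- y$hurdle
  cfg <- do.call(sim_config, sim_args)
  list(
    sim = cfg,
    cuts = cut_points(y$sedentary_max %||% 57, y$mvpa_min %||% 104),
    windows = window_spec(y$windows %||% c(15, 30, 60, 120)),
    coverage_min = y$coverage_min %||% 1.0,
    nAGQ = y$nAGQ %||% 15L
  )
}
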