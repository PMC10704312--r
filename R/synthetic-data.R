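#' Configuration of the synthetic EMA-accelerometer study
#'
#' Bundles every parameter of the synthetic-data generator: study scale
#' (participants, days, prompts per day), the daily prompting design, the
#' Likert item model, prompt response behaviour, and the two-part
#' (hurdle) ground-truth model that links the driver item to subsequent
#' activity minutes.
#'
#' The defaults emulate the study design the package targets: 64
#' participants observed for 7 days with 6 time-based prompts per day in
#' one-hour frames between 09:00 and 22:00 (42 scheduled prompts per
#' person), 7 momentary items on a 1-7 Likert scale, a response
#' probability matching a 77.33% completion rate, and activity outcomes
#' whose zero/positive split and positive counts depend on the
#' within-person centered driver item with negative-binomial
#' overdispersion.
#'
#' Item means and total SDs follow typical momentary-item descriptives
#' (e.g. relaxation high with moderate spread, irritation low and
#' right-skewed on the latent scale); each item's variance is split 60%
#' within / 40% between persons so that every item passes a >50%
#' within-share screen.
#'
#' @param n_participants,n_days,prompts_per_day Study scale (64, 7, 6).
#' @param day_start,day_end Day window in minutes since midnight
#'   (09:00-22:00).
#' @param frame_duration Frame length in minutes (60).
#' @param items data.frame with columns `item`, `mu` (grand mean, Likert
#'   units), `tau` (between-person SD), `sigma` (within-person SD).
#' @param response_prob Probability that a prompt is answered.
#' @param driver_item Item whose (centered) score drives the activity
#'   outcome.
#' @param hurdle Named list with elements `lpa` and `mvpa`, each a list
#'   with logistic part `alpha0` (intercept), `omega_a` (random-intercept
#'   SD), `beta_w`, `beta_b` (within/between effects) and count part
#'   `gamma0` (log-scale intercept), `omega_c`, `delta_w`, `delta_b`,
#'   `theta` (NB2 dispersion). Count intercepts refer to the longest
#'   (120-minute) window.
#' @param truncation_mode `"truncated"` (positive counts drawn from the
#'   zero-truncated NB) or `"untruncated"` (plain NB draws with zeros
#'   promoted to 1; simple but biased, kept for sensitivity checks).
#' @param likert_mode `"discrete"` (scores rounded and clamped to 1..7) or
#'   `"continuous"` (latent scores returned, for unbiased parameter
#'   recovery).
#' @param signal_level `"observation"`, `"minute"` or `"raw"` — the level
#'   of data the simulator materialises.
#' @param sample_rate_hz Sampling rate for raw-signal generation.
#' @param seed Integer seed; all generator output is reproducible from it.
#' @return An object of class `"sim_config"`.
#' @export
sim_config <- function(n_participants = 64, n_days = 7, prompts_per_day = 6,
                       day_start = 540, day_end = 1320, frame_duration = 60,
                       items = default_items(),
                       response_prob = 0.7733,
                       driver_item = "intention",
                       hurdle = default_hurdle(),
                       truncation_mode = c("truncated", "untruncated"),
                       likert_mode = c("discrete", "continuous"),
                       signal_level = c("minute", "observation", "raw"),
                       sample_rate_hz = 10,
                       seed = 1L) {
  truncation_mode <- match.arg(truncation_mode)
  likert_mode <- match.arg(likert_mode)
  signal_level <- match.arg(signal_level)
  stopifnot(n_participants >= 1, n_days >= 1, prompts_per_day >= 1)
  if (prompts_per_day * frame_duration > day_end - day_start) {
    stop("prompts_per_day x frame_duration exceeds the day window",
         call. = FALSE)
  }
  if (response_prob < 0 || response_prob > 1) {
    stop("response_prob must be in [0, 1]", call. = FALSE)
  }
  if (any(items$tau < 0) || any(items$sigma < 0)) {
    stop("item SDs must be non-negative", call. = FALSE)
  }
  for (part in hurdle) {
    if (part$omega_a < 0 || part$omega_c < 0 || part$theta <= 0) {
      stop("hurdle SDs must be >= 0 and theta > 0", call. = FALSE)
    }
  }
  if (!driver_item %in% items$item) {
    stop("driver_item not among the configured items", call. = FALSE)
  }
  structure(list(
    n_participants = as.integer(n_participants),
    n_days = as.integer(n_days),
    prompts_per_day = as.integer(prompts_per_day),
    day_start = day_start, day_end = day_end,
    frame_duration = frame_duration,
    items = items, response_prob = response_prob,
    driver_item = driver_item, hurdle = hurdle,
    truncation_mode = truncation_mode, likert_mode = likert_mode,
    signal_level = signal_level, sample_rate_hz = sample_rate_hz,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' @rdname sim_config
#' @export
default_items <- function() {
  sd_tot <- c(1.5, 1.4, 1.0, 0.8, 1.1, 2.1, 2.1)
  data.frame(
    item = c("relax", "satisf", "irrit", "down", "fatigue",
             "intention", "selfeff"),
    mu = c(4.7, 4.8, 1.5, 1.3, 1.9, 3.7, 4.2),
    tau = sd_tot * sqrt(0.4),
    sigma = sd_tot * sqrt(0.6)
  )
}

#' @rdname sim_config
#' @export
default_hurdle <- function() {
  list(
    lpa = list(alpha0 = 1.6, omega_a = 1.0,
               beta_w = log(1.33), beta_b = 0.15,
               gamma0 = log(12), omega_c = 0.5,
               delta_w = log(1.08), delta_b = 0.05, theta = 1.5),
    mvpa = list(alpha0 = 0.2, omega_a = 1.2,
                beta_w = log(1.38), beta_b = 0.15,
                gamma0 = log(7), omega_c = 0.6,
                delta_w = log(1.12), delta_b = 0.05, theta = 1.2)
  )
}

#' Generate the participant roster with its latent random intercepts
#'
#' Draws every person-level latent quantity of the generative model: the
#' item random intercepts \eqn{u_{ik} \sim N(0, \tau_k^2)} and the
#' hurdle-part intercepts \eqn{a_i \sim N(0, \omega_a^2)} (logistic) and
#' \eqn{c_i \sim N(0, \omega_c^2)} (count) for each intensity. All draws
#' are reproducible from `config$seed`.
#'
#' @param config A [sim_config()] object.
#' @return A list with `roster` (data.frame of participant ids and hurdle
#'   intercepts), `item_intercepts` (matrix, participants x items) and
#'   `ground_truth` (config effect sizes echoed alongside the latents).
#' @export
gen_participants <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_participants
  ids <- sprintf("P%03d", seq_len(n))
  K <- nrow(config$items)
  u <- matrix(stats::rnorm(n * K, 0, rep(config$items$tau, each = n)),
              nrow = n, ncol = K,
              dimnames = list(ids, config$items$item))
  roster <- data.frame(participant_id = ids)
  for (nm in names(config$hurdle)) {
    h <- config$hurdle[[nm]]
    roster[[paste0("a_", nm)]] <- stats::rnorm(n, 0, h$omega_a)
    roster[[paste0("c_", nm)]] <- stats::rnorm(n, 0, h$omega_c)
  }
  list(roster = roster, item_intercepts = u,
       ground_truth = list(config = config, item_intercepts = u,
                           hurdle_intercepts = roster))
}

#' Generate the prompt log for every participant-day
#'
#' Lays out the daily frames with [build_frames()], draws one uniform
#' trigger per frame with [draw_trigger()], and marks each prompt answered
#' with probability `response_prob`, independently of momentary state.
#' Answered prompts get a response latency (mostly immediate, occasionally
#' several minutes, never past the 20-minute expiry) and a completion
#' duration around 1.8 minutes.
#'
#' @param config A [sim_config()] object.
#' @param start_date First study day (default `"2020-01-06"`).
#' @return data.frame with one row per scheduled prompt: `participant_id`,
#'   `day`, `date`, `frame`, `trigger_min`, `trigger_time` (POSIXct UTC),
#'   `status`, `latency_min`, `duration_min`.
#' @export
gen_prompts <- function(config, start_date = "2020-01-06") {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  frames <- build_frames(config$day_start, config$day_end,
                         config$prompts_per_day, config$frame_duration)
  grid <- expand.grid(frame = frames$frame,
                      day = seq_len(config$n_days),
                      participant_id = sprintf("P%03d",
                                               seq_len(config$n_participants)),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  n <- nrow(grid)
  fs <- frames$start_min[grid$frame]
  fe <- frames$end_min[grid$frame]
  trig <- stats::runif(n, fs, fe)
  answered <- stats::runif(n) < config$response_prob
  lat <- ifelse(stats::runif(n) < 0.55, stats::runif(n, 0, 0.49),
                pmin(stats::rexp(n, 1 / 4), 19.5))
  dur <- pmin(stats::rlnorm(n, log(1.79), 0.35), 15)
  date <- as.Date(start_date) + grid$day - 1L
  out <- data.frame(
    participant_id = grid$participant_id,
    day = grid$day, date = date, frame = grid$frame,
    trigger_min = trig,
    trigger_time = as.POSIXct(date, tz = "UTC") + trig * 60,
    status = ifelse(answered, "completed", "missed"),
    latency_min = ifelse(answered, round(lat, 2), NA_real_),
    duration_min = ifelse(answered, round(dur, 2), NA_real_)
  )
  out[order(out$participant_id, out$trigger_time), , drop = FALSE]
}

#' Generate momentary item scores for answered prompts
#'
#' Latent scores follow \eqn{x_{ijk} = \mu_k + u_{ik} + e_{ijk}} with
#' \eqn{e \sim N(0, \sigma_k^2)}. In `likert_mode = "discrete"` scores are
#' rounded to the nearest integer and clamped to the 1-7 scale (the form
#' real data takes); `"continuous"` returns the latent value, which keeps
#' parameter-recovery checks free of coarsening bias.
#'
#' @param participants Output of [gen_participants()].
#' @param prompts Output of [gen_prompts()].
#' @param config A [sim_config()] object.
#' @return The completed rows of `prompts` with one score column per item.
#' @export
gen_item_scores <- function(participants, prompts, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 2L)
  done <- prompts[prompts$status == "completed", , drop = FALSE]
  u <- participants$item_intercepts
  idx <- match(done$participant_id, rownames(u))
  for (k in seq_len(nrow(config$items))) {
    it <- config$items[k, ]
    latent <- it$mu + u[idx, it$item] +
      stats::rnorm(nrow(done), 0, it$sigma)
    done[[it$item]] <- if (config$likert_mode == "discrete") {
      pmin(pmax(round(latent), 1), 7)
    } else {
      latent
    }
  }
  rownames(done) <- NULL
  done
}

# Exact zero-truncated NB2 sampler via the inverse-CDF trick: draw the CDF
# position uniformly above P(Y = 0) and invert.
rtrunc_nbinom <- function(n, mu, theta) {
  p0 <- (theta / (theta + mu))^theta
  u <- stats::runif(n, p0, 1)
  stats::qnbinom(pmin(u, 1 - 1e-12), size = theta, mu = mu)
}

#' Generate hurdle activity-minute outcomes for answered prompts
#'
#' For each answered prompt the hurdle draws
#' \eqn{z \sim \mathrm{Bernoulli}(\mathrm{logit}^{-1}(\alpha_0 + a_i +
#' \beta_w (x_{ij} - \bar x_i) + \beta_b \bar x_i))}; when \eqn{z = 1} the
#' positive minute count comes from an NB2 with mean
#' \eqn{\exp(\gamma_0 + c_i + \delta_w (x_{ij} - \bar x_i) +
#' \delta_b \bar x_i)} and dispersion \eqn{\theta}, conditioned on
#' \eqn{y \ge 1} (zero-truncated) in `truncation_mode = "truncated"`, or
#' drawn unconditionally with zeros promoted to 1 otherwise. The centering
#' uses the person's realised mean of the driver item, matching the
#' centering applied at analysis time. Counts are capped at the window
#' length; capping is rare under the default intercepts and is reported
#' with a warning.
#'
#' @param scores Output of [gen_item_scores()].
#' @param participants Output of [gen_participants()].
#' @param config A [sim_config()] object.
#' @param window_min Window length in minutes the counts refer to
#'   (default 120, the longest window).
#' @param intensity `"lpa"` or `"mvpa"` — which hurdle parameter set to use.
#' @param seed_offset Internal offset so LPA and MVPA draws differ.
#' @return `scores` with columns `x_within`, `x_between`, `any_pa`
#'   and `minutes` added.
#' @export
gen_outcome_minutes <- function(scores, participants, config,
                                window_min = 120,
                                intensity = c("lpa", "mvpa"),
                                seed_offset = 0L) {
  stopifnot(inherits(config, "sim_config"))
  intensity <- match.arg(intensity)
  h <- config$hurdle[[intensity]]
  set.seed(config$seed + 3L + seed_offset +
             2654435L * match(intensity, c("lpa", "mvpa")))
  x <- scores[[config$driver_item]]
  cw <- center_within(x, scores$participant_id)
  ros <- participants$roster
  idx <- match(scores$participant_id, ros$participant_id)
  a_i <- ros[[paste0("a_", intensity)]][idx]
  c_i <- ros[[paste0("c_", intensity)]][idx]
  eta_z <- h$alpha0 + a_i + h$beta_w * cw$within + h$beta_b * cw$between
  eta_c <- h$gamma0 + c_i + h$delta_w * cw$within + h$delta_b * cw$between
  if (any(eta_c > log(1e6))) {
    bad <- which.max(eta_c)
    stop(sprintf("count mean overflow at prompt %s / %s",
                 scores$participant_id[bad],
                 format(scores$trigger_time[bad])), call. = FALSE)
  }
  n <- nrow(scores)
  z <- stats::rbinom(n, 1, stats::plogis(eta_z))
  mu <- exp(eta_c)
  y <- integer(n)
  pos <- z == 1L
  if (any(pos)) {
    y[pos] <- if (config$truncation_mode == "truncated") {
      rtrunc_nbinom(sum(pos), mu[pos], h$theta)
    } else {
      pmax(stats::rnbinom(sum(pos), size = h$theta, mu = mu[pos]), 1L)
    }
  }
  capped <- y > window_min
  if (any(capped)) {
    warning(sprintf("%d of %d positive counts capped at the %d-minute window",
                    sum(capped), sum(pos), window_min))
    y[capped] <- window_min
  }
  scores$x_within <- cw$within
  scores$x_between <- cw$between
  scores$any_pa <- z
  scores$minutes <- y
  scores
}

#' Materialise a minute-level ENMO trace consistent with prompt outcomes
#'
#' Builds a continuous per-minute ENMO series per participant covering the
#' whole study period (full wear, no gaps). Every minute starts as
#' sedentary background (ENMO uniform on \[0, 57)); for each answered
#' prompt, in time order, the target LPA and MVPA minutes are placed at
#' random positions within the prompt's window (the `window_min` clock
#' minutes starting at the first minute boundary strictly after the
#' trigger), skipping minutes already claimed by an earlier overlapping
#' window. LPA minutes get ENMO uniform on (57, 104), MVPA minutes
#' 104 mg plus a lognormal excursion. When overlapping windows leave too
#' few free minutes, the shortfall is reported and the realised counts are
#' returned so that round-trip checks compare against what was actually
#' placed.
#'
#' @param outcomes data.frame with per-prompt targets: needs
#'   `participant_id`, `trigger_time`, `lpa_target`, `mvpa_target`.
#' @param config A [sim_config()] object.
#' @param window_min Window the targets refer to (default 120).
#' @return A list with `minutes` (data.frame `participant_id`,
#'   `minute_start`, `enmo_mg`) and `realized` (the input with
#'   `lpa_placed`, `mvpa_placed` columns).
#' @export
gen_minute_trace <- function(outcomes, config, window_min = 120) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 7L)
  if (any(outcomes$lpa_target + outcomes$mvpa_target > window_min)) {
    stop("activity targets exceed the window length", call. = FALSE)
  }
  days <- unique(as.Date(outcomes$trigger_time, tz = "UTC"))
  span_start <- as.POSIXct(min(days), tz = "UTC")
  span_end <- as.POSIXct(max(days) + 1, tz = "UTC")
  minute_grid <- seq(span_start, span_end - 60, by = 60)
  nmin <- length(minute_grid)
  pids <- unique(outcomes$participant_id)
  out_min <- vector("list", length(pids))
  outcomes$lpa_placed <- 0L
  outcomes$mvpa_placed <- 0L
  for (pi in seq_along(pids)) {
    pid <- pids[pi]
    enmo <- stats::runif(nmin, 0, 56.99)
    taken <- logical(nmin)
    rows <- which(outcomes$participant_id == pid)
    rows <- rows[order(outcomes$trigger_time[rows])]
    for (r in rows) {
      first <- floor(as.numeric(outcomes$trigger_time[r]) / 60) * 60 + 60
      w0 <- (first - as.numeric(span_start)) / 60 + 1
      slots <- w0:(w0 + window_min - 1)
      slots <- slots[slots >= 1 & slots <= nmin]
      free <- slots[!taken[slots]]
      n_l <- min(outcomes$lpa_target[r], length(free))
      pick_l <- if (n_l > 0) sample(free, n_l) else integer(0)
      free <- setdiff(free, pick_l)
      n_m <- min(outcomes$mvpa_target[r], length(free))
      pick_m <- if (n_m > 0) sample(free, n_m) else integer(0)
      enmo[pick_l] <- stats::runif(n_l, 57.001, 103.999)
      enmo[pick_m] <- pmin(104 + stats::rlnorm(n_m, log(30), 0.6), 500)
      taken[c(pick_l, pick_m)] <- TRUE
      outcomes$lpa_placed[r] <- n_l
      outcomes$mvpa_placed[r] <- n_m
    }
    out_min[[pi]] <- data.frame(participant_id = pid,
                                minute_start = minute_grid,
                                enmo_mg = enmo)
  }
  short <- sum(outcomes$lpa_placed < outcomes$lpa_target) +
    sum(outcomes$mvpa_placed < outcomes$mvpa_target)
  if (short > 0) {
    warning(sprintf(
      "%d prompt windows had too few free minutes; targets trimmed", short))
  }
  list(minutes = do.call(rbind, out_min), realized = outcomes)
}

#' Synthesise a raw triaxial signal reproducing a minute-level ENMO series
#'
#' Emits `sample_rate_hz` triaxial samples per second: a unit gravity
#' vector along z plus a 1 Hz sinusoidal excursion whose amplitude is
#' calibrated against the sampling phases so that the minute's ENMO,
#' recomputed through the full processing chain (per-sample ENMO, 1-s
#' means, 1-min means), reproduces the target to numerical precision.
#' A zero-ENMO minute yields constant (0, 0, 1) samples.
#'
#' @param minutes data.frame with `participant_id`, `minute_start`,
#'   `enmo_mg` (targets; must be < 600 mg).
#' @param config A [sim_config()] object (uses `sample_rate_hz`).
#' @return data.frame with `participant_id`, `timestamp`, `x_g`, `y_g`,
#'   `z_g`.
#' @export
gen_raw_signal <- function(minutes, config) {
  stopifnot(inherits(config, "sim_config"))
  r <- as.integer(config$sample_rate_hz)
  if (r < 4) stop("sample_rate_hz must be at least 4", call. = FALSE)
  if (any(minutes$enmo_mg < 0)) {
    stop("negative ENMO target is unreachable", call. = FALSE)
  }
  if (any(minutes$enmo_mg >= 600)) {
    stop("ENMO targets must stay below 600 mg for the sinusoid model",
         call. = FALSE)
  }
  phase <- 2 * pi * (seq_len(r) - 1L) / r
  scale <- mean(pmax(0, sin(phase)))
  n_row <- nrow(minutes)
  per_min <- 60L * r
  offs <- rep(seq_len(per_min) - 1L, times = n_row) / r
  amp <- minutes$enmo_mg / 1000 / scale
  osc <- rep(amp, each = per_min) * sin(2 * pi * (offs %% 1))
  data.frame(
    participant_id = rep(minutes$participant_id, each = per_min),
    timestamp = rep(as.numeric(minutes$minute_start), each = per_min) + offs,
    x_g = 0, y_g = 0,
    z_g = 1 + osc
  )
}

#' Run the full synthetic study
#'
#' Orchestrates the generator: roster and latents, prompt log, item
#' scores, hurdle outcomes for the longest window (both LPA and MVPA),
#' and — depending on `signal_level` — the minute-level ENMO trace and the
#' raw triaxial signal.
#'
#' @param config A [sim_config()] object.
#' @param window_min Longest window the minute trace must support
#'   (default 120).
#' @return A list with `config`, `participants`, `prompts`, `ema` (scored
#'   prompts), `outcomes` (per-prompt LPA/MVPA targets), and when
#'   requested `minutes` (classified with default cut points applied
#'   downstream) plus `raw`.
#' @export
sim_study <- function(config = sim_config(), window_min = 120) {
  parts <- gen_participants(config)
  prompts <- gen_prompts(config)
  ema <- gen_item_scores(parts, prompts, config)
  lpa <- gen_outcome_minutes(ema, parts, config, window_min, "lpa")
  mvpa <- gen_outcome_minutes(ema, parts, config, window_min, "mvpa")
  outcomes <- ema[, c("participant_id", "trigger_time")]
  outcomes$lpa_target <- lpa$minutes
  outcomes$mvpa_target <- mvpa$minutes
  # the two intensities are drawn marginally; a window only holds
  # window_min minutes in total, so trim the rare joint excess
  over <- pmax(outcomes$lpa_target + outcomes$mvpa_target - window_min, 0L)
  if (any(over > 0L)) {
    warning(sprintf("%d prompts had LPA+MVPA targets above the window; %s",
                    sum(over > 0L), "MVPA (then LPA) targets trimmed"))
    trim_m <- pmin(over, outcomes$mvpa_target)
    outcomes$mvpa_target <- outcomes$mvpa_target - trim_m
    outcomes$lpa_target <- outcomes$lpa_target - (over - trim_m)
  }
  res <- list(config = config, participants = parts, prompts = prompts,
              ema = ema, outcomes = outcomes)
  if (config$signal_level %in% c("minute", "raw")) {
    tr <- gen_minute_trace(outcomes, config, window_min)
    res$minutes <- tr$minutes
    res$outcomes <- tr$realized
    if (config$signal_level == "raw") {
      res$raw <- gen_raw_signal(tr$minutes, config)
    }
  }
  res
}
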