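test_that("config validation rejects impossible designs", {
  expect_error(sim_config(prompts_per_day = 14), "exceeds the day window")
  expect_error(sim_config(response_prob = 1.2), "response_prob")
  bad <- default_hurdle(); bad$lpa$theta <- 0
  expect_error(sim_config(hurdle = bad), "theta")
  expect_error(sim_config(driver_item = "nope"), "driver_item")
})

test_that("participant generation is seed-deterministic with correct scale", {
  cfg <- sim_config(n_participants = 12, seed = 31)
  a <- gen_participants(cfg)
  b <- gen_participants(cfg)
  expect_identical(a, b)
  # zero between-person SD collapses the item intercepts to exactly 0
  it0 <- default_items(); it0$tau <- 0
  z <- gen_participants(sim_config(n_participants = 10, items = it0,
                                   seed = 31))
  expect_equal(unname(z$item_intercepts), matrix(0, 10, 7))
  # at large n the realised intercept SD approaches tau
  it <- default_items(); it$tau <- 1.5
  big <- gen_participants(sim_config(n_participants = 2000, items = it,
                                     seed = 32))
  expect_lt(abs(sd(big$item_intercepts[, "intention"]) / 1.5 - 1), 0.05)
})

test_that("item scores follow the latent two-level model", {
  it <- default_items(); it$tau <- 0; it$sigma <- 0; it$mu <- 4
  cfg <- sim_config(n_participants = 5, n_days = 1, items = it, seed = 41,
                    response_prob = 1)
  parts <- gen_participants(cfg)
  sc <- gen_item_scores(parts, gen_prompts(cfg), cfg)
  expect_true(all(sc$intention == 4))

  cfg2 <- sim_config(n_participants = 30, n_days = 7, seed = 42,
                     response_prob = 1)
  parts2 <- gen_participants(cfg2)
  sc2 <- gen_item_scores(parts2, gen_prompts(cfg2), cfg2)
  for (item in cfg2$items$item) {
    expect_true(all(sc2[[item]] %in% 1:7))    # discrete mode clamps to scale
  }
})

test_that("within-person variance share matches the tau/sigma arithmetic", {
  it <- default_items()
  it[it$item == "intention", c("tau", "sigma")] <- c(0.8, 1.2)
  cfg <- sim_config(n_participants = 200, n_days = 5, items = it,
                    likert_mode = "continuous", response_prob = 1, seed = 43)
  parts <- gen_participants(cfg)
  sc <- gen_item_scores(parts, gen_prompts(cfg), cfg)
  vd <- variance_decomposition(sc$intention, sc$participant_id)
  expect_lt(abs(vd$within_share - 1.2^2 / (1.2^2 + 0.8^2)), 0.05)
})

test_that("hurdle outcomes honour the gate, the cap and the NB mean", {
  base <- default_hurdle()
  # gate closed: a very negative logistic intercept yields all-zero counts
  h0 <- base; h0$lpa$alpha0 <- -30; h0$lpa$omega_a <- 0
  cfg <- sim_config(n_participants = 20, n_days = 3, hurdle = h0, seed = 51,
                    response_prob = 1)
  parts <- gen_participants(cfg)
  sc <- gen_item_scores(parts, gen_prompts(cfg), cfg)
  out <- gen_outcome_minutes(sc, parts, cfg, 120, "lpa")
  expect_true(all(out$minutes == 0))

  # gate open, no effects, huge theta: Poisson-like counts with mean gamma0
  h1 <- base
  h1$lpa[c("alpha0", "beta_w", "beta_b", "delta_w", "delta_b")] <- 0
  h1$lpa$alpha0 <- 30; h1$lpa$omega_a <- 0; h1$lpa$omega_c <- 0
  h1$lpa$gamma0 <- log(5); h1$lpa$theta <- 1e6
  cfg1 <- sim_config(n_participants = 150, n_days = 7, hurdle = h1,
                     truncation_mode = "untruncated", seed = 52,
                     response_prob = 1)
  parts1 <- gen_participants(cfg1)
  sc1 <- gen_item_scores(parts1, gen_prompts(cfg1), cfg1)
  out1 <- gen_outcome_minutes(sc1, parts1, cfg1, 120, "lpa")
  # untruncated mode promotes zeros to 1: E[y] = 5 + P(0)*1 ~ 5.007
  expect_equal(mean(out1$minutes), 5, tolerance = 0.02)

  # counts never exceed the window
  cfg2 <- sim_config(n_participants = 40, n_days = 7, seed = 53,
                     response_prob = 1)
  parts2 <- gen_participants(cfg2)
  sc2 <- gen_item_scores(parts2, gen_prompts(cfg2), cfg2)
  out2 <- suppressWarnings(gen_outcome_minutes(sc2, parts2, cfg2, 15, "lpa"))
  expect_true(all(out2$minutes <= 15))
})

test_that("the zero-truncated NB sampler matches the truncated pmf", {
  set.seed(54)
  n <- 2e5; mu <- 3.2; th <- 1.4
  y <- emahurdle:::rtrunc_nbinom(n, rep(mu, n), th)
  expect_true(all(y >= 1))
  p0 <- (th / (th + mu))^th
  for (k in 1:4) {
    expect_equal(mean(y == k),
                 dnbinom(k, size = th, mu = mu) / (1 - p0),
                 tolerance = 0.02)
  }
})

test_that("minute traces reproduce the per-prompt targets", {
  # widely spaced prompts: windows never overlap, placement is exact
  cfg <- sim_config(n_participants = 8, n_days = 3, prompts_per_day = 2,
                    seed = 55)
  st <- sim_study(cfg)
  expect_identical(st$outcomes$lpa_placed, st$outcomes$lpa_target)
  expect_identical(st$outcomes$mvpa_placed, st$outcomes$mvpa_target)
  mins <- classify_minutes_df(st$minutes)
  for (i in sample(nrow(st$outcomes), 25)) {
    w <- extract_window(mins[mins$participant_id ==
                               st$outcomes$participant_id[i], ],
                        st$outcomes$trigger_time[i], 120)
    expect_equal(w$lpa, st$outcomes$lpa_target[i])
    expect_equal(w$mvpa, st$outcomes$mvpa_target[i])
  }
  # every emitted ENMO is consistent with its class band
  cls <- classify_minute(st$minutes$enmo_mg)
  expect_false(any(cls == "MISSING"))
  # infeasible targets are refused
  bad <- st$outcomes[1, ]; bad$lpa_target <- 100; bad$mvpa_target <- 100
  expect_error(gen_minute_trace(bad, cfg, 120), "exceed")
})

test_that("full determinism: identical config gives identical study data", {
  cfg <- sim_config(n_participants = 5, n_days = 2, seed = 56)
  expect_identical(sim_study(cfg), sim_study(cfg))
})

test_that("raw signal reproduces minute ENMO through the processing chain", {
  cfg <- sim_config(seed = 57, sample_rate_hz = 10)
  minutes <- data.frame(
    participant_id = "P001",
    minute_start = as.POSIXct("2020-01-06 10:00:00", tz = "UTC") +
      60 * (0:19),
    enmo_mg = c(0, runif(19, 0, 400))
  )
  raw <- gen_raw_signal(minutes, cfg)
  expect_equal(nrow(raw), 20 * 60 * 10)       # 60 x rate samples per minute
  # a zero-ENMO minute is pure resting gravity
  first_min <- raw[raw$timestamp < as.numeric(minutes$minute_start[2]), ]
  expect_true(all(first_min$x_g == 0 & first_min$y_g == 0 &
                    first_min$z_g == 1))
  out <- process_raw_signal(raw)
  expect_lt(max(abs(out$enmo_mg - minutes$enmo_mg)), 1)
  expect_error(gen_raw_signal(transform(minutes, enmo_mg = -1), cfg),
               "unreachable")
})

test_that("marginal zero fraction matches 1-D integration over the intercept", {
  h <- default_hurdle()
  h$lpa$beta_w <- 0; h$lpa$beta_b <- 0
  cfg <- sim_config(n_participants = 400, n_days = 7, hurdle = h, seed = 58,
                    response_prob = 1)
  parts <- gen_participants(cfg)
  sc <- gen_item_scores(parts, gen_prompts(cfg), cfg)
  out <- suppressWarnings(gen_outcome_minutes(sc, parts, cfg, 120, "lpa"))
  p_zero_theory <- stats::integrate(function(a) {
    (1 - plogis(h$lpa$alpha0 + a)) * dnorm(a, 0, h$lpa$omega_a)
  }, -Inf, Inf)$value
  expect_equal(mean(out$minutes == 0), p_zero_theory, tolerance = 0.02)
})
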