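test_that("within/between centering reconstructs the predictor exactly", {
  cw <- center_within(c(3, 5, 7), rep("a", 3))
  expect_equal(cw$between, rep(5, 3))
  expect_equal(cw$within, c(-2, 0, 2))

  cw2 <- center_within(c(1, 1, 7, 7), c("a", "a", "b", "b"))
  expect_equal(cw2$between, c(1, 1, 7, 7))
  expect_equal(cw2$within, rep(0, 4))

  set.seed(61)
  x <- rnorm(200); cl <- sample(letters[1:8], 200, replace = TRUE)
  cw3 <- center_within(x, cl)
  expect_equal(cw3$within + cw3$between, x)
  expect_lt(max(abs(tapply(cw3$within, cl, mean))), 1e-10)
  # single-observation cluster has zero within-deviation
  cw4 <- center_within(c(2, 9), c("a", "b"))
  expect_equal(cw4$within, c(0, 0))
})

test_that("variance decomposition separates pure-between and pure-within", {
  # constant within cluster, different across clusters: share ~ 0
  x_b <- rep(c(1, 4, 7, 2, 9, 5), each = 10)
  cl <- rep(1:6, each = 10)
  expect_lt(variance_decomposition(x_b, cl)$within_share, 0.01)
  # equal cluster means, pure noise within: share ~ 1
  set.seed(62)
  x_w <- rnorm(600)
  cl_w <- rep(1:20, each = 30)
  expect_gt(variance_decomposition(x_w, cl_w)$within_share, 0.9)
  expect_warning(vd <- variance_decomposition(rep(4, 20), rep(1:4, 5)),
                 "constant")
  expect_true(is.na(vd$within_share))
})

test_that("sigma_u = 0 fits coincide with the plain GLM oracle", {
  set.seed(63)
  d <- make_glmm_data(30, 15, sigma_u = 0.6, family = "binomial")
  ours <- fit_glmm(d$y, d$x, d$cluster, eh_family("binomial"), sigma_u = 0)
  oracle <- glm(d$y ~ d$xw + d$xb, family = binomial)
  expect_lt(max(abs(unname(ours$coefficients) - unname(coef(oracle)))), 1e-6)
  expect_equal(ours$logLik, as.numeric(logLik(oracle)), tolerance = 1e-9)

  dp <- make_glmm_data(30, 15, beta = c(0.5, 0.2, 0.05), sigma_u = 0.4,
                       family = "poisson")
  ours_p <- fit_glmm(dp$y, dp$x, dp$cluster, eh_family("poisson"),
                     sigma_u = 0)
  oracle_p <- glm(dp$y ~ dp$xw + dp$xb, family = poisson)
  expect_lt(max(abs(unname(ours_p$coefficients) -
                      unname(coef(oracle_p)))), 1e-6)

  # negbin with fixed theta against the exponential-family GLM
  skip_if_not_installed("MASS")
  dn <- make_glmm_data(30, 15, beta = c(1, 0.1, 0.05), sigma_u = 0.4,
                       family = "negbin", theta = 2)
  fit_nb <- MASS::glm.nb(dn$y ~ dn$xw + dn$xb)
  ours_nb <- fit_glmm(dn$y, dn$x, dn$cluster, eh_family("negbin"),
                      sigma_u = 0)
  expect_lt(max(abs(unname(ours_nb$coefficients) -
                      unname(coef(fit_nb)))), 1e-4)
  expect_equal(ours_nb$theta, fit_nb$theta, tolerance = 1e-3)
})

test_that("quadrature log-likelihood matches dense integration on toys", {
  # evaluate the AGQ approximation at fixed parameter values on 3-cluster
  # toys and compare with a 10^4-point trapezoid integration per cluster
  agq_at <- function(fam, y, eta0, cluster, sigma_u, extra = NULL,
                     nAGQ = 15) {
    g <- as.integer(factor(cluster))
    emahurdle:::agq_loglik(fam, y, eta0, g, max(g), sigma_u, extra,
                           pracma::gaussHermite(nAGQ), new.env())
  }
  set.seed(64)
  d <- make_glmm_data(3, 10, sigma_u = 0.9, family = "binomial")
  eta0 <- 0.2 + 0.3 * d$xw + 0.1 * d$xb
  expect_equal(agq_at(eh_family("binomial"), d$y, eta0, d$cluster, 0.9),
               dense_marginal_ll(d$y, eta0, d$cluster, 0.9, "binomial"),
               tolerance = 1e-6)

  dn <- make_glmm_data(3, 12, beta = c(1, 0.15, 0.02), sigma_u = 0.7,
                       family = "negbin", theta = 2)
  eta0n <- 1 + 0.15 * dn$xw + 0.02 * dn$xb
  expect_equal(agq_at(eh_family("negbin"), dn$y, eta0n, dn$cluster, 0.7,
                      extra = 2),
               dense_marginal_ll(dn$y, eta0n, dn$cluster, 0.7, "negbin",
                                 theta = 2),
               tolerance = 1e-6)

  # zero-truncated NB likelihood agrees with its dense oracle too
  keep <- dn$y >= 1
  expect_equal(agq_at(eh_family("negbin", truncated = TRUE), dn$y[keep],
                      eta0n[keep], dn$cluster[keep], 0.7, extra = 2),
               dense_marginal_ll(dn$y[keep], eta0n[keep], dn$cluster[keep],
                                 0.7, "negbin", theta = 2,
                                 truncated = TRUE),
               tolerance = 1e-6)
})

test_that("estimates agree with an independent AGQ implementation", {
  skip_if_not_installed("lme4")
  set.seed(65)
  d <- make_glmm_data(50, 20, sigma_u = 0.8, family = "binomial")
  ours <- fit_glmm(d$y, d$x, d$cluster, eh_family("binomial"))
  df <- data.frame(y = d$y, xw = d$xw, xb = d$xb, cluster = d$cluster)
  ref <- lme4::glmer(y ~ xw + xb + (1 | cluster), data = df,
                     family = binomial, nAGQ = 15)
  expect_equal(unname(ours$coefficients), unname(lme4::fixef(ref)),
               tolerance = 1e-4)
  expect_equal(ours$logLik, as.numeric(logLik(ref)), tolerance = 1e-5)
  expect_equal(unname(ours$se),
               unname(summary(ref)$coefficients[, "Std. Error"]),
               tolerance = 1e-3)
})

test_that("NB at huge theta collapses onto the Poisson fit", {
  set.seed(66)
  d <- make_glmm_data(25, 12, beta = c(1, 0.1, 0.03), sigma_u = 0.5,
                      family = "poisson")
  pois <- fit_glmm(d$y, d$x, d$cluster, eh_family("poisson"))
  # evaluate the NB marginal likelihood at the Poisson solution, theta = 1e6
  gh <- pracma::gaussHermite(15)
  eta0 <- pois$coefficients[1] + pois$coefficients[2] * d$xw +
    pois$coefficients[3] * d$xb
  cache <- new.env()
  ll_nb <- emahurdle:::agq_loglik(eh_family("negbin"), d$y, eta0,
                                  as.integer(factor(d$cluster)), 25,
                                  pois$sigma_u, 1e6, gh, cache)
  expect_equal(ll_nb, pois$logLik, tolerance = 1e-3)
})

test_that("likelihood is invariant to row permutation and node-stable", {
  set.seed(67)
  d <- make_glmm_data(20, 10, sigma_u = 0.7, family = "binomial")
  f1 <- fit_glmm(d$y, d$x, d$cluster, eh_family("binomial"))
  perm <- sample(length(d$y))
  f2 <- fit_glmm(d$y[perm], d$x[perm], d$cluster[perm],
                 eh_family("binomial"))
  expect_lt(abs(f1$logLik - f2$logLik), 1e-7)
  # increasing quadrature nodes barely moves the optimum
  f5 <- fit_glmm(d$y, d$x, d$cluster, eh_family("binomial"), nAGQ = 5)
  f31 <- fit_glmm(d$y, d$x, d$cluster, eh_family("binomial"), nAGQ = 31)
  expect_lt(abs(f5$logLik - f31$logLik), 1e-4)
  expect_lt(abs(f1$logLik - f31$logLik), 1e-4)
})

test_that("boundary variance refits as a plain GLM with a flag", {
  set.seed(68)
  d <- make_glmm_data(25, 12, sigma_u = 0, family = "binomial")
  fit <- fit_glmm(d$y, d$x, d$cluster, eh_family("binomial"))
  expect_true(fit$boundary)
  expect_equal(fit$sigma_u, 0)
  oracle <- glm(d$y ~ d$xw + d$xb, family = binomial)
  expect_lt(max(abs(unname(fit$coefficients) - unname(coef(oracle)))), 1e-6)
})

test_that("family selection minimises AIC with the documented tie rule", {
  mk <- function(family, aic, converged = TRUE) {
    structure(list(AIC = aic, converged = converged,
                   family = eh_family(family)), class = "eh_glmm")
  }
  fits <- list(gaussian = mk("gaussian", 500), poisson = mk("poisson", 480),
               negbin = mk("negbin", 460))
  expect_equal(attr(select_family(fits), "selected"), "negbin")
  tie <- list(gaussian = mk("gaussian", 100), negbin = mk("negbin", 100))
  expect_warning(sel <- select_family(tie), "tie")
  expect_equal(attr(sel, "selected"), "negbin")
  part <- list(negbin = mk("negbin", 90, converged = FALSE),
               poisson = mk("poisson", 95))
  expect_warning(sel2 <- select_family(part), "non-converged")
  expect_equal(attr(sel2, "selected"), "poisson")
  all_bad <- list(negbin = mk("negbin", 90, converged = FALSE))
  expect_error(suppressWarnings(select_family(all_bad)), "all candidate")
})

test_that("AIC uses the fitted-parameter count", {
  set.seed(69)
  d <- make_glmm_data(40, 15, sigma_u = 1.2, family = "binomial")
  fit <- fit_glmm(d$y, d$x, d$cluster, eh_family("binomial"))
  expect_false(fit$boundary)
  expect_equal(fit$AIC, 2 * 4 - 2 * fit$logLik)   # 3 betas + sigma_u
  dn <- make_glmm_data(40, 15, beta = c(1, 0.1, 0), sigma_u = 0.6,
                       family = "negbin", theta = 2)
  fitn <- fit_glmm(dn$y, dn$x, dn$cluster, eh_family("negbin"))
  expect_equal(fitn$AIC, 2 * 5 - 2 * fitn$logLik) # + theta
})

test_that("effect summaries exponentiate with Wald duality", {
  fake <- structure(list(coefficients = c("(Intercept)" = 0, within = 0),
                         se = c("(Intercept)" = 1, within = 0.1)),
                    class = "eh_glmm")
  e <- summarize_effect(fake, "within", "OR")
  expect_equal(e$point, 1)
  expect_equal(e$ci_low, exp(-qnorm(0.975) * 0.1), tolerance = 1e-12)
  expect_equal(round(e$ci_low, 2), 0.82)
  expect_equal(round(e$ci_high, 2), 1.22)
  expect_equal(e$p, 1)
  expect_false(e$significant)

  strong <- structure(list(coefficients = c(within = log(1.33)),
                           se = c(within = 0.01)), class = "eh_glmm")
  es <- summarize_effect(strong, "within", "OR")
  expect_equal(es$point, 1.33)
  expect_true(es$significant)

  # CI excludes 1 exactly when p < alpha
  set.seed(70)
  for (i in 1:50) {
    b <- rnorm(1, 0, 0.3); se <- runif(1, 0.05, 0.4)
    f <- structure(list(coefficients = c(within = b),
                        se = c(within = se)), class = "eh_glmm")
    e <- summarize_effect(f, "within", "OR")
    excludes <- e$ci_low > 1 || e$ci_high < 1
    expect_equal(excludes, e$p < 0.05)
  }
})
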