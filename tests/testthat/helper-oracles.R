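# Independent oracles and small data generators used across the suite.
# The marginal-likelihood oracle integrates each cluster's likelihood on a
# dense trapezoid grid using base-R densities only, so it shares no code
# with the quadrature path it checks.

dense_marginal_ll <- function(y, eta0, cluster, sigma_u, family = "binomial",
                              theta = NULL, truncated = FALSE,
                              half_width = 8, n_grid = 10001) {
  cl <- as.factor(cluster)
  total <- 0
  for (lev in levels(cl)) {
    sel <- cl == lev
    us <- seq(-half_width * sigma_u, half_width * sigma_u,
              length.out = n_grid)
    lg <- vapply(us, function(u) {
      eta <- eta0[sel] + u
      ll <- switch(family,
        binomial = sum(stats::dbinom(y[sel], 1, stats::plogis(eta),
                                     log = TRUE)),
        poisson = sum(stats::dpois(y[sel], exp(eta), log = TRUE)),
        negbin = {
          mu <- exp(eta)
          base <- stats::dnbinom(y[sel], size = theta, mu = mu, log = TRUE)
          if (truncated) {
            base <- base - log(1 - (theta / (theta + mu))^theta)
          }
          sum(base)
        })
      ll + stats::dnorm(u, 0, sigma_u, log = TRUE)
    }, numeric(1))
    m <- max(lg)
    total <- total + m + log(pracma::trapz(us, exp(lg - m)))
  }
  total
}

# Clustered data from a random-intercept model, written independently of
# the package's synthetic-data module.
make_glmm_data <- function(G, m, beta = c(0.2, 0.3, 0.1), sigma_u = 0.8,
                           family = "binomial", theta = 1.5,
                           x_mean = 4, x_sd = 1.5) {
  cl <- rep(seq_len(G), each = m)
  u <- stats::rnorm(G, 0, sigma_u)
  x <- stats::rnorm(G * m, x_mean, x_sd)
  xb <- stats::ave(x, cl)
  xw <- x - xb
  eta <- beta[1] + beta[2] * xw + beta[3] * xb + u[cl]
  y <- switch(family,
    binomial = stats::rbinom(G * m, 1, stats::plogis(eta)),
    poisson = stats::rpois(G * m, exp(eta)),
    negbin = stats::rnbinom(G * m, size = theta, mu = exp(eta)))
  list(y = y, x = x, cluster = cl, xw = xw, xb = xb, u = u)
}

# Minute series builder for linkage tests: classes at given minute starts.
toy_minutes <- function(start, classes, pid = "P001") {
  enmo <- vapply(classes, function(cl) {
    switch(cl, SED = 10, LPA = 80, MVPA = 200, MISSING = NA_real_)
  }, numeric(1))
  data.frame(
    participant_id = pid,
    minute_start = start + 60 * (seq_along(classes) - 1),
    enmo_mg = enmo,
    intensity = factor(classes, levels = c("SED", "LPA", "MVPA", "MISSING"))
  )
}
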