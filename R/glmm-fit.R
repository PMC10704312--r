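#' Within- and between-person decomposition of a time-varying predictor
#'
#' Splits a momentary predictor into the person mean (between-person
#' component) and the momentary deviation from that mean (within-person
#' component), the standard hybrid-model decomposition for intensive
#' longitudinal data.
#'
#' @param x Numeric vector of predictor values.
#' @param cluster Vector of cluster (participant) identifiers, same length
#'   as `x`.
#' @return A list with numeric vectors `within` and `between`, each aligned
#'   with `x`. Clusters with a single observation get `within = 0`.
#' @examples
#' center_within(c(3, 5, 7), c("a", "a", "a"))
#' @export
center_within <- function(x, cluster) {
  if (length(x) == 0L) stop("empty input", call. = FALSE)
  if (length(x) != length(cluster)) {
    stop("x and cluster must have the same length", call. = FALSE)
  }
  cl <- as.factor(cluster)
  m <- tapply(x, cl, mean)
  between <- as.numeric(m[cl])
  list(within = x - between, between = between)
}

#' Within-person share of variance of a momentary item
#'
#' Fits an intercept-only Gaussian random-intercept model by maximum
#' likelihood and reports the proportion of total variance attributable to
#' within-person fluctuation,
#' \eqn{\sigma^2_w / (\sigma^2_w + \sigma^2_b)}. Items whose within-person
#' share exceeds 0.5 vary mostly from moment to moment rather than between
#' people, which is the usual screening rule for momentary determinants.
#'
#' @inheritParams center_within
#' @return A list with `within_share` (in \[0, 1\], or `NA` when degenerate),
#'   `sigma_within`, `sigma_between`, and `degenerate` flag.
#' @export
variance_decomposition <- function(x, cluster) {
  cl <- as.factor(cluster)
  if (nlevels(cl) < 2L) stop("need at least 2 clusters", call. = FALSE)
  if (stats::var(x) < 1e-12) {
    warning("predictor is constant; variance shares undefined")
    return(list(within_share = NA_real_, sigma_within = 0,
                sigma_between = 0, degenerate = TRUE))
  }
  fit <- fit_glmm(y = x, x = NULL, cluster = cluster,
                  family = eh_family("gaussian"))
  sw <- fit$sigma_res
  sb <- fit$sigma_u
  list(within_share = sw^2 / (sw^2 + sb^2),
       sigma_within = sw, sigma_between = sb, degenerate = FALSE)
}

# log(sum(exp(x))) along rows of a matrix, stable.
row_logsumexp <- function(m) {
  mx <- apply(m, 1L, max)
  mx + log(rowSums(exp(m - mx)))
}

# Adaptive Gauss-Hermite marginal log-likelihood for a random-intercept GLMM.
# y, eta0 observation-level; g integer cluster index (1..G); sig2 = sigma_u^2;
# gh = pracma::gaussHermite nodes; env caches the per-cluster modes between
# calls so each likelihood evaluation warm-starts the Newton search.
agq_loglik <- function(fam, y, eta0, g, G, sigma_u, extra, gh, cache) {
  sig2 <- sigma_u^2
  if (sigma_u < 1e-8) {
    return(sum(fam_logf(fam, y, eta0, extra)))
  }
  u <- cache$u
  if (is.null(u) || length(u) != G) u <- numeric(G)
  grad <- NULL
  for (iter in 1:100) {
    eta <- eta0 + u[g]
    s1 <- rowsum(fam_d1(fam, y, eta, extra), g)[, 1L]
    s2 <- rowsum(fam_d2(fam, y, eta, extra), g)[, 1L]
    grad <- s1 - u / sig2
    hess <- s2 - 1 / sig2          # strictly negative for our families
    step <- grad / hess
    step[!is.finite(step)] <- 0
    step <- pmin(pmax(step, -4), 4)
    u <- u - step
    if (max(abs(grad)) < 1e-9) break
  }
  cache$u <- u
  eta <- eta0 + u[g]
  h <- 1 / sig2 - rowsum(fam_d2(fam, y, eta, extra), g)[, 1L]
  if (any(h <= 0) || any(!is.finite(h))) return(NA_real_)
  s <- 1 / sqrt(h)
  K <- length(gh$x)
  n <- length(y)
  U <- u + sqrt(2) * outer(s, gh$x)                       # G x K node grid
  lf <- matrix(fam_logf_kernel(fam, y, eta0 + U[g, ], extra), n, K)
  lfs <- rowsum(lf, g) + rowsum(fam_logf_const(fam, y, extra), g)[, 1L]
  lognode <- lfs - U^2 / (2 * sig2) +
    matrix(log(gh$w) + gh$x^2, G, K, byrow = TRUE) + 0.5 * log(2) + log(s)
  sum(row_logsumexp(lognode)) - G * (log(sigma_u) + 0.5 * log(2 * pi))
}

# Closed-form marginal log-likelihood of the Gaussian random-intercept model
# (compound-symmetry covariance per cluster, via Woodbury identities).
lmm_loglik <- function(y, eta0, g, sigma_u, sigma_e) {
  r <- y - eta0
  n_i <- tabulate(g)
  sr <- rowsum(r, g)[, 1L]
  sr2 <- rowsum(r^2, g)[, 1L]
  se2 <- sigma_e^2
  su2 <- sigma_u^2
  denom <- se2 + n_i * su2
  quad <- sr2 / se2 - su2 * sr^2 / (se2 * denom)
  logdet <- (n_i - 1) * log(se2) + log(denom)
  -0.5 * sum(n_i * log(2 * pi) + logdet + quad)
}

#' Fit a random-intercept generalized linear mixed model
#'
#' Maximizes the exact marginal likelihood
#' \deqn{\ell = \sum_i \log \int \prod_j f(y_{ij} \mid \eta_{ij} + u_i)\,
#'   \phi(u_i; 0, \sigma_u^2)\, du_i}
#' with \eqn{\eta_{ij} = \beta_0 + \beta_w x^{(w)}_{ij} + \beta_b x^{(b)}_i},
#' the integral evaluated by adaptive Gauss-Hermite quadrature centred and
#' scaled at each cluster's conditional mode (Gaussian outcomes use the
#' closed-form linear-mixed-model likelihood instead). The predictor is
#' decomposed into within- and between-person components via
#' [center_within()]; both enter the model simultaneously.
#'
#' Standard errors come from the inverse of the numerically differentiated
#' observed information at the optimum. When the random-intercept SD is
#' driven to the boundary (\eqn{\sigma_u \approx 0}) the model is refitted as
#' a plain GLM (\eqn{\sigma_u = 0}) and flagged.
#'
#' @param y Outcome vector (0/1 for binomial; non-negative integers for
#'   count families; numeric for Gaussian).
#' @param x Momentary predictor, or `NULL` for an intercept-only model.
#' @param cluster Participant identifiers.
#' @param family An [eh_family()] object.
#' @param nAGQ Number of quadrature nodes (default 15).
#' @param sigma_u `NULL` to estimate the random-intercept SD, or a fixed
#'   non-negative value (0 gives a plain GLM fitted by the same machinery).
#' @param control List; `maxit` (default 500) and `reltol`.
#' @return An object of class `"eh_glmm"`: coefficients, standard errors and
#'   covariance on the link scale, `sigma_u`, family dispersion (`theta` or
#'   `sigma_res`), `logLik`, `AIC`, sample sizes, convergence flags and the
#'   number of quadrature nodes used.
#' @export
fit_glmm <- function(y, x, cluster, family = eh_family("binomial"),
                     nAGQ = 15L, sigma_u = NULL, control = list()) {
  fam <- family
  if (!inherits(fam, "eh_family")) stop("family must be an eh_family object")
  fam_check_y(fam, y)
  cl <- as.factor(cluster)
  g <- as.integer(cl)
  G <- nlevels(cl)
  n <- length(y)
  if (!is.null(x)) {
    cw <- center_within(x, cl)
    X <- cbind("(Intercept)" = 1, within = cw$within, between = cw$between)
  } else {
    X <- matrix(1, nrow = n, ncol = 1L,
                dimnames = list(NULL, "(Intercept)"))
  }
  p <- ncol(X)
  est_sigma <- is.null(sigma_u)
  n_extra <- fam_n_extra(fam)
  gh <- pracma::gaussHermite(as.integer(nAGQ))
  cache <- new.env(parent = emptyenv())

  # --- starting values -------------------------------------------------
  beta0 <- glm_start(fam, y, X)
  start <- beta0
  if (est_sigma) start <- c(start, log(0.5))
  if (fam$family == "negbin") {
    mu0 <- exp(pmin(drop(X %*% beta0), ETA_MAX))
    v <- mean((y - mu0)^2)
    th0 <- if (v > mean(mu0)) mean(mu0)^2 / (v - mean(mu0)) else 5
    start <- c(start, log(max(min(th0, 50), 0.05)))
  } else if (fam$family == "gaussian") {
    start <- c(start, log(stats::sd(y - drop(X %*% beta0)) + 1e-6))
  }

  negll <- function(par) {
    beta <- par[seq_len(p)]
    su <- if (est_sigma) exp(par[p + 1L]) else sigma_u
    eta0 <- drop(X %*% beta)
    ll <- if (fam$family == "gaussian") {
      se <- exp(par[p + est_sigma + 1L])
      if (su < 1e-10) su <- 1e-10
      lmm_loglik(y, eta0, g, su, se)
    } else {
      extra <- if (n_extra) exp(par[p + est_sigma + 1L]) else NULL
      agq_loglik(fam, y, eta0, g, G, su, extra, gh, cache)
    }
    if (!is.finite(ll)) return(1e10)
    -ll
  }

  maxit <- control$maxit %||% 500L
  opt <- stats::nlminb(start, negll,
                       control = list(iter.max = maxit, eval.max = 4L * maxit,
                                      rel.tol = control$reltol %||% 1e-9))
  conv <- opt$convergence == 0L
  par <- opt$par
  boundary <- FALSE
  if (est_sigma && exp(par[p + 1L]) < 1e-3) {
    # sigma_u at the boundary: refit the plain GLM and flag.
    refit <- fit_glmm(y, x, cluster, family = fam, nAGQ = nAGQ,
                      sigma_u = 0, control = control)
    refit$boundary <- TRUE
    refit$message <- "random-intercept SD converged to 0; plain GLM refit"
    return(refit)
  }

  hess <- try(stats::optimHess(par, negll), silent = TRUE)
  se_all <- rep(NA_real_, length(par))
  vcov_beta <- matrix(NA_real_, p, p, dimnames = list(colnames(X), colnames(X)))
  if (!inherits(hess, "try-error")) {
    vc <- try(solve(hess), silent = TRUE)
    if (!inherits(vc, "try-error") && all(is.finite(diag(vc))) &&
        all(diag(vc)[seq_len(p)] > 0)) {
      se_all <- sqrt(pmax(diag(vc), 0))
      vcov_beta <- vc[seq_len(p), seq_len(p), drop = FALSE]
      dimnames(vcov_beta) <- list(colnames(X), colnames(X))
    } else {
      conv <- FALSE
    }
  } else {
    conv <- FALSE
  }

  beta <- par[seq_len(p)]
  names(beta) <- colnames(X)
  se_beta <- se_all[seq_len(p)]
  names(se_beta) <- colnames(X)
  su_hat <- if (est_sigma) exp(par[p + 1L]) else sigma_u
  theta <- sigma_res <- NULL
  if (fam$family == "negbin") theta <- exp(par[p + est_sigma + 1L])
  if (fam$family == "gaussian") sigma_res <- exp(par[p + est_sigma + 1L])
  ll <- -opt$objective
  k <- p + as.integer(est_sigma) + n_extra
  structure(list(
    coefficients = beta, se = se_beta, vcov = vcov_beta,
    sigma_u = su_hat, theta = theta, sigma_res = sigma_res,
    logLik = ll, AIC = 2 * k - 2 * ll, n_par = k,
    n_obs = n, n_clusters = G,
    converged = conv, boundary = boundary, nAGQ = as.integer(nAGQ),
    family = fam, message = if (conv) "converged" else opt$message
  ), class = "eh_glmm")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Moment/IRLS-free starting values for the fixed effects: one call to the
# base GLM fitter on the matching (or nearest) exponential family.
glm_start <- function(fam, y, X) {
  f <- switch(fam$family,
    binomial = stats::binomial(),
    poisson = stats::poisson(),
    negbin = stats::poisson(),
    gaussian = stats::gaussian()
  )
  yy <- y
  if (fam$truncated) yy <- pmax(y - 1, 0)  # crude de-shift for the start
  co <- tryCatch(
    suppressWarnings(stats::glm.fit(X, yy, family = f)$coefficients),
    error = function(e) NULL
  )
  if (is.null(co) || anyNA(co)) co <- c(mean_link(fam, y), rep(0, ncol(X) - 1L))
  unname(co)
}

mean_link <- function(fam, y) {
  m <- mean(y)
  switch(fam$family,
    binomial = stats::qlogis(min(max(m, 0.02), 0.98)),
    gaussian = m,
    log(max(m, 0.05))
  )
}

#' @export
print.eh_glmm <- function(x, ...) {
  cat(sprintf("Random-intercept GLMM (%s%s), %d obs in %d clusters\n",
              x$family$family,
              if (x$family$truncated) ", zero-truncated" else "",
              x$n_obs, x$n_clusters))
  tab <- cbind(Estimate = x$coefficients, `Std. Error` = x$se)
  print(round(tab, 4))
  cat(sprintf("sigma_u = %.4f", x$sigma_u))
  if (!is.null(x$theta)) cat(sprintf(", theta = %.4f", x$theta))
  if (!is.null(x$sigma_res)) cat(sprintf(", sigma_res = %.4f", x$sigma_res))
  cat(sprintf("\nlogLik = %.4f, AIC = %.4f, %s\n", x$logLik, x$AIC,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' @export
logLik.eh_glmm <- function(object, ...) {
  structure(object$logLik, df = object$n_par, class = "logLik")
}

#' @export
coef.eh_glmm <- function(object, ...) object$coefficients

#' Choose the best-fitting count family by AIC
#'
#' Given candidate fits of the same data under different conditional
#' families, returns the one with the lowest AIC. Non-converged candidates
#' are dropped with a warning; exact AIC ties are broken by the fixed
#' preference order negative binomial, Poisson, Gaussian, with a warning.
#'
#' @param fits Named list of [fit_glmm()] results on identical data.
#' @return The selected `"eh_glmm"` fit, with the winning family name in
#'   attribute `"selected"`.
#' @export
select_family <- function(fits) {
  if (length(fits) == 0L) stop("no candidate fits", call. = FALSE)
  if (is.null(names(fits)) || any(names(fits) == "")) {
    names(fits) <- vapply(fits, function(f) f$family$family, "")
  }
  ok <- vapply(fits, function(f) isTRUE(f$converged), logical(1))
  if (any(!ok)) {
    warning("dropping non-converged candidates: ",
            paste(names(fits)[!ok], collapse = ", "))
  }
  fits <- fits[ok]
  if (length(fits) == 0L) stop("all candidate fits failed", call. = FALSE)
  pref <- c("negbin", "poisson", "gaussian")
  ord <- order(match(names(fits), pref, nomatch = length(pref) + 1L))
  fits <- fits[ord]
  aic <- vapply(fits, function(f) f$AIC, numeric(1))
  best <- which.min(aic)
  if (sum(abs(aic - aic[best]) < 1e-9) > 1L) {
    warning("AIC tie; keeping first family in preference order")
  }
  out <- fits[[best]]
  attr(out, "selected") <- names(fits)[best]
  out
}

#' Exponentiated effect estimate with Wald confidence interval
#'
#' Summarizes one coefficient of a fitted model on the multiplicative scale
#' used for reporting: odds ratios (`"OR"`) for the logistic hurdle part and
#' exponentiated count-model coefficients (`"expB"`) for the amount part.
#'
#' @param fit An `"eh_glmm"` fit.
#' @param coefficient Name of the coefficient (default `"within"`).
#' @param scale `"OR"` or `"expB"` (label only; both exponentiate).
#' @param conf_level Confidence level (default 0.95).
#' @param alpha Significance threshold for the `significant` flag
#'   (default 0.05).
#' @return A list with `scale`, `point`, `ci_low`, `ci_high`, two-sided Wald
#'   `p`, `significant`, and the link-scale `estimate` and `se`.
#' @export
summarize_effect <- function(fit, coefficient = "within",
                             scale = c("OR", "expB"),
                             conf_level = 0.95, alpha = 0.05) {
  scale <- match.arg(scale)
  if (!coefficient %in% names(fit$coefficients)) {
    stop("no coefficient named '", coefficient, "' in fit", call. = FALSE)
  }
  b <- unname(fit$coefficients[coefficient])
  se <- unname(fit$se[coefficient])
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  p <- 2 * stats::pnorm(-abs(b / se))
  list(scale = scale, point = exp(b),
       ci_low = exp(b - z * se), ci_high = exp(b + z * se),
       p = p, significant = is.finite(p) && p < alpha,
       estimate = b, se = se)
}
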