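#' Conditional response families for random-intercept mixed models
#'
#' Builds the family object used by [fit_glmm()]. Each family supplies the
#' conditional log-density together with its first and second derivatives
#' with respect to the linear predictor, which drive the inner Newton
#' mode-search of the adaptive quadrature.
#'
#' Supported families:
#' \describe{
#'   \item{`binomial`}{Bernoulli outcome, logit link.}
#'   \item{`poisson`}{Poisson counts, log link.}
#'   \item{`negbin`}{NB2 negative binomial (variance \eqn{\mu + \mu^2/\theta}),
#'     log link, dispersion \eqn{\theta} estimated jointly.}
#'   \item{`gaussian`}{Identity link; the marginal likelihood is evaluated in
#'     closed form (no quadrature), residual SD estimated jointly.}
#' }
#'
#' @param family One of `"binomial"`, `"poisson"`, `"negbin"`, `"gaussian"`.
#' @param truncated Logical; if `TRUE` the conditional density is
#'   zero-truncated (support \eqn{y \ge 1}). Only available for the Poisson
#'   and negative-binomial families; used when the hurdle count part is
#'   fitted as a zero-truncated likelihood rather than a plain fit to the
#'   positive subset.
#' @return An object of class `"eh_family"`.
#' @export
eh_family <- function(family = c("binomial", "poisson", "negbin", "gaussian"),
                      truncated = FALSE) {
  family <- match.arg(family)
  if (truncated && !family %in% c("poisson", "negbin")) {
    stop("zero-truncation is only defined for count families", call. = FALSE)
  }
  structure(list(family = family, truncated = truncated),
            class = "eh_family")
}

#' @export
print.eh_family <- function(x, ...) {
  cat(sprintf("<eh_family: %s%s>\n", x$family,
              if (x$truncated) ", zero-truncated" else ""))
  invisible(x)
}

# Linear predictors are clamped before exponentiation so a wild step in the
# optimizer cannot overflow the Poisson/NB mean.
ETA_MAX <- 30

# The conditional log-density is split as logf = const(y, theta) +
# kernel(y, eta, theta): the constant part does not depend on the linear
# predictor, so the quadrature can evaluate it once per observation instead
# of once per node.
fam_logf_const <- function(fam, y, extra = NULL) {
  switch(fam$family,
    binomial = numeric(length(y)),
    poisson = -lgamma(y + 1),
    negbin = {
      th <- extra
      lgamma(y + th) - lgamma(th) - lgamma(y + 1) + th * log(th)
    },
    stop("no conditional log-density for family ", fam$family)
  )
}

fam_logf_kernel <- function(fam, y, eta, extra = NULL) {
  switch(fam$family,
    binomial = y * eta - log1p(exp(eta)),
    poisson = {
      eta <- pmin(eta, ETA_MAX)
      ker <- y * eta - exp(eta)
      if (fam$truncated) ker <- ker - log1p(-exp(-exp(eta)))
      ker
    },
    negbin = {
      eta <- pmin(eta, ETA_MAX)
      mu <- exp(eta)
      th <- extra
      ker <- y * (eta - log(th + mu)) - th * log(th + mu)
      if (fam$truncated) ker <- ker - log1p(-(th / (th + mu))^th)
      ker
    }
  )
}

# Full log-density of y given eta, vectorized; extra = theta for negbin.
fam_logf <- function(fam, y, eta, extra = NULL) {
  fam_logf_const(fam, y, extra) + fam_logf_kernel(fam, y, eta, extra)
}

# First derivative of log f with respect to eta.
fam_d1 <- function(fam, y, eta, extra = NULL) {
  switch(fam$family,
    binomial = y - stats::plogis(eta),
    poisson = {
      mu <- exp(pmin(eta, ETA_MAX))
      d <- y - mu
      if (fam$truncated) d <- d - mu * exp(-mu) / (1 - exp(-mu))
      d
    },
    negbin = {
      mu <- exp(pmin(eta, ETA_MAX))
      th <- extra
      d <- (y - mu) * th / (th + mu)
      if (fam$truncated) {
        p0 <- (th / (th + mu))^th
        d <- d - th * mu * p0 / ((th + mu) * (1 - p0))
      }
      d
    }
  )
}

# Second derivative of log f with respect to eta. For truncated families the
# truncation correction is differentiated numerically; it only steers the
# Newton mode-search, the likelihood itself stays exact.
fam_d2 <- function(fam, y, eta, extra = NULL) {
  base <- switch(fam$family,
    binomial = {
      p <- stats::plogis(eta)
      -p * (1 - p)
    },
    poisson = -exp(pmin(eta, ETA_MAX)),
    negbin = {
      mu <- exp(pmin(eta, ETA_MAX))
      th <- extra
      -th * mu * (th + y) / (th + mu)^2
    }
  )
  if (fam$truncated) {
    mu <- exp(pmin(eta, ETA_MAX))
    base <- base + switch(fam$family,
      poisson = {
        E <- exp(-mu)
        S <- 1 - E
        -mu * E * (1 - mu) / S + mu^2 * E^2 / S^2
      },
      negbin = {
        th <- extra
        p0 <- (th / (th + mu))^th
        q <- 1 - p0
        th^2 * mu * p0 / (th + mu)^2 * (mu / q^2 - 1 / q)
      })
  }
  base
}

# Validates outcome support for a family.
fam_check_y <- function(fam, y) {
  if (anyNA(y) || any(!is.finite(y))) {
    stop("outcome contains missing or non-finite values", call. = FALSE)
  }
  switch(fam$family,
    binomial = if (!all(y %in% c(0, 1))) {
      stop("binomial-logit family requires a 0/1 outcome", call. = FALSE)
    },
    poisson = ,
    negbin = {
      if (any(y < 0) || any(y != round(y))) {
        stop("count families require non-negative integer outcomes",
             call. = FALSE)
      }
      if (fam$truncated && any(y < 1)) {
        stop("zero-truncated families require outcomes >= 1", call. = FALSE)
      }
    },
    gaussian = invisible(NULL)
  )
  invisible(TRUE)
}

# Number of auxiliary dispersion-type parameters estimated by the family.
fam_n_extra <- function(fam) {
  switch(fam$family, negbin = 1L, gaussian = 1L, 0L)
}
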