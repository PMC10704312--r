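---
title: "Hurdle mixed models for EMA-accelerometer data: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hurdle mixed models for EMA-accelerometer data: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emahurdle)
```

## The problem

Time-based ecological momentary assessment (EMA) studies prompt
participants a handful of times per day to rate momentary states —
emotions, fatigue, intention, self-efficacy — while a wrist-worn
accelerometer records movement continuously. The scientific question is
*within-person and prospective*: when a person's momentary state is
higher than their own typical level, are they more (or less) active in
the following minutes to hours? Activity minutes in short windows are
heavily zero-inflated with genuine zeros (many prompts are simply
followed by no activity), which motivates a two-part, or hurdle,
analysis rather than a single count model.

## From raw signal to minutes

Raw triaxial samples in gravitational units are reduced to the
Euclidean norm minus one, clamped at zero and scaled to mg
(`compute_enmo()`), averaged over 1-second and then 1-minute epochs
aligned to wall-clock boundaries (`aggregate_epochs()`), and classified
by ENMO cut points for older adults: sedentary at or below 57 mg, MVPA
at or above 104 mg, light activity between (`classify_minute()`).

Numerical choices worth stating:

* **Boundary ties.** 57 mg is sedentary and 104 mg is MVPA: the
  inclusive inequalities of the cut-point definition take precedence
  over the open band label "57–104".
* **Negative ENMO** is clamped to zero *before* averaging, the
  convention under which wrist cut points are derived.
* **Empty epochs are missing, never zero.** A minute without samples
  propagates as `MISSING` through classification and reduces window
  coverage downstream. No non-wear detection is applied — the
  processing chain defines none, and inventing one would silently
  change the outcome variable.
* When every second of a minute contains samples, the two-stage
  1 s → 60 s path is algebraically identical to single-pass minute
  means; the test suite checks agreement to 1e−9 mg.

## Protocol model

Six one-hour frames per day between 09:00 and 22:00, one uniform
random trigger per frame, reminders at +5 and +10 minutes, expiry at
+20 minutes. The exact frame intervals of any given deployment are an
app configuration; the default layout spaces the frames evenly (start
spacing 144 min, between-frame gaps 84 min), and an explicit frame list
can override it. Delivered triggers outside every frame, and any
trigger after the sixth of a participant-day, are invalid and excluded.
Participants are retained when they complete at least
`ceiling(42/3) = 14` prompts. Reminders are metadata only: analysis
windows are anchored at the *trigger* time, because the question is
what follows the assessed momentary state.

## Linkage

For each answered prompt, the window of duration `d` comprises the `d`
clock minutes starting at the first minute boundary strictly after the
trigger; the minute already in progress is excluded so that pre-trigger
movement is never counted. Within a window we total LPA and MVPA
minutes and their sum (TPA), and dichotomise each count as
"any activity" (≥ 1 minute). A window containing any missing minute is
dropped for that outcome by default (`coverage_min = 1`); the threshold
is a configuration knob, not a hidden rule. Windows of consecutive
prompts may overlap (the 120-minute window more often than not); they
are deliberately kept, matching the real design's behaviour.

## The hurdle model and its estimation

Each determinant × intensity × window cell is fitted in two parts, with
the predictor split into a person mean (`between`) and the momentary
deviation from it (`within`); both enter simultaneously and the
within-person effect is the reported quantity.

* **Logistic part** on all rows: binomial-logit GLMM with a random
  intercept per participant; effect reported as an odds ratio.
* **Count part** on the rows with at least one active minute: Gaussian,
  Poisson and NB2 negative-binomial random-intercept candidates, the
  lowest-AIC fit retained (ties broken negbin → poisson → gaussian with
  a warning). Effects are exponentiated coefficients.

The marginal likelihood of the non-Gaussian models,
$$\ell = \sum_i \log \int \prod_j f(y_{ij}\mid \eta_{ij}+u_i)\,
\phi(u_i;0,\sigma_u^2)\,du_i,$$
is evaluated by *adaptive* Gauss–Hermite quadrature: for each cluster
the integrand's mode is found by a damped Newton search (analytic first
and second derivatives of every conditional log-density, including the
zero-truncated variants), and 15 Hermite nodes are centred and scaled
there. The Gaussian family uses the closed-form linear-mixed-model
likelihood instead. Optimisation is quasi-Newton (`nlminb`) over
`(β, log σ_u[, log θ or log σ_e])` starting from a plain-GLM fit with
`σ_u = 0.5`; standard errors come from the inverse of the numerically
differentiated observed information, and AIC is `2k − 2ℓ` with `k` the
number of estimated parameters.

Degenerate situations are handled explicitly rather than silently:
`σ_u → 0` triggers a plain-GLM refit with a boundary flag; an outcome
with no variation skips the logistic part; a positive subset below 50
rows or 10 clusters skips the count part; every cell of a grid run
yields a result object even when a fit fails.

By default the count part is an *untruncated* fit to the positive
subset — the two-step procedure the hurdle formulation describes — and
`truncated = TRUE` switches to the zero-truncated likelihood as a
sensitivity analysis. With truncated data-generation, the truncated
likelihood is the correctly specified choice and is what the recovery
tests use.

### Verification strategy

The fitter is checked along two independent routes: (i) the quadrature
log-likelihood agrees with dense trapezoid integration (10⁴ nodes per
cluster) to 1e−6 on small toys, for binomial, NB and zero-truncated NB
families; (ii) at `σ_u = 0` the fit reproduces `stats::glm` (and
`MASS::glm.nb`) to 1e−6, and on clustered binary data it reproduces
`lme4::glmer` (nAGQ = 15) coefficients, standard errors and
log-likelihood. Increasing the node count 5 → 31 moves the optimum by
less than 1e−4, and the likelihood is invariant to row permutation.

## The synthetic-data generator

The generator is first-class, tested code; it emulates the target study
design: 64 participants × 7 days × 6 prompts (42 scheduled prompts per
person), a response probability of 0.7733 (the design's completion
rate), seven Likert items, and hurdle outcomes driven by one
configurable item (default: intention).

* **Items.** Latent scores `x = μ_k + u_ik + e`, with item means and
  total SDs chosen at values typical for these constructs (relaxation
  4.7 ± 1.5 down to feeling-down 1.3 ± 0.8, intention 3.7 ± 2.1) and
  each item's variance split 60/40 within/between, so every item passes
  the >50% within-person variance screen used to select momentary
  determinants. Discrete mode rounds and clamps to 1–7; continuous mode
  returns the latent score so that recovery tests are free of
  coarsening bias — discretisation attenuates effects, and the package
  treats that as a measurement property to study, not a property of the
  estimator.
* **Hurdle outcomes.** Logistic gate and NB2 positive counts as in the
  fitted model, with centring on the person's *realised* item mean —
  exactly what the analysis will compute. Default effect sizes
  (OR 1.33, expB 1.08 for LPA) are of the magnitude such studies
  report; the count intercepts (`log 12` LPA, `log 7` MVPA for the
  120-minute window) and dispersions (1.5, 1.2) give zero-shares and
  positive-count magnitudes in the realistic range. Counts are capped
  at the window length with a warning; under the defaults caps touch
  well under 1% of draws, and recovery tests use `γ0 = log 10, θ = 2`
  to keep them below 0.1%.
* **Minute traces.** The per-prompt targets for the longest window are
  placed at random positions inside that window on a sedentary
  background (ENMO bands: uniform below 57, uniform in (57, 104),
  104 + lognormal for MVPA), so the shorter nested windows inherit
  counts monotonically, as physics requires. Placement is exact when
  windows do not overlap; overlapping windows share minutes, as in real
  data.
* **Raw signal.** Each minute becomes a 1 Hz sinusoidal excursion on
  top of unit gravity, with amplitude calibrated against the sampling
  phases so the full processing chain reproduces the target ENMO to
  machine precision.
* **Nonresponse** is Bernoulli and state-independent; the design models
  compliance but nothing about missingness mechanisms.

What passing these tests does *not* show about real data: circadian and
weekday structure, autocorrelated affect dynamics, informative
missingness, device non-wear and calibration error are all absent from
the generator, so the tests certify the estimator and the pipeline
plumbing, not robustness to those phenomena.

## Study-scale checks and problem sizes

The acceptance suite verifies, at fixed seeds: the 84-cell grid
enumeration; the protocol arithmetic (2057/2660 → 77.33%,
2057/64 → 32.1, threshold 14 of 42); quadrature-vs-dense-integration
and GLM-limit equivalences; parameter recovery with 150 replicates of
150 clusters × 30 observations (|bias| < 0.05 on the link scale, 95% CI
coverage within [0.92, 0.98] for both hurdle parts); type-I error for
the within-effect at the null over 400 replicates of 64 × 30
(rejection rate within [0.03, 0.07]); and AIC selecting the negative
binomial in ≥ 90% of 100 overdispersed replicates. These replicate
counts are the package's chosen problem sizes for desk-scale runs; the
thresholds are the substantive claims.

## Known limitations

Random intercepts only (no slope heterogeneity); no covariates beyond
the decomposed determinant; no multiple-testing correction in the main
report (a Benjamini–Hochberg column is emitted as supplementary
output); Wald inference throughout; `.cwa` device binaries are out of
scope — the pipeline starts from raw-sample or minute-level CSV.
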