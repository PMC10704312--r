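#' Specification of the determinant x intensity x window model grid
#'
#' @param determinants Item (determinant) names; default the 7 momentary
#'   items.
#' @param intensities Activity outcomes; default LPA, MVPA and TPA.
#' @param windows A [window_spec()].
#' @return An object of class `"model_grid"`.
#' @export
model_grid <- function(determinants = c("relax", "satisf", "irrit", "down",
                                        "fatigue", "intention", "selfeff"),
                       intensities = c("lpa", "mvpa", "tpa"),
                       windows = window_spec()) {
  if (length(determinants) == 0L || length(intensities) == 0L ||
      length(windows) == 0L) {
    stop("empty grid dimension", call. = FALSE)
  }
  structure(list(determinants = determinants, intensities = intensities,
                 windows = windows), class = "model_grid")
}

#' Enumerate the model cells of a grid
#'
#' Deterministic determinant-major order (then intensity, then window); the
#' default grid of 7 determinants x 3 intensities x 4 windows yields 84
#' cells.
#'
#' @param grid A [model_grid()].
#' @return data.frame with `cell_id`, `determinant`, `intensity`, `window`.
#' @export
enumerate_models <- function(grid) {
  stopifnot(inherits(grid, "model_grid"))
  cells <- expand.grid(window = as.integer(grid$windows),
                       intensity = grid$intensities,
                       determinant = grid$determinants,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  cells <- cells[, c("determinant", "intensity", "window")]
  cells$cell_id <- sprintf("%s_%s_%d", cells$determinant, cells$intensity,
                           cells$window)
  rownames(cells) <- NULL
  cells[, c("cell_id", "determinant", "intensity", "window")]
}

#' Fit the two-part hurdle model for one grid cell
#'
#' Part one fits a binomial-logit random-intercept GLMM to the
#' any-activity indicator on all rows with a non-missing outcome. Part two
#' restricts to rows with at least one active minute and fits the
#' candidate count families (Gaussian, Poisson, negative binomial),
#' keeping the lowest-AIC fit. By default the count candidates are plain
#' (untruncated) fits to the positive subset, mirroring the two-step
#' procedure the hurdle formulation describes; `truncated = TRUE` switches
#' the count families to their zero-truncated likelihoods as a sensitivity
#' analysis. Within-person effects are summarised as odds ratios (logistic
#' part) and exponentiated coefficients (count part).
#'
#' @param dataset Output of [build_dataset()].
#' @param determinant Item column to use as predictor.
#' @param intensity `"lpa"`, `"mvpa"` or `"tpa"`.
#' @param window Window duration in minutes.
#' @param truncated Fit zero-truncated count likelihoods (default FALSE).
#' @param min_positive Minimum positive rows (and clusters) for the count
#'   part; below it the count part is skipped (defaults 50 rows,
#'   10 clusters).
#' @param min_clusters See `min_positive`.
#' @param nAGQ Quadrature nodes passed to [fit_glmm()].
#' @param alpha Significance level for flags (default 0.05).
#' @return An object of class `"hurdle_result"`: cell identifiers, the
#'   logistic-part fit and effect summary, the selected count family with
#'   its fit and effect summary, sample sizes and accumulated warnings.
#' @export
fit_hurdle_cell <- function(dataset, determinant, intensity, window,
                            truncated = FALSE, min_positive = 50,
                            min_clusters = 10, nAGQ = 15L, alpha = 0.05) {
  ycol <- paste0(intensity, "_", window)
  if (!ycol %in% names(dataset) || !determinant %in% names(dataset)) {
    stop("dataset lacks column ", ycol, " or ", determinant, call. = FALSE)
  }
  keep <- !is.na(dataset[[ycol]]) & !is.na(dataset[[determinant]])
  d <- dataset[keep, , drop = FALSE]
  y <- d[[ycol]]
  x <- d[[determinant]]
  cl <- d$participant_id
  warns <- character(0)
  res <- list(cell_id = sprintf("%s_%s_%d", determinant, intensity, window),
              determinant = determinant, intensity = intensity,
              window = window, n_logistic = nrow(d), n_count = 0L)

  yb <- dichotomize(y)
  if (length(unique(yb)) < 2L) {
    warns <- c(warns, "degenerate any-activity outcome; logistic part skipped")
    res$logistic <- NULL
  } else {
    lfit <- tryCatch(
      fit_glmm(yb, x, cl, eh_family("binomial"), nAGQ = nAGQ),
      error = function(e) e)
    if (inherits(lfit, "error")) {
      warns <- c(warns, paste("logistic part failed:", conditionMessage(lfit)))
      res$logistic <- NULL
    } else {
      if (!lfit$converged) warns <- c(warns, "logistic part not converged")
      res$logistic <- lfit
      res$logistic_effect <- summarize_effect(lfit, "within", "OR",
                                              alpha = alpha)
    }
  }

  pos <- y >= 1
  n_cl_pos <- length(unique(cl[pos]))
  res$n_count <- sum(pos)
  if (sum(pos) < min_positive || n_cl_pos < min_clusters) {
    warns <- c(warns, sprintf(
      "positive subset too small (%d rows, %d clusters); count part skipped",
      sum(pos), n_cl_pos))
  } else {
    yp <- y[pos]; xp <- x[pos]; clp <- cl[pos]
    fams <- list(
      gaussian = eh_family("gaussian"),
      poisson = eh_family("poisson", truncated = truncated),
      negbin = eh_family("negbin", truncated = truncated)
    )
    fits <- lapply(fams, function(f) {
      tryCatch(fit_glmm(yp, xp, clp, f, nAGQ = nAGQ),
               error = function(e) e)
    })
    bad <- vapply(fits, inherits, logical(1), "error")
    for (nm in names(fits)[bad]) {
      warns <- c(warns, sprintf("%s count candidate failed: %s", nm,
                                conditionMessage(fits[[nm]])))
    }
    fits <- fits[!bad]
    if (length(fits) > 0L) {
      sel <- withCallingHandlers(
        tryCatch(select_family(fits), error = function(e) e),
        warning = function(w) {
          warns <<- c(warns, conditionMessage(w))
          invokeRestart("muffleWarning")
        })
      if (!inherits(sel, "error")) {
        res$count <- sel
        res$count_family <- attr(sel, "selected")
        res$count_aic <- vapply(fits, function(f) f$AIC, numeric(1))
        res$count_effect <- summarize_effect(sel, "within", "expB",
                                             alpha = alpha)
      } else {
        warns <- c(warns, conditionMessage(sel))
      }
    }
  }
  res$warnings <- warns
  structure(res, class = "hurdle_result")
}

#' @export
print.hurdle_result <- function(x, ...) {
  cat(sprintf("Hurdle cell %s (n=%d, positives=%d)\n", x$cell_id,
              x$n_logistic, x$n_count))
  if (!is.null(x$logistic_effect)) {
    e <- x$logistic_effect
    cat(sprintf("  logistic within-effect OR %.2f (%.2f-%.2f), p=%s\n",
                e$point, e$ci_low, e$ci_high, format_p(e$p)))
  }
  if (!is.null(x$count_effect)) {
    e <- x$count_effect
    cat(sprintf("  count part (%s) expB %.2f (%.2f-%.2f), p=%s\n",
                x$count_family, e$point, e$ci_low, e$ci_high, format_p(e$p)))
  }
  if (length(x$warnings)) cat("  warnings:", length(x$warnings), "\n")
  invisible(x)
}

#' Fit the full hurdle model grid
#'
#' Runs [fit_hurdle_cell()] for every cell of the grid. Per-cell failures
#' are caught and recorded so one pathological cell never aborts the grid;
#' every cell yields a result object.
#'
#' @param dataset Output of [build_dataset()].
#' @param grid A [model_grid()].
#' @param ... Passed to [fit_hurdle_cell()].
#' @return A list of `"hurdle_result"` objects, one per cell, in
#'   [enumerate_models()] order, with class `"hurdle_grid"`.
#' @export
run_grid <- function(dataset, grid = model_grid(), ...) {
  cells <- enumerate_models(grid)
  results <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    results[[i]] <- tryCatch(
      suppressWarnings(
        fit_hurdle_cell(dataset, cells$determinant[i], cells$intensity[i],
                        cells$window[i], ...)),
      error = function(e) {
        structure(list(cell_id = cells$cell_id[i],
                       determinant = cells$determinant[i],
                       intensity = cells$intensity[i],
                       window = cells$window[i],
                       n_logistic = 0L, n_count = 0L,
                       warnings = paste("cell failed:",
                                        conditionMessage(e))),
                  class = "hurdle_result")
      })
  }
  names(results) <- cells$cell_id
  structure(results, class = "hurdle_grid")
}

# P values rendered in the journal style: no leading zero, two decimals
# (".03", ".49"), three decimals below .01 (".006"), "<.001" below .001 and
# ">.99" above .99.
format_p <- function(p) {
  vapply(p, function(pi) {
    if (is.na(pi)) return(NA_character_)
    if (pi < 0.001) return("<.001")
    if (pi > 0.99) return(">.99")
    digits <- if (pi < 0.0095) 3L else 2L
    sub("^0", "", sprintf(paste0("%.", digits, "f"), pi))
  }, character(1))
}

#' Render grid results as an effects table and a sign map
#'
#' Produces the wide reporting table — one row per cell with the
#' logistic-part odds ratio and the count-part exponentiated coefficient,
#' each with its 95% CI and p value — plus a compact sign map marking
#' significantly positive (`+`) and negative (`-`) within-person effects
#' and leaving non-significant cells blank. Effects are printed to two
#' decimals and CIs as `"lo-hi"`. A Benjamini-Hochberg adjusted p value
#' column is appended as supplementary output; the significance flags
#' themselves use the unadjusted alpha = .05 rule.
#'
#' @param results A `"hurdle_grid"` from [run_grid()].
#' @param alpha Significance level for the sign map (default 0.05).
#' @return A list with `table` (data.frame) and `sign_map` (data.frame of
#'   determinant x (intensity, window) entries `+`, `-` or `""`).
#' @export
render_results <- function(results, alpha = 0.05) {
  rows <- lapply(results, function(r) {
    le <- r$logistic_effect
    ce <- r$count_effect
    data.frame(
      cell_id = r$cell_id, determinant = r$determinant,
      intensity = r$intensity, window = r$window,
      n = r$n_logistic, n_positive = r$n_count,
      or = if (!is.null(le)) sprintf("%.2f (%.2f-%.2f)", le$point,
                                     le$ci_low, le$ci_high) else NA,
      or_p = if (!is.null(le)) format_p(le$p) else NA,
      or_p_raw = if (!is.null(le)) le$p else NA_real_,
      count_family = if (!is.null(r$count_family)) r$count_family else NA,
      expb = if (!is.null(ce)) sprintf("%.2f (%.2f-%.2f)", ce$point,
                                       ce$ci_low, ce$ci_high) else NA,
      expb_p = if (!is.null(ce)) format_p(ce$p) else NA,
      expb_p_raw = if (!is.null(ce)) ce$p else NA_real_,
      n_warnings = length(r$warnings)
    )
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  tab$or_p_bh <- stats::p.adjust(tab$or_p_raw, method = "BH")
  tab$expb_p_bh <- stats::p.adjust(tab$expb_p_raw, method = "BH")

  sign_of <- function(r) {
    e <- r$logistic_effect
    if (is.null(e) || is.na(e$p) || e$p >= alpha) return("")
    if (e$point > 1) "+" else "-"
  }
  dets <- unique(vapply(results, `[[`, "", "determinant"))
  cols <- unique(vapply(results, function(r) {
    paste0(r$intensity, "_", r$window)
  }, ""))
  sm <- matrix("", nrow = length(dets), ncol = length(cols),
               dimnames = list(dets, cols))
  for (r in results) {
    sm[r$determinant, paste0(r$intensity, "_", r$window)] <- sign_of(r)
  }
  list(table = tab, sign_map = as.data.frame(sm))
}

#' Descriptive summary of the momentary items
#'
#' Mean (SD), median and quartiles per item, in the shape used for EMA
#' item descriptives.
#'
#' @param dataset Output of [build_dataset()] (or any data.frame holding
#'   the item columns).
#' @param items Item column names (default the 7 momentary items).
#' @return data.frame with one row per item.
#' @export
item_descriptives <- function(dataset,
                              items = c("relax", "satisf", "irrit", "down",
                                        "fatigue", "intention", "selfeff")) {
  rows <- lapply(items, function(it) {
    v <- dataset[[it]]
    v <- v[!is.na(v)]
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
    data.frame(item = it, mean = round(mean(v), 1),
               sd = round(stats::sd(v), 1), median = round(q[2], 1),
               q1 = round(q[1], 1), q3 = round(q[3], 1), n = length(v))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
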