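#' Fit a calibration curve with data-driven weighting selection
#'
#' Weighted least squares of the response ratio on nominal concentration
#' for each candidate weighting (`1`, `1/x`, `1/x^2`), i.e. for the
#' variance models `Var(ratio)` constant, proportional to `x`, and
#' proportional to `x^2` (constant CV). The retained weighting maximizes
#' the profile likelihood of its variance model,
#' `-n/2 * log(sum(w * resid^2) / n) + sum(log(w)) / 2`, which is the
#' proper way to compare residual sums of squares across weightings: the
#' raw weighted RSS values live on different scales, and the summed
#' squared relative back-calculation error is (up to a slope factor) the
#' `1/x^2` fit's own objective, so neither responds to the actual noise
#' structure of the data. Ties (e.g. exact data) break toward the simpler
#' weighting in the order `1`, `1/x`, `1/x^2`. The selected fit is then
#' passed through [accept_calibration_levels()].
#'
#' @param data A data frame with numeric columns `nominal` (ug/mL, > 0)
#'   and `ratio` (light/heavy response ratio). At least 6 levels.
#' @param candidate_weights Subset of `c("1", "1/x", "1/x^2")`.
#' @param peptide_id Optional label stored on the curve.
#' @param lloq_level Level treated as the lowest standard for the wider
#'   acceptance band; defaults to the smallest nominal.
#' @param selection `"likelihood"` (default, profile likelihood of the
#'   variance model), `"loo"` (leave-one-out summed squared relative
#'   back-calculation error) or `"insample"` (the same relative error
#'   criterion on the full fit, kept for comparison).
#' @return An object of class `"calibration_curve"`: selected `weighting`,
#'   `slope`, `intercept`, `r2` (on the selected weighted fit), per-level
#'   back-calculation table, acceptance flags and `curve_valid`. Use
#'   [tidy()] for the per-level table, [glance()] for the one-row summary,
#'   and [autoplot()] to draw the curve.
#' @examples
#' d <- tibble::tibble(nominal = default_calibration_levels(),
#'                     ratio = 0.01 * nominal)
#' glance(fit_calibration(d))
#' @export
fit_calibration <- function(data, candidate_weights = c("1", "1/x", "1/x^2"),
                            peptide_id = NULL, lloq_level = NULL,
                            selection = c("likelihood", "loo", "insample")) {
  selection <- match.arg(selection)
  assert_cols(data, c("nominal", "ratio"), "calibration data")
  data <- as_tibble(data[, c("nominal", "ratio")])
  if (nrow(data) < 6L) abort("calibration requires at least 6 levels")
  if (any(data$nominal <= 0)) abort("nominal concentrations must be > 0")
  if (length(unique(data$nominal)) < 2L) {
    abort("degenerate calibration: all nominal concentrations are equal")
  }
  candidate_weights <- match.arg(candidate_weights, several.ok = TRUE)

  x <- data$nominal
  y <- data$ratio
  wts_for <- function(w) switch(w, "1" = rep(1, length(x)),
                                "1/x" = 1 / x, "1/x^2" = 1 / x^2)
  fit_line <- function(xs, ys, ws) {
    fit <- lm(ys ~ xs, weights = ws)
    unname(coef(fit))
  }

  crit <- vapply(candidate_weights, function(w) {
    ws <- wts_for(w)
    if (selection == "likelihood") {
      fit <- lm(y ~ x, weights = ws)
      s2 <- mean(ws * stats::resid(fit)^2)
      if (s2 <= 0) return(-Inf)
      # negated log-likelihood so every selection rule minimizes
      -(-length(x) / 2 * log(s2) + sum(log(ws)) / 2)
    } else if (selection == "loo") {
      err2 <- vapply(seq_along(x), function(i) {
        cf <- fit_line(x[-i], y[-i], ws[-i])
        if (!is.finite(cf[2]) || cf[2] == 0) return(Inf)
        bc <- (y[i] - cf[1]) / cf[2]
        ((bc - x[i]) / x[i])^2
      }, numeric(1))
      sum(err2)
    } else {
      cf <- fit_line(x, y, ws)
      if (!is.finite(cf[2]) || cf[2] == 0) return(Inf)
      bc <- (y - cf[1]) / cf[2]
      sum(((bc - x) / x)^2)
    }
  }, numeric(1))
  # Exact data fit every variance model perfectly up to float noise; any
  # comparison is then a tie, broken toward the simpler weighting.
  ols_rss <- sum(stats::resid(lm(y ~ x))^2)
  best <- if (ols_rss <= 1e-20 * sum(y^2)) {
    candidate_weights[1]
  } else {
    tol <- 1e-9 * max(1, abs(min(crit)))
    candidate_weights[which(crit <= min(crit) + tol)[1]]
  }

  ws <- wts_for(best)
  fit <- lm(y ~ x, weights = ws)
  cf <- unname(coef(fit))
  # summary.lm warns on essentially perfect fits (noise-free batches);
  # r^2 = 1 is the correct value there
  r2 <- suppressWarnings(summary(fit)$r.squared)

  curve <- structure(list(
    peptide_id = peptide_id %||% NA_character_,
    levels = data,
    weighting = best,
    selection = selection,
    selection_criterion = setNames(as.numeric(crit), candidate_weights),
    slope = cf[2], intercept = cf[1], r2 = r2,
    back_calc = NULL, curve_valid = NA
  ), class = "calibration_curve")
  accept_calibration_levels(curve, lloq_level = lloq_level %||% min(x))
}

#' Apply back-calculation acceptance rules to a fitted curve
#'
#' Each standard is back-calculated through the curve; a level is accepted
#' when its accuracy lies within 85-115% of nominal (80-120% at the lowest
#' standard), boundaries inclusive. The curve is valid when at least 75% of
#' the levels and at least 6 levels are accepted and the slope is positive.
#'
#' @param curve A `"calibration_curve"` from [fit_calibration()].
#' @param lloq_level Nominal concentration of the lowest standard.
#' @return The curve with `back_calc` (per-level tibble) and `curve_valid`
#'   filled in.
#' @export
accept_calibration_levels <- function(curve, lloq_level = NULL) {
  stopifnot(inherits(curve, "calibration_curve"))
  lloq_level <- lloq_level %||% min(curve$levels$nominal)
  nominal <- curve$levels$nominal
  bc <- (curve$levels$ratio - curve$intercept) / curve$slope
  accuracy <- bc / nominal * 100
  is_lloq <- nominal == lloq_level
  lo <- ifelse(is_lloq, 80, 85)
  hi <- ifelse(is_lloq, 120, 115)
  accepted <- is.finite(accuracy) & accuracy >= lo & accuracy <= hi
  curve$back_calc <- tibble(
    nominal = nominal, ratio = curve$levels$ratio, back_calc = bc,
    accuracy_pct = accuracy, is_lloq = is_lloq, accepted = accepted
  )
  curve$lloq_level <- lloq_level
  curve$curve_valid <- mean(accepted) >= 0.75 && sum(accepted) >= 6 &&
    is.finite(curve$slope) && curve$slope > 0
  curve
}

#' Back-calculate concentrations from response ratios
#'
#' Inverse regression through a valid calibration curve:
#' `(ratio - intercept) / slope`. Negative results are floored at zero and
#' flagged in the `"floored"` attribute.
#'
#' @param curve A valid `"calibration_curve"`.
#' @param ratio Numeric vector of response ratios.
#' @return Concentrations in ug/mL.
#' @export
back_calculate <- function(curve, ratio) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (!isTRUE(curve$curve_valid)) {
    abort("calibration curve is not valid; cannot back-calculate")
  }
  if (curve$slope == 0) abort("calibration slope is zero")
  conc <- (ratio - curve$intercept) / curve$slope
  floored <- is.finite(conc) & conc < 0
  conc[floored] <- 0
  structure(conc, floored = floored)
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("Calibration curve%s: ratio = %.6g + %.6g * conc\n",
              if (is.na(x$peptide_id)) "" else paste0(" [", x$peptide_id, "]"),
              x$intercept, x$slope))
  crit <- switch(x$selection,
                 likelihood = "variance-model likelihood",
                 loo = "leave-one-out back-calculation error",
                 insample = "in-sample back-calculation error")
  cat(sprintf("  weighting %s (selected by %s), r2 = %.5f\n",
              x$weighting, crit, x$r2))
  cat(sprintf("  %d/%d levels accepted; curve %s\n",
              sum(x$back_calc$accepted), nrow(x$back_calc),
              if (isTRUE(x$curve_valid)) "VALID" else "NOT VALID"))
  invisible(x)
}

#' @rdname fit_calibration
#' @param x,object A `"calibration_curve"`.
#' @param ... Unused.
#' @method tidy calibration_curve
#' @export
tidy.calibration_curve <- function(x, ...) x$back_calc

#' @rdname fit_calibration
#' @method glance calibration_curve
#' @export
glance.calibration_curve <- function(x, ...) {
  tibble(
    peptide_id = x$peptide_id, weighting = x$weighting,
    slope = x$slope, intercept = x$intercept, r2 = x$r2,
    n_levels = nrow(x$back_calc), n_accepted = sum(x$back_calc$accepted),
    curve_valid = x$curve_valid
  )
}
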