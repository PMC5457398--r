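#' Precision and accuracy of replicate QC measurements
#'
#' The core EMA battery statistic: precision as the coefficient of
#' variation `CV = sd/mean * 100` (sample sd, n-1) and accuracy as
#' `mean/nominal * 100`. Acceptance limits are CV <= 15% and accuracy
#' within 85-115% of nominal, widened to 20% and 80-120% at the LLOQ;
#' all limits are boundary inclusive.
#'
#' @param measured Numeric vector of measured concentrations (ug/mL),
#'   length >= 2.
#' @param nominal Nominal concentration (> 0).
#' @param is_lloq Apply the wider LLOQ limits?
#' @param scope Label for the battery context (`"intra_day"`,
#'   `"inter_day"`, `"matrix_effect"`, `"stability"`).
#' @return A one-row tibble: `scope`, `level_nominal`, `n`, `mean`, `sd`,
#'   `cv_pct`, `accuracy_pct`, `cv_limit`, `acc_low`, `acc_high`, `pass`.
#' @examples
#' precision_accuracy(c(78.9, 80.1, 80.2), nominal = 90)
#' @export
precision_accuracy <- function(measured, nominal, is_lloq = FALSE,
                               scope = "intra_day") {
  if (length(measured) < 2L) abort("precision requires at least 2 replicates")
  if (nominal <= 0) abort("nominal must be > 0")
  m <- mean(measured)
  s <- sd(measured)
  cv <- if (m == 0) NA_real_ else s / m * 100
  acc <- m / nominal * 100
  cv_limit <- if (is_lloq) 20 else 15
  band <- if (is_lloq) c(80, 120) else c(85, 115)
  pass <- is.finite(cv) && cv <= cv_limit && acc >= band[1] && acc <= band[2]
  tibble(
    scope = scope, level_nominal = nominal, n = length(measured),
    mean = m, sd = s, cv_pct = cv, accuracy_pct = acc,
    cv_limit = cv_limit, acc_low = band[1], acc_high = band[2], pass = pass
  )
}

# Battery row for a level where fewer than 2 replicates were reported
# (e.g. consensus withheld by the concordance gate): precision cannot be
# demonstrated, so the level fails rather than erroring out of a batch.
battery_or_fail <- function(measured, nominal, is_lloq = FALSE,
                            scope = "intra_day") {
  v <- measured[is.finite(measured)]
  if (length(v) >= 2L) {
    return(precision_accuracy(v, nominal, is_lloq = is_lloq, scope = scope))
  }
  cv_limit <- if (is_lloq) 20 else 15
  band <- if (is_lloq) c(80, 120) else c(85, 115)
  tibble(
    scope = scope, level_nominal = nominal, n = length(v),
    mean = if (length(v)) mean(v) else NA_real_, sd = NA_real_,
    cv_pct = NA_real_, accuracy_pct = NA_real_,
    cv_limit = cv_limit, acc_low = band[1], acc_high = band[2], pass = FALSE
  )
}

#' Inter-day precision and accuracy
#'
#' Pools every replicate across days (matching the printed inter-day `n`
#' and common EMA practice, rather than averaging day means) and applies
#' [precision_accuracy()].
#'
#' @param day_table A data frame with columns `day` and `measured`, or a
#'   named list of per-day measurement vectors.
#' @inheritParams precision_accuracy
#' @return A one-row battery tibble with scope `"inter_day"`.
#' @export
inter_day_battery <- function(day_table, nominal, is_lloq = FALSE) {
  if (is.data.frame(day_table)) {
    assert_cols(day_table, c("day", "measured"), "day table")
    days <- split(day_table$measured, day_table$day)
  } else {
    days <- day_table
  }
  if (length(days) < 2L) abort("inter-day battery requires >= 2 days")
  precision_accuracy(unlist(days, use.names = FALSE), nominal,
                     is_lloq = is_lloq, scope = "inter_day")
}

#' Matrix-effect assessment across plasma lots
#'
#' One LLOQ-level measurement per independent plasma lot; the design
#' requires at least six lots. LLOQ limits apply (CV <= 20%, accuracy
#' 80-120%).
#'
#' @param lot_values Numeric vector of measured concentrations, one per
#'   lot (named or not).
#' @param nominal Nominal (LLOQ) concentration.
#' @return A one-row battery tibble with scope `"matrix_effect"`.
#' @export
assess_matrix_effect <- function(lot_values, nominal) {
  if (length(lot_values) < 6L) {
    abort("matrix effect assessment requires at least 6 plasma lots")
  }
  precision_accuracy(lot_values, nominal, is_lloq = TRUE,
                     scope = "matrix_effect")
}

#' Selectivity check against blank interference
#'
#' Passes when the blank-plasma signal at the analyte's retention time is
#' less than 20% of the LLOQ signal.
#'
#' @param blank_peak_area Peak area measured in the blank.
#' @param lloq_peak_area Peak area at the LLOQ (> 0).
#' @return `TRUE`/`FALSE`.
#' @export
assess_selectivity <- function(blank_peak_area, lloq_peak_area) {
  if (lloq_peak_area <= 0) abort("LLOQ peak area must be > 0")
  blank_peak_area < 0.20 * lloq_peak_area
}

#' LLOQ qualification
#'
#' The lower limit of quantification is the lowest level determined with
#' accuracy 80-120% and CV at or below 20%.
#'
#' @param candidate_result A one-row battery tibble for the candidate
#'   level (from [precision_accuracy()] and friends).
#' @return `TRUE` when the level qualifies as LLOQ.
#' @export
qualify_lloq <- function(candidate_result) {
  cv <- candidate_result$cv_pct[[1]]
  acc <- candidate_result$accuracy_pct[[1]]
  is.finite(cv) && cv <= 20 && acc >= 80 && acc <= 120
}

#' Stability assessment
#'
#' Accuracy and precision of stored QC samples (e.g. 4 weeks at -80 degC
#' or 2 h at room temperature), at the standard non-LLOQ limits.
#'
#' @param stored Measured concentrations after storage (>= 3 replicates).
#' @param nominal Nominal concentration.
#' @return A one-row battery tibble with scope `"stability"`.
#' @export
assess_stability <- function(stored, nominal) {
  if (length(stored) < 3L) abort("stability requires at least 3 replicates")
  precision_accuracy(stored, nominal, is_lloq = FALSE, scope = "stability")
}

#' Recovery of a sample-preparation stage
#'
#' Recovery of a stage (trypsin digestion, SPE extraction, ionization) as
#' the ratio of mean peak-area responses measured after versus before the
#' stage, in percent; the CV is computed over the paired per-replicate
#' ratios.
#'
#' @param areas_before,areas_after Paired response vectors (>= 3
#'   replicates each).
#' @param peptide_id,stage Labels stored on the result.
#' @return A one-row tibble: `peptide_id`, `stage`, `recovery_pct`,
#'   `cv_pct`, `n`.
#' @export
stage_recovery <- function(areas_before, areas_after,
                           peptide_id = NA_character_, stage = "stage") {
  if (length(areas_before) != length(areas_after)) {
    abort("before/after recovery measurements must be paired")
  }
  if (length(areas_before) < 3L) abort("recovery requires >= 3 replicates")
  if (mean(areas_before) == 0) abort("mean of before-stage responses is zero")
  ratios <- areas_after / areas_before
  tibble(
    peptide_id = peptide_id, stage = stage,
    recovery_pct = mean(areas_after) / mean(areas_before) * 100,
    cv_pct = cv_pct(ratios), n = length(ratios)
  )
}

#' Total recovery across preparation stages
#'
#' Product of the digestion, SPE and ionization stage recoveries. The CV
#' of the product is approximated by the root sum of squares of the stage
#' CVs (first-order delta method for a product of independent stages).
#'
#' @param stages A tibble of stage results ([stage_recovery()]) containing
#'   exactly the stages `digestion`, `spe` and `ionization` for one
#'   peptide.
#' @return A one-row tibble with `stage = "total"`.
#' @export
total_recovery <- function(stages) {
  needed <- c("digestion", "spe", "ionization")
  missing <- setdiff(needed, stages$stage)
  if (length(missing)) {
    abort(sprintf("missing stage recovery for: %s",
                  paste(missing, collapse = ", ")))
  }
  rows <- stages[match(needed, stages$stage), ]
  tibble(
    peptide_id = rows$peptide_id[1], stage = "total",
    recovery_pct = prod(rows$recovery_pct / 100) * 100,
    cv_pct = sqrt(sum(rows$cv_pct^2)),
    n = min(rows$n)
  )
}

#' Linearity summary over validation runs
#'
#' Mean and standard deviation of the regression coefficient (r^2) across
#' repeated calibration runs.
#'
#' @param curves A list of `"calibration_curve"` objects (>= 2).
#' @return A one-row tibble: `n_curves`, `mean_r2`, `sd_r2`.
#' @export
assess_linearity <- function(curves) {
  if (length(curves) < 2L) abort("linearity summary requires >= 2 curves")
  r2 <- vapply(curves, function(cv) cv$r2, numeric(1))
  tibble(n_curves = length(r2), mean_r2 = mean(r2), sd_r2 = sd(r2))
}
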