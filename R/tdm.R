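#' Exposure summary statistics
#'
#' Sample mean, SD, CV%, and range of a cohort's trough (Cmin) or peak
#' (Cmax) concentrations.
#'
#' @param cohort A cohort tibble with columns `cmin`, `cmax` (ug/mL) and
#'   `outcome`.
#' @param which `"cmin"` or `"cmax"`.
#' @return A one-row tibble: `which`, `n`, `mean`, `sd`, `cv_pct`, `min`,
#'   `max`.
#' @export
summarize_exposure <- function(cohort, which = c("cmin", "cmax")) {
  which <- match.arg(which)
  x <- cohort[[which]]
  if (length(x) < 2L) abort("exposure summary requires n >= 2")
  tibble(which = which, n = length(x), mean = mean(x), sd = sd(x),
         cv_pct = cv_pct(x), min = min(x), max = max(x))
}

#' Compare exposure between outcome groups
#'
#' Two-sided two-sample t-test of the exposure metric between patients
#' with clinical benefit and patients with progressive disease. The
#' default is the pooled-variance Student's test (the "standard t-test" of
#' legacy biostatistics software); set `var_equal = FALSE` for Welch.
#'
#' @inheritParams summarize_exposure
#' @param var_equal Pooled-variance Student's test (default) or Welch.
#' @return A one-row tibble: group means, `t`, `df`, `p_value`.
#' @export
compare_groups_ttest <- function(cohort, which = c("cmin", "cmax"),
                                 var_equal = TRUE) {
  which <- match.arg(which)
  x <- cohort[[which]][cohort$outcome == "clinical_benefit"]
  y <- cohort[[which]][cohort$outcome == "progressive_disease"]
  if (length(x) < 2L || length(y) < 2L) {
    abort("both outcome groups need >= 2 patients")
  }
  tt <- t.test(x, y, var.equal = var_equal)
  tibble(
    which = which,
    mean_benefit = mean(x), mean_progressive = mean(y),
    t = unname(tt$statistic), df = unname(tt$parameter),
    p_value = tt$p.value
  )
}

#' Empirical ROC analysis and threshold discovery
#'
#' Builds the empirical ROC curve of the exposure metric as a classifier
#' of clinical benefit, with the convention `exposure >= threshold`
#' predicts benefit. Candidate thresholds are the observed exposure values;
#' sensitivity is the fraction of benefit patients at or above the
#' threshold and specificity the fraction of progressive patients below
#' it. The operating threshold maximizes the Youden index
#' `J = sensitivity + specificity - 1`, ties broken toward the lower
#' threshold; the AUC is the trapezoidal area under the empirical curve
#' (equal to the Mann-Whitney U statistic over `n1 * n2` on tie-free
#' data).
#'
#' @inheritParams summarize_exposure
#' @return An object of class `"tdm_roc"` with the optimal `threshold`
#'   (ug/mL), `sensitivity_pct`, `specificity_pct`, `auc`, the full
#'   `roc_points` table, and the low/high group sizes at the threshold.
#'   [tidy()] returns the ROC points, [glance()] the one-row summary,
#'   [autoplot()] the curve.
#' @export
roc_analysis <- function(cohort, which = c("cmin", "cmax")) {
  which <- match.arg(which)
  x <- cohort[[which]]
  pos <- cohort$outcome == "clinical_benefit"
  if (!any(pos) || all(pos)) {
    abort("ROC analysis needs both outcome classes present")
  }
  cuts <- sort(unique(x))
  sens <- vapply(cuts, function(th) mean(x[pos] >= th) * 100, numeric(1))
  spec <- vapply(cuts, function(th) mean(x[!pos] < th) * 100, numeric(1))
  pts <- tibble(
    threshold = c(-Inf, cuts, Inf),
    sensitivity_pct = c(100, sens, 0),
    specificity_pct = c(0, spec, 100)
  ) %>%
    mutate(fpr = 1 - .data$specificity_pct / 100,
           tpr = .data$sensitivity_pct / 100)

  ord <- order(pts$fpr, pts$tpr)
  auc <- trapz(pts$fpr[ord], pts$tpr[ord])

  youden <- sens + spec - 100
  i_best <- which(youden >= max(youden) - 1e-12)[1]  # ties -> lower threshold
  threshold <- cuts[i_best]

  structure(list(
    which = which,
    threshold = threshold,
    sensitivity_pct = sens[i_best],
    specificity_pct = spec[i_best],
    youden = youden[i_best],
    auc = auc,
    roc_points = pts,
    n_low = sum(x < threshold), n_high = sum(x >= threshold),
    n_benefit = sum(pos), n_progressive = sum(!pos)
  ), class = "tdm_roc")
}

#' @export
print.tdm_roc <- function(x, ...) {
  cat(sprintf("ROC analysis of %s (benefit n=%d vs progressive n=%d)\n",
              x$which, x$n_benefit, x$n_progressive))
  cat(sprintf("  AUC %.3f; optimal threshold %.1f ug/mL (sensitivity %.0f%%, specificity %.0f%%)\n",
              x$auc, x$threshold, x$sensitivity_pct, x$specificity_pct))
  cat(sprintf("  %d patients below / %d at or above the threshold\n",
              x$n_low, x$n_high))
  invisible(x)
}

#' @rdname roc_analysis
#' @param x,object A `"tdm_roc"`.
#' @param ... Unused.
#' @method tidy tdm_roc
#' @export
tidy.tdm_roc <- function(x, ...) x$roc_points

#' @rdname roc_analysis
#' @method glance tdm_roc
#' @export
glance.tdm_roc <- function(x, ...) {
  tibble(
    which = x$which, auc = x$auc, threshold = x$threshold,
    sensitivity_pct = x$sensitivity_pct, specificity_pct = x$specificity_pct,
    youden = x$youden, n_low = x$n_low, n_high = x$n_high,
    n_benefit = x$n_benefit, n_progressive = x$n_progressive
  )
}

#' Classify patients against an exposure threshold
#'
#' Splits the cohort into a low-exposure group (`exposure < threshold`)
#' and a high-exposure group (`exposure >= threshold`; patients exactly at
#' the threshold count as high).
#'
#' @inheritParams summarize_exposure
#' @param threshold Exposure threshold (ug/mL).
#' @return A list: `n_low`, `n_high`, `pct_low`, `pct_high`, and
#'   `patients`, the cohort tibble with an added `exposure_group` column.
#' @export
classify_threshold <- function(cohort, threshold, which = c("cmin", "cmax")) {
  which <- match.arg(which)
  x <- cohort[[which]]
  grp <- ifelse(x >= threshold, "high", "low")
  patients <- mutate(cohort, exposure_group = grp)
  n <- length(x)
  list(
    n_low = sum(grp == "low"), n_high = sum(grp == "high"),
    pct_low = sum(grp == "low") / n * 100,
    pct_high = sum(grp == "high") / n * 100,
    patients = patients
  )
}

#' Exact 2x2 association test
#'
#' Two-sided Fisher exact test of a 2x2 contingency table: the p-value
#' sums the noncentral-hypergeometric probabilities of all tables (with
#' margins fixed) no more probable than the observed one; the odds ratio
#' is the conditional maximum-likelihood estimate with its exact 95%
#' confidence interval from inverting the test.
#'
#' @param table A 2x2 matrix (or object coercible to one) of non-negative
#'   counts with positive margins. Rows are exposure groups, columns
#'   outcome classes.
#' All quantities are computed directly on the conditional (noncentral
#' hypergeometric) distribution of the top-left cell given the margins, so
#' the odds-ratio estimate is solved to full numeric precision (the
#' general-purpose optimizer behind [stats::fisher.test()] stops around
#' 1e-5 relative).
#'
#' @param table A 2x2 matrix (or object coercible to one) of non-negative
#'   counts with positive margins. Rows are exposure groups, columns
#'   outcome classes.
#' @param conf_level Confidence level of the exact interval.
#' @return A one-row tibble: `odds_ratio` (conditional MLE), `ci_low`,
#'   `ci_high`, `p_value`.
#' @examples
#' exact_association(matrix(c(13, 3, 2, 7), nrow = 2))
#' @export
exact_association <- function(table, conf_level = 0.95) {
  m <- round(as.matrix(table))
  if (!all(dim(m) == c(2L, 2L))) abort("table must be 2x2")
  if (any(m < 0)) abort("counts must be non-negative")
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    abort("all margins of the 2x2 table must be positive")
  }
  a <- m[1, 1]
  r1 <- sum(m[1, ]); r2 <- sum(m[2, ]); c1 <- sum(m[, 1])
  kk <- seq.int(max(0, c1 - r2), min(r1, c1))
  lw <- lchoose(r1, kk) + lchoose(r2, c1 - kk)
  # conditional distribution of the top-left cell at log-odds-ratio lpsi
  cond <- function(lpsi) {
    l <- lw + kk * lpsi
    w <- exp(l - max(l))
    w / sum(w)
  }

  # two-sided p at psi = 1: sum of tables no more probable than observed
  # (relative tolerance absorbs float ties between equal probabilities)
  pr <- cond(0)
  p <- min(1, sum(pr[pr <= pr[kk == a] * (1 + 1e-7)]))

  or <- if (a <= min(kk) && a >= max(kk)) {
    NaN  # single support point: OR not identifiable
  } else if (a <= min(kk)) 0 else if (a >= max(kk)) Inf else {
    exp(stats::uniroot(function(lpsi) sum(kk * cond(lpsi)) - a,
                       c(-75, 75), tol = 1e-12)$root)
  }

  alpha <- (1 - conf_level) / 2
  ci_low <- if (a <= min(kk)) 0 else {
    exp(stats::uniroot(function(lpsi) sum(cond(lpsi)[kk >= a]) - alpha,
                       c(-75, 75), tol = 1e-10)$root)
  }
  ci_high <- if (a >= max(kk)) Inf else {
    exp(stats::uniroot(function(lpsi) sum(cond(lpsi)[kk <= a]) - alpha,
                       c(-75, 75), tol = 1e-10)$root)
  }

  tibble(odds_ratio = or, ci_low = ci_low, ci_high = ci_high, p_value = p)
}

#' Full exposure-response analysis of a cohort
#'
#' Convenience wrapper running, for the chosen exposure metric: the group
#' summaries and pooled summary, the Student t-test between outcome
#' groups, ROC threshold discovery, threshold classification, and the
#' exact 2x2 association between exposure group and outcome.
#'
#' @inheritParams summarize_exposure
#' @param threshold Optional fixed threshold; defaults to the ROC-optimal
#'   one.
#' @return A list of class `"tdm_analysis"`: `summary`, `by_group`,
#'   `t_test`, `roc` (a `"tdm_roc"`), `classification`, `table` (2x2
#'   counts, exposure group x outcome), `association`.
#' @export
tdm_analysis <- function(cohort, which = c("cmin", "cmax"), threshold = NULL) {
  which <- match.arg(which)
  roc <- roc_analysis(cohort, which)
  threshold <- threshold %||% roc$threshold
  cls <- classify_threshold(cohort, threshold, which)
  tab <- table(
    factor(cls$patients$exposure_group, levels = c("high", "low")),
    factor(cls$patients$outcome,
           levels = c("clinical_benefit", "progressive_disease"))
  )
  by_group <- cohort %>%
    group_by(.data$outcome) %>%
    summarise(n = dplyr::n(), mean = mean(.data[[which]]),
              sd = sd(.data[[which]]), .groups = "drop")
  structure(list(
    which = which,
    summary = summarize_exposure(cohort, which),
    by_group = by_group,
    t_test = compare_groups_ttest(cohort, which),
    roc = roc,
    threshold = threshold,
    classification = cls[c("n_low", "n_high", "pct_low", "pct_high")],
    table = unclass(tab),
    association = if (all(rowSums(tab) > 0) && all(colSums(tab) > 0)) {
      exact_association(tab)
    }  # a zero margin leaves the exact test undefined
  ), class = "tdm_analysis")
}

#' @export
print.tdm_analysis <- function(x, ...) {
  s <- x$summary
  cat(sprintf("Exposure-response analysis of %s (n = %d)\n", x$which, s$n))
  cat(sprintf("  pooled %.1f +/- %.1f ug/mL (CV %.0f%%, range %.1f-%.1f)\n",
              s$mean, s$sd, s$cv_pct, s$min, s$max))
  tt <- x$t_test
  cat(sprintf("  benefit %.1f vs progressive %.1f ug/mL, t = %.2f, p = %.4g\n",
              tt$mean_benefit, tt$mean_progressive, tt$t, tt$p_value))
  print(x$roc)
  a <- x$association
  cat(sprintf("  exact association at threshold %.1f: OR %.2f (95%% CI %.2f-%.2f), p = %.4g\n",
              x$threshold, a$odds_ratio, a$ci_low, a$ci_high, a$p_value))
  invisible(x)
}
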