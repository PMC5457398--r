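# Shared fixtures and independent oracles, built in code at test time.

# A single Gaussian peak on a flat baseline, parameterized by apex HEIGHT
# (closed-form area = height * sigma * sqrt(2*pi)).
gaussian_chrom <- function(height = 1000, center = 8.8, sigma = 0.05,
                           from = center - 0.5, to = center + 0.5,
                           by = 0.005, baseline = 0) {
  t <- seq(from, to, by = by)
  tibble::tibble(time = t,
                 intensity = baseline + height * exp(-(t - center)^2 / (2 * sigma^2)))
}

# Brute-force Fisher oracle: enumerate every table with the observed
# margins, with probabilities built from log-gamma factorials (independent
# of the package's code path). Returns the two-sided p and the
# conditional-MLE odds ratio (score equation solved on the enumerated
# distribution).
fisher_oracle <- function(m) {
  a <- m[1, 1]
  r1 <- sum(m[1, ]); r2 <- sum(m[2, ]); c1 <- sum(m[, 1])
  kk <- seq.int(max(0, c1 - r2), min(r1, c1))
  lfac <- function(x) lgamma(x + 1)
  lw <- (lfac(r1) - lfac(kk) - lfac(r1 - kk)) +
    (lfac(r2) - lfac(c1 - kk) - lfac(r2 - c1 + kk))
  pr <- exp(lw - max(lw))
  pr <- pr / sum(pr)
  p <- min(1, sum(pr[pr <= pr[kk == a] * (1 + 1e-7)]))
  or <- if (a <= min(kk)) 0 else if (a >= max(kk)) Inf else {
    score <- function(lpsi) {
      w <- exp(lw + kk * lpsi - max(lw + kk * lpsi))
      sum(kk * w) / sum(w) - a
    }
    exp(stats::uniroot(score, c(-60, 60), tol = 1e-13)$root)
  }
  list(p = p, or = or)
}

# Every 2x2 table of total n with all-positive margins.
all_tables_of_total <- function(n) {
  out <- list()
  for (a in 0:n) for (b in 0:(n - a)) for (cc in 0:(n - a - b)) {
    d <- n - a - b - cc
    m <- matrix(c(a, cc, b, d), 2, 2)
    if (all(rowSums(m) > 0) && all(colSums(m) > 0)) out[[length(out) + 1]] <- m
  }
  out
}

# Fabricated peptide measurement row with a clean transition-ratio
# template, for exercising the consensus logic directly.
fake_measurement <- function(sample_id, peptide_id, ratio, rt = 5,
                             heavy_area = 1000, qfrac = c(0.6, 0.4)) {
  tibble::tibble(
    sample_id = sample_id, peptide_id = peptide_id,
    light_quantifier_area = ratio * heavy_area,
    heavy_quantifier_area = heavy_area,
    light_rt = rt, heavy_rt = rt, response_ratio = ratio,
    qualifiers = list(tibble::tibble(
      product_mz = c(700, 750), product_label = c("q1", "q2"),
      light_area = ratio * heavy_area * qfrac,
      heavy_area = heavy_area * qfrac
    )),
    coelution_ok = TRUE, transition_ratio_ok = TRUE, qc_flags = ""
  )
}

# Exact calibration curve with known slope/intercept (noise-free levels).
exact_curve <- function(slope = 0.01, intercept = 0,
                        levels = default_calibration_levels(),
                        peptide_id = NULL) {
  fit_calibration(tibble::tibble(nominal = levels,
                                 ratio = intercept + slope * levels),
                  peptide_id = peptide_id)
}

# One complete simulated quantification run at the study conditions:
# calibration batch, one spiked sample, intra-day QC design.
simulate_quant_run <- function(seed, spike_conc = 100, noise_cv = 0.05) {
  cfg <- sim_config(seed = seed, noise_cv = noise_cv)
  set.seed(seed)
  inner <- cfg
  inner$seed <- NULL
  assay <- cetuximab_assay()
  cal <- simulate_calibration_batch(assay, config = inner)
  smeas <- dplyr::inner_join(measure_peptides(cal$chromatograms),
                             cal$manifest, by = "sample_id")
  curves <- lapply(split(smeas, smeas$peptide_id), function(d) {
    fit_calibration(tibble::tibble(nominal = d$nominal_conc,
                                   ratio = d$response_ratio),
                    peptide_id = d$peptide_id[1])
  })
  if (!all(vapply(curves, function(cv) isTRUE(cv$curve_valid), logical(1)))) {
    # batch rejected: report a failed run rather than erroring
    return(list(curves = curves,
                spike = tibble::tibble(consensus_conc = NA_real_),
                battery = tibble::tibble(pass = FALSE)))
  }
  spike <- srmtdm:::sim_sample_impl(assay, spike_conc, 1000, inner, "SPIKE")
  spike_res <- quantify_samples(measure_peptides(spike), curves)
  qc <- simulate_qc_replicates(assay, n_reps = 6, n_days = 1, config = inner)
  qc_res <- dplyr::inner_join(quantify_samples(measure_peptides(qc$chromatograms),
                                               curves),
                              qc$manifest, by = "sample_id")
  battery <- purrr::map_dfr(sort(unique(qc_res$nominal_conc)), function(lev) {
    v <- qc_res$consensus_conc[qc_res$nominal_conc == lev]
    srmtdm:::battery_or_fail(v, lev, is_lloq = lev <= 1)
  })
  list(curves = curves, spike = spike_res, battery = battery)
}
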