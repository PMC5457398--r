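#' Simulation configuration for synthetic SRM chromatograms
#'
#' Collects the physical and statistical knobs of the chromatogram
#' generator. Peaks are Gaussian on a flat baseline (symmetric UPLC peaks;
#' the closed-form area `height * sigma * sqrt(2*pi)` makes every
#' integration testable), sampled at ~15 points per peak. The light-channel
#' quantifier area is `true_conc * response_factor * prod(stage_recoveries)`
#' and carries the assay imprecision; heavy (SIL) areas are fixed by the
#' spiked internal-standard amount, so `noise_cv` is the CV of the
#' light/heavy response ratio. Qualifier areas are fixed fractions of the
#' quantifier on both channels, giving an exact transition-ratio template.
#'
#' @param seed Integer seed; `NULL` leaves the RNG state untouched.
#' @param peak_sigma Gaussian peak width (minutes).
#' @param sampling_interval Time between acquisition points (minutes); must
#'   be smaller than `peak_sigma`.
#' @param response_factor Named per-peptide response (ratio units per
#'   ug/mL) of the light quantifier before recovery losses.
#' @param stage_recoveries Named list, one numeric vector per peptide with
#'   `digestion`, `spe` and `ionization` fractional recoveries (each in
#'   (0, 1.2]). Defaults are the measured plasma recoveries of the two
#'   cetuximab peptides.
#' @param noise_cv CV of the multiplicative area noise (fraction);
#'   point-level trace noise has sd `noise_cv * baseline_level`, so
#'   `noise_cv = 0` is an exactly noise-free limit.
#' @param noise_model `"proportional"` (CV-constant, the default for
#'   stable-isotope-dilution data) or `"constant"` (additive area noise of
#'   fixed sd, exercising calibration weighting selection).
#' @param constant_noise_ref Concentration (ug/mL) whose signal sets the
#'   absolute noise sd in the `"constant"` model:
#'   `sd = noise_cv * response_factor * recovery * constant_noise_ref`.
#' @param baseline_level Flat baseline intensity (counts).
#' @param rt_jitter_sd Per-sample, per-peptide retention-time jitter sd
#'   (minutes); light and heavy share one jittered apex.
#' @param interference_probability Probability that a light transition
#'   carries a small interfering peak offset from the analyte.
#' @param day_effect_sd SD of the multiplicative between-day effect applied
#'   to light areas when a batch spans several days.
#' @param qualifier_fractions Areas of the two qualifier transitions as
#'   fractions of the quantifier area.
#' @param window_halfwidth Half-width (minutes) of the scheduled acquisition
#'   window simulated around each peptide's expected retention time.
#' @return A validated list of class `"sim_config"`.
#' @export
sim_config <- function(seed = NULL,
                       peak_sigma = 0.05,
                       sampling_interval = 0.005,
                       response_factor = c(HT4 = 500, LT3 = 500),
                       stage_recoveries = list(
                         HT4 = c(digestion = 0.895, spe = 0.481, ionization = 0.508),
                         LT3 = c(digestion = 1.033, spe = 0.636, ionization = 0.479)
                       ),
                       noise_cv = 0.05,
                       noise_model = c("proportional", "constant"),
                       constant_noise_ref = 31.62,
                       baseline_level = 20,
                       rt_jitter_sd = 0.02,
                       interference_probability = 0,
                       day_effect_sd = 0.05,
                       qualifier_fractions = c(0.65, 0.40),
                       window_halfwidth = 0.5) {
  cfg <- list(
    seed = seed, peak_sigma = peak_sigma,
    sampling_interval = sampling_interval,
    response_factor = response_factor, stage_recoveries = stage_recoveries,
    noise_cv = noise_cv, noise_model = match.arg(noise_model),
    constant_noise_ref = constant_noise_ref,
    baseline_level = baseline_level, rt_jitter_sd = rt_jitter_sd,
    interference_probability = interference_probability,
    day_effect_sd = day_effect_sd,
    qualifier_fractions = qualifier_fractions,
    window_halfwidth = window_halfwidth
  )
  if (peak_sigma <= 0) abort("configuration error: peak_sigma must be > 0")
  if (sampling_interval <= 0 || sampling_interval >= peak_sigma) {
    abort("configuration error: sampling_interval must lie in (0, peak_sigma)")
  }
  recs <- unlist(stage_recoveries)
  if (any(recs <= 0 | recs > 1.2)) {
    abort("configuration error: stage recoveries must lie in (0, 1.2]")
  }
  if (noise_cv < 0) abort("configuration error: noise_cv must be >= 0")
  if (rt_jitter_sd < 0) abort("configuration error: rt_jitter_sd must be >= 0")
  structure(cfg, class = "sim_config")
}

#' Default 9-level calibration design
#'
#' Nine geometrically spaced concentrations spanning 1 to 1000 ug/mL, the
#' calibration range of the assay. Geometric spacing over the three-decade
#' range is a generator default, not a measured design.
#'
#' @return Numeric vector of nominal concentrations (ug/mL).
#' @export
default_calibration_levels <- function() {
  exp(seq(log(1), log(1000), length.out = 9))
}

total_recovery_fraction <- function(config, peptide_id) {
  prod(config$stage_recoveries[[peptide_id]])
}

# Gaussian trace on a flat baseline with optional point noise.
sim_trace <- function(times, rt, area, sigma, baseline, point_sd) {
  y <- baseline + area * dnorm(times, rt, sigma)
  if (point_sd > 0) y <- y + rnorm(length(times), 0, point_sd)
  pmax(y, 0)
}

# Core sample generator; never touches the seed so batch generators can
# draw sequentially from one stream.
sim_sample_impl <- function(assay, true_conc, sil_amount, config,
                            sample_id, day_factor = 1) {
  out <- vector("list", length(unique(assay$peptide_id)))
  names(out) <- unique(assay$peptide_id)
  point_sd <- config$noise_cv * config$baseline_level
  for (pid in names(out)) {
    tra <- assay[assay$peptide_id == pid, ]
    rt0 <- tra$expected_rt[1]
    rt <- rt0 + if (config$rt_jitter_sd > 0) rnorm(1, 0, config$rt_jitter_sd) else 0
    times <- seq(rt0 - config$window_halfwidth, rt0 + config$window_halfwidth,
                 by = config$sampling_interval)
    rec <- total_recovery_fraction(config, pid)
    rf <- config$response_factor[[pid]]
    qfrac <- c(1, config$qualifier_fractions)

    # Assay imprecision enters once, on the light quantifier; qualifier
    # areas are fixed fractions of the (noisy) quantifier on both channels,
    # so the transition-ratio template is exact by construction.
    lq0 <- true_conc * rf * rec * day_factor
    lq <- switch(config$noise_model,
      proportional = lq0 * max(0, 1 + rnorm(1, 0, config$noise_cv)),
      constant = max(0, lq0 + rnorm(
        1, 0, config$noise_cv * rf * rec * config$constant_noise_ref))
    )
    if (true_conc == 0) lq <- 0
    light <- lq * qfrac
    heavy <- sil_amount * qfrac

    traces <- vector("list", nrow(tra))
    for (i in seq_len(nrow(tra))) {
      area <- if (tra$channel[i] == "light") light[(i - 1L) %% 3L + 1L]
              else heavy[(i - 1L) %% 3L + 1L]
      y <- sim_trace(times, rt, area, config$peak_sigma,
                     config$baseline_level, point_sd)
      if (tra$channel[i] == "light" &&
          config$interference_probability > 0 &&
          runif(1) < config$interference_probability) {
        y <- y + 0.25 * sil_amount *
          dnorm(times, rt + 4 * config$peak_sigma, config$peak_sigma)
      }
      np <- length(times)
      traces[[i]] <- fast_tibble(list(
        sample_id = rep(sample_id, np), peptide_id = rep(pid, np),
        channel = rep(tra$channel[i], np),
        product_mz = rep(tra$product_mz[i], np),
        product_label = rep(tra$product_label[i], np),
        is_quantifier = rep(tra$is_quantifier[i], np),
        time = times, intensity = y
      ))
    }
    out[[pid]] <- bind_rows(traces)
  }
  bind_rows(out)
}

#' Simulate the SRM chromatograms of one plasma sample
#'
#' Generates one time-intensity trace per assay transition. Light and heavy
#' channels of a peptide share a single jittered apex (the SIL internal
#' standard co-elutes); the light quantifier area equals
#' `true_conc * response_factor * prod(stage_recoveries) * (1 + noise)`,
#' heavy areas are fixed by `sil_amount`, and qualifier areas follow the
#' configured quantifier fractions on both channels. A blank
#' (`true_conc = 0`) yields baseline and noise only.
#'
#' @param assay Assay tibble ([cetuximab_assay()]).
#' @param true_conc True cetuximab concentration (ug/mL, >= 0).
#' @param sil_amount Heavy quantifier peak area produced by the SIL spike
#'   (arbitrary area units).
#' @param config A [sim_config()]; its `seed` (if any) is set on entry.
#' @param sample_id Sample identifier stored in the output.
#' @return A long tibble: `sample_id`, `peptide_id`, `channel`,
#'   `product_mz`, `product_label`, `is_quantifier`, `time`, `intensity`.
#' @export
simulate_sample_chromatograms <- function(assay, true_conc, sil_amount = 1000,
                                          config = sim_config(),
                                          sample_id = "S1") {
  if (!inherits(config, "sim_config")) abort("configuration error: not a sim_config")
  if (true_conc < 0) abort("true_conc must be >= 0")
  if (!is.null(config$seed)) set.seed(config$seed)
  sim_sample_impl(assay, true_conc, sil_amount, config, sample_id)
}

#' Simulate a calibration batch
#'
#' One standard per level, labelled in the manifest with its nominal
#' concentration. The default design is the assay's 9-level curve spanning
#' 1 to 1000 ug/mL.
#'
#' @inheritParams simulate_sample_chromatograms
#' @param levels Strictly increasing nominal concentrations (>= 2).
#' @return A list with `manifest` (sample_id, role, nominal_conc, day) and
#'   `chromatograms` (long tibble over all standards).
#' @export
simulate_calibration_batch <- function(assay,
                                       levels = default_calibration_levels(),
                                       config = sim_config(),
                                       sil_amount = 1000) {
  if (length(levels) < 2L) abort("at least 2 calibration levels are required")
  if (any(diff(levels) <= 0)) abort("calibration levels must be strictly increasing")
  if (!is.null(config$seed)) set.seed(config$seed)
  ids <- sprintf("STD%02d", seq_along(levels))
  chroms <- purrr::map2(ids, levels, function(id, conc) {
    sim_sample_impl(assay, conc, sil_amount, config, id)
  })
  list(
    manifest = tibble(sample_id = ids, role = "standard",
                      nominal_conc = levels, day = 1L),
    chromatograms = bind_rows(chroms)
  )
}

#' Simulate a QC precision/accuracy design
#'
#' Replicated QC samples at each level, optionally across several days with
#' a multiplicative day random effect on the light-channel response (sd
#' `day_effect_sd`), emulating between-run drifts of digestion and
#' extraction. The default design is the validation protocol of the assay:
#' the four QC levels (1, 1.8, 90 and 175 ug/mL) assayed six times on each
#' of three days.
#'
#' @inheritParams simulate_sample_chromatograms
#' @param qc_levels Nominal QC concentrations (ug/mL).
#' @param n_reps Replicates per level per day (>= 2).
#' @param n_days Number of days; `1` gives the intra-day design.
#' @return A list with `manifest` (sample_id, role, nominal_conc, day, rep)
#'   and `chromatograms`.
#' @export
simulate_qc_replicates <- function(assay, qc_levels = c(1, 1.8, 90, 175),
                                   n_reps = 6, n_days = 3,
                                   config = sim_config(), sil_amount = 1000) {
  if (n_reps < 2L) abort("n_reps must be >= 2")
  if (n_days < 1L) abort("n_days must be >= 1")
  if (!is.null(config$seed)) set.seed(config$seed)
  day_factors <- if (n_days > 1L && config$day_effect_sd > 0) {
    pmax(0.1, rnorm(n_days, 1, config$day_effect_sd))
  } else rep(1, n_days)

  design <- tidyr::expand_grid(day = seq_len(n_days),
                               nominal_conc = qc_levels,
                               rep = seq_len(n_reps)) %>%
    mutate(sample_id = sprintf("QC_d%d_c%g_r%d",
                               .data$day, .data$nominal_conc, .data$rep),
           role = "qc")
  chroms <- purrr::pmap(design, function(day, nominal_conc, rep, sample_id, role) {
    sim_sample_impl(assay, nominal_conc, sil_amount, config, sample_id,
                    day_factor = day_factors[day])
  })
  list(
    manifest = select(design, "sample_id", "role", "nominal_conc",
                      "day", "rep"),
    chromatograms = bind_rows(chroms)
  )
}

#' Simulate calibration response ratios directly
#'
#' Bypasses the chromatogram layer and draws (nominal, ratio) pairs from a
#' straight line with either CV-constant (`"proportional"`: sd of the ratio
#' proportional to concentration) or constant-variance (`"constant"`: fixed
#' absolute sd set by the signal at `constant_noise_ref`) noise. Used to
#' study calibration weighting selection under a known noise structure.
#'
#' @param levels Nominal concentrations (ug/mL).
#' @param slope,intercept True calibration line.
#' @param noise_cv Relative noise (fraction).
#' @param noise_model `"proportional"` or `"constant"`.
#' @param constant_noise_ref Concentration whose response sets the absolute
#'   noise sd in the constant model.
#' @param seed Optional integer seed.
#' @return A tibble with `nominal` and `ratio`.
#' @export
simulate_calibration_ratios <- function(levels = default_calibration_levels(),
                                        slope = 0.01, intercept = 0,
                                        noise_cv = 0.05,
                                        noise_model = c("proportional", "constant"),
                                        constant_noise_ref = 31.62,
                                        seed = NULL) {
  noise_model <- match.arg(noise_model)
  if (!is.null(seed)) set.seed(seed)
  mu <- intercept + slope * levels
  ratio <- switch(noise_model,
    proportional = mu * (1 + rnorm(length(levels), 0, noise_cv)),
    constant = mu + rnorm(length(levels), 0,
                          noise_cv * slope * constant_noise_ref)
  )
  tibble(nominal = levels, ratio = ratio)
}
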