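test_that("simulation is seed-deterministic and seed-sensitive", {
  assay <- cetuximab_assay()
  a <- simulate_sample_chromatograms(assay, 50, config = sim_config(seed = 11))
  b <- simulate_sample_chromatograms(assay, 50, config = sim_config(seed = 11))
  c <- simulate_sample_chromatograms(assay, 50, config = sim_config(seed = 12))
  expect_identical(a, b)
  expect_false(identical(a$intensity, c$intensity))
})

test_that("a blank sample carries baseline and noise only on the light channel", {
  cfg <- sim_config(seed = 3)
  chroms <- simulate_sample_chromatograms(cetuximab_assay(), true_conc = 0,
                                          config = cfg)
  light <- chroms[chroms$channel == "light", ]
  expect_lt(max(light$intensity), cfg$baseline_level + 10 * cfg$noise_cv *
              cfg$baseline_level)
  m <- measure_peptides(chroms)
  expect_true(all(grepl("light_peak_not_found", m$qc_flags)))
})

test_that("the noise-free response ratio equals conc x response x recovery / SIL", {
  cfg <- sim_config(noise_cv = 0, rt_jitter_sd = 0)
  chroms <- simulate_sample_chromatograms(cetuximab_assay(), true_conc = 100,
                                          sil_amount = 1000, config = cfg)
  m <- measure_peptides(chroms)
  for (pid in c("HT4", "LT3")) {
    expected <- 100 * cfg$response_factor[[pid]] *
      prod(cfg$stage_recoveries[[pid]]) / 1000
    expect_equal(m$response_ratio[m$peptide_id == pid], expected,
                 tolerance = 1e-9)
  }
})

test_that("quantifier/qualifier ratios equal the configured template at zero noise", {
  cfg <- sim_config(noise_cv = 0, rt_jitter_sd = 0)
  m <- measure_peptides(simulate_sample_chromatograms(
    cetuximab_assay(), 200, config = cfg))
  for (i in seq_len(nrow(m))) {
    q <- m$qualifiers[[i]]
    expect_equal(q$light_area / m$light_quantifier_area[i],
                 cfg$qualifier_fractions, tolerance = 1e-9)
    expect_equal(q$heavy_area / m$heavy_quantifier_area[i],
                 cfg$qualifier_fractions, tolerance = 1e-9)
  }
})

test_that("an LLOQ-level sample still produces a detectable peak", {
  cfg <- sim_config(seed = 1)
  chroms <- simulate_sample_chromatograms(cetuximab_assay(), true_conc = 1,
                                          config = cfg)
  m <- measure_peptides(chroms)
  expect_true(all(is.finite(m$response_ratio)))
  expect_true(all(m$coelution_ok))
})

test_that("calibration batch follows the 9-level 1-1000 design", {
  assay <- cetuximab_assay()
  cfg <- sim_config(seed = 2)
  cal <- simulate_calibration_batch(assay, config = cfg)
  expect_equal(nrow(cal$manifest), 9L)
  expect_equal(min(cal$manifest$nominal_conc), 1)
  expect_equal(max(cal$manifest$nominal_conc), 1000)

  two <- simulate_calibration_batch(assay, levels = c(1, 10), config = cfg)
  expect_equal(nrow(two$manifest), 2L)

  expect_error(simulate_calibration_batch(assay, levels = numeric(0)),
               "levels")
  expect_error(simulate_calibration_batch(assay, levels = c(10, 5)),
               "increasing")
})

test_that("QC design enumerates levels x replicates x days", {
  assay <- cetuximab_assay()
  cfg <- sim_config(seed = 2)
  full <- simulate_qc_replicates(assay, config = cfg)
  expect_equal(nrow(full$manifest), 4 * 6 * 3)
  expect_setequal(unique(full$manifest$nominal_conc), c(1, 1.8, 90, 175))

  intra <- simulate_qc_replicates(assay, n_days = 1, config = cfg)
  expect_equal(nrow(intra$manifest), 24L)
  expect_error(simulate_qc_replicates(assay, n_reps = 1, config = cfg),
               "n_reps")
})

test_that("configuration invariants are enforced", {
  expect_error(sim_config(peak_sigma = -1), "configuration error")
  expect_error(sim_config(sampling_interval = 0.1), "configuration error")
  expect_error(sim_config(stage_recoveries = list(
    HT4 = c(digestion = 1.5, spe = 0.5, ionization = 0.5),
    LT3 = c(digestion = 1, spe = 0.6, ionization = 0.5))),
    "configuration error")
})

test_that("cohort simulation reproduces the study design", {
  cohort <- simulate_cohort(cohort_sim_config(seed = 7))
  expect_equal(nrow(cohort), 25L)
  expect_equal(sum(cohort$outcome == "clinical_benefit"), 15L)
  expect_equal(sum(cohort$outcome == "progressive_disease"), 10L)
  expect_true(all(cohort$cmin >= 0 & cohort$cmax >= 0))

  degenerate <- simulate_cohort(cohort_sim_config(
    cmin_benefit_sd = 0, cmin_progressive_sd = 0,
    cmax_benefit_sd = 0, cmax_progressive_sd = 0, seed = 1))
  expect_true(all(degenerate$cmin[degenerate$outcome == "clinical_benefit"] == 49.0))
  expect_true(all(degenerate$cmin[degenerate$outcome == "progressive_disease"] == 25.8))
})

test_that("pooled trough mean matches the cohort mixture expectation", {
  pooled <- vapply(1:200, function(s) {
    mean(simulate_cohort(cohort_sim_config(seed = s))$cmin)
  }, numeric(1))
  # mixture expectation (15*49.0 + 10*25.8)/25 = 39.7, nudged up ~1 by the
  # zero-truncation of the progressive group
  expect_lt(abs(mean(pooled) - 40.3), 3)
})
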