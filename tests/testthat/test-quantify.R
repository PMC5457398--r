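make_peak <- function(rt, found = TRUE) {
  tibble::tibble(apex_rt = rt, height = 100, left_bound = rt - 0.1,
                 right_bound = rt + 0.1, baseline = 0, noise = 1,
                 signal_to_noise = 100, found = found, area = 25)
}

test_that("co-elution rule is inclusive at 0.1 min", {
  expect_true(coelution_check(make_peak(8.80), make_peak(8.85)))
  expect_false(coelution_check(make_peak(8.80), make_peak(8.95)))
  expect_true(coelution_check(make_peak(8.80), make_peak(8.90)))  # boundary
  missing <- coelution_check(make_peak(8.8), make_peak(8.8, found = FALSE))
  expect_false(missing)
  expect_match(attr(missing, "reason"), "heavy")
})

test_that("transition-ratio rule is inclusive at +/-25%", {
  base <- fake_measurement("S", "HT4", ratio = 1)
  expect_true(transition_ratio_check(base))

  off <- base
  off$qualifiers[[1]]$light_area[1] <- off$qualifiers[[1]]$light_area[1] * 1.30
  expect_false(transition_ratio_check(off))

  edge <- base
  edge$qualifiers[[1]]$light_area <- edge$qualifiers[[1]]$light_area * 0.75
  expect_true(transition_ratio_check(edge))  # boundary

  zero <- base
  zero$heavy_quantifier_area <- 0
  res <- transition_ratio_check(zero)
  expect_false(res)
  expect_match(attr(res, "reason"), "quantifier")
})

test_that("consensus averages concordant peptides and withholds discordant ones", {
  curves <- list(HT4 = exact_curve(peptide_id = "HT4"),
                 LT3 = exact_curve(peptide_id = "LT3"))

  ok <- quantify_sample(fake_measurement("S1", "HT4", 0.49),
                        fake_measurement("S1", "LT3", 0.51), curves)
  expect_equal(ok$consensus_conc, 50.0)
  expect_equal(ok$concordance_pct, 4.0, tolerance = 1e-9)
  expect_true(ok$valid)

  off <- quantify_sample(fake_measurement("S2", "HT4", 0.40),
                         fake_measurement("S2", "LT3", 0.50), curves)
  expect_equal(off$concordance_pct, 100 * 10 / 45, tolerance = 1e-9)
  expect_true(is.na(off$consensus_conc))
  expect_false(off$valid)
  expect_match(off$qc_flags, "discordance")
})

test_that("concordance is symmetric in the two peptides", {
  curves <- list(HT4 = exact_curve(), LT3 = exact_curve())
  ab <- quantify_sample(fake_measurement("S", "HT4", 0.40),
                        fake_measurement("S", "LT3", 0.50), curves)
  ba <- quantify_sample(fake_measurement("S", "HT4", 0.50),
                        fake_measurement("S", "LT3", 0.40), curves)
  expect_equal(ab$concordance_pct, ba$concordance_pct)
})

test_that("specificity failures and ULOQ overflow withhold the consensus", {
  curves <- list(HT4 = exact_curve(), LT3 = exact_curve())

  bad <- fake_measurement("S", "HT4", 0.49)
  bad$coelution_ok <- FALSE
  res <- quantify_sample(bad, fake_measurement("S", "LT3", 0.51), curves)
  expect_false(res$valid)
  expect_match(res$qc_flags, "specificity")

  high <- quantify_sample(fake_measurement("S", "HT4", 15),
                          fake_measurement("S", "LT3", 15.2), curves)
  expect_true(is.na(high$conc_ht4))
  expect_match(high$qc_flags, "above_uloq")

  expect_error(quantify_sample(fake_measurement("S", "HT4", 1),
                               fake_measurement("S", "LT3", 1),
                               list(HT4 = exact_curve())),
               "missing calibration curve")
})

test_that("response ratios are invariant under a detector gain change", {
  cfg <- sim_config(seed = 5)
  chroms <- simulate_sample_chromatograms(cetuximab_assay(), 80, config = cfg)
  m1 <- measure_peptides(chroms)
  scaled <- chroms
  scaled$intensity <- scaled$intensity * 4.2
  m2 <- measure_peptides(scaled)
  expect_equal(m2$response_ratio, m1$response_ratio, tolerance = 1e-9)
})

test_that("an end-to-end simulated sample recovers its true concentration", {
  cfg0 <- sim_config(noise_cv = 0, rt_jitter_sd = 0)
  assay <- cetuximab_assay()
  cal <- simulate_calibration_batch(assay, config = cfg0)
  meas <- dplyr::inner_join(measure_peptides(cal$chromatograms),
                            cal$manifest, by = "sample_id")
  curves <- lapply(split(meas, meas$peptide_id), function(d) {
    fit_calibration(tibble::tibble(nominal = d$nominal_conc,
                                   ratio = d$response_ratio),
                    peptide_id = d$peptide_id[1])
  })
  sample <- simulate_sample_chromatograms(assay, 100,
                                          config = sim_config(seed = 7))
  res <- quantify_samples(measure_peptides(sample), curves)
  expect_true(res$valid)
  expect_lt(abs(res$consensus_conc - 100) / 100, 0.15)
})
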