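# srmtdm

Targeted LC-MS/MS quantification and therapeutic drug monitoring (TDM) of
the anti-EGFR monoclonal antibody **cetuximab** in plasma.

Cetuximab exposure varies widely between patients, and trough plasma
concentration (Cmin) is a candidate predictor of clinical benefit in
head-and-neck cancer. Monitoring it routinely requires a bioanalytical
pipeline, not just an instrument: peak integration, isotope-dilution
quantification, calibration acceptance, EMA-style validation statistics,
and the statistics that turn measured exposures into a clinical decision
threshold. `srmtdm` implements that pipeline end to end for the two
proteotypic surrogate peptides of cetuximab — **HT4**
(`GLEWLGVIWSGGNTDYNTPFTSR`, heavy chain, RT 8.8 min) and **LT3**
(`ASQSIGTNIHWYQQR`, light chain, RT 3.6 min) — each monitored by three SRM
transitions on the analyte and on the co-eluting stable-isotope-labeled
(SIL) internal-standard channel. It is aimed at bioanalytical and clinical
pharmacology groups who want a transparent, scriptable reference
implementation of such an assay's data analysis.

## What it computes

* **Peak processing** — apex search near the scheduled retention time on a
  lightly smoothed trace, 5%-of-apex boundaries, trapezoidal integration
  with off-peak baseline subtraction, MAD-based noise (`detect_peak()`,
  `integrate_peak()`, `estimate_noise()`).
* **Quantification** — response ratio `area_light / area_heavy`; SIL
  co-elution within 0.1 min and qualifier ion ratios within ±25% as
  specificity gates; per-peptide back-calculation; consensus = mean of the
  HT4 and LT3 concentrations when they agree within 20%
  (`measure_peptides()`, `quantify_samples()`).
* **Calibration** — weighted least squares of ratio on nominal over
  1–1000 µg/mL with weighting (1, 1/x, 1/x²) selected by the profile
  likelihood of the variance model; back-calculated standards accepted at
  ±15% (±20% at the lowest level), curve valid at ≥75% and ≥6 accepted
  levels (`fit_calibration()`, broom-style `tidy()`/`glance()`,
  `autoplot()`).
* **Validation battery** — CV = sd/mean·100, accuracy = mean/nominal·100,
  intra-/inter-day designs, matrix effect across six plasma lots,
  selectivity (<20% of LLOQ), LLOQ qualification (80–120%, CV ≤ 20%),
  stability, stage and total recovery (`precision_accuracy()` and
  friends).
* **Exposure–response** — pooled-variance t-test between outcome groups,
  empirical ROC with Youden-optimal threshold (`exposure ≥ threshold ⇒
  predicted benefit`), and the exact 2×2 association (two-sided Fisher p,
  conditional-MLE odds ratio and exact CI computed directly on the
  noncentral hypergeometric distribution) (`roc_analysis()`,
  `exact_association()`, `tdm_analysis()`).
* **Synthetic data** — Gaussian SRM chromatograms at the assay's retention
  times with the measured per-stage recoveries (HT4 89.5/48.1/50.8%, LT3
  103.3/63.6/47.9%), the 9-level calibration and 4×6×3 QC designs, and
  25-patient cohorts (15 benefit vs 10 progressive; Cmin 49.0 ± 16.3 vs
  25.8 ± 17 µg/mL) so the whole pipeline runs with no external data
  (`simulate_study()`, `simulate_cohort()`).

## Worked example

Simulate a complete study (calibration batch, QC design, 25 patients) and
run the pipeline on it:

```r
library(srmtdm)

study <- simulate_study(config = sim_config(seed = 3))
run <- run_pipeline(study$chromatograms, study$manifest,
                    cohort = study$cohort)
print(run)
#> SRM quantification run
#> Calibration curve [HT4]: ratio = -0.00440246 + 0.114216 * conc
#>   weighting 1/x^2 (selected by variance-model likelihood), r2 = 0.99754
#>   9/9 levels accepted; curve VALID
#> Calibration curve [LT3]: ratio = 0.00208188 + 0.16002 * conc
#>   weighting 1/x^2 (selected by variance-model likelihood), r2 = 0.99953
#>   9/9 levels accepted; curve VALID
#>   QC battery: 8/8 level checks pass
#>   122 samples quantified (121 valid consensus)
#> Exposure-response analysis of cmin (n = 25)
#>   pooled 36.1 +/- 16.6 ug/mL (CV 46%, range 1.4-63.6)
#>   benefit 43.5 vs progressive 24.9 ug/mL, t = 3.25, p = 0.003491
#> ROC analysis of cmin (benefit n=15 vs progressive n=10)
#>   AUC 0.813; optimal threshold 31.4 ug/mL (sensitivity 93%, specificity 70%)
#>   8 patients below / 17 at or above the threshold
#>   exact association at threshold 31.4: OR 26.64 (95% CI 2.27-1572.20), p = 0.001706
```

Reading the output: both calibration curves are linear over three decades
(r² ≈ 0.998) with 1/x² weighting selected, as expected for CV-constant
detector noise; all QC levels meet the EMA precision/accuracy limits; and
on this synthetic cohort the benefit group's troughs (43.5 µg/mL) sit well
above the progressive group's (24.9 µg/mL, p = 0.0035), giving a
Youden-optimal decision threshold of 31.4 µg/mL whose low/high split is
strongly associated with outcome (OR 26.6, exact p = 0.0017). Individual
results live in `run$sample_results`; `write_run_report(run, dir)` writes
the CSV tables and a machine-readable JSON report.

A thin command-line front end with `simulate`, `quantify` and `tdm`
subcommands ships at `inst/exec/srmtdm.R`.

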