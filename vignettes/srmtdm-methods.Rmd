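---
title: "Quantifying cetuximab by SRM: models, validation statistics, and exposure-response analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying cetuximab by SRM: models, validation statistics, and exposure-response analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(srmtdm)
library(dplyr)
```

# The measurement problem

Cetuximab, an anti-EGFR IgG1 monoclonal antibody used in head-and-neck and
colorectal cancer, shows marked between-patient pharmacokinetic variability,
and trough plasma concentration (Cmin) is a candidate predictor of clinical
benefit. Routine therapeutic drug monitoring (TDM) requires a plasma assay
that is simple, fast and precise. The bottom-up LC-MS/MS approach quantifies
the protein through two proteotypic surrogate peptides from its
complementarity-determining regions — HT4 (`GLEWLGVIWSGGNTDYNTPFTSR`, heavy
chain) and LT3 (`ASQSIGTNIHWYQQR`, light chain) — each monitored by scheduled
selected-reaction monitoring (SRM) with three transitions, alongside
co-eluting stable-isotope-labeled (SIL) internal-standard peptides carrying a
`[13C6;15N4]` C-terminal arginine (+10 Da, i.e. +10/3 m/z on the 3+
precursors).

`srmtdm` implements the complete computational pipeline behind such an
assay: peak detection and integration of the SRM traces, isotope-ratio
quantification with specificity gating, weighted linear calibration with
data-driven weighting selection, the EMA-style validation battery, and the
cohort-level exposure–response analysis. A synthetic-data module generates
chromatograms, calibration/QC batches and patient cohorts with the
statistical structure the analysis assumes, so every stage is testable
without instrument data.

# The signal model and the synthetic-data generator

The generator (`sim_config()`, `simulate_sample_chromatograms()` and
friends) emulates scheduled SRM acquisition:

* **Peak shape.** Gaussian peaks on a flat baseline, width
  `peak_sigma = 0.05` min sampled every `0.005` min (~15 points per peak,
  the acquisition density of the assay). Symmetric UPLC peaks make the
  closed-form area `height * sigma * sqrt(2*pi)` available for testing.
* **Retention.** HT4 elutes at 8.8 min, LT3 at 3.6 min; light and heavy
  channels of a peptide share a single apex, jittered per sample
  (`rt_jitter_sd = 0.02` min) — the SIL standard co-elutes by construction.
* **Response.** The light quantifier area is
  `true_conc * response_factor * digestion * spe * ionization`, with the
  stage recoveries defaulting to the measured plasma values (HT4
  0.895/0.481/0.508, LT3 1.033/0.636/0.479). Heavy areas are fixed by the
  spiked SIL amount. Qualifier transitions are fixed fractions (0.65, 0.40)
  of the quantifier on both channels, so the transition-ratio template is
  exact and the ±25% identity check responds to interference, not to
  simulation noise.
* **Noise.** `noise_cv` (default 0.05) is the CV of the light/heavy response
  ratio — the quantity bioanalysts mean by "assay imprecision" — applied
  multiplicatively to the light quantifier. Point-level trace noise has sd
  `noise_cv * baseline_level`, so `noise_cv = 0` is an exactly noise-free
  limit. A `"constant"` noise model (fixed absolute sd, scaled by the signal
  at `constant_noise_ref = 31.62` µg/mL, the geometric mid-range) exists to
  exercise calibration-weighting selection. Multi-day QC designs add a
  multiplicative between-day effect (`day_effect_sd = 0.05`) to the light
  response.
* **Cohort.** 15 patients with clinical benefit and 10 with progressive
  disease; Cmin ~ N(49.0, 16.3²) vs N(25.8, 17²) µg/mL, Cmax ~ N(143.7,
  37.9²) vs N(100.9, 24.6²), truncated at zero by resampling (observed
  troughs start at 0). Cmin and Cmax are drawn independently per patient —
  a deliberate simplification, since the analysis uses them marginally; no
  dosing-history PK model is simulated. The implied pooled trough mean is
  ≈40.7 µg/mL (mixture 39.7 plus ≈1 from truncation).

What passing simulation tests do **not** show about real data: real
chromatograms have tailing peaks, drifting baselines, co-eluting
interferences and heteroscedastic point noise; real cohorts have joint
Cmin–Cmax structure and outcome-dependent sampling. The simulator is a
statistical stand-in at the level the analysis consumes (areas, ratios,
marginal exposures), not a physical instrument model.

# Peak processing

`detect_peak()` searches ±`window` (default 0.3 min) around the expected
retention time on a 5-point moving average (raw argmax is noise-sensitive
at 15 points/peak; plateau ties resolve to the earliest time). Boundaries
are the outermost samples at or above 5% of the apex height over baseline.
Baseline and noise (1.4826 × MAD) come from the trace outside the search
window; a peak is "found" when the smoothed apex rises ≥3 noise units above
baseline — a conventional detection floor, deliberately below the
quantification limit that the LLOQ rules enforce later.

`integrate_peak()` applies the trapezoid between the bounds after
subtracting a straight baseline anchored on the median off-peak intensity
on each side. Anchoring on the off-peak medians rather than on the
boundary samples themselves is what makes a Gaussian on a flat baseline
integrate to within ~1.5% of its analytic area (the 5%-threshold boundary
samples are themselves elevated by the peak; a chord through them would
clip ~10% of the area). Because light and heavy traces share shape and
grid, the truncation factor cancels exactly in the response ratio — the
quantity every downstream result is built on. The integration definition
is this package's own; vendor software the assay originally relied on does
not document its algorithm.

# Quantification protocol

A peptide measurement is accepted only if (i) the analyte co-elutes with
its SIL partner within 0.1 min, and (ii) every qualifier/quantifier ratio
on the analyte channel is within ±25% of its SIL counterpart. Cetuximab
concentration is the mean of the HT4 and LT3 back-calculated
concentrations, reported only when the two agree within 20%
(`|c1 − c2| / mean(c1, c2) × 100`; the mean denominator is our choice —
the protocol only states "difference below 20%"). All acceptance
boundaries in the package (0.1 min, ±25%, ±15/±20%, 20% concordance, CV
limits) are read inclusively: "within" and "below" are interpreted as
closed intervals, one convention applied everywhere. The one exception is
selectivity, whose rule is explicitly "less than 20% of the LLOQ signal"
and is strict. Concentrations above the top standard are flagged
`above_uloq`, never extrapolated (dilution re-assay is out of scope).

## Calibration and weighting selection

Calibration is weighted least squares of ratio on nominal over 9 levels
spanning 1–1000 µg/mL (geometric spacing is a generator default; the
assay's exact level placement is not prescribed). Candidate weightings are
1, 1/x and 1/x², i.e. variance models Var ∝ 1, x, x². Selection is by the
profile likelihood of the variance model,
`-n/2·log(Σ w·e²/n) + Σ log(w)/2`: raw weighted residual sums of squares
are not comparable across weightings, and the popular "sum of squared
relative back-calculation errors" is — up to a slope factor — the 1/x²
fit's own objective, so it selects 1/x² almost regardless of the data (we
measured 86% even on constant-variance data). The likelihood comparison
selects 1/x² on 97% of CV-constant batches and unweighted on 96% of
constant-variance batches at the default noise level; leave-one-out and
in-sample variants of the relative-error criterion remain available via
`selection=`. Ties (exact data) break to the simpler weighting.

Back-calculated standards must fall within 85–115% of nominal (80–120% at
the lowest standard); a curve is valid when ≥75% of levels and ≥6 levels
pass — the EMA curve-acceptance rule the assay's validation follows.

## Validation battery

`precision_accuracy()` implements CV = sd/mean × 100 (sample sd, n−1 —
the protocol says only "SD") and accuracy = mean/nominal × 100, with
limits 15%/85–115% (20%/80–120% at LLOQ). Inter-day statistics pool all
replicates across days rather than averaging day means, matching the
printed inter-day n and common EMA practice. Matrix effect requires six
plasma lots at LLOQ; stability uses triplicates at the standard limits;
total recovery is the product of stage recoveries with a
root-sum-of-squares CV (first-order approximation for a product of
independent stages). A QC level whose consensus was withheld in all but
one replicate cannot demonstrate precision and is reported as failed
rather than erroring out of the batch.

# Exposure-response analysis

`roc_analysis()` builds the empirical ROC of exposure as a classifier of
clinical benefit with the convention *exposure ≥ threshold → predicted
benefit* (the "high" group at the assay's 33.8 µg/mL threshold counts the
patients at or above it). The operating threshold maximizes the Youden
index, ties resolving to the lower observed value; AUC is the trapezoid
under the empirical curve and equals the Mann–Whitney U over n₁n₂ on
tie-free data. Group comparison uses the pooled-variance Student t-test
(the "standard t-test" of legacy biostatistics software; Welch is an
option). `exact_association()` computes the two-sided Fisher exact
p-value, the conditional-MLE odds ratio and its exact confidence interval
directly on the noncentral hypergeometric distribution; the odds-ratio
score equation is solved to ~1e-12, tighter than the ~1e-4 of
general-purpose implementations, and ties between equal-probability
tables are absorbed with a 1e-7 relative tolerance.

# Numerical choices and degenerate inputs

* Boundary epsilon 1e-9 on the co-elution and transition-ratio checks so
  exact-boundary data stay inclusive under float rounding.
* `detect_peak()` on a flat or constant trace reports `found = FALSE` and
  zero area; `estimate_noise()` of a constant trace is 0.
* A 2×2 table with a zero margin leaves the exact test undefined; the
  pipeline records the classification but skips the association.
* Negative back-calculated concentrations floor at zero with a flag.
* All simulation is seed-driven; identical seeds give byte-identical
  outputs, including the JSON run report.

# Problem sizes

The simulation-backed properties are evaluated at the study's own scale:
9-level calibration batches, the 4 × 6 × 3 QC design, 25-patient cohorts,
and 200-seed Monte Carlo panels for the rate properties (threshold
recovery, t-test power, spiked-sample accuracy, weighting selection). A
complete simulate–quantify–validate–analyze chain runs in a few seconds;
the 200-seed panels take on the order of two minutes on one CPU.

# Known limitations

* No peak deconvolution or cross-run retention alignment; interference is
  handled by rejection (specificity checks), not modeling.
* The linear calibration is the assay's validated model; no quadratic/4PL
  option is provided.
* mzML ingestion is not implemented; the long-format CSV is the interchange
  format.
* The empirical Youden threshold at n = 25 is highly variable (its central
  80% interval spans roughly 26–50 µg/mL under the cohort model), so a
  single-cohort threshold estimate should be read as indicative, not
  definitive — consistent with the proof-of-concept character of the
  underlying assay study.
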