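#' SIL co-elution check
#'
#' The analyte peak must co-elute strictly with its stable-isotope-labeled
#' internal standard: the check passes when both peaks were found and their
#' apex retention times agree within `tolerance` minutes (boundary
#' inclusive).
#'
#' @param light_peak,heavy_peak One-row peak tibbles from [detect_peak()].
#' @param tolerance Maximum apex retention-time difference (minutes).
#' @return `TRUE`/`FALSE`; a missing peak fails the check (with the reason
#'   in the `"reason"` attribute) rather than raising.
#' @export
coelution_check <- function(light_peak, heavy_peak, tolerance = 0.1) {
  if (!isTRUE(light_peak$found[1]) || !isTRUE(heavy_peak$found[1])) {
    missing <- c("light", "heavy")[!c(isTRUE(light_peak$found[1]),
                                      isTRUE(heavy_peak$found[1]))]
    return(structure(FALSE, reason = sprintf(
      "peak not found on %s channel", paste(missing, collapse = " and "))))
  }
  # small epsilon keeps exact-boundary cases inclusive under float rounding
  abs(light_peak$apex_rt[1] - heavy_peak$apex_rt[1]) <= tolerance + 1e-9
}

#' Qualifier transition-ratio check
#'
#' For each qualifier transition, the relative ratio (qualifier area divided
#' by quantifier area) is computed on the analyte and on the SIL channel;
#' the identity of the peptide is confirmed when every analyte relative
#' ratio lies within `tolerance_pct` percent of its SIL counterpart
#' (boundary inclusive).
#'
#' @param meas A one-row peptide measurement (a row of
#'   [measure_peptides()] output), or any list with numeric
#'   `light_quantifier_area`, `heavy_quantifier_area` and a `qualifiers`
#'   tibble carrying `light_area` and `heavy_area`.
#' @param tolerance_pct Allowed relative deviation in percent.
#' @return `TRUE`/`FALSE`; zero or missing areas fail with the reason in
#'   the `"reason"` attribute.
#' @export
transition_ratio_check <- function(meas, tolerance_pct = 25) {
  lq <- meas$light_quantifier_area[[1]]
  hq <- meas$heavy_quantifier_area[[1]]
  qual <- meas$qualifiers[[1]]
  if (!is.finite(lq) || !is.finite(hq) || hq <= 0 || lq <= 0) {
    return(structure(FALSE, reason = "zero or missing quantifier area"))
  }
  if (is.null(qual) || nrow(qual) == 0 ||
      any(!is.finite(qual$light_area) | !is.finite(qual$heavy_area)) ||
      any(qual$heavy_area <= 0)) {
    return(structure(FALSE, reason = "zero or missing qualifier area"))
  }
  light_rel <- qual$light_area / lq
  heavy_rel <- qual$heavy_area / hq
  all(abs(light_rel / heavy_rel - 1) <= tolerance_pct / 100 + 1e-9)
}

#' Measure peptide responses from SRM chromatograms
#'
#' Turns raw traces into per-sample, per-peptide measurements: every
#' transition is searched near its expected retention time, quantifier
#' areas on the two channels give the response ratio (light/heavy), and the
#' two specificity rules of the quantification protocol are applied - SIL
#' co-elution within `rt_tolerance` minutes and qualifier relative ratios
#' within `ratio_tolerance_pct` percent of the SIL template.
#'
#' @param chromatograms Long chromatogram tibble (`sample_id`,
#'   `peptide_id`, `channel`, `product_mz`, `time`, `intensity`), e.g. from
#'   [simulate_sample_chromatograms()] or [read_chromatograms()].
#' @param assay Assay tibble ([cetuximab_assay()]).
#' @param window Peak-search half-window in minutes.
#' @param rt_tolerance Co-elution tolerance in minutes.
#' @param ratio_tolerance_pct Transition-ratio tolerance in percent.
#' @return A tibble with one row per sample x peptide: quantifier areas and
#'   apex times on both channels, `response_ratio`, the qualifier area
#'   table as a list column, `coelution_ok`, `transition_ratio_ok` and a
#'   semicolon-separated `qc_flags` string (empty when clean).
#' @export
measure_peptides <- function(chromatograms, assay = cetuximab_assay(),
                             window = 0.3, rt_tolerance = 0.1,
                             ratio_tolerance_pct = 25) {
  assert_cols(chromatograms,
              c("sample_id", "peptide_id", "channel", "product_mz",
                "time", "intensity"), "chromatograms")
  key <- paste(chromatograms$sample_id, chromatograms$peptide_id, sep = "\r")
  groups <- split(seq_len(nrow(chromatograms)), factor(key, unique(key)))
  rows <- lapply(groups, function(ix) {
    sid <- chromatograms$sample_id[ix[1]]
    pid <- chromatograms$peptide_id[ix[1]]
    sub <- fast_tibble(list(
      channel = chromatograms$channel[ix],
      product_mz = chromatograms$product_mz[ix],
      time = chromatograms$time[ix],
      intensity = chromatograms$intensity[ix]
    ))
    measure_one_peptide(sub, assay[assay$peptide_id == pid, ], sid, pid,
                        window, rt_tolerance, ratio_tolerance_pct)
  })
  bind_rows(rows)
}

measure_one_peptide <- function(traces, tra, sample_id, peptide_id, window,
                                rt_tolerance, ratio_tolerance_pct) {
  tr_channel <- traces$channel
  tr_mz <- traces$product_mz
  tr_time <- traces$time
  tr_int <- traces$intensity
  peak_for <- function(channel, product_mz) {
    sel <- tr_channel == channel & abs(tr_mz - product_mz) < 0.1
    if (!any(sel)) return(NULL)
    ord <- order(tr_time[sel])
    detect_peak(fast_tibble(list(time = tr_time[sel][ord],
                                 intensity = tr_int[sel][ord])),
                expected_rt = tra$expected_rt[1], window = window)
  }
  quant <- tra[tra$is_quantifier, ]
  qual <- tra[!tra$is_quantifier, ]

  lp <- peak_for("light", quant$product_mz[quant$channel == "light"])
  hp <- peak_for("heavy", quant$product_mz[quant$channel == "heavy"])
  flags <- character()
  if (is.null(lp) || is.null(hp)) {
    abort(sprintf("%s/%s: quantifier trace missing", sample_id, peptide_id))
  }
  if (!lp$found) flags <- c(flags, "light_peak_not_found")
  if (!hp$found) flags <- c(flags, "heavy_peak_not_found")

  ql <- qual[qual$channel == "light", ]
  qh <- qual[qual$channel == "heavy", ]
  q_light <- q_heavy <- rep(NA_real_, nrow(ql))
  for (i in seq_len(nrow(ql))) {
    plq <- peak_for("light", ql$product_mz[i])
    phq <- peak_for("heavy", qh$product_mz[i])
    if (!is.null(plq)) q_light[i] <- plq$area
    if (!is.null(phq)) q_heavy[i] <- phq$area
  }
  qualifiers <- fast_tibble(list(
    product_mz = ql$product_mz, product_label = ql$product_label,
    light_area = q_light, heavy_area = q_heavy
  ))

  ratio <- if (hp$found && hp$area > 0 && lp$found) lp$area / hp$area
           else NA_real_

  meas <- fast_tibble(list(
    sample_id = sample_id, peptide_id = peptide_id,
    light_quantifier_area = lp$area, heavy_quantifier_area = hp$area,
    light_rt = if (lp$found) lp$apex_rt else NA_real_,
    heavy_rt = if (hp$found) hp$apex_rt else NA_real_,
    response_ratio = ratio,
    qualifiers = list(qualifiers),
    coelution_ok = FALSE, transition_ratio_ok = FALSE, qc_flags = ""
  ))

  co <- coelution_check(lp, hp, tolerance = rt_tolerance)
  if (!co) flags <- c(flags, paste0("no_coelution",
    if (!is.null(attr(co, "reason"))) paste0(":", attr(co, "reason"))))
  tr_ok <- transition_ratio_check(meas, tolerance_pct = ratio_tolerance_pct)
  if (!tr_ok) flags <- c(flags, "transition_ratio_fail")

  meas$coelution_ok <- as.logical(co)
  meas$transition_ratio_ok <- as.logical(tr_ok)
  meas$qc_flags <- paste(flags, collapse = ";")
  meas
}
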