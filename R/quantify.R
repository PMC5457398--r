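#' Dual-peptide consensus quantification of one sample
#'
#' Back-calculates the cetuximab concentration independently from the HT4
#' and LT3 response ratios, then forms the consensus as the arithmetic mean
#' of the two, provided both peptide measurements passed their specificity
#' checks and the two concentrations agree: the concordance
#' `|c_HT4 - c_LT3| / mean(c_HT4, c_LT3) * 100` must not exceed
#' `concordance_limit` percent (boundary inclusive). Concentrations above
#' the top calibration standard are flagged `above_uloq` and not
#' extrapolated.
#'
#' @param meas_ht4,meas_lt3 One-row measurement tibbles for the two
#'   peptides (rows of [measure_peptides()] output for one sample).
#' @param curves Named list of valid `"calibration_curve"` objects, one per
#'   peptide (`HT4`, `LT3`).
#' @param concordance_limit Maximum inter-peptide difference in percent.
#' @return A one-row tibble: `sample_id`, `conc_ht4`, `conc_lt3`,
#'   `consensus_conc`, `concordance_pct`, `qc_flags`, `valid`.
#' @export
quantify_sample <- function(meas_ht4, meas_lt3, curves,
                            concordance_limit = 20) {
  for (pid in c("HT4", "LT3")) {
    if (is.null(curves[[pid]])) abort(sprintf("missing calibration curve for %s", pid))
  }
  one <- function(meas, pid) {
    flags <- character()
    if (nzchar(meas$qc_flags[[1]])) flags <- strsplit(meas$qc_flags[[1]], ";")[[1]]
    conc <- NA_real_
    checks_ok <- isTRUE(meas$coelution_ok[[1]]) &&
      isTRUE(meas$transition_ratio_ok[[1]])
    if (is.finite(meas$response_ratio[[1]])) {
      conc <- as.numeric(back_calculate(curves[[pid]],
                                        meas$response_ratio[[1]]))
      uloq <- max(curves[[pid]]$levels$nominal)
      if (conc > uloq) {
        flags <- c(flags, "above_uloq")
        conc <- NA_real_
      }
    }
    list(conc = conc, ok = checks_ok,
         flags = if (length(flags)) paste0(pid, ":", flags) else character())
  }
  ht4 <- one(meas_ht4, "HT4")
  lt3 <- one(meas_lt3, "LT3")
  flags <- c(ht4$flags, lt3$flags)

  concordance <- NA_real_
  consensus <- NA_real_
  valid <- FALSE
  if (is.finite(ht4$conc) && is.finite(lt3$conc) && ht4$ok && lt3$ok) {
    m <- mean(c(ht4$conc, lt3$conc))
    concordance <- if (m > 0) abs(ht4$conc - lt3$conc) / m * 100 else 0
    if (concordance <= concordance_limit) {
      consensus <- m
      valid <- TRUE
    } else {
      flags <- c(flags, "peptide_discordance")
    }
  } else if (!ht4$ok || !lt3$ok) {
    flags <- c(flags, "specificity_check_failed")
  }

  tibble(
    sample_id = meas_ht4$sample_id[[1]],
    conc_ht4 = ht4$conc, conc_lt3 = lt3$conc,
    consensus_conc = consensus, concordance_pct = concordance,
    qc_flags = paste(unique(flags), collapse = ";"), valid = valid
  )
}

#' Quantify every sample of a measurement table
#'
#' Applies [quantify_sample()] to each sample having both peptide
#' measurements.
#'
#' @param measurements Output of [measure_peptides()].
#' @param curves Named list of calibration curves (`HT4`, `LT3`).
#' @param concordance_limit Passed to [quantify_sample()].
#' @return A tibble with one row per sample.
#' @export
quantify_samples <- function(measurements, curves, concordance_limit = 20) {
  ids <- unique(measurements$sample_id)
  purrr::map_dfr(ids, function(id) {
    mh <- measurements[measurements$sample_id == id &
                         measurements$peptide_id == "HT4", ]
    ml <- measurements[measurements$sample_id == id &
                         measurements$peptide_id == "LT3", ]
    if (nrow(mh) != 1L || nrow(ml) != 1L) {
      abort(sprintf("sample %s lacks a measurement for both peptides", id))
    }
    quantify_sample(mh, ml, curves, concordance_limit)
  })
}
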