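#' Read and write long-format chromatogram CSV
#'
#' The on-disk format is a comma-separated, UTF-8, headered table with one
#' row per acquisition point: `sample_id`, `channel`, `product_mz`, `time`
#' (minutes), `intensity`. On reading, every trace is matched to an assay
#' transition by channel and product m/z within 0.1; unmatched traces are
#' skipped with a warning, and matching fills in `peptide_id`,
#' `product_label` and `is_quantifier` from the assay. Times are minutes
#' and concentrations ug/mL throughout the package.
#'
#' @param path CSV file path.
#' @param assay Assay tibble used for transition matching.
#' @param format Only `"csv"` is supported.
#' @return `read_chromatograms()` returns the canonical long tibble;
#'   `write_chromatograms()` returns `path` invisibly.
#' @export
read_chromatograms <- function(path, assay = cetuximab_assay(),
                               format = c("csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  assert_cols(raw, c("sample_id", "channel", "product_mz", "time",
                     "intensity"), sprintf("chromatogram file '%s'", path))

  key <- distinct(raw, .data$channel, .data$product_mz)
  key$peptide_id <- NA_character_
  key$product_label <- NA_character_
  key$is_quantifier <- NA
  key$assay_product_mz <- NA_real_
  for (i in seq_len(nrow(key))) {
    hit <- which(assay$channel == key$channel[i] &
                   abs(assay$product_mz - key$product_mz[i]) <= 0.1)
    if (length(hit) == 1L) {
      key$peptide_id[i] <- assay$peptide_id[hit]
      key$product_label[i] <- assay$product_label[hit]
      key$is_quantifier[i] <- assay$is_quantifier[hit]
      key$assay_product_mz[i] <- assay$product_mz[hit]
    }
  }
  dropped <- key[is.na(key$peptide_id), ]
  if (nrow(dropped)) {
    warn(sprintf("skipping %d trace(s) with no assay transition within 0.1 m/z: %s",
                 nrow(dropped),
                 paste(sprintf("%s/%.1f", dropped$channel,
                               dropped$product_mz), collapse = ", ")))
  }
  out <- raw %>%
    dplyr::inner_join(key[!is.na(key$peptide_id), ],
                      by = c("channel", "product_mz")) %>%
    mutate(product_mz = .data$assay_product_mz) %>%
    select("sample_id", "peptide_id", "channel", "product_mz",
           "product_label", "is_quantifier", "time", "intensity") %>%
    arrange(.data$sample_id, .data$peptide_id, .data$channel,
            .data$product_mz, .data$time)
  if (nrow(out) == 0) abort("no trace in the file matched any assay transition")
  out
}

#' @rdname read_chromatograms
#' @param chromatograms Long chromatogram tibble.
#' @export
write_chromatograms <- function(chromatograms, path) {
  readr::write_csv(
    select(chromatograms, "sample_id", "channel", "product_mz",
           "time", "intensity"),
    path)
  invisible(path)
}

#' Read and write sample manifests and cohort tables
#'
#' The manifest lists one row per sample: `sample_id`, `role`
#' (`standard`/`qc`/`patient`), `nominal_conc` (standards and QCs), `day`,
#' and for patient samples `patient_id` and `draw_type` (`cmin`/`cmax`).
#' The cohort table has one row per patient: `patient_id`, `outcome`,
#' `severe_toxicity`.
#'
#' @param manifest,cohort Tibbles to write.
#' @param path CSV file path.
#' @return Readers return tibbles; writers return `path` invisibly.
#' @export
read_manifest <- function(path) {
  m <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_manifest(m)
  m
}

#' @rdname read_manifest
#' @export
write_manifest <- function(manifest, path) {
  readr::write_csv(manifest, path)
  invisible(path)
}

#' @rdname read_manifest
#' @export
read_cohort <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' @rdname read_manifest
#' @export
write_cohort <- function(cohort, path) {
  readr::write_csv(cohort, path)
  invisible(path)
}

validate_manifest <- function(manifest) {
  assert_cols(manifest, c("sample_id", "role"), "manifest")
  if (anyDuplicated(manifest$sample_id)) {
    abort("manifest sample_ids must be unique")
  }
  std <- manifest[manifest$role == "standard", ]
  if (nrow(std) && (!"nominal_conc" %in% names(manifest) ||
                    any(!is.finite(std$nominal_conc)))) {
    abort("calibration standards must carry nominal_conc")
  }
  pat <- manifest[manifest$role == "patient", ]
  if (nrow(pat) && (!"draw_type" %in% names(manifest) ||
                    any(is.na(pat$draw_type)))) {
    abort("patient samples must carry draw_type (cmin/cmax)")
  }
  invisible(manifest)
}

#' Run the full quantification pipeline
#'
#' Chains the analysis stages on one batch: peptide measurement of every
#' sample, calibration fitting per peptide from the standards (aborting
#' with an explicit error if either curve fails acceptance), consensus
#' quantification of QC and patient samples, the intra-/inter-day QC
#' battery when a QC design is present, and - when a cohort outcome table
#' is supplied - the exposure-response analysis on the measured patient
#' troughs. Deterministic given its inputs.
#'
#' @param chromatograms Long chromatogram tibble.
#' @param manifest Sample manifest (see [read_manifest()]).
#' @param assay Assay tibble.
#' @param cohort Optional cohort outcome tibble (`patient_id`, `outcome`).
#' @param window Peak-search half-window (minutes).
#' @return A list of class `"srm_run"`: `curves`, `measurements`,
#'   `sample_results`, `qc_battery`, `patient_exposures`, `tdm`, `notes`.
#' @export
run_pipeline <- function(chromatograms, manifest, assay = cetuximab_assay(),
                         cohort = NULL, window = 0.3) {
  validate_manifest(manifest)
  notes <- character()
  meas <- measure_peptides(chromatograms, assay, window = window)

  std <- manifest[manifest$role == "standard", ]
  if (nrow(std) < 6L) abort("pipeline needs >= 6 calibration standards")
  std_meas <- meas %>%
    dplyr::inner_join(select(std, "sample_id", "nominal_conc"),
                      by = "sample_id")
  curves <- lapply(split(std_meas, std_meas$peptide_id), function(d) {
    fit_calibration(tibble(nominal = d$nominal_conc, ratio = d$response_ratio),
                    peptide_id = d$peptide_id[1])
  })
  for (pid in names(curves)) {
    if (!isTRUE(curves[[pid]]$curve_valid)) {
      abort(sprintf(
        "calibration curve for %s failed acceptance (%d/%d levels); aborting sample quantification",
        pid, sum(curves[[pid]]$back_calc$accepted),
        nrow(curves[[pid]]$back_calc)))
    }
  }

  non_std <- manifest[manifest$role != "standard", ]
  results <- NULL
  if (nrow(non_std)) {
    results <- quantify_samples(
      meas[meas$sample_id %in% non_std$sample_id, ], curves) %>%
      left_join(non_std, by = "sample_id")
  }

  qc_battery <- NULL
  qc <- manifest[manifest$role == "qc", ]
  if (nrow(qc)) {
    qcr <- results[results$role == "qc", ]
    lloq <- min(manifest$nominal_conc[manifest$role == "standard"])
    qc_battery <- purrr::map_dfr(sort(unique(qcr$nominal_conc)), function(lev) {
      rows <- qcr[qcr$nominal_conc == lev, ]
      is_lloq <- lev <= lloq
      intra <- rows[rows$day == min(rows$day), ]
      out <- battery_or_fail(intra$consensus_conc, lev, is_lloq = is_lloq)
      if (length(unique(rows$day)) > 1L) {
        keep <- is.finite(rows$consensus_conc)
        inter <- if (sum(keep) >= 2L && length(unique(rows$day[keep])) > 1L) {
          inter_day_battery(tibble(day = rows$day[keep],
                                   measured = rows$consensus_conc[keep]),
                            lev, is_lloq = is_lloq)
        } else {
          battery_or_fail(rows$consensus_conc[keep], lev,
                          is_lloq = is_lloq, scope = "inter_day")
        }
        out <- bind_rows(out, inter)
      }
      out
    })
  } else {
    notes <- c(notes, "no QC design in manifest; validation battery skipped")
  }

  patient_exposures <- NULL
  tdm <- NULL
  pat <- manifest[manifest$role == "patient", ]
  if (nrow(pat)) {
    patient_exposures <- results[results$role == "patient", ] %>%
      select("patient_id", "draw_type", "consensus_conc") %>%
      tidyr::pivot_wider(names_from = "draw_type",
                         values_from = "consensus_conc")
    if (!is.null(cohort)) {
      measured_cohort <- dplyr::inner_join(patient_exposures, cohort,
                                           by = "patient_id")
      if ("cmin" %in% names(measured_cohort) &&
          sum(is.finite(measured_cohort$cmin)) >= 4) {
        tdm <- tdm_analysis(
          measured_cohort[is.finite(measured_cohort$cmin), ], "cmin")
      } else {
        notes <- c(notes, "too few measured troughs; exposure-response skipped")
      }
    } else {
      notes <- c(notes, "no cohort outcome table; exposure-response skipped")
    }
  } else if (!is.null(cohort)) {
    notes <- c(notes, "cohort table supplied but manifest has no patient samples")
  }

  structure(list(
    curves = curves, measurements = meas, sample_results = results,
    qc_battery = qc_battery, patient_exposures = patient_exposures,
    tdm = tdm, notes = notes
  ), class = "srm_run")
}

#' @export
print.srm_run <- function(x, ...) {
  cat("SRM quantification run\n")
  for (pid in names(x$curves)) print(x$curves[[pid]])
  if (!is.null(x$qc_battery)) {
    cat(sprintf("  QC battery: %d/%d level checks pass\n",
                sum(x$qc_battery$pass), nrow(x$qc_battery)))
  }
  if (!is.null(x$sample_results)) {
    cat(sprintf("  %d samples quantified (%d valid consensus)\n",
                nrow(x$sample_results), sum(x$sample_results$valid)))
  }
  if (!is.null(x$tdm)) print(x$tdm)
  for (n in x$notes) cat("  note:", n, "\n")
  invisible(x)
}

#' Write a machine-readable run report
#'
#' Emits `sample_results.csv`, `qc_battery.csv` (when present) and
#' `report.json` (curve parameters, QC battery, exposure-response results,
#' flags) into a directory. Output is byte-identical across reruns on
#' identical inputs.
#'
#' @param run An `"srm_run"` from [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_run_report <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(run$sample_results)) {
    readr::write_csv(select(run$sample_results, -dplyr::any_of("qualifiers")),
                     file.path(dir, "sample_results.csv"))
  }
  if (!is.null(run$qc_battery)) {
    readr::write_csv(run$qc_battery, file.path(dir, "qc_battery.csv"))
  }
  report <- list(
    curves = lapply(run$curves, function(cv) {
      c(as.list(glance(cv)), list(back_calc = cv$back_calc))
    }),
    qc_battery = run$qc_battery,
    tdm = if (!is.null(run$tdm)) list(
      summary = run$tdm$summary, by_group = run$tdm$by_group,
      t_test = run$tdm$t_test, roc = glance(run$tdm$roc),
      threshold = run$tdm$threshold, table = run$tdm$table,
      association = run$tdm$association
    ),
    notes = run$notes
  )
  jsonlite::write_json(report, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(dir)
}

#' Simulate a complete study
#'
#' Generates, from one seed, everything the pipeline consumes: a
#' calibration batch, the QC precision/accuracy design, patient trough and
#' peak samples drawn from the cohort model, the corresponding manifest,
#' and the cohort outcome table.
#'
#' @param config A [sim_config()]; its seed drives all stages.
#' @param cohort_config A [cohort_sim_config()] (its own seed is ignored;
#'   the study seed is used).
#' @param assay Assay tibble.
#' @param sil_amount Heavy-channel spike area.
#' @param n_qc_days,n_qc_reps QC design.
#' @param draw_types Patient draws to simulate (`"cmin"`, `"cmax"`).
#' @return A list: `chromatograms`, `manifest`, `cohort`, `true_values`.
#' @export
simulate_study <- function(config = sim_config(seed = 1),
                           cohort_config = cohort_sim_config(),
                           assay = cetuximab_assay(),
                           sil_amount = 1000,
                           n_qc_days = 3, n_qc_reps = 6,
                           draw_types = c("cmin", "cmax")) {
  if (!is.null(config$seed)) set.seed(config$seed)
  inner <- config
  inner$seed <- NULL
  cal <- simulate_calibration_batch(assay, config = inner,
                                    sil_amount = sil_amount)
  qc <- simulate_qc_replicates(assay, n_reps = n_qc_reps, n_days = n_qc_days,
                               config = inner, sil_amount = sil_amount)

  cc <- cohort_config
  cc$seed <- NULL
  cohort <- simulate_cohort(cc)

  pat_rows <- list()
  pat_chroms <- list()
  for (i in seq_len(nrow(cohort))) {
    for (dt in draw_types) {
      sid <- sprintf("%s_%s", cohort$patient_id[i], dt)
      pat_chroms[[sid]] <- sim_sample_impl(assay, cohort[[dt]][i], sil_amount,
                                           inner, sid)
      pat_rows[[sid]] <- tibble(
        sample_id = sid, role = "patient", nominal_conc = NA_real_,
        day = 1L, patient_id = cohort$patient_id[i], draw_type = dt
      )
    }
  }

  manifest <- bind_rows(
    mutate(cal$manifest, patient_id = NA_character_,
           draw_type = NA_character_),
    mutate(select(qc$manifest, -"rep"), patient_id = NA_character_,
           draw_type = NA_character_),
    bind_rows(pat_rows)
  )
  list(
    chromatograms = bind_rows(cal$chromatograms, qc$chromatograms,
                              bind_rows(pat_chroms)),
    manifest = manifest,
    cohort = select(cohort, "patient_id", "outcome", "severe_toxicity"),
    true_values = cohort
  )
}
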