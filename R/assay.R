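#' The cetuximab SRM assay definition
#'
#' Builds the fixed transition dictionary of the cetuximab assay: two
#' proteotypic surrogate peptides, HT4 (heavy chain,
#' `GLEWLGVIWSGGNTDYNTPFTSR`) and LT3 (light chain, `ASQSIGTNIHWYQQR`), each
#' monitored through three SRM transitions on the analyte ("light") channel
#' and three on the co-eluting stable-isotope-labeled internal-standard
#' ("heavy", `[13C6;15N4]` C-terminal Arg) channel. The first transition of
#' each peptide/channel is the quantifier; the other two are qualifiers used
#' for identity confirmation via relative ion ratios.
#'
#' @return A tibble with one row per transition and columns `peptide_id`,
#'   `sequence`, `average_mass` (Da), `channel` (`"light"`/`"heavy"`),
#'   `precursor_mz`, `precursor_charge`, `product_mz`, `product_label`,
#'   `collision_energy` (eV), `expected_rt` (minutes), `is_quantifier`.
#' @examples
#' assay <- cetuximab_assay()
#' dplyr::filter(assay, is_quantifier)
#' @seealso [validate_assay()], [read_assay()], [write_assay()]
#' @export
cetuximab_assay <- function() {
  tr <- function(peptide_id, sequence, average_mass, channel, precursor_mz,
                 product_mz, product_label, ce, rt) {
    tibble(
      peptide_id = peptide_id, sequence = sequence,
      average_mass = average_mass, channel = channel,
      precursor_mz = precursor_mz, precursor_charge = 3L,
      product_mz = product_mz, product_label = product_label,
      collision_energy = ce, expected_rt = rt,
      is_quantifier = c(TRUE, FALSE, FALSE)
    )
  }
  ht4 <- "GLEWLGVIWSGGNTDYNTPFTSR"
  lt3 <- "ASQSIGTNIHWYQQR"
  bind_rows(
    tr("HT4", ht4, 2570.8, "light", 857.6,
       c(908.6, 851.6, 759.0), c("y16^2+", "y15^2+", "y14^2+"), 16, 8.8),
    tr("HT4", ht4, 2580.8, "heavy", 860.9,
       c(913.6, 857.2, 764.0), c("y16^2+", "y15^2+", "y14^2+"), 16, 8.8),
    tr("LT3", lt3, 1788.9, "light", 597.2,
       c(652.0, 708.6, 752.2), c("y10^2+", "y11^2+", "y12^2+"), 15, 3.6),
    tr("LT3", lt3, 1798.9, "heavy", 600.6,
       c(657.0, 713.6, 757.2), c("y10^2+", "y11^2+", "y12^2+"), 15, 3.6)
  )
}

#' Validate an assay definition against its structural invariants
#'
#' Checks positivity of m/z, charge and retention time, the
#' one-quantifier-per-channel rule, the three-light-plus-three-heavy design,
#' the existence of a co-eluting heavy partner for every light transition,
#' and that the isotope label adds mass to the heavy precursor. Violations
#' are reported as messages, never raised, so a partially built assay can be
#' inspected.
#'
#' @param assay An assay tibble as returned by [cetuximab_assay()].
#' @return A character vector of violation messages; empty when the assay is
#'   valid.
#' @examples
#' validate_assay(cetuximab_assay())  # character(0)
#' @export
validate_assay <- function(assay) {
  msgs <- character()
  say <- function(...) msgs <<- c(msgs, sprintf(...))

  assert_cols(assay, c("peptide_id", "channel", "precursor_mz",
                       "precursor_charge", "product_mz", "collision_energy",
                       "expected_rt", "is_quantifier"), "assay")

  bad <- assay$precursor_charge < 1
  if (any(bad)) say("precursor_charge < 1 for %s", paste(
    unique(assay$peptide_id[bad]), collapse = ", "))
  for (col in c("precursor_mz", "product_mz")) {
    if (any(assay[[col]] <= 0)) say("non-positive %s in %s", col, paste(
      unique(assay$peptide_id[assay[[col]] <= 0]), collapse = ", "))
  }
  if (any(assay$expected_rt <= 0)) say("non-positive expected_rt in %s", paste(
    unique(assay$peptide_id[assay$expected_rt <= 0]), collapse = ", "))

  per_chan <- assay %>%
    group_by(.data$peptide_id, .data$channel) %>%
    summarise(n_quant = sum(.data$is_quantifier), n_tr = dplyr::n(),
              .groups = "drop")
  for (i in seq_len(nrow(per_chan))) {
    if (per_chan$n_quant[i] != 1L) {
      say("%s/%s: expected exactly 1 quantifier transition, found %d",
          per_chan$peptide_id[i], per_chan$channel[i], per_chan$n_quant[i])
    }
    if (per_chan$n_tr[i] != 3L) {
      say("%s/%s: expected 3 transitions, found %d",
          per_chan$peptide_id[i], per_chan$channel[i], per_chan$n_tr[i])
    }
  }

  for (pid in unique(assay$peptide_id)) {
    light <- filter(assay, .data$peptide_id == pid, .data$channel == "light")
    heavy <- filter(assay, .data$peptide_id == pid, .data$channel == "heavy")
    if (nrow(light) == 0 || nrow(heavy) == 0) {
      say("%s: missing %s channel", pid,
          if (nrow(light) == 0) "light" else "heavy")
      next
    }
    if (nrow(heavy) < nrow(light)) {
      say("%s: %d light transitions but only %d heavy partners",
          pid, nrow(light), nrow(heavy))
    }
    if (length(unique(c(light$expected_rt, heavy$expected_rt))) != 1L) {
      say("%s: heavy expected_rt differs from light (SIL must co-elute)", pid)
    }
    if (any(heavy$precursor_mz <= light$precursor_mz[1])) {
      say("%s: heavy precursor m/z not greater than light", pid)
    }
  }
  msgs
}

#' Read or write an assay definition as a YAML config
#'
#' The assay tibble is serialized one peptide per block, with per-channel
#' transition lists; re-reading reproduces the tibble field-for-field. A
#' packaged copy of the default cetuximab assay ships at
#' `system.file("extdata", "cetuximab_assay.yaml", package = "srmtdm")`.
#'
#' @param assay An assay tibble ([cetuximab_assay()]).
#' @param path File path of the YAML document.
#' @return `read_assay()` returns the assay tibble; `write_assay()` returns
#'   `path` invisibly.
#' @export
write_assay <- function(assay, path) {
  peptides <- lapply(split(assay, assay$peptide_id), function(p) {
    list(
      peptide_id = p$peptide_id[1],
      sequence = unique(p$sequence[p$channel == "light"]),
      transitions = lapply(seq_len(nrow(p)), function(i) {
        as.list(p[i, c("channel", "average_mass", "precursor_mz",
                       "precursor_charge", "product_mz", "product_label",
                       "collision_energy", "expected_rt", "is_quantifier")])
      })
    )
  })
  yaml::write_yaml(list(peptides = unname(peptides)), path,
                   precision = 12L)
  invisible(path)
}

#' @rdname write_assay
#' @export
read_assay <- function(path) {
  doc <- yaml::read_yaml(path)
  if (is.null(doc$peptides)) abort("assay config has no 'peptides' section")
  out <- purrr::map_dfr(doc$peptides, function(p) {
    purrr::map_dfr(p$transitions, as_tibble) %>%
      mutate(peptide_id = p$peptide_id, sequence = p$sequence)
  })
  out %>%
    mutate(precursor_charge = as.integer(.data$precursor_charge)) %>%
    select("peptide_id", "sequence", "average_mass", "channel",
           "precursor_mz", "precursor_charge", "product_mz", "product_label",
           "collision_energy", "expected_rt", "is_quantifier")
}
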