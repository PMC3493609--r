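#' Correct a quantified concentration for surrogate losses
#'
#' Targeted assays spike deuterated surrogates before extraction; dividing
#' the raw concentration by the observed surrogate recovery corrects for
#' analyte loss during sample preparation.
#'
#' @param raw_concentration Positive raw concentration(s).
#' @param surrogate_recovery Recovery fraction(s), strictly positive
#'   (1 means full recovery).
#' @return `raw_concentration / surrogate_recovery`.
#' @export
correct_surrogate_loss <- function(raw_concentration, surrogate_recovery) {
  if (any(!is.finite(raw_concentration)) || any(!is.finite(surrogate_recovery))) {
    abort("raw concentration and recovery must be finite")
  }
  if (any(surrogate_recovery <= 0)) {
    abort("surrogate recovery must be > 0 to correct for losses")
  }
  raw_concentration / surrogate_recovery
}

#' Build a table of per-analyte quantification records
#'
#' @param analyte Analyte identifiers.
#' @param raw_concentration Positive raw concentrations.
#' @param signal_to_noise Non-negative S/N ratios.
#' @param surrogate_recovery Recovery fractions (>= 0).
#' @param lowest_calibrant Positive lowest calibration-curve concentrations.
#' @return A tibble, one record per row.
#' @export
quant_records <- function(analyte, raw_concentration, signal_to_noise,
                          surrogate_recovery, lowest_calibrant) {
  rec <- tibble(analyte = as.character(analyte),
                raw_concentration = raw_concentration,
                signal_to_noise = signal_to_noise,
                surrogate_recovery = surrogate_recovery,
                lowest_calibrant = lowest_calibrant)
  num <- rec[, -1]
  if (any(!vapply(num, is.numeric, logical(1))) ||
      any(!is.finite(as.matrix(num)))) {
    abort("all quantification fields must be finite numbers")
  }
  if (any(rec$raw_concentration <= 0) || any(rec$lowest_calibrant <= 0)) {
    abort("raw concentrations and lowest calibrants must be positive")
  }
  if (any(rec$signal_to_noise < 0) || any(rec$surrogate_recovery < 0)) {
    abort("signal-to-noise and recovery must be non-negative")
  }
  rec
}

#' Apply analyte reporting criteria
#'
#' A record fails reporting if its signal-to-noise ratio is below `sn_min`,
#' its calculated concentration is below the lowest calibrant, or its
#' surrogate recovery is below `recovery_min`. All three rules are strict
#' inequalities, so a record exactly at a threshold is kept.
#'
#' @param records A tibble from [quant_records()].
#' @param sn_min Minimum signal-to-noise ratio (default 2).
#' @param recovery_min Minimum surrogate recovery fraction (default 0.40).
#' @return A list with `kept` (records passing every rule) and `dropped`
#'   (failing records with a `reasons` column listing every triggered rule,
#'   separated by `"; "`).
#' @export
apply_reporting_criteria <- function(records, sn_min = 2, recovery_min = 0.40) {
  if (sn_min <= 0 || recovery_min <= 0) abort("reporting thresholds must be positive")
  fail_sn <- records$signal_to_noise < sn_min
  fail_cal <- records$raw_concentration < records$lowest_calibrant
  fail_rec <- records$surrogate_recovery < recovery_min
  reasons <- purrr::pmap_chr(
    list(fail_sn, fail_cal, fail_rec),
    function(s, c, r) {
      paste(c(if (s) sprintf("S/N < %g", sn_min),
              if (c) "below lowest calibrant",
              if (r) sprintf("recovery < %g%%", 100 * recovery_min)),
            collapse = "; ")
    })
  drop <- fail_sn | fail_cal | fail_rec
  dropped <- records[drop, , drop = FALSE]
  dropped$reasons <- reasons[drop]
  list(kept = records[!drop, , drop = FALSE], dropped = dropped)
}

#' Mask or exclude unreportable measurements in a cohort table
#'
#' The reporting criteria act per measurement, but a panel-level decision is
#' needed for metabolites that are partly unreportable. Two policies are
#' supported: mask the offending measurements per subject (`"per_subject"`),
#' or drop a metabolite from the panel entirely when more than
#' `max_unreportable` of either group's measurements are unreportable
#' (`"exclude_metabolite"`, the default).
#'
#' @param table A `cohort_tbl`.
#' @param unreportable Logical subjects-by-metabolites matrix (TRUE = failed
#'   reporting), with column names matching metabolite columns.
#' @param mode `"exclude_metabolite"` or `"per_subject"`.
#' @param max_unreportable Group-wise fraction above which a metabolite is
#'   excluded (default 0.5).
#' @return A `cohort_tbl` with masked values and/or dropped columns.
#' @export
mask_unreportable <- function(table, unreportable,
                              mode = c("exclude_metabolite", "per_subject"),
                              max_unreportable = 0.5) {
  mode <- match.arg(mode)
  mets <- intersect(metabolite_names(table), colnames(unreportable))
  out <- table
  for (m in mets) {
    out[[m]][unreportable[, m]] <- NA_real_
  }
  if (mode == "exclude_metabolite") {
    frac <- vapply(mets, function(m) {
      max(tapply(unreportable[, m], table$group, mean))
    }, numeric(1))
    drop <- mets[frac > max_unreportable]
    if (length(drop) > 0) {
      out <- out[, setdiff(names(out), drop)]
    }
  }
  out
}
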