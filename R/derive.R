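#' Derive analysis features for a cohort
#'
#' Turns raw patient records into the analysis table: applies the optional
#' VAC restriction, excludes patients missing height, gender, or all daily
#' tidal volumes (with a per-reason exclusion count mirroring the study flow
#' diagram), then computes predicted body weight, the lowest standardized
#' tidal volume, the pooled-cohort height z-score, the hypoxemia severity
#' band (ARDS cohort only), and the analysis subgroup.
#'
#' @param records Cohort tibble from [read_cohort()] or [generate_cohort()].
#' @param config A [cohort_config()].
#' @return The analyzable records with added columns `pbw_kg`,
#'   `vhat_lowest`, `height_z`, `severity`, `subgroup`. Exclusion counts are
#'   in `attr(, "exclusions")`; the VAC filter report (when used) in
#'   `attr(, "vac_report")`.
#' @examples
#' cohort <- generate_cohort(cohort_sim_config(n_ards = 60, n_control = 30,
#'                                             seed = 1))
#' derived <- derive_features(cohort$records)
#' dplyr::count(derived, subgroup)
#' @export
derive_features <- function(records, config = cohort_config()) {
  stopifnot(is.data.frame(records))
  vac_report <- NULL
  if (isTRUE(config$vac_filter)) {
    records <- vac_filter(records)
    vac_report <- attr(records, "vac_report")
  }

  no_height <- is.na(records$height_cm)
  no_gender <- is.na(records$gender)
  no_vt <- map_lgl(records$daily_vt_ml, function(v) all(is.na(v)) || length(v) == 0L)
  excluded <- no_height | no_gender | no_vt
  exclusions <- tibble(
    reason = c("missing_height", "missing_gender", "no_tidal_volume"),
    n = c(sum(no_height), sum(no_gender), sum(no_vt))
  )
  out <- records[!excluded, , drop = FALSE]
  if (nrow(out) == 0L) abort("no analyzable patients after exclusions")

  out$pbw_kg <- compute_pbw(out$height_cm, out$gender)
  out$vhat_lowest <- map2_dbl(out$daily_vt_ml, out$pbw_kg,
                              lowest_standardized_vt)
  out$height_z <- height_zscore(out$height_cm)

  pf <- if (config$severity_basis == "lowest") out$pf_lowest else out$pf_entry
  is_ards <- out$cohort == "ARDS"
  if (any(!is.na(pf[is_ards]) & pf[is_ards] > 300)) {
    abort("ARDS-cohort patient with PaO2/FiO2 above 300 mm Hg")
  }
  out$severity <- NA_character_
  out$severity[is_ards] <- assign_severity(pf[is_ards])

  out$subgroup <- assign_subgroup(out$cohort, out$doc_entry, out$doc_end,
                                  rule = config$documentation_rule)

  attr(out, "exclusions") <- exclusions
  attr(out, "vac_report") <- vac_report
  attr(out, "config") <- config
  out
}
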