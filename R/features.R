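#' Predicted body weight from height and gender
#'
#' Computes predicted body weight (PBW, kg) using the ARDSNet convention:
#' males `50 + 0.91 * (height - 152.4)`, females `45.5 + 0.91 * (height -
#' 152.4)`. PBW is the denominator of the standardized tidal volume
#' (mL/kg PBW) used throughout the package.
#'
#' @param height_cm Numeric vector of heights in cm. Values must lie in the
#'   plausible adult range \[120, 220\].
#' @param gender Character vector, `"male"` or `"female"`, recycled against
#'   `height_cm` if length 1.
#' @return Numeric vector of predicted body weights in kg.
#' @examples
#' compute_pbw(152.4, "male") # 50
#' compute_pbw(c(175, 160), c("male", "female"))
#' @export
compute_pbw <- function(height_cm, gender) {
  if (length(gender) == 1L) gender <- rep(gender, length(height_cm))
  stopifnot(length(gender) == length(height_cm))
  bad_gender <- !is.na(gender) & !gender %in% c("male", "female")
  if (any(bad_gender)) {
    abort(paste0("unknown gender code(s): ",
                 paste(unique(gender[bad_gender]), collapse = ", ")))
  }
  ok <- !is.na(height_cm)
  if (any(height_cm[ok] < 120)) {
    abort("height_cm below lower plausibility bound of 120 cm")
  }
  if (any(height_cm[ok] > 220)) {
    abort("height_cm above upper plausibility bound of 220 cm")
  }
  base <- if_else(gender == "male", 50, 45.5)
  base + 0.91 * (height_cm - 152.4)
}

#' Lowest standardized tidal volume across study days
#'
#' The lowest standardized tidal volume V^T (mL/kg PBW) is the minimum over
#' non-missing study days of the delivered tidal volume divided by predicted
#' body weight. A patient with no recorded tidal volume on any day yields
#' `NA`, the feature-missing marker that triggers exclusion downstream.
#'
#' @param daily_vt_ml Numeric vector of daily tidal volumes in mL (may
#'   contain `NA` for unrecorded days).
#' @param pbw_kg Predicted body weight in kg (positive scalar).
#' @return Scalar: the lowest V^T in mL/kg PBW, or `NA_real_` if no day has
#'   a recorded tidal volume.
#' @examples
#' lowest_standardized_vt(c(500, 450, 480), 70.566)
#' lowest_standardized_vt(c(NA, 400), 80)
#' @export
lowest_standardized_vt <- function(daily_vt_ml, pbw_kg) {
  stopifnot(length(pbw_kg) == 1L, is.finite(pbw_kg), pbw_kg > 0)
  vt <- daily_vt_ml[!is.na(daily_vt_ml)]
  if (length(vt) == 0L) return(NA_real_)
  min(vt) / pbw_kg
}

#' Height z-scores against a reference set
#'
#' Standardizes heights against the mean and sample (n-1) standard deviation
#' of a reference set, by default the heights themselves (the pooled
#' analysis cohort). The output has mean 0 and sd 1 over the reference set.
#'
#' @param heights_cm Numeric vector of heights to standardize.
#' @param reference Numeric vector defining the reference population
#'   (default: `heights_cm`). Needs at least two distinct non-missing values.
#' @return Numeric vector of z-scores.
#' @examples
#' height_zscore(c(160, 170, 180))
#' @export
height_zscore <- function(heights_cm, reference = heights_cm) {
  ref <- reference[!is.na(reference)]
  if (length(unique(ref)) < 2L) {
    abort("height z-score reference needs at least 2 distinct values")
  }
  s <- sd(ref)
  if (!is.finite(s) || s == 0) {
    abort("zero variance in height z-score reference set")
  }
  (heights_cm - mean(ref)) / s
}

#' Hypoxemia severity category from the PaO2/FiO2 ratio
#'
#' Berlin-definition severity bands: mild `200 < PF <= 300`, moderate
#' `100 < PF <= 200`, severe `PF <= 100` (mm Hg). ARDS-cohort patients must
#' have `PF <= 300`; larger values raise a validation error.
#'
#' @param pf_lowest Numeric vector of PaO2/FiO2 ratios (mm Hg); `NA` allowed
#'   and propagated.
#' @return Character vector with levels `"mild"`, `"moderate"`, `"severe"`.
#' @examples
#' assign_severity(c(250, 200, 100))
#' @export
assign_severity <- function(pf_lowest) {
  ok <- !is.na(pf_lowest)
  if (any(pf_lowest[ok] <= 0)) {
    abort("PaO2/FiO2 must be positive")
  }
  if (any(pf_lowest[ok] > 300)) {
    abort("PaO2/FiO2 above 300 mm Hg: outside the ARDS severity range")
  }
  case_when(
    is.na(pf_lowest) ~ NA_character_,
    pf_lowest <= 100 ~ "severe",
    pf_lowest <= 200 ~ "moderate",
    TRUE ~ "mild"
  )
}

#' Analysis subgroup from cohort and documentation flags
#'
#' Splits patients into the three analysis subgroups. Under the default
#' `both_forms` rule a patient counts as documented only when ARDS was
#' selected on both the study-entry and study-end case report forms; the
#' `end_form_only` sensitivity rule uses the study-end form alone.
#' Documented patients from either cohort form the pooled documented
#' subgroup; the remainder split by cohort.
#'
#' @param cohort Character vector, `"ARDS"` or `"control"`.
#' @param doc_entry,doc_end Logical vectors: ARDS selected on the
#'   study-entry / study-end case report form.
#' @param rule Documentation rule, `"both_forms"` (default) or
#'   `"end_form_only"`.
#' @return Character vector with levels `"pooled_documented"`,
#'   `"ards_non_documented"`, `"control_non_documented"`.
#' @examples
#' assign_subgroup("ARDS", TRUE, TRUE)
#' assign_subgroup("ARDS", TRUE, FALSE)
#' @export
assign_subgroup <- function(cohort, doc_entry, doc_end,
                            rule = c("both_forms", "end_form_only")) {
  rule <- match.arg(rule)
  bad <- !is.na(cohort) & !cohort %in% c("ARDS", "control")
  if (any(bad)) {
    abort(paste0("unknown cohort label(s): ",
                 paste(unique(cohort[bad]), collapse = ", ")))
  }
  documented <- if (rule == "both_forms") doc_entry & doc_end else doc_end
  case_when(
    documented ~ "pooled_documented",
    cohort == "ARDS" ~ "ards_non_documented",
    TRUE ~ "control_non_documented"
  )
}
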