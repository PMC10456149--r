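#' Analysis configuration
#'
#' Bundles the switches that define one analysis run: the documentation rule
#' (primary definition requires ARDS on both case report forms; the
#' sensitivity definition uses the study-end form only), the optional
#' restriction to patients ventilated on assist control/volume control (VAC)
#' on a majority of days, the z-score reference population, and which
#' PaO2/FiO2 measurement drives the severity bands.
#'
#' @param documentation_rule `"both_forms"` (default) or `"end_form_only"`.
#' @param vac_filter Logical: restrict to VAC-majority patients.
#' @param zscore_reference Currently only `"pooled_cohorts"`: heights are
#'   standardized against the pooled analyzable cohort (ARDS + control).
#' @param severity_basis `"lowest"` (default) or `"entry"`: which PF value
#'   defines hypoxemia severity.
#' @return A list of class `cohort_config`.
#' @examples
#' cohort_config(documentation_rule = "end_form_only")
#' @export
cohort_config <- function(documentation_rule = c("both_forms", "end_form_only"),
                          vac_filter = FALSE,
                          zscore_reference = "pooled_cohorts",
                          severity_basis = c("lowest", "entry")) {
  documentation_rule <- match.arg(documentation_rule)
  severity_basis <- match.arg(severity_basis)
  zscore_reference <- match.arg(zscore_reference, "pooled_cohorts")
  stopifnot(is.logical(vac_filter), length(vac_filter) == 1L)
  structure(
    list(documentation_rule = documentation_rule,
         vac_filter = vac_filter,
         zscore_reference = zscore_reference,
         severity_basis = severity_basis),
    class = "cohort_config"
  )
}

# Scalar columns of the cohort CSV schema, in canonical order.
cohort_scalar_cols <- function() {
  c("patient_id", "cohort", "gender", "height_cm", "age_years",
    "admission_weight_kg", "region",
    "pf_entry", "pf_end", "pf_lowest",
    "pplat_entry", "pplat_end", "pplat_highest",
    "cxr_quadrants_entry", "cxr_quadrants_end", "cxr_quadrants_highest",
    "sofa_entry", "sofa_end", "sofa_highest",
    "doc_entry", "doc_end")
}

#' Read a patient cohort from CSV
#'
#' Reads the documented cohort schema: one row per patient, scalar clinical
#' columns plus day-indexed columns `vt_d1..vt_dK` (tidal volume, mL) and
#' `mode_d1..mode_dK` (ventilator mode codes). Day columns are gathered into
#' the list-columns `daily_vt_ml` and `daily_mode`. Empty cells become
#' missing values, never zeros. Rows with an unknown gender code or a
#' non-numeric height are reported with their row numbers and dropped;
#' duplicated patient ids are a fatal error.
#'
#' @param path Path to a UTF-8 CSV file.
#' @param config A [cohort_config()] (kept for provenance; attached to the
#'   result).
#' @return A tibble of patient records with list-columns `daily_vt_ml` and
#'   `daily_mode`; dropped rows are described in `attr(, "problems")`.
#' @seealso [write_cohort()]
#' @export
read_cohort <- function(path, config = cohort_config()) {
  if (!file.exists(path)) abort(paste0("cohort file not found: ", path))
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  needed <- cohort_scalar_cols()
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols)) {
    abort(paste0("cohort header is missing required column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(raw$patient_id)) {
    abort(paste0("duplicate patient_id values: ",
                 paste(unique(raw$patient_id[duplicated(raw$patient_id)]),
                       collapse = ", ")))
  }

  problems <- tibble(row = integer(), column = character(), issue = character())
  note <- function(rows, column, issue) {
    if (length(rows)) {
      problems <<- bind_rows(problems,
                             tibble(row = as.integer(rows), column = column,
                                    issue = issue))
    }
  }

  num <- function(x) suppressWarnings(as.numeric(x))
  lgl <- function(x) {
    out <- rep(NA, length(x))
    out[!is.na(x) & toupper(x) %in% c("TRUE", "T", "1")] <- TRUE
    out[!is.na(x) & toupper(x) %in% c("FALSE", "F", "0")] <- FALSE
    out
  }

  bad_gender <- which(!is.na(raw$gender) & !raw$gender %in% c("male", "female"))
  note(bad_gender, "gender", "unknown gender code")
  bad_height <- which(!is.na(raw$height_cm) & is.na(num(raw$height_cm)))
  note(bad_height, "height_cm", "non-numeric height")

  numeric_cols <- setdiff(needed, c("patient_id", "cohort", "gender", "region",
                                    "doc_entry", "doc_end"))
  rec <- tibble(
    patient_id = raw$patient_id,
    cohort = raw$cohort,
    gender = raw$gender,
    region = raw$region,
    doc_entry = lgl(raw$doc_entry),
    doc_end = lgl(raw$doc_end)
  )
  for (cl in numeric_cols) rec[[cl]] <- num(raw[[cl]])

  cxr_cols <- grep("^cxr_quadrants_", numeric_cols, value = TRUE)
  for (cl in cxr_cols) {
    bad <- which(!is.na(rec[[cl]]) & !rec[[cl]] %in% 0:4)
    note(bad, cl, "chest imaging quadrants outside 0..4")
  }

  vt_cols <- grep("^vt_d[0-9]+$", names(raw), value = TRUE)
  mode_cols <- grep("^mode_d[0-9]+$", names(raw), value = TRUE)
  vt_cols <- vt_cols[order(as.integer(sub("^vt_d", "", vt_cols)))]
  mode_cols <- mode_cols[order(as.integer(sub("^mode_d", "", mode_cols)))]
  if (length(vt_cols)) {
    vt_mat <- vapply(raw[vt_cols], num, numeric(nrow(raw)))
    vt_mat <- matrix(vt_mat, nrow = nrow(raw))
    rec$daily_vt_ml <- lapply(seq_len(nrow(raw)), function(i) unname(vt_mat[i, ]))
  } else {
    rec$daily_vt_ml <- rep(list(numeric(0)), nrow(raw))
  }
  if (length(mode_cols)) {
    md <- as.matrix(raw[mode_cols])
    rec$daily_mode <- lapply(seq_len(nrow(raw)), function(i) unname(md[i, ]))
  } else {
    rec$daily_mode <- rep(list(character(0)), nrow(raw))
  }

  drop_rows <- sort(unique(problems$row[problems$issue %in%
    c("unknown gender code", "non-numeric height",
      "chest imaging quadrants outside 0..4")]))
  if (length(drop_rows)) {
    warn(paste0("dropping ", length(drop_rows), " malformed record(s) at row(s): ",
                paste(drop_rows, collapse = ", ")))
    rec <- rec[-drop_rows, , drop = FALSE]
  }
  attr(rec, "problems") <- problems
  attr(rec, "config") <- config
  rec
}

#' Write a patient cohort to CSV
#'
#' Inverse of [read_cohort()]: spreads the `daily_vt_ml` and `daily_mode`
#' list-columns back into `vt_d1..vt_dK` / `mode_d1..mode_dK` columns and
#' writes a UTF-8 CSV with empty cells for missing values.
#'
#' @param records Cohort tibble as produced by [read_cohort()] or
#'   [generate_cohort()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(records, path) {
  stopifnot(is.data.frame(records))
  k_vt <- max(c(0L, lengths(records$daily_vt_ml)))
  k_md <- max(c(0L, lengths(records$daily_mode)))
  out <- records[intersect(cohort_scalar_cols(), names(records))]
  pad <- function(x, k, fill) c(x, rep(fill, k - length(x)))
  if (k_vt > 0) {
    vt <- t(vapply(records$daily_vt_ml, pad, numeric(k_vt), k = k_vt,
                   fill = NA_real_))
    vt <- matrix(vt, ncol = k_vt)
    colnames(vt) <- paste0("vt_d", seq_len(k_vt))
    out <- dplyr::bind_cols(out, as_tibble(vt))
  }
  if (k_md > 0) {
    md <- t(vapply(records$daily_mode, pad, character(k_md), k = k_md,
                   fill = NA_character_))
    md <- matrix(md, ncol = k_md)
    colnames(md) <- paste0("mode_d", seq_len(k_md))
    out <- dplyr::bind_cols(out, as_tibble(md))
  }
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' Restrict to assist-control-majority patients
#'
#' Keeps patients whose ventilator mode was the assist control/volume
#' control code on a strict majority (more than half) of the days with a
#' recorded mode. Ties and patients with no mode data are excluded; the
#' exclusion counts are attached as `attr(, "vac_report")`.
#'
#' @param records Cohort tibble with a `daily_mode` list-column.
#' @param vac_code Mode code treated as assist control/volume control
#'   (default `"VAC"`).
#' @return The filtered tibble.
#' @export
vac_filter <- function(records, vac_code = "VAC") {
  stopifnot(is.data.frame(records), "daily_mode" %in% names(records))
  frac <- map_dbl(records$daily_mode, function(m) {
    m <- m[!is.na(m)]
    if (length(m) == 0L) return(NA_real_)
    mean(m == vac_code)
  })
  keep <- !is.na(frac) & frac > 0.5
  out <- records[keep, , drop = FALSE]
  attr(out, "vac_report") <- tibble(
    n_input = nrow(records),
    n_retained = sum(keep),
    n_no_mode_data = sum(is.na(frac)),
    n_minority_or_tie = sum(!is.na(frac) & frac <= 0.5)
  )
  out
}
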