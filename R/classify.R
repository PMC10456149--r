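#' Classify non-documented ARDS patients as recognized or unrecognized
#'
#' Applies the naive Bayes rule pointwise: a patient is `"recognized"` when
#' the documented-class posterior at their (X, lowest V^T) point exceeds
#' 0.5, `"unrecognized"` otherwise. A posterior of exactly 0.5 — including
#' points outside the support of both densities — is conservatively labelled
#' unrecognized. Wherever the boundary is defined this is equivalent to the
#' below/above-boundary rule.
#'
#' @param data Tibble of patients to classify (typically the
#'   `ards_non_documented` subgroup) with the model's X and vhat columns.
#' @param model_doc,model_ctrl `vt_kde` models.
#' @param x,vhat Column names (defaults `"height_z"`, `"vhat_lowest"`).
#' @param eps Density floor.
#' @return `data` with added columns `posterior`, `out_of_support`,
#'   `recognition` (`"recognized"`/`"unrecognized"`).
#' @export
classify_patients <- function(data, model_doc, model_ctrl,
                              x = "height_z", vhat = "vhat_lowest",
                              eps = 1e-12) {
  stopifnot(is.data.frame(data), x %in% names(data), vhat %in% names(data))
  post <- posterior_documented(data[[x]], data[[vhat]], model_doc, model_ctrl,
                               eps = eps)
  data$posterior <- post$posterior
  data$out_of_support <- post$out_of_support
  data$recognition <- if_else(post$posterior > 0.5, "recognized",
                              "unrecognized")
  data
}

#' Recognition rates by hypoxemia severity
#'
#' Combines documentation and classification into the recognition report:
#' every documented ARDS patient counts as recognized; non-documented ARDS
#' patients count as recognized when the classifier labelled them so. Per
#' severity stratum the recognition rate is
#' `100 * (n_documented + n_classified_recognized) / n_ards`. Strata with no
#' patients are reported as absent.
#'
#' @param data Derived ARDS-cohort tibble (control rows are ignored) with
#'   columns `subgroup`, `severity`, and — for the
#'   `ards_non_documented` rows — the `recognition` column added by
#'   [classify_patients()].
#' @param config Optional [cohort_config()] echoed into the report.
#' @return Tibble of class `recognition_report`: one row per severity with
#'   `n_ards`, `n_documented`, `documentation_rate`, `n_recognized`,
#'   `recognition_rate` (percent), plus an `"overall"` attribute row.
#' @examples
#' df <- tibble::tibble(
#'   cohort = "ARDS",
#'   severity = rep("mild", 30),
#'   subgroup = rep(c("pooled_documented", "ards_non_documented"), c(10, 20)),
#'   recognition = rep(c(NA, "recognized", "unrecognized"), c(10, 5, 15))
#' )
#' recognition_report(df)
#' @export
recognition_report <- function(data, config = NULL) {
  stopifnot(is.data.frame(data),
            all(c("subgroup", "severity") %in% names(data)))
  ards <- filter(data, .data$cohort == "ARDS")
  nondoc <- ards$subgroup == "ards_non_documented"
  if (any(nondoc) &&
      (!"recognition" %in% names(ards) ||
       any(is.na(ards$recognition[nondoc])))) {
    abort("every non-documented ARDS patient must carry a recognition label")
  }
  if (!"recognition" %in% names(ards)) ards$recognition <- NA_character_
  ards$recognized <- ards$subgroup == "pooled_documented" |
    (nondoc & !is.na(ards$recognition) & ards$recognition == "recognized")
  ards$documented <- ards$subgroup == "pooled_documented"

  summarize_stratum <- function(d) {
    tibble(
      n_ards = nrow(d),
      n_documented = sum(d$documented),
      documentation_rate = 100 * sum(d$documented) / nrow(d),
      n_recognized = sum(d$recognized),
      recognition_rate = 100 * sum(d$recognized) / nrow(d)
    )
  }
  strata <- c("mild", "moderate", "severe")
  rows <- lapply(strata, function(s) {
    d <- filter(ards, .data$severity == s)
    if (nrow(d) == 0L) return(NULL)
    mutate(summarize_stratum(d), severity = s, .before = 1)
  })
  out <- bind_rows(rows)
  class(out) <- c("recognition_report", class(out))
  attr(out, "overall") <- summarize_stratum(ards)
  attr(out, "n_unclassified_severity") <- sum(is.na(ards$severity))
  attr(out, "config") <- config
  out
}

#' @export
print.recognition_report <- function(x, ...) {
  cat("Clinician ARDS recognition by hypoxemia severity\n")
  cat(sprintf("%-10s %10s %18s %18s\n", "Severity", "N", "Documented N (%)",
              "Recognized N (%)"))
  for (i in seq_len(nrow(x))) {
    cat(sprintf("%-10s %10d %12d (%2.0f) %12d (%2.0f)\n",
                x$severity[i], x$n_ards[i],
                x$n_documented[i], x$documentation_rate[i],
                x$n_recognized[i], x$recognition_rate[i]))
  }
  ov <- attr(x, "overall")
  cat(sprintf("%-10s %10d %12d (%2.0f) %12d (%2.0f)\n", "overall",
              ov$n_ards, ov$n_documented, ov$documentation_rate,
              ov$n_recognized, ov$recognition_rate))
  invisible(x)
}

#' @rdname recognition_report
#' @param x A `recognition_report`.
#' @param ... Unused.
#' @method tidy recognition_report
#' @export
tidy.recognition_report <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- setdiff(class(out), "recognition_report")
  out
}

#' @rdname recognition_report
#' @method glance recognition_report
#' @export
glance.recognition_report <- function(x, ...) {
  ov <- attr(x, "overall")
  wide <- tidyr::pivot_wider(
    select(tidy(x), "severity", "recognition_rate"),
    names_from = "severity", values_from = "recognition_rate",
    names_prefix = "recognition_rate_"
  )
  dplyr::bind_cols(
    tibble(n_ards = ov$n_ards,
           overall_documentation_rate = ov$documentation_rate,
           overall_recognition_rate = ov$recognition_rate),
    wide
  )
}

#' Plot a recognition report
#'
#' @param object A `recognition_report`.
#' @param ... Unused.
#' @return A ggplot comparing documentation and estimated recognition rates
#'   per severity stratum.
#' @method autoplot recognition_report
#' @export
autoplot.recognition_report <- function(object, ...) {
  df <- tidyr::pivot_longer(
    select(tidy(object), "severity", "documentation_rate",
           "recognition_rate"),
    cols = -"severity", names_to = "measure", values_to = "rate"
  )
  df$measure <- if_else(df$measure == "documentation_rate", "documented",
                        "recognized (estimated)")
  df$severity <- factor(df$severity, levels = c("mild", "moderate", "severe"))
  ggplot(df, aes(x = .data$severity, y = .data$rate, fill = .data$measure)) +
    geom_col(position = "dodge") +
    labs(x = "hypoxemia severity", y = "rate (%)", fill = NULL,
         title = "ARDS documentation vs estimated recognition") +
    ylim(0, 100) +
    theme_minimal()
}
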