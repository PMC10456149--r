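#' Bonferroni-corrected significance threshold
#'
#' @param alpha Family-wise alpha (default 0.01).
#' @param m Number of comparisons in the family.
#' @return `alpha / m`, at full precision (display may round, e.g.
#'   `0.01/111` prints as 0.00009).
#' @examples
#' bonferroni_threshold(0.01, 111)
#' bonferroni_threshold(0.01, 10)
#' @export
bonferroni_threshold <- function(alpha = 0.01, m) {
  stopifnot(length(alpha) == 1L, alpha > 0, alpha < 1)
  if (length(m) != 1L || is.na(m) || m < 1) {
    abort("m must be a positive integer number of comparisons")
  }
  alpha / m
}

#' Factor accessors for the tidal-volume screen
#'
#' Returns the catalogue of candidate predictors of lowest standardized
#' tidal volume: each entry maps the derived cohort table to one numeric
#' factor. Documentation flags are coded 0/1, region as an integer level
#' code, and ventilator modality as the fraction of recorded days on the
#' assist control/volume control mode.
#'
#' @param vac_code Mode code treated as assist control (default `"VAC"`).
#' @return Named list of accessor functions `data -> numeric vector`.
#' @export
ards_factor_specs <- function(vac_code = "VAC") {
  frac_vac <- function(data) {
    map_dbl(data$daily_mode, function(m) {
      m <- m[!is.na(m)]
      if (length(m) == 0L) return(NA_real_)
      mean(m == vac_code)
    })
  }
  list(
    height_z = function(d) d$height_z,
    pf_entry = function(d) d$pf_entry,
    pf_end = function(d) d$pf_end,
    pf_lowest = function(d) d$pf_lowest,
    doc_entry = function(d) as.numeric(d$doc_entry),
    doc_end = function(d) as.numeric(d$doc_end),
    doc_both = function(d) as.numeric(d$doc_entry & d$doc_end),
    pplat_entry = function(d) d$pplat_entry,
    pplat_end = function(d) d$pplat_end,
    pplat_highest = function(d) d$pplat_highest,
    cxr_entry = function(d) d$cxr_quadrants_entry,
    cxr_end = function(d) d$cxr_quadrants_end,
    cxr_highest = function(d) d$cxr_quadrants_highest,
    sofa_entry = function(d) d$sofa_entry,
    sofa_end = function(d) d$sofa_end,
    sofa_highest = function(d) d$sofa_highest,
    admission_weight = function(d) d$admission_weight_kg,
    age = function(d) d$age_years,
    region = function(d) as.numeric(as.integer(factor(d$region))),
    modality = frac_vac
  )
}

#' Univariable OLS with a standardized predictor
#'
#' Fits `y ~ z(x)` by ordinary least squares, where `z(x)` is the predictor
#' standardized to mean 0 and sd 1 over the complete cases. The outcome is
#' left on its own scale (mL/kg PBW for the tidal-volume screen), so the
#' standardized coefficient is the change in outcome per 1 sd of the
#' predictor. The 95% CI uses the normal approximation `beta +/- 1.96 se`.
#'
#' @param x Numeric predictor.
#' @param y Numeric outcome, same length.
#' @return One-row tibble: `beta_std`, `ci_low`, `ci_high`, `p_value`,
#'   `n_used`.
#' @examples
#' set.seed(1)
#' x <- rnorm(50, sd = 2)
#' univariable_std_ols(x, 3 * x)
#' @export
univariable_std_ols <- function(x, y) {
  keep <- complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L) abort("fewer than 3 complete (factor, outcome) pairs")
  if (sd(x) == 0) abort("zero-variance factor")
  z <- (x - mean(x)) / sd(x)
  fit <- lm(y ~ z)
  sm <- summary(fit)$coefficients
  beta <- sm["z", "Estimate"]
  se <- sm["z", "Std. Error"]
  tibble(
    beta_std = beta,
    ci_low = beta - qnorm(0.975) * se,
    ci_high = beta + qnorm(0.975) * se,
    p_value = sm["z", "Pr(>|t|)"],
    n_used = n
  )
}

#' Logistic regression of documentation on a standardized factor
#'
#' Fits a logistic regression of the documentation flag on the standardized
#' factor; the coefficient is on the log-odds scale per 1 sd of the factor.
#' Complete separation is detected (divergent coefficient or the fitted
#' probabilities collapsing to 0/1) and flagged rather than silently
#' returned.
#'
#' @param x Numeric factor.
#' @param documented Logical outcome, same length; both classes must occur.
#' @return One-row tibble: `beta_std`, `ci_low`, `ci_high`, `p_value`,
#'   `n_used`, `separation_flag`.
#' @export
logistic_documentation_fit <- function(x, documented) {
  keep <- complete.cases(x, documented)
  x <- x[keep]; documented <- as.logical(documented[keep])
  if (length(unique(documented)) < 2L) {
    abort("degenerate outcome: documentation has a single class")
  }
  if (sd(x) == 0) abort("zero-variance factor")
  z <- (x - mean(x)) / sd(x)
  sep <- FALSE
  fit <- withCallingHandlers(
    glm(documented ~ z, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)) ||
          grepl("did not converge", conditionMessage(w))) {
        sep <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  sm <- summary(fit)$coefficients
  beta <- sm["z", "Estimate"]
  se <- sm["z", "Std. Error"]
  if (abs(beta) > 15 || se > 100) sep <- TRUE
  tibble(
    beta_std = beta,
    ci_low = beta - qnorm(0.975) * se,
    ci_high = beta + qnorm(0.975) * se,
    p_value = sm["z", "Pr(>|z|)"],
    n_used = length(z),
    separation_flag = sep
  )
}

#' Univariable screen of tidal-volume predictors
#'
#' Runs [univariable_std_ols()] of the outcome (lowest standardized tidal
#' volume by default) on every factor in the catalogue, using complete
#' cases per factor. Factors that cannot be evaluated (zero variance, too
#' few complete cases) are kept in the output with a `note` rather than
#' aborting the screen. Significance is judged at the Bonferroni threshold
#' `alpha / m`; by default the family size `m` is the number of evaluable
#' tests in this screen, and it can be set to the family size of a wider
#' analysis.
#'
#' @param data Derived cohort tibble (see [derive_features()]).
#' @param outcome Name of the outcome column (default `"vhat_lowest"`).
#' @param factors Named list of accessors (default [ards_factor_specs()]).
#' @param alpha Family-wise alpha (default 0.01).
#' @param m Family size for the Bonferroni threshold; `NULL` means the
#'   number of evaluable factors in this call.
#' @return A tibble of class `ards_screen` with one row per factor:
#'   `factor`, `beta_std`, `ci_low`, `ci_high`, `p_value`, `n_used`,
#'   `availability`, `significant`, `note`. The threshold and family size
#'   are in attributes `threshold` and `m`.
#' @export
screen_vt <- function(data, outcome = "vhat_lowest",
                      factors = ards_factor_specs(),
                      alpha = 0.01, m = NULL) {
  stopifnot(is.data.frame(data), outcome %in% names(data))
  y <- data[[outcome]]
  rows <- purrr::imap(factors, function(fn, nm) {
    x <- fn(data)
    avail <- mean(!is.na(x))
    res <- tryCatch(univariable_std_ols(x, y), error = function(e) e)
    if (inherits(res, "error")) {
      tibble(factor = nm, beta_std = NA_real_, ci_low = NA_real_,
             ci_high = NA_real_, p_value = NA_real_, n_used = sum(complete.cases(x, y)),
             availability = avail, note = conditionMessage(res))
    } else {
      mutate(res, factor = nm, availability = avail, note = NA_character_,
             .before = 1)
    }
  })
  out <- bind_rows(rows)
  m_eff <- m %||% sum(is.na(out$note))
  thr <- bonferroni_threshold(alpha, m_eff)
  out$significant <- !is.na(out$p_value) & out$p_value < thr
  out <- select(out, "factor", "beta_std", "ci_low", "ci_high", "p_value",
                "n_used", "availability", "significant", "note")
  class(out) <- c("ards_screen", class(out))
  attr(out, "threshold") <- thr
  attr(out, "m") <- m_eff
  attr(out, "alpha") <- alpha
  attr(out, "outcome") <- outcome
  out
}

#' Covariance screen between significant factors
#'
#' Applies the two exclusion rules for joint use of factors: (a) a pair is
#' non-evaluable when the difference in data availability between its two
#' factors exceeds 10% of the cohort size; (b) remaining pairs are tested
#' for covariance by standardized pairwise OLS at the Bonferroni threshold
#' `alpha / m` (default 0.01/10), and significant pairs are flagged so only
#' one member enters a multivariable model.
#'
#' @param data Derived cohort tibble.
#' @param factor_names Character vector of factors to test pairwise.
#' @param factors Accessor catalogue (default [ards_factor_specs()]).
#' @param alpha,m Threshold parameters for the covariate test (defaults
#'   0.01 and 10, i.e. p < 0.001).
#' @param availability_frac Availability-difference cutoff as a fraction of
#'   cohort size (default 0.10).
#' @return Tibble with one row per unordered pair: `factor_a`, `factor_b`,
#'   `availability_a`, `availability_b`, `non_evaluable`, `beta_std`,
#'   `p_value`, `covariate`.
#' @export
covariance_screen <- function(data, factor_names,
                              factors = ards_factor_specs(),
                              alpha = 0.01, m = 10,
                              availability_frac = 0.10) {
  stopifnot(length(factor_names) >= 1L,
            all(factor_names %in% names(factors)))
  vals <- lapply(factors[factor_names], function(fn) fn(data))
  avail <- vapply(vals, function(x) mean(!is.na(x)), numeric(1))
  thr <- bonferroni_threshold(alpha, m)
  if (length(factor_names) < 2L) {
    return(tibble(factor_a = character(), factor_b = character(),
                  availability_a = numeric(), availability_b = numeric(),
                  non_evaluable = logical(), beta_std = numeric(),
                  p_value = numeric(), covariate = logical()))
  }
  pairs <- combn(factor_names, 2L)
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    a <- pairs[1, k]; b <- pairs[2, k]
    ne <- abs(avail[[a]] - avail[[b]]) > availability_frac
    if (ne) {
      tibble(factor_a = a, factor_b = b,
             availability_a = avail[[a]], availability_b = avail[[b]],
             non_evaluable = TRUE, beta_std = NA_real_, p_value = NA_real_,
             covariate = FALSE)
    } else {
      xa <- vals[[a]]; xb <- vals[[b]]
      keep <- complete.cases(xa, xb)
      fit <- tryCatch(
        univariable_std_ols(xa[keep], (xb[keep] - mean(xb[keep])) / sd(xb[keep])),
        error = function(e) NULL)
      tibble(factor_a = a, factor_b = b,
             availability_a = avail[[a]], availability_b = avail[[b]],
             non_evaluable = FALSE,
             beta_std = if (is.null(fit)) NA_real_ else fit$beta_std,
             p_value = if (is.null(fit)) NA_real_ else fit$p_value,
             covariate = !is.null(fit) && fit$p_value < thr)
    }
  })
  out <- bind_rows(rows)
  attr(out, "threshold") <- thr
  out
}

#' Enumerate candidate multivariable models
#'
#' Builds every non-empty subset of the admissible significant factors,
#' dropping subsets that contain a flagged covariate (or non-evaluable)
#' pair. When a subset contains both the documentation factor and the
#' severity factor, a second variant with their interaction term is added.
#'
#' @param significant_factors Character vector of factor names.
#' @param covariance Output of [covariance_screen()] (or `NULL` for no
#'   exclusions).
#' @param doc_factor,severity_factor Names of the documentation and
#'   severity (PaO2/FiO2) factors that may interact.
#' @return Tibble with columns `model_id`, `factors` (list-column),
#'   `interaction` (logical: documentation x severity term included).
#' @export
build_candidate_models <- function(significant_factors, covariance = NULL,
                                   doc_factor = "doc_both",
                                   severity_factor = "pf_lowest") {
  if (length(significant_factors) == 0L) {
    abort("no significant factors: cannot build candidate models")
  }
  banned <- list()
  if (!is.null(covariance) && nrow(covariance)) {
    flagged <- covariance[covariance$covariate | covariance$non_evaluable, ]
    banned <- purrr::map2(flagged$factor_a, flagged$factor_b, c)
  }
  subsets <- unlist(lapply(seq_along(significant_factors), function(k) {
    asplit(combn(significant_factors, k), 2)
  }), recursive = FALSE)
  admissible <- purrr::keep(subsets, function(s) {
    !any(map_lgl(banned, function(p) all(p %in% s)))
  })
  if (length(admissible) == 0L) {
    abort("covariance exclusions leave no admissible factor subset")
  }
  rows <- purrr::imap(admissible, function(s, i) {
    base <- tibble(factors = list(as.character(s)), interaction = FALSE)
    if (all(c(doc_factor, severity_factor) %in% s)) {
      bind_rows(base, tibble(factors = list(as.character(s)), interaction = TRUE))
    } else base
  })
  out <- bind_rows(rows)
  out$model_id <- seq_len(nrow(out))
  select(out, "model_id", "factors", "interaction")
}

#' Fit candidate models and select the best by BIC
#'
#' Fits each candidate multivariable OLS model (all predictors
#' standardized, complete cases per model), computes AIC and BIC, and
#' returns the fit minimizing BIC. When AIC and BIC disagree on the winner,
#' BIC wins and the disagreement is recorded. Non-convergent (rank
#' deficient) fits are dropped with a warning.
#'
#' @param data Derived cohort tibble.
#' @param candidates Tibble from [build_candidate_models()].
#' @param outcome Outcome column name (default `"vhat_lowest"`).
#' @param factors Accessor catalogue.
#' @param doc_factor,severity_factor Interaction term parents.
#' @return Tibble of class `ards_model_selection` with per-candidate `aic`,
#'   `bic`, `n_used`, `selected`; the winning [stats::lm] object is in
#'   `attr(, "best_fit")` and `attr(, "aic_bic_disagree")` records whether
#'   the two criteria picked different models.
#' @export
select_best_model <- function(data, candidates, outcome = "vhat_lowest",
                              factors = ards_factor_specs(),
                              doc_factor = "doc_both",
                              severity_factor = "pf_lowest") {
  stopifnot(nrow(candidates) >= 1L)
  y <- data[[outcome]]
  fits <- vector("list", nrow(candidates))
  stats_rows <- vector("list", nrow(candidates))
  for (i in seq_len(nrow(candidates))) {
    fnames <- candidates$factors[[i]]
    X <- lapply(factors[fnames], function(fn) fn(data))
    df <- as_tibble(c(list(.y = y), X))
    df <- df[complete.cases(df), ]
    df[fnames] <- lapply(df[fnames], function(x) (x - mean(x)) / sd(x))
    terms <- fnames
    if (isTRUE(candidates$interaction[i])) {
      terms <- c(terms, paste0(doc_factor, ":", severity_factor))
    }
    fml <- as.formula(paste(".y ~", paste(terms, collapse = " + ")))
    fit <- lm(fml, data = df)
    ok <- fit$rank == length(coef(fit)) && all(is.finite(coef(fit)))
    if (!ok) {
      warn(paste0("candidate model ", candidates$model_id[i],
                  " dropped: non-convergent/rank-deficient fit"))
      fits[[i]] <- NULL
      stats_rows[[i]] <- tibble(model_id = candidates$model_id[i],
                                aic = NA_real_, bic = NA_real_,
                                n_used = nrow(df), converged = FALSE)
    } else {
      fits[[i]] <- fit
      stats_rows[[i]] <- tibble(model_id = candidates$model_id[i],
                                aic = AIC(fit), bic = BIC(fit),
                                n_used = nrow(df), converged = TRUE)
    }
  }
  res <- left_join(candidates, bind_rows(stats_rows), by = "model_id")
  ok_idx <- which(res$converged)
  if (length(ok_idx) == 0L) abort("no candidate model converged")
  best_bic <- ok_idx[which.min(res$bic[ok_idx])]
  best_aic <- ok_idx[which.min(res$aic[ok_idx])]
  res$selected <- seq_len(nrow(res)) == best_bic
  class(res) <- c("ards_model_selection", class(res))
  attr(res, "best_fit") <- fits[[best_bic]]
  attr(res, "aic_bic_disagree") <- best_aic != best_bic
  res
}

#' Select the most influential factor X shared by both subgroups
#'
#' The recognition model's X axis is the factor with the highest
#' standardized coefficient magnitude in the tidal-volume screens of *both*
#' the pooled documented and control non-documented subgroups. Among
#' factors significant in both screens, the one maximizing the smaller of
#' the two |beta_std| values wins; ties break toward greater data
#' availability. On cohorts like this study's, the expected winner is the
#' height z-score.
#'
#' @param screen_documented,screen_control `ards_screen` tibbles from
#'   [screen_vt()] run on the two subgroups.
#' @return The selected factor name (length-1 character), with the joined
#'   comparison table as `attr(, "comparison")`.
#' @export
select_factor_x <- function(screen_documented, screen_control) {
  joined <- inner_join(
    select(as_tibble(screen_documented), "factor", beta_doc = "beta_std",
           sig_doc = "significant", n_doc = "n_used"),
    select(as_tibble(screen_control), "factor", beta_ctrl = "beta_std",
           sig_ctrl = "significant", n_ctrl = "n_used"),
    by = "factor"
  )
  eligible <- filter(joined, .data$sig_doc & .data$sig_ctrl)
  if (nrow(eligible) == 0L) {
    abort(paste("no factor is significant in both the pooled documented and",
                "control non-documented screens; inspect the screen tables"))
  }
  eligible <- mutate(eligible,
                     score = pmin(abs(.data$beta_doc), abs(.data$beta_ctrl)),
                     avail = pmin(.data$n_doc, .data$n_ctrl))
  eligible <- arrange(eligible, dplyr::desc(.data$score), dplyr::desc(.data$avail),
                      .data$factor)
  out <- eligible$factor[1]
  attr(out, "comparison") <- joined
  out
}
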