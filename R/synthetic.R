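#' Configuration for the synthetic ICU cohort generator
#'
#' Defines the statistical structure of a simulated cohort of invasively
#' ventilated patients: an ARDS cohort and a hypoxemic non-ARDS control
#' cohort, a latent clinician-recognition state that becomes more likely
#' with worse hypoxemia, and tidal volume delivery following the
#' default-absolute-tidal-volume heuristic — unrecognized and control
#' patients receive a default absolute tidal volume (around 500 mL) whose
#' implied standardized value is pulled toward plateau values at the
#' extremes of height, while recognized patients are targeted on a
#' lung-protective standardized tidal volume. Documentation is a noisy,
#' one-sided observation of recognition (documented implies recognized).
#'
#' Cohort sizes default to 2705 ARDS and 1261 control patients; the
#' distributional defaults are stylized choices calibrated so that the
#' generated cohort reproduces the qualitative geometry the recognition
#' tool expects (see the methods vignette).
#'
#' @param n_ards,n_control Cohort sizes.
#' @param male_fraction Proportion of male patients.
#' @param height_mean_male,height_mean_female,height_sd Height distribution
#'   (cm) per gender.
#' @param default_vt_ml_mean,default_vt_ml_sd Default absolute tidal volume
#'   (mL) for unrecognized/control patients.
#' @param plateau_high,plateau_low Standardized tidal volume plateaus
#'   (mL/kg PBW) toward which extreme-height patients are pulled (defaults
#'   8 and 6).
#' @param plateau_shrink Fraction of the excess beyond a plateau that is
#'   retained (0 = hard clip; default 0.3, a partial "adjustment for
#'   extremes of height").
#' @param plateau_jitter_sd Noise (mL/kg PBW) added after clipping.
#' @param recognized_vhat_mean,recognized_vhat_sd Standardized tidal volume
#'   target for recognized patients (mL/kg PBW).
#' @param recognized_vhat_height_slope Change in the recognized target per
#'   height z-score unit (negative: taller recognized patients get slightly
#'   lower V^T, as seen in documented subgroups).
#' @param recognition_logit_intercept,recognition_logit_slope_pf Logistic
#'   model of latent recognition on the lowest PaO2/FiO2 (mm Hg): worse
#'   hypoxemia (lower PF) means higher recognition probability when the
#'   slope is negative.
#' @param doc_given_recognized Probability that a recognized ARDS patient is
#'   documented on both case report forms.
#' @param mixed_flag_prob Probability that a recognized, non-documented
#'   patient carries ARDS on exactly one of the two forms.
#' @param control_doc_prob Probability that a control patient is documented
#'   as ARDS on both forms (these patients join the pooled documented
#'   subgroup).
#' @param pf_range_ards,pf_range_control Uniform ranges (mm Hg) for the
#'   lowest PaO2/FiO2 per cohort.
#' @param pplat_noise_sd,cxr_noise_sd,sofa_noise_sd Noise scales of the
#'   severity-correlated ancillary variables.
#' @param n_days Number of study days with recorded ventilation.
#' @param vt_day_jitter_sd Day-to-day tidal volume jitter (mL) above the
#'   patient's assigned value.
#' @param vac_majority_prob Probability a patient is ventilated mostly on
#'   the assist control/volume control mode.
#' @param missing_frac Fraction of optional ancillary values set missing.
#' @param seed Optional integer seed; [generate_cohort()] seeds its RNG with
#'   it for byte-identical replays.
#' @return A list of class `cohort_sim_config`.
#' @export
cohort_sim_config <- function(n_ards = 2705, n_control = 1261,
                              male_fraction = 0.6,
                              height_mean_male = 175,
                              height_mean_female = 162,
                              height_sd = 7,
                              default_vt_ml_mean = 530,
                              default_vt_ml_sd = 40,
                              plateau_high = 8, plateau_low = 6,
                              plateau_shrink = 0.3,
                              plateau_jitter_sd = 0.25,
                              recognized_vhat_mean = 5.8,
                              recognized_vhat_sd = 0.6,
                              recognized_vhat_height_slope = -0.3,
                              recognition_logit_intercept = 1.25,
                              recognition_logit_slope_pf = -0.005,
                              doc_given_recognized = 0.45,
                              mixed_flag_prob = 0.15,
                              control_doc_prob = 0.05,
                              pf_range_ards = c(40, 300),
                              pf_range_control = c(100, 300),
                              pplat_noise_sd = 3,
                              cxr_noise_sd = 0.7,
                              sofa_noise_sd = 2,
                              n_days = 3,
                              vt_day_jitter_sd = 15,
                              vac_majority_prob = 0.15,
                              missing_frac = 0.08,
                              seed = NULL) {
  cfg <- as.list(environment())
  probs <- c("male_fraction", "doc_given_recognized", "mixed_flag_prob",
             "control_doc_prob", "vac_majority_prob", "missing_frac")
  for (p in probs) {
    if (cfg[[p]] < 0 || cfg[[p]] > 1) abort(paste0(p, " must be in [0, 1]"))
  }
  sds <- c("height_sd", "default_vt_ml_sd", "plateau_jitter_sd",
           "recognized_vhat_sd", "pplat_noise_sd", "cxr_noise_sd",
           "sofa_noise_sd", "vt_day_jitter_sd")
  for (s in sds) {
    if (!is.finite(cfg[[s]]) || cfg[[s]] <= 0) {
      abort(paste0(s, " must be a positive standard deviation"))
    }
  }
  if (n_ards < 0 || n_control < 0) abort("cohort sizes must be nonnegative")
  for (rng in c("pf_range_ards", "pf_range_control")) {
    r <- cfg[[rng]]
    if (length(r) != 2L || r[1] <= 0 || r[2] > 300 || r[1] >= r[2]) {
      abort(paste0(rng, " must be an increasing interval within (0, 300]"))
    }
  }
  if (n_days < 1) abort("n_days must be at least 1")
  structure(cfg, class = "cohort_sim_config")
}

#' Generate a synthetic ventilated-patient cohort with ground truth
#'
#' Draws a full cohort from a [cohort_sim_config()]: gender and height, the
#' lowest PaO2/FiO2, a latent recognition label (logistic in PF for ARDS
#' patients), documentation flags (documented implies recognized), tidal
#' volumes following the default-volume heuristic with height-extreme
#' plateaus, severity-correlated plateau pressure / chest imaging / SOFA
#' values, multi-day tidal volume and ventilator-mode sequences, and
#' plausible ancillary fields. Identical seeds give identical output.
#'
#' @param config A [cohort_sim_config()].
#' @return A list with `records` (cohort tibble in the [read_cohort()]
#'   schema, list-columns included) and `truth` (per-patient
#'   `latent_recognized`, recognition probability, and the assigned
#'   standardized tidal volume).
#' @examples
#' sim <- generate_cohort(cohort_sim_config(n_ards = 50, n_control = 25,
#'                                          seed = 7))
#' table(sim$truth$latent_recognized)
#' @export
generate_cohort <- function(config = cohort_sim_config()) {
  if (!inherits(config, "cohort_sim_config")) {
    abort("config must be created by cohort_sim_config()")
  }
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_ards + config$n_control
  cohort <- rep(c("ARDS", "control"), c(config$n_ards, config$n_control))

  gender <- if_else(runif(n) < config$male_fraction, "male", "female")
  height <- rnorm(n, if_else(gender == "male", config$height_mean_male,
                             config$height_mean_female), config$height_sd)
  height <- pmin(pmax(height, 130), 210)
  pbw <- compute_pbw(height, gender)
  hz <- height_zscore(height)

  pf_rng <- rbind(config$pf_range_ards, config$pf_range_control)
  ci <- if_else(cohort == "ARDS", 1L, 2L)
  pf_lowest <- runif(n, pf_rng[ci, 1], pf_rng[ci, 2])

  # latent recognition: logistic in PF for ARDS; controls are "recognized"
  # only in the vacuous sense that a few get documented as ARDS
  p_rec <- plogis(config$recognition_logit_intercept +
                    config$recognition_logit_slope_pf * pf_lowest)
  latent_recognized <- cohort == "ARDS" & runif(n) < p_rec
  documented <- latent_recognized & runif(n) < config$doc_given_recognized
  ctrl_doc <- cohort == "control" & runif(n) < config$control_doc_prob
  documented <- documented | ctrl_doc
  latent_recognized <- latent_recognized | ctrl_doc

  doc_entry <- documented
  doc_end <- documented
  mixed <- latent_recognized & !documented & runif(n) < config$mixed_flag_prob
  entry_side <- runif(n) < 0.5
  doc_entry <- doc_entry | (mixed & entry_side)
  doc_end <- doc_end | (mixed & !entry_side)

  # tidal volume assignment
  low_target <- latent_recognized
  vhat <- numeric(n)
  vhat[low_target] <- rnorm(sum(low_target),
                            config$recognized_vhat_mean +
                              config$recognized_vhat_height_slope * hz[low_target],
                            config$recognized_vhat_sd)
  raw <- rnorm(sum(!low_target), config$default_vt_ml_mean,
               config$default_vt_ml_sd) / pbw[!low_target]
  hi <- config$plateau_high; lo <- config$plateau_low; sh <- config$plateau_shrink
  clipped <- raw
  clipped[raw > hi] <- hi + sh * (raw[raw > hi] - hi)
  clipped[raw < lo] <- lo + sh * (raw[raw < lo] - lo)
  clipped <- clipped + rnorm(length(clipped), 0, config$plateau_jitter_sd) *
    as.numeric(raw > hi | raw < lo)
  vhat[!low_target] <- clipped
  vhat <- pmax(vhat, 2.5)
  assigned_vt <- vhat * pbw

  # daily sequences: day minimum sits at the assigned value
  k <- config$n_days
  daily_vt <- lapply(seq_len(n), function(i) {
    v <- assigned_vt[i] + abs(rnorm(k, 0, config$vt_day_jitter_sd))
    v[sample.int(k, 1)] <- assigned_vt[i]
    if (k > 1) v[-1][runif(k - 1) < config$missing_frac] <- NA_real_
    round(v, 1)
  })
  vac_major <- runif(n) < config$vac_majority_prob
  other_modes <- c("PSV", "SIMV", "PCV")
  daily_mode <- lapply(seq_len(n), function(i) {
    p_vac <- if (vac_major[i]) 0.9 else 0.15
    if_else(runif(k) < p_vac, "VAC", sample(other_modes, k, replace = TRUE))
  })

  # severity-correlated ancillary variables (driven by PF with noise)
  sev_drive <- (300 - pf_lowest) / 100
  pplat_highest <- round(18 + 3 * sev_drive + rnorm(n, 0, config$pplat_noise_sd), 1)
  pplat_entry <- round(pplat_highest - abs(rnorm(n, 1, 1.5)), 1)
  pplat_end <- round(pplat_highest - abs(rnorm(n, 1, 1.5)), 1)
  cxr_highest <- pmin(pmax(round(1 + 1.1 * sev_drive +
                                   rnorm(n, 0, config$cxr_noise_sd)), 0), 4)
  cxr_entry <- pmax(cxr_highest - rbinom(n, 1, 0.3), 0)
  cxr_end <- pmax(cxr_highest - rbinom(n, 1, 0.3), 0)
  sofa_highest <- pmin(pmax(round(5 + 2 * sev_drive +
                                    rnorm(n, 0, config$sofa_noise_sd)), 0), 24)
  sofa_entry <- pmax(sofa_highest - rbinom(n, 2, 0.4), 0)
  sofa_end <- pmax(sofa_highest - rbinom(n, 2, 0.4), 0)
  pf_entry <- pmin(pf_lowest + abs(rnorm(n, 30, 25)), 300)
  pf_end <- pmin(pf_lowest + abs(rnorm(n, 40, 30)), 300)

  miss <- function(x, frac = config$missing_frac) {
    x[runif(n) < frac] <- NA
    x
  }
  records <- tibble(
    patient_id = sprintf("pt%05d", seq_len(n)),
    cohort = cohort,
    gender = gender,
    height_cm = round(height, 1),
    age_years = round(runif(n, 20, 90)),
    admission_weight_kg = miss(round(pbw * rnorm(n, 1.15, 0.18), 1)),
    region = sample(c("Europe", "North America", "South America", "Asia",
                      "Africa", "Oceania"), n, replace = TRUE,
                    prob = c(0.45, 0.2, 0.1, 0.15, 0.05, 0.05)),
    pf_entry = round(pf_entry, 1),
    pf_end = miss(round(pf_end, 1)),
    pf_lowest = round(pf_lowest, 1),
    pplat_entry = miss(pplat_entry, 0.25),
    pplat_end = miss(pplat_end, 0.25),
    pplat_highest = miss(pplat_highest, 0.2),
    cxr_quadrants_entry = cxr_entry,
    cxr_quadrants_end = miss(cxr_end),
    cxr_quadrants_highest = cxr_highest,
    sofa_entry = miss(sofa_entry),
    sofa_end = miss(sofa_end),
    sofa_highest = miss(sofa_highest),
    doc_entry = doc_entry,
    doc_end = doc_end,
    daily_vt_ml = daily_vt,
    daily_mode = daily_mode
  )
  # pf_lowest must not exceed the recorded entry/end values
  records$pf_entry <- pmax(records$pf_entry, records$pf_lowest)
  records$pf_end <- pmax(records$pf_end, records$pf_lowest)

  truth <- tibble(
    patient_id = records$patient_id,
    cohort = cohort,
    latent_recognized = latent_recognized,
    p_recognized = if_else(cohort == "ARDS", p_rec, NA_real_),
    assigned_vhat = vhat,
    documented = documented
  )
  list(records = records, truth = truth,
       config = config)
}

#' Write a committed-size synthetic fixture
#'
#' Emits a small cohort CSV plus its ground-truth sidecar for fast tests:
#' the `tiny` size has 60 patients (40 ARDS, 20 control), the `default`
#' size uses the full generator defaults.
#'
#' @param dir Output directory (created if needed).
#' @param size `"tiny"` (default) or `"default"`.
#' @param seed Seed for the generator (default 193).
#' @return Named character vector of the two file paths, invisibly.
#' @export
emit_fixture <- function(dir, size = c("tiny", "default"), seed = 193) {
  size <- match.arg(size)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  cfg <- if (size == "tiny") {
    cohort_sim_config(n_ards = 40, n_control = 20, seed = seed)
  } else {
    cohort_sim_config(seed = seed)
  }
  sim <- generate_cohort(cfg)
  cohort_path <- file.path(dir, paste0(size, "_cohort.csv"))
  truth_path <- file.path(dir, paste0(size, "_truth.csv"))
  write_cohort(sim$records, cohort_path)
  readr::write_csv(sim$truth, truth_path, na = "")
  invisible(c(cohort = cohort_path, truth = truth_path))
}
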