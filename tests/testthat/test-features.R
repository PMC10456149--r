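test_that("predicted body weight follows the ARDSNet formula", {
  expect_equal(compute_pbw(152.4, "male"), 50)
  expect_equal(compute_pbw(152.4, "female"), 45.5)
  expect_equal(compute_pbw(175, "male"), 50 + 0.91 * (175 - 152.4))
  expect_equal(compute_pbw(175, "male"), 70.566)
  # vectorized with per-element gender
  expect_equal(compute_pbw(c(152.4, 152.4), c("male", "female")), c(50, 45.5))
  expect_error(compute_pbw(100, "male"), "lower plausibility bound")
  expect_error(compute_pbw(240, "female"), "upper plausibility bound")
  expect_error(compute_pbw(170, "unknown"), "gender")
})

test_that("lowest standardized tidal volume is the min over recorded days", {
  expect_equal(lowest_standardized_vt(c(500, 450, 480), 70.566), 450 / 70.566)
  expect_equal(round(lowest_standardized_vt(c(500, 450, 480), 70.566), 3),
               6.377)
  expect_equal(lowest_standardized_vt(500, 50), 10)
  expect_equal(lowest_standardized_vt(c(NA, 400), 80), 5)
  expect_true(is.na(lowest_standardized_vt(c(NA_real_, NA_real_), 80)))
})

test_that("vhat_lowest times PBW recovers the minimum daily tidal volume", {
  set.seed(7)
  for (i in 1:25) {
    vt <- runif(5, 300, 700)
    vt[sample(5, sample(0:3, 1))] <- NA
    if (all(is.na(vt))) next
    pbw <- runif(1, 40, 90)
    expect_equal(lowest_standardized_vt(vt, pbw) * pbw, min(vt, na.rm = TRUE),
                 tolerance = 1e-9)
  }
})

test_that("height z-scores standardize against the pooled reference", {
  expect_equal(height_zscore(c(160, 170, 180)), c(-1, 0, 1))
  set.seed(3)
  h <- rnorm(50, 168, 8)
  z <- height_zscore(h)
  expect_equal(mean(z), 0, tolerance = 1e-9)
  expect_equal(sd(z), 1, tolerance = 1e-9)
  # out-of-reference heights standardized against the given reference
  expect_equal(height_zscore(190, reference = c(160, 170, 180)), 2)
  expect_error(height_zscore(rep(170, 5)), "distinct")
})

test_that("severity bands use the printed closed/open interval ends", {
  expect_equal(assign_severity(250), "mild")
  expect_equal(assign_severity(200), "moderate")
  expect_equal(assign_severity(100), "severe")
  expect_equal(assign_severity(300), "mild")
  expect_equal(assign_severity(100.5), "moderate")
  expect_true(is.na(assign_severity(NA_real_)))
  expect_error(assign_severity(301), "above 300")
  expect_error(assign_severity(0), "positive")
})

test_that("severity agrees with a brute-force interval oracle on a pf grid", {
  oracle <- function(pf) {
    if (pf > 200 && pf <= 300) "mild"
    else if (pf > 100 && pf <= 200) "moderate"
    else "severe"
  }
  grid <- seq(1, 300, by = 0.5)
  expect_equal(assign_severity(grid), vapply(grid, oracle, character(1)))
})

test_that("subgroup assignment follows the documentation rule", {
  expect_equal(assign_subgroup("ARDS", TRUE, TRUE), "pooled_documented")
  expect_equal(assign_subgroup("control", TRUE, TRUE), "pooled_documented")
  expect_equal(assign_subgroup("ARDS", TRUE, FALSE), "ards_non_documented")
  expect_equal(assign_subgroup("ARDS", TRUE, FALSE, rule = "end_form_only"),
               "ards_non_documented")
  expect_equal(assign_subgroup("ARDS", FALSE, TRUE, rule = "end_form_only"),
               "pooled_documented")
  expect_equal(assign_subgroup("control", FALSE, FALSE),
               "control_non_documented")
  expect_error(assign_subgroup("other", TRUE, TRUE), "cohort")
})

test_that("subgroup assignment partitions any cohort exhaustively", {
  set.seed(11)
  n <- 500
  cohort <- sample(c("ARDS", "control"), n, replace = TRUE)
  e <- sample(c(TRUE, FALSE), n, replace = TRUE)
  d <- sample(c(TRUE, FALSE), n, replace = TRUE)
  for (rule in c("both_forms", "end_form_only")) {
    sg <- assign_subgroup(cohort, e, d, rule = rule)
    expect_false(any(is.na(sg)))
    expect_true(all(sg %in% c("pooled_documented", "ards_non_documented",
                              "control_non_documented")))
    # each patient lands in exactly one subgroup, and non-documented
    # subgroups never cross cohorts
    expect_true(all(sg[cohort == "ARDS"] != "control_non_documented"))
    expect_true(all(sg[cohort == "control"] != "ards_non_documented"))
  }
})

test_that("the VAC filter keeps strict-majority assist-control patients", {
  rec <- tibble::tibble(
    patient_id = c("a", "b", "c", "d"),
    daily_mode = list(c("VAC", "VAC", "PSV"), c("VAC", "PSV"),
                      character(0), c(NA, "VAC"))
  )
  out <- vac_filter(rec)
  expect_equal(out$patient_id, c("a", "d"))
  rep <- attr(out, "vac_report")
  expect_equal(rep$n_no_mode_data, 1)
  expect_equal(rep$n_minority_or_tie, 1)
})
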