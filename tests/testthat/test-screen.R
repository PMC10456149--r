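test_that("Bonferroni thresholds divide alpha by the family size", {
  expect_equal(bonferroni_threshold(0.01, 111), 0.01 / 111)
  expect_equal(bonferroni_threshold(0.01, 10), 0.001)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_error(bonferroni_threshold(0.01, 0), "positive integer")
})

test_that("standardized OLS recovers the closed-form slope on exact data", {
  x <- 1:20
  x <- (x - mean(x)) / sd(x) * 2 # sd exactly 2
  fit <- suppressWarnings(univariable_std_ols(x, 3 * x))
  expect_equal(fit$beta_std, 6, tolerance = 1e-9)
  expect_lt(fit$p_value, 1e-12)
  expect_equal(fit$n_used, 20)
  expect_error(univariable_std_ols(rep(1, 10), rnorm(10)), "zero-variance")
  expect_error(univariable_std_ols(1:2, 1:2), "fewer than 3")
})

test_that("standardized OLS matches a direct normal-equations solve", {
  set.seed(101)
  for (i in 1:100) {
    n <- sample(10:60, 1)
    x <- rnorm(n, sd = runif(1, 0.5, 5))
    y <- rnorm(n, 2 * x, sd = runif(1, 0.5, 3))
    fit <- univariable_std_ols(x, y)
    z <- (x - mean(x)) / sd(x)
    X <- cbind(1, z)
    beta <- unname(solve(t(X) %*% X, t(X) %*% y))
    resid <- y - X %*% beta
    se <- sqrt(drop(t(resid) %*% resid) / (n - 2) *
                 solve(t(X) %*% X)[2, 2])
    expect_equal(fit$beta_std, unname(beta[2, 1]), tolerance = 1e-9)
    expect_equal(fit$ci_high - fit$beta_std, qnorm(0.975) * se,
                 tolerance = 1e-9)
  }
})

test_that("standardized coefficients are invariant to predictor rescaling", {
  set.seed(55)
  for (i in 1:10) {
    x <- rnorm(80)
    y <- rnorm(80, 1.5 * x)
    k <- runif(1, 0.01, 100)
    a <- univariable_std_ols(x, y)
    b <- univariable_std_ols(k * x, y)
    expect_equal(a$beta_std, b$beta_std, tolerance = 1e-9)
    expect_equal(a$p_value, b$p_value, tolerance = 1e-9)
    expect_equal(a$ci_low, b$ci_low, tolerance = 1e-9)
  }
})

test_that("a null factor at n = 5000 stays below the screen's radar", {
  set.seed(2024)
  x <- rnorm(5000)
  y <- rnorm(5000)
  fit <- univariable_std_ols(x, y)
  expect_lt(abs(fit$beta_std), 0.1)
  expect_gt(fit$p_value, bonferroni_threshold(0.01, 111))
})

test_that("logistic documentation fits behave under null and signal", {
  set.seed(77)
  x <- rnorm(4000)
  doc_null <- runif(4000) < 0.3
  nullfit <- logistic_documentation_fit(x, doc_null)
  expect_gt(nullfit$p_value, bonferroni_threshold(0.01, 111))
  expect_false(nullfit$separation_flag)
  # documentation probability increases as the factor decreases
  doc_sig <- runif(4000) < plogis(-1.2 * x)
  sigfit <- logistic_documentation_fit(x, doc_sig)
  expect_lt(sigfit$beta_std, 0)
  expect_error(logistic_documentation_fit(x, rep(TRUE, 4000)),
               "single class")
})

test_that("complete separation is flagged, not silently returned", {
  x <- c(rnorm(50, -3), rnorm(50, 3))
  doc <- x > 0
  fit <- logistic_documentation_fit(x, doc)
  expect_true(fit$separation_flag)
})

test_that("the screen evaluates every factor and notes the degenerate ones", {
  sim <- small_sim(n_ards = 400, n_control = 200, seed = 21)
  der <- derive_features(sim$records)
  ctl <- dplyr::filter(der, subgroup == "control_non_documented")
  scr <- screen_vt(ctl)
  expect_s3_class(scr, "ards_screen")
  expect_equal(nrow(scr), length(ards_factor_specs()))
  # documentation flags are constant in this subgroup -> noted, not fatal
  expect_true(all(!is.na(scr$note[scr$factor %in% c("doc_entry", "doc_both")])))
  expect_true(scr$significant[scr$factor == "height_z"])
  expect_lt(scr$beta_std[scr$factor == "height_z"], 0)
  g <- glance(scr)
  expect_equal(g$bonferroni_m, g$n_evaluable)
  expect_equal(attr(scr, "threshold"), 0.01 / g$n_evaluable)
})

test_that("availability gaps above 10% of cohort size exclude a pair", {
  set.seed(31)
  n <- 1000
  d <- tibble::tibble(
    height_z = rnorm(n),
    pf_lowest = ifelse(runif(n) < 0.95, rnorm(n, 150, 40), NA),
    pplat_highest = ifelse(runif(n) < 0.80, rnorm(n, 25, 4), NA),
    vhat_lowest = rnorm(n, 8)
  )
  cov <- covariance_screen(d, c("pf_lowest", "pplat_highest", "height_z"))
  row <- dplyr::filter(cov, factor_a == "pf_lowest",
                       factor_b == "pplat_highest")
  expect_true(row$non_evaluable)
  expect_false(row$covariate)
})

test_that("duplicated information is covariate; independent factors are not", {
  set.seed(32)
  n <- 5000
  d <- tibble::tibble(
    pf_lowest = rnorm(n, 150, 40),
    pf_entry = NA_real_,
    height_z = rnorm(n),
    vhat_lowest = rnorm(n, 8)
  )
  d$pf_entry <- d$pf_lowest + rnorm(n, 0, 1) # near-copy
  cov <- covariance_screen(d, c("pf_lowest", "pf_entry", "height_z"))
  expect_true(dplyr::filter(cov, factor_a == "pf_lowest",
                            factor_b == "pf_entry")$covariate)
  expect_false(dplyr::filter(cov, factor_a == "pf_lowest",
                             factor_b == "height_z")$covariate)
  expect_equal(attr(cov, "threshold"), 0.001)
})

test_that("candidate enumeration covers subsets and honors exclusions", {
  cands <- build_candidate_models(c("A", "B"))
  expect_equal(nrow(cands), 3)
  excl <- tibble::tibble(factor_a = "A", factor_b = "B",
                         non_evaluable = FALSE, covariate = TRUE)
  cands2 <- build_candidate_models(c("A", "B"), excl)
  expect_equal(sort(sapply(cands2$factors, paste, collapse = "+")),
               c("A", "B"))
  cands3 <- build_candidate_models(c("A", "B", "C"))
  expect_equal(nrow(cands3), 7) # 2^3 - 1, no interaction parents present
  # documentation x severity interaction variant appears when both are in
  cands4 <- build_candidate_models(c("doc_both", "pf_lowest"))
  expect_equal(nrow(cands4), 4)
  expect_equal(sum(cands4$interaction), 1)
  expect_error(build_candidate_models(character(0)), "no significant")
})

test_that("BIC selection recovers the generating factor set", {
  specs <- list(A = function(d) d$A, B = function(d) d$B)
  hits <- 0L
  set.seed(99)
  for (i in 1:100) {
    n <- 150
    d <- tibble::tibble(A = rnorm(n), B = rnorm(n))
    d$vhat_lowest <- 8 - 1.5 * d$A + rnorm(n, 0, 0.5)
    cands <- build_candidate_models(c("A", "B"))
    sel <- select_best_model(d, cands, factors = specs)
    picked <- sel$factors[sel$selected][[1]]
    if (identical(picked, "A")) hits <- hits + 1L
  }
  expect_gte(hits, 95)
})

test_that("model selection tie and degenerate rules are deterministic", {
  specs <- list(A = function(d) d$A)
  set.seed(5)
  d <- tibble::tibble(A = rnorm(50))
  d$vhat_lowest <- 7 - d$A + rnorm(50, 0, 0.3)
  single <- build_candidate_models("A")
  sel <- select_best_model(d, single, factors = specs)
  expect_equal(which(sel$selected), 1L)
  # duplicated candidate: first listed wins
  dup <- dplyr::bind_rows(single, single)
  dup$model_id <- 1:2
  sel2 <- select_best_model(d, dup, factors = specs)
  expect_equal(which(sel2$selected), 1L)
  expect_false(attr(sel2, "aic_bic_disagree"))
})

test_that("factor X is the largest shared significant coefficient", {
  s_doc <- fake_screen(c("height_z", "pf_lowest"), c(-3.7, 0.5), c(TRUE, TRUE))
  s_ctl <- fake_screen(c("height_z", "pf_lowest"), c(-7.7, 0.3), c(TRUE, TRUE))
  expect_equal(as.character(select_factor_x(s_doc, s_ctl)), "height_z")
  # a factor significant in only one screen is ineligible
  s_ctl2 <- fake_screen(c("height_z", "pf_lowest"), c(-7.7, 0.3),
                        c(FALSE, TRUE))
  expect_equal(as.character(select_factor_x(s_doc, s_ctl2)), "pf_lowest")
  # ties break toward greater data availability
  s_doc3 <- fake_screen(c("a", "b"), c(2, 2), c(TRUE, TRUE), n_used = c(500, 900))
  s_ctl3 <- fake_screen(c("a", "b"), c(-2, 2), c(TRUE, TRUE), n_used = c(500, 900))
  expect_equal(as.character(select_factor_x(s_doc3, s_ctl3)), "b")
  s_none <- fake_screen("height_z", -3, FALSE)
  expect_error(select_factor_x(s_none, s_none), "inspect")
})
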