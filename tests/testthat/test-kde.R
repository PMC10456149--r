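test_that("the fitted density integrates to 1 over a generous grid", {
  m <- two_class_models(n = 300, seed = 1)$doc
  xg <- seq(-6, 6, length.out = 241)
  vg <- seq(0, 12, length.out = 241)
  dens <- ardsrecog:::kde_grid_density(m, xg, vg)
  expect_equal(trapz2d(dens, xg, vg), 1, tolerance = 0.01)
})

test_that("a symmetric training set yields a symmetric density", {
  set.seed(2)
  x <- rnorm(200)
  v <- rnorm(200, 7)
  d <- data.frame(height_z = c(x, -x), vhat_lowest = c(v, v))
  m <- fit_kde(d)
  xg <- seq(-3, 3, length.out = 51)
  vg <- seq(4, 10, length.out = 51)
  dens <- ardsrecog:::kde_grid_density(m, xg, vg)
  expect_lt(max(abs(dens - dens[rev(seq_along(xg)), ])), 1e-6)
})

test_that("a tight cluster puts the mode within one bandwidth of its mean", {
  set.seed(3)
  d <- data.frame(height_z = rnorm(100, 1.2, 0.05),
                  vhat_lowest = rnorm(100, 6.4, 0.05))
  m <- fit_kde(d)
  xg <- seq(-3, 3, length.out = 201)
  vg <- seq(2, 14, length.out = 201)
  dens <- ardsrecog:::kde_grid_density(m, xg, vg)
  peak <- which(dens == max(dens), arr.ind = TRUE)
  expect_lt(abs(xg[peak[1]] - mean(d$height_z)), m$h[1] + 0.05)
  expect_lt(abs(vg[peak[2]] - mean(d$vhat_lowest)), m$h[2] + 0.05)
})

test_that("degenerate training data is rejected", {
  expect_error(fit_kde(data.frame(height_z = rnorm(5),
                                  vhat_lowest = rnorm(5))),
               "at least 10")
  expect_error(fit_kde(data.frame(height_z = rep(1, 20),
                                  vhat_lowest = rnorm(20))),
               "zero variance")
})

test_that("grid and pointwise density evaluations agree with MASS::kde2d", {
  skip_if_not_installed("MASS")
  set.seed(4)
  d <- data.frame(height_z = rnorm(120), vhat_lowest = rnorm(120, 7, 1.5))
  m <- fit_kde(d)
  # kde2d divides its h by 4 before use, so pass 4x our bandwidths
  ref <- MASS::kde2d(d$height_z, d$vhat_lowest, h = 4 * m$h, n = 31,
                     lims = c(-3, 3, 3, 11))
  ours <- ardsrecog:::kde_grid_density(m, ref$x, ref$y)
  expect_equal(ours, ref$z, tolerance = 1e-10, ignore_attr = TRUE)
  pointwise <- predict(m, rep(ref$x, times = 31),
                       rep(ref$y, each = 31))
  expect_equal(matrix(pointwise, 31, 31), ref$z, tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("the posterior is a proper probability and respects priors", {
  set.seed(5)
  pts <- data.frame(height_z = rnorm(100), vhat_lowest = rnorm(100, 7))
  same_a <- fit_kde(pts, label = "pooled_documented", prior = 0.5)
  same_b <- fit_kde(pts, label = "control_non_documented", prior = 0.5)
  qx <- runif(50, -2, 2)
  qv <- runif(50, 5, 9)
  post <- posterior_documented(qx, qv, same_a, same_b)
  # identical classes with equal priors: exactly 0.5 everywhere
  expect_equal(post$posterior, rep(0.5, 50), tolerance = 1e-12)
  # posterior and its complement sum to one
  swapped <- posterior_documented(qx, qv, same_b, same_a)
  expect_equal(post$posterior + swapped$posterior, rep(1, 50),
               tolerance = 1e-12)
  # prior 0.9 at a density-ratio-1 point moves the posterior to 0.9
  tilted_a <- fit_kde(pts, label = "doc", prior = 0.9)
  tilted_b <- fit_kde(pts, label = "ctrl", prior = 0.1)
  post9 <- posterior_documented(qx, qv, tilted_a, tilted_b)
  expect_equal(post9$posterior, rep(0.9, 50), tolerance = 1e-9)
  # mismatched priors are rejected
  bad <- fit_kde(pts, prior = 0.6)
  expect_error(posterior_documented(0, 7, bad, same_b), "sum to 1")
})

test_that("points deep inside one class's support are classified surely", {
  mods <- two_class_models(n = 400, seed = 6)
  post <- posterior_documented(0, 5.5, mods$doc, mods$ctrl)
  expect_gt(post$posterior, 0.99)
  post2 <- posterior_documented(0, 9.5, mods$doc, mods$ctrl)
  expect_lt(post2$posterior, 0.01)
  # far outside both supports: flagged and neutral
  far <- posterior_documented(0, 60, mods$doc, mods$ctrl)
  expect_true(far$out_of_support)
  expect_equal(far$posterior, 0.5)
})

test_that("raising the documented prior never demotes a recognized point", {
  mods <- two_class_models(n = 200, seed = 7)
  qx <- runif(40, -2, 2)
  qv <- runif(40, 4, 11)
  base <- posterior_documented(qx, qv, mods$doc, mods$ctrl)
  up_doc <- fit_kde(data.frame(height_z = mods$doc$x,
                               vhat_lowest = mods$doc$vhat), prior = 0.8)
  up_ctrl <- fit_kde(data.frame(height_z = mods$ctrl$x,
                                vhat_lowest = mods$ctrl$vhat), prior = 0.2)
  up <- posterior_documented(qx, qv, up_doc, up_ctrl)
  recognized <- base$posterior > 0.5
  expect_true(all(up$posterior[recognized] > 0.5))
})
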