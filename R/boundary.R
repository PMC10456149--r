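#' Extract the equal-posterior decision boundary
#'
#' Locates, for every X grid column, the lowest-standardized-tidal-volume
#' value where the documented-class posterior crosses 0.5, i.e. where
#' `P(documented | x, vhat) = P(control | x, vhat)`. Crossings are found by
#' sign change with linear interpolation; if a column has several crossings
#' (a kernel-density artifact), the one nearest the midpoint of the two
#' subgroup vhat means is kept. Columns with no crossing are left undefined
#' (`NA`); if no column has a crossing at all, the class overlap is
#' degenerate and an error is raised.
#'
#' @param model_doc,model_ctrl `vt_kde` models for the pooled documented and
#'   control non-documented subgroups.
#' @param x_grid,vhat_grid Evaluation grid. Defaults cover height z-scores
#'   in \[-3, 3\] and tidal volumes in \[2, 14\] mL/kg PBW at 201 x 201.
#' @param eps Density floor (see [posterior_documented()]).
#' @return Tibble of class `vt_boundary` with columns `x` and
#'   `vhat_threshold`; grids, priors and the crossing-selection midpoint are
#'   stored in attributes.
#' @examples
#' set.seed(42)
#' doc <- data.frame(height_z = rnorm(300), vhat_lowest = rnorm(300, 6))
#' ctl <- data.frame(height_z = rnorm(300), vhat_lowest = rnorm(300, 9))
#' b <- extract_boundary(fit_kde(doc, label = "pooled_documented"),
#'                       fit_kde(ctl, label = "control_non_documented"))
#' head(b)
#' @export
extract_boundary <- function(model_doc, model_ctrl,
                             x_grid = seq(-3, 3, length.out = 201),
                             vhat_grid = seq(2, 14, length.out = 201),
                             eps = 1e-12) {
  stopifnot(inherits(model_doc, "vt_kde"), inherits(model_ctrl, "vt_kde"),
            !is.unsorted(x_grid, strictly = TRUE),
            !is.unsorted(vhat_grid, strictly = TRUE))
  dd <- kde_grid_density(model_doc, x_grid, vhat_grid)
  dc <- kde_grid_density(model_ctrl, x_grid, vhat_grid)
  midpoint <- (mean(model_doc$vhat) + mean(model_ctrl$vhat)) / 2
  thr <- boundary_from_grids(dd, dc, model_doc$prior, model_ctrl$prior,
                             vhat_grid, midpoint, eps)
  if (all(is.na(thr))) {
    abort("no equal-posterior crossing anywhere on the grid: degenerate class overlap")
  }
  out <- tibble(x = x_grid, vhat_threshold = thr)
  class(out) <- c("vt_boundary", class(out))
  attr(out, "x_grid") <- x_grid
  attr(out, "vhat_grid") <- vhat_grid
  attr(out, "midpoint") <- midpoint
  attr(out, "priors") <- c(doc = model_doc$prior, ctrl = model_ctrl$prior)
  attr(out, "labels") <- c(doc = model_doc$label, ctrl = model_ctrl$label)
  out
}

# Per-column 0.5-posterior crossing from two density grids (rows = x).
boundary_from_grids <- function(dd, dc, p_doc, p_ctrl, vhat_grid, midpoint,
                                eps = 1e-12) {
  nx <- nrow(dd)
  thr <- rep(NA_real_, nx)
  for (i in seq_len(nx)) {
    fd <- dd[i, ]; fc <- dc[i, ]
    supported <- !(fd < eps & fc < eps)
    g <- p_doc * fd - p_ctrl * fc  # > 0 where documented posterior > 0.5
    g[!supported] <- NA_real_
    ok <- which(!is.na(g))
    if (length(ok) < 2L) next
    cross_v <- numeric(0)
    for (j in ok[-length(ok)]) {
      if (is.na(g[j]) || is.na(g[j + 1])) next
      if (g[j] == 0) cross_v <- c(cross_v, vhat_grid[j])
      if (g[j] * g[j + 1] < 0) {
        w <- g[j] / (g[j] - g[j + 1])
        cross_v <- c(cross_v, vhat_grid[j] + w * (vhat_grid[j + 1] - vhat_grid[j]))
      }
    }
    if (length(cross_v) == 0L) next
    thr[i] <- cross_v[which.min(abs(cross_v - midpoint))]
  }
  thr
}

#' Bootstrap confidence bands for the decision boundary
#'
#' Resamples the control non-documented subgroup with replacement at its
#' own size, refits its kernel density (bandwidths recomputed on each
#' resample), recomputes the boundary against the fixed documented-class
#' model, and reports per-column 2.5th/97.5th percentile bands across the
#' iterations. The default of 100 iterations matches the analysis the tool
#' reproduces. A resample with zero variance in either dimension is redrawn
#' (counted, capped at 10 x `n_iter`).
#'
#' @param boundary A `vt_boundary` from [extract_boundary()] (point
#'   estimate; supplies the grid).
#' @param model_doc Fixed `vt_kde` model of the pooled documented subgroup.
#' @param model_ctrl `vt_kde` model of the control subgroup to resample.
#' @param n_iter Number of bootstrap iterations (default 100).
#' @param seed Optional integer seed for reproducible bands.
#' @param eps Density floor.
#' @return The `boundary` tibble with added `band_low` and `band_high`
#'   columns; `attr(, "n_bootstrap")`, `attr(, "seed")` and
#'   `attr(, "n_redrawn")` record the run.
#' @export
bootstrap_bands <- function(boundary, model_doc, model_ctrl, n_iter = 100,
                            seed = NULL, eps = 1e-12) {
  stopifnot(inherits(boundary, "vt_boundary"), inherits(model_doc, "vt_kde"),
            inherits(model_ctrl, "vt_kde"), n_iter >= 2)
  if (!is.null(seed)) set.seed(seed)
  x_grid <- attr(boundary, "x_grid")
  vhat_grid <- attr(boundary, "vhat_grid")
  dd <- kde_grid_density(model_doc, x_grid, vhat_grid)
  n <- model_ctrl$n
  bw_rule <- model_ctrl$bandwidth_rule
  bw_arg <- if (bw_rule == "fixed") model_ctrl$h else bw_rule
  mids <- matrix(NA_real_, nrow = n_iter, ncol = length(x_grid))
  redrawn <- 0L
  max_redraw <- 10L * n_iter
  for (it in seq_len(n_iter)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      bx <- model_ctrl$x[idx]; bv <- model_ctrl$vhat[idx]
      if (sd(bx) > 0 && sd(bv) > 0) break
      redrawn <- redrawn + 1L
      if (redrawn > max_redraw) {
        abort("bootstrap resampling kept producing zero-variance resamples")
      }
    }
    bmod <- fit_kde(data.frame(x = bx, v = bv), x = "x", vhat = "v",
                    bandwidth = bw_arg, label = model_ctrl$label,
                    prior = model_ctrl$prior)
    dcb <- kde_grid_density(bmod, x_grid, vhat_grid)
    midpoint <- (mean(model_doc$vhat) + mean(bv)) / 2
    mids[it, ] <- boundary_from_grids(dd, dcb, model_doc$prior,
                                      model_ctrl$prior, vhat_grid, midpoint,
                                      eps)
  }
  qs <- apply(mids, 2, function(col) {
    if (all(is.na(col))) return(c(NA_real_, NA_real_))
    quantile(col, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
  })
  boundary$band_low <- qs[1, ]
  boundary$band_high <- qs[2, ]
  attr(boundary, "n_bootstrap") <- n_iter
  attr(boundary, "seed") <- seed %||% NA_integer_
  attr(boundary, "n_redrawn") <- redrawn
  boundary
}

#' Tidiers for boundary and density objects
#'
#' `tidy()` on a `vt_boundary` returns the per-column boundary (and bands
#' when present) as a plain tibble; `glance()` on a `vt_kde` summarises the
#' fitted density model in one row.
#'
#' @param x A `vt_boundary` or `vt_kde` object.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy vt_boundary
#' @export
tidy.vt_boundary <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- setdiff(class(out), "vt_boundary")
  out
}

#' Plot a recognition boundary with its bootstrap bands
#'
#' @param object A `vt_boundary`.
#' @param ... Unused.
#' @return A ggplot: boundary curve, shaded bootstrap band (when present),
#'   over the (X, lowest V^T) plane.
#' @method autoplot vt_boundary
#' @export
autoplot.vt_boundary <- function(object, ...) {
  df <- tidy(object)
  p <- ggplot(df, aes(x = .data$x, y = .data$vhat_threshold))
  if (all(c("band_low", "band_high") %in% names(df))) {
    p <- p + geom_ribbon(aes(ymin = .data$band_low, ymax = .data$band_high),
                         fill = "grey70", alpha = 0.5)
  }
  p +
    geom_line(linewidth = 0.8) +
    labs(x = "factor X (height z-score)",
         y = "lowest standardized tidal volume (mL/kg PBW)",
         title = "Equal-posterior recognition boundary") +
    theme_minimal()
}
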