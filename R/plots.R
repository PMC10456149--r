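#' Tidiers and plots for screen results
#'
#' An `ards_screen` is already tabular; `tidy()` strips the class and
#' `glance()` reports the family size and threshold used. `autoplot()`
#' draws a forest plot of the standardized coefficients with their 95%
#' confidence intervals, marking factors significant at the Bonferroni
#' threshold.
#'
#' @param x,object An `ards_screen` from [screen_vt()].
#' @param ... Unused.
#' @return A tibble (`tidy`, `glance`) or a ggplot (`autoplot`).
#' @method tidy ards_screen
#' @export
tidy.ards_screen <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- setdiff(class(out), "ards_screen")
  out
}

#' @rdname tidy.ards_screen
#' @method glance ards_screen
#' @export
glance.ards_screen <- function(x, ...) {
  tibble(
    n_factors = nrow(x),
    n_evaluable = sum(is.na(x$note)),
    n_significant = sum(x$significant, na.rm = TRUE),
    bonferroni_m = attr(x, "m"),
    threshold = attr(x, "threshold"),
    outcome = attr(x, "outcome")
  )
}

#' @rdname tidy.ards_screen
#' @method autoplot ards_screen
#' @export
autoplot.ards_screen <- function(object, ...) {
  df <- filter(tidy(object), !is.na(.data$beta_std))
  df$factor <- stats::reorder(df$factor, abs(df$beta_std))
  ggplot(df, aes(x = .data$beta_std, y = .data$factor,
                 colour = .data$significant)) +
    geom_vline(xintercept = 0, linetype = "dashed", colour = "grey60") +
    geom_point() +
    geom_errorbarh(aes(xmin = .data$ci_low, xmax = .data$ci_high),
                   height = 0.25) +
    scale_colour_manual(values = c(`TRUE` = "#7570b3", `FALSE` = "grey55")) +
    labs(x = "standardized coefficient (mL/kg PBW per 1 sd)", y = NULL,
         colour = "Bonferroni-significant",
         title = "Predictors of lowest standardized tidal volume") +
    theme_minimal()
}

#' Heatmap of a fitted class density with the decision boundary
#'
#' @param model A `vt_kde` model.
#' @param boundary Optional `vt_boundary` to overlay.
#' @param x_grid,vhat_grid Evaluation grid (defaults as in
#'   [extract_boundary()]).
#' @return A ggplot heatmap of the density over the (X, lowest V^T) plane.
#' @export
plot_density_map <- function(model, boundary = NULL,
                             x_grid = seq(-3, 3, length.out = 201),
                             vhat_grid = seq(2, 14, length.out = 201)) {
  stopifnot(inherits(model, "vt_kde"))
  dens <- kde_grid_density(model, x_grid, vhat_grid)
  df <- tidyr::expand_grid(x = x_grid, vhat = vhat_grid)
  df$density <- dens[cbind(match(df$x, x_grid), match(df$vhat, vhat_grid))]
  p <- ggplot(df, aes(x = .data$x, y = .data$vhat, fill = .data$density)) +
    geom_raster() +
    scale_fill_viridis_c() +
    labs(x = "factor X (height z-score)",
         y = "lowest standardized tidal volume (mL/kg PBW)",
         title = paste0("Class density: ", model$label)) +
    theme_minimal()
  if (!is.null(boundary)) {
    p <- p + geom_line(data = tidy(boundary),
                       aes(x = .data$x, y = .data$vhat_threshold),
                       inherit.aes = FALSE, colour = "black", linewidth = 0.8)
  }
  p
}
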