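#' Fit a two-dimensional kernel density model to a subgroup
#'
#' Estimates the class-conditional density of (X, lowest standardized tidal
#' volume) pairs for one subgroup with a product Gaussian kernel and
#' per-dimension bandwidths. The default bandwidth is Scott's rule for two
#' dimensions, `h_j = sd_j * n^(-1/6)`; Silverman's rule and fixed numeric
#' bandwidths are also accepted. The fitted model evaluates the density at
#' arbitrary points and is one of the two class models feeding the naive
#' Bayes posterior.
#'
#' @param data Data frame holding the training points.
#' @param x,vhat Column names of the X factor (default `"height_z"`) and the
#'   lowest standardized tidal volume (default `"vhat_lowest"`).
#' @param bandwidth `"scott"` (default), `"silverman"`, or a numeric vector
#'   of two fixed bandwidths `(h_x, h_vhat)`.
#' @param label Subgroup label stored in the model (e.g.
#'   `"pooled_documented"`).
#' @param prior Prior probability of this class (default 0.5, the
#'   equal-prior assumption).
#' @return An object of class `vt_kde`.
#' @examples
#' pts <- data.frame(height_z = rnorm(50), vhat_lowest = rnorm(50, 8))
#' fit_kde(pts, label = "control_non_documented")
#' @export
fit_kde <- function(data, x = "height_z", vhat = "vhat_lowest",
                    bandwidth = "scott", label = "subgroup", prior = 0.5) {
  stopifnot(is.data.frame(data), x %in% names(data), vhat %in% names(data),
            prior > 0, prior < 1)
  px <- data[[x]]
  pv <- data[[vhat]]
  keep <- complete.cases(px, pv)
  px <- px[keep]; pv <- pv[keep]
  n <- length(px)
  if (n < 10L) abort("kernel density needs at least 10 complete points")
  if (!all(is.finite(px)) || !all(is.finite(pv))) {
    abort("non-finite coordinates in kernel density training data")
  }
  if (sd(px) == 0 || sd(pv) == 0) {
    abort("zero variance in a kernel density dimension")
  }
  h <- kde_bandwidth(px, pv, bandwidth)
  structure(
    list(x = px, vhat = pv, h = h, n = n, kernel = "gaussian",
         bandwidth_rule = if (is.character(bandwidth)) bandwidth else "fixed",
         label = label, prior = prior,
         x_name = x, vhat_name = vhat),
    class = "vt_kde"
  )
}

kde_bandwidth <- function(px, pv, bandwidth) {
  if (is.numeric(bandwidth)) {
    stopifnot(length(bandwidth) == 2L, all(bandwidth > 0))
    return(unname(bandwidth))
  }
  rule <- match.arg(bandwidth, c("scott", "silverman"))
  n <- length(px)
  # d = 2: Scott n^(-1/(d+4)); Silverman adds the (4/(d+2))^(1/(d+4)) factor
  fac <- if (rule == "scott") n^(-1 / 6) else (4 / 4)^(1 / 6) * n^(-1 / 6)
  c(sd(px) * fac, sd(pv) * fac)
}

#' Evaluate a fitted kernel density at arbitrary points
#'
#' @param object A `vt_kde` model.
#' @param x,vhat Numeric vectors of evaluation coordinates (same length).
#' @param ... Unused.
#' @return Numeric vector of density values.
#' @export
predict.vt_kde <- function(object, x, vhat, ...) {
  stopifnot(length(x) == length(vhat))
  hx <- object$h[1]; hv <- object$h[2]
  m <- length(x)
  out <- numeric(m)
  # chunked so the m x n kernel matrix stays small
  chunk <- max(1L, floor(2e6 / object$n))
  for (s in seq(1L, m, by = chunk)) {
    idx <- s:min(m, s + chunk - 1L)
    kx <- dnorm(outer(x[idx], object$x, "-") / hx)
    kv <- dnorm(outer(vhat[idx], object$vhat, "-") / hv)
    out[idx] <- rowMeans(kx * kv) / (hx * hv)
  }
  out
}

# Density on the full outer grid, exploiting the product-kernel structure:
# D[i, j] = (1/n) sum_k K((xg_i - x_k)/hx)/hx * K((vg_j - v_k)/hv)/hv
kde_grid_density <- function(object, x_grid, vhat_grid) {
  hx <- object$h[1]; hv <- object$h[2]
  kx <- dnorm(outer(x_grid, object$x, "-") / hx) / hx
  kv <- dnorm(outer(vhat_grid, object$vhat, "-") / hv) / hv
  (kx %*% t(kv)) / object$n
}

#' @export
print.vt_kde <- function(x, ...) {
  cat("2-D Gaussian kernel density (", x$label, ")\n", sep = "")
  cat("  n = ", x$n, ", bandwidths (", x$x_name, ", ", x$vhat_name, ") = (",
      signif(x$h[1], 4), ", ", signif(x$h[2], 4), ") [", x$bandwidth_rule,
      "], prior = ", x$prior, "\n", sep = "")
  invisible(x)
}

#' @rdname tidy.vt_boundary
#' @method glance vt_kde
#' @export
glance.vt_kde <- function(x, ...) {
  tibble(label = x$label, n = x$n, bandwidth_x = x$h[1],
         bandwidth_vhat = x$h[2], bandwidth_rule = x$bandwidth_rule,
         prior = x$prior)
}

#' Posterior probability of the documented class
#'
#' The naive Bayes posterior
#' `P(doc | x, vhat) = p_doc f_doc / (p_doc f_doc + p_ctrl f_ctrl)` with the
#' class priors taken from the two models (0.5/0.5 by default). Points where
#' both densities fall below the floor `eps` are outside the support of
#' either class: the posterior defaults to 0.5 and the point is flagged.
#'
#' @param x,vhat Numeric vectors of evaluation coordinates.
#' @param model_doc,model_ctrl `vt_kde` models for the pooled documented and
#'   control non-documented subgroups.
#' @param eps Density floor guarding against underflow (default 1e-12).
#' @return Tibble with columns `x`, `vhat`, `posterior`, `out_of_support`.
#' @export
posterior_documented <- function(x, vhat, model_doc, model_ctrl, eps = 1e-12) {
  stopifnot(inherits(model_doc, "vt_kde"), inherits(model_ctrl, "vt_kde"))
  p_doc <- model_doc$prior
  p_ctrl <- model_ctrl$prior
  if (abs(p_doc + p_ctrl - 1) > 1e-8) {
    abort("class priors must sum to 1")
  }
  if (any(!is.finite(x)) || any(!is.finite(vhat))) {
    abort("non-finite coordinates passed to posterior_documented")
  }
  fd <- predict(model_doc, x, vhat)
  fc <- predict(model_ctrl, x, vhat)
  oos <- fd < eps & fc < eps
  num <- p_doc * fd
  den <- num + p_ctrl * fc
  post <- if_else(oos, 0.5, num / pmax(den, .Machine$double.xmin))
  tibble(x = x, vhat = vhat, posterior = post, out_of_support = oos)
}
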