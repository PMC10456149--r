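# Shared in-code fixtures for the suite. Everything is generated
# programmatically under fixed seeds; nothing is read from disk except the
# committed tiny cohort (itself generated by emit_fixture()).

small_sim <- function(n_ards = 400, n_control = 200, seed = 42, ...) {
  generate_cohort(cohort_sim_config(n_ards = n_ards, n_control = n_control,
                                    seed = seed, ...))
}

# Two well-separated synthetic classes in the (x, vhat) plane:
# documented vhat ~ N(6, 1), control vhat ~ N(9, 1). x is independent of
# class and uniform over the evaluation grid so every boundary column has
# data support.
two_class_models <- function(n = 500, seed = 42, mu = c(6, 9), sd = 1) {
  set.seed(seed)
  doc <- data.frame(height_z = runif(n, -3, 3),
                    vhat_lowest = rnorm(n, mu[1], sd))
  ctl <- data.frame(height_z = runif(n, -3, 3),
                    vhat_lowest = rnorm(n, mu[2], sd))
  list(doc = fit_kde(doc, label = "pooled_documented"),
       ctrl = fit_kde(ctl, label = "control_non_documented"))
}

# Minimal screen-shaped tibble for select_factor_x() unit tests.
fake_screen <- function(factor, beta_std, significant, n_used = 1000) {
  out <- tibble::tibble(factor = factor, beta_std = beta_std,
                        ci_low = beta_std - 1, ci_high = beta_std + 1,
                        p_value = ifelse(significant, 1e-10, 0.5),
                        n_used = n_used,
                        availability = 1, significant = significant,
                        note = NA_character_)
  class(out) <- c("ards_screen", class(out))
  out
}

trapz2d <- function(z, xg, yg) {
  wx <- diff(xg)
  wy <- diff(yg)
  inner <- apply(z, 1, function(row) sum((row[-1] + row[-length(row)]) / 2 * wy))
  sum((inner[-1] + inner[-length(inner)]) / 2 * wx)
}
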