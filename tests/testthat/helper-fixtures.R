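# Shared fixtures (memoised: the small synthetic study and its fit are
# built once per test run) and independent oracles.

.sl_cache <- new.env(parent = emptyenv())

sl_small_config <- function(seed = 42L) {
  sim_config(n_countries = 6L, registries_per_country = 1L, seed = seed)
}

# 288-stratum synthetic study + full-model fit + robust vcov + surface
sl_small_fit <- function() {
  if (is.null(.sl_cache$small)) {
    sim <- simulate_study(sl_small_config())
    design <- build_design(sim$strata, sim$cross_basis)
    fit <- fit_negbin(design)
    robust <- cluster_sandwich(fit, design)
    surface <- predict_surface(fit, sim$cross_basis, vcov = robust)
    .sl_cache$small <- list(sim = sim, design = design, fit = fit,
                            robust = robust, surface = surface)
  }
  .sl_cache$small
}

# flat prevalence panel with one value per cell, invertible to its inputs
sl_toy_panel <- function(years = 1975:2012, value = function(band, year) 30) {
  bands <- panel_age_bands(30L)
  grid <- expand.grid(country = "X", gender = "F", age_band = bands,
                      year = years, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  grid$prevalence <- mapply(value, grid$age_band, grid$year)
  prevalence_panel(grid)
}

# truncated-power natural cubic spline basis (independent oracle):
# columns x and d_j(x) - d_{K-1}(x), j = 1..K-2, with
# d_j(x) = ((x - t_j)_+^3 - (x - t_K)_+^3) / (t_K - t_j).
tp_natural_spline <- function(x, knots) {
  knots <- sort(knots)
  K <- length(knots)
  stopifnot(K >= 2)
  pp3 <- function(u) pmax(u, 0)^3
  d <- function(j) {
    (pp3(x - knots[j]) - pp3(x - knots[K])) / (knots[K] - knots[j])
  }
  out <- matrix(x, ncol = 1)
  if (K > 2) {
    dK1 <- d(K - 1)
    for (j in seq_len(K - 2)) out <- cbind(out, d(j) - dK1)
  }
  out
}

# max residual of projecting each column of `target` onto span(1, basis)
sl_projection_residual <- function(target, basis) {
  fit <- stats::lm.fit(cbind(1, basis), target)
  max(abs(as.matrix(fit$residuals)))
}
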