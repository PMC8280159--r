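# Registry-structured synthetic data. The generator states a world shaped
# like the study design: 43 countries with a couple of registries each,
# eight 5-year age bands (40-44..75-79), two genders, outcome years
# 2010-2012, a 30-year lag window, smooth bounded smoking-prevalence
# trajectories back to 1980 (and down to the 10-14 band so backward cohort
# matching always resolves), and negative binomial counts whose log-mean
# follows the incidence model exactly, with a known true exposure-lag
# surface.

default_wave_surface <- function(x, l) {
  # wave-like truth: inverted-U then U over lag, direction set by the sign
  # of the prevalence increment relative to 50%; zero at lag 0 and at 50%
  g <- (x - 50) / 50
  0.3 * (g + 0.3 * g^2) * sin(pi * l / 11) * exp(-l / 25)
}

#' Simulation configuration
#'
#' Defaults state a registry world at the scale of the real study: 43
#' countries x 2 registries, 8 age bands, 2 genders, outcome years
#' 2010-2012 (2064 strata), lag 0..30, NB dispersion theta = 5. Baseline
#' rate and age/gender effects are anchored to the order of magnitude of
#' the observed case counts (about 1e-4 .. 5e-3 cases per person-year,
#' rising steeply with age, male excess growing with age). Prevalence
#' trajectories are mean-reverting AR(1) walks reflected into [0, 100].
#'
#' @param n_countries,registries_per_country registry structure.
#' @param outcome_years integer vector of outcome years.
#' @param lag_max maximal lag (years).
#' @param df_exposure,df_lag spline degrees of freedom used to build the
#'   generating cross-basis.
#' @param lag_knot_scale knot scale of the lag basis.
#' @param reference reference prevalence (%) for the reported true surface.
#' @param alpha baseline log incidence rate (female, 40-44, first country
#'   and year, at zero cross-basis contribution).
#' @param theta NB2 dispersion; var = mu + mu^2 / theta.
#' @param age_effects length-8 log rate ratios across age bands (first 0).
#' @param gender_effect male main effect (log scale).
#' @param interaction_effects length-8 extra male effect by age band
#'   (first 0).
#' @param year_effects log effects per outcome year (first 0).
#' @param country_sd sd of country random intercepts (drawn once per
#'   country).
#' @param population_meanlog,population_sdlog log-normal person-years per
#'   stratum.
#' @param prevalence list: `mean_male`, `mean_female` (long-run levels, %),
#'   `band_sd` (spread of band-specific levels), `phi` (AR(1)
#'   autocorrelation), `innovation_sd` (annual innovation, percentage
#'   points).
#' @param true_surface either a function f(x, l) (projected onto the
#'   generating cross-basis, so the truth is exactly representable) or a
#'   numeric coefficient vector of length `df_exposure * df_lag` used
#'   directly.
#' @param seed integer seed.
#' @return a list of class `"sim_config"`.
#' @export
sim_config <- function(n_countries = 43L, registries_per_country = 2L,
                       outcome_years = 2010:2012, lag_max = 30L,
                       df_exposure = 4L, df_lag = 4L,
                       lag_knot_scale = "log-lag",
                       reference = 50,
                       alpha = log(8e-5), theta = 5,
                       age_effects = c(0, 1.0, 1.7, 2.14, 2.63, 3.09,
                                       3.33, 3.47),
                       gender_effect = 0.03,
                       interaction_effects = seq(0, 0.6, length.out = 8L),
                       year_effects = NULL,
                       country_sd = 0.3,
                       population_meanlog = log(2.1e5),
                       population_sdlog = 0.6,
                       prevalence = list(mean_male = 42, mean_female = 22,
                                         band_sd = 8, phi = 0.95,
                                         innovation_sd = 1.2),
                       true_surface = default_wave_surface,
                       seed = 1L) {
  if (is.null(year_effects)) {
    year_effects <- seq(0, by = -0.01, length.out = length(outcome_years))
  }
  stopifnot(n_countries >= 1L, registries_per_country >= 1L,
            lag_max >= 1L, theta > 0,
            length(age_effects) == 8L, length(interaction_effects) == 8L,
            length(year_effects) == length(outcome_years))
  structure(list(
    n_countries = as.integer(n_countries),
    registries_per_country = as.integer(registries_per_country),
    outcome_years = as.integer(outcome_years), lag_max = as.integer(lag_max),
    df_exposure = as.integer(df_exposure), df_lag = as.integer(df_lag),
    lag_knot_scale = lag_knot_scale, reference = reference,
    alpha = alpha, theta = theta,
    age_effects = age_effects, gender_effect = gender_effect,
    interaction_effects = interaction_effects, year_effects = year_effects,
    country_sd = country_sd,
    population_meanlog = population_meanlog,
    population_sdlog = population_sdlog,
    prevalence = prevalence, true_surface = true_surface,
    seed = as.integer(seed)), class = "sim_config")
}

sim_countries <- function(config) sprintf("C%02d", seq_len(config$n_countries))

#' Generate a synthetic smoking-prevalence panel
#'
#' One trajectory per (country, gender, age band): a mean-reverting AR(1)
#' process around a band- and gender-specific long-run level, reflected at
#' 0 and 100, started at its stationary distribution, covering every
#' calendar year and band that backward cohort matching can reach.
#'
#' @param config a [sim_config()].
#' @param seed seed (defaults to `config$seed`).
#' @return a [prevalence_panel()].
#' @export
generate_prevalence_panel <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  pv <- config$prevalence
  years <- (min(config$outcome_years) - config$lag_max):max(config$outcome_years)
  bands <- panel_age_bands(config$lag_max)
  grid <- expand.grid(country = sim_countries(config), gender = c("F", "M"),
                      age_band = bands, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  sd_stat <- pv$innovation_sd / sqrt(max(1 - pv$phi^2, 1e-8))
  reflect <- function(v) {
    v <- abs(v)
    ifelse(v > 100, 200 - v, v)
  }
  out <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    m <- if (grid$gender[i] == "M") pv$mean_male else pv$mean_female
    m <- min(max(m + stats::rnorm(1, 0, pv$band_sd), 2), 98)
    v <- numeric(length(years))
    v[1] <- reflect(m + stats::rnorm(1, 0, sd_stat))
    for (t in seq_along(years)[-1]) {
      v[t] <- reflect(m + pv$phi * (v[t - 1] - m) +
                        stats::rnorm(1, 0, pv$innovation_sd))
    }
    out[[i]] <- data.frame(country = grid$country[i], gender = grid$gender[i],
                           age_band = grid$age_band[i], year = years,
                           prevalence = v, stringsAsFactors = FALSE)
  }
  prevalence_panel(do.call(rbind, out))
}

project_surface <- function(f, cb) {
  xg <- seq(cb$exposure_spec$boundary_knots[1],
            cb$exposure_spec$boundary_knots[2], length.out = 60)
  lg <- 0:cb$lag_max
  P <- do.call(rbind, lapply(lg, function(l) point_basis_matrix(xg, l, cb)))
  target <- as.numeric(vapply(lg, function(l) f(xg, l), numeric(length(xg))))
  qr.coef(qr(P), target)
}

#' Generate synthetic registry counts from a known surface
#'
#' Builds the full strata grid, draws populations, assembles cohort-matched
#' exposure histories from the panel, constructs the generating cross-basis
#' (knots placed exactly as the fitting pipeline would place them on these
#' data, so the truth lies in the model space), and draws NB counts with
#' log-mean alpha + log P + cross-basis + covariate effects.
#'
#' @param config a [sim_config()].
#' @param panel a [prevalence_panel()] covering the required rectangle.
#' @param seed seed (defaults to `config$seed + 1`).
#' @return list: `strata` (validated strata table including the drawn
#'   `cases`), `histories`, `cross_basis`, `true_beta`, `true_log_irr`
#'   (matrix on `exposure_grid` x `lag_grid`, contrasts against the
#'   configured reference), `exposure_grid`, `lag_grid`, `linpred`, `config`.
#' @export
generate_counts <- function(config, panel, seed = config$seed + 1L) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  countries <- sim_countries(config)
  bands <- outcome_age_bands()
  grid <- expand.grid(
    registry_no = seq_len(config$registries_per_country),
    country = countries, age_group = bands, gender = c("F", "M"),
    outcome_year = config$outcome_years,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  strata <- data.frame(
    country = grid$country,
    registry = sprintf("%s-R%d", grid$country, grid$registry_no),
    age_group = grid$age_group, gender = grid$gender,
    outcome_year = grid$outcome_year,
    cases = 0, population = stats::rlnorm(nrow(grid),
                                          config$population_meanlog,
                                          config$population_sdlog),
    stringsAsFactors = FALSE)
  histories <- exposure_histories(panel, strata, config$lag_max)
  cb <- cross_basis(
    histories,
    default_knots(as.numeric(histories), config$df_exposure),
    default_knots(0:config$lag_max, config$df_lag,
                  scale = config$lag_knot_scale))
  beta <- if (is.function(config$true_surface)) {
    project_surface(config$true_surface, cb)
  } else {
    stopifnot(length(config$true_surface) == cb$df_x * cb$df_lag)
    as.numeric(config$true_surface)
  }
  gamma <- stats::setNames(c(0, stats::rnorm(length(countries) - 1L, 0,
                                             config$country_sd)), countries)
  age_idx <- match(strata$age_group, bands)
  year_idx <- match(strata$outcome_year, config$outcome_years)
  male <- as.numeric(strata$gender == "M")
  linpred <- config$alpha + log(strata$population) +
    drop(cb$matrix %*% beta) +
    gamma[strata$country] +
    config$age_effects[age_idx] +
    config$gender_effect * male +
    config$year_effects[year_idx] +
    config$interaction_effects[age_idx] * male
  mu <- exp(linpred)
  if (any(!is.finite(mu)) || max(mu) > 1e10) {
    stop("synthetic means overflow; choose smaller effects in sim_config",
         call. = FALSE)
  }
  strata$cases <- stats::rnbinom(nrow(strata), mu = mu, size = config$theta)
  strata <- validate_strata(strata)
  exposure_grid <- 1:81
  lag_grid <- 0:config$lag_max
  true_log_irr <- vapply(lag_grid, function(l) {
    drop((point_basis_matrix(exposure_grid, l, cb) -
            point_basis_matrix(rep(config$reference, length(exposure_grid)),
                               l, cb)) %*% beta)
  }, numeric(length(exposure_grid)))
  dimnames(true_log_irr) <- list(paste0("x", exposure_grid),
                                 paste0("lag", lag_grid))
  list(strata = strata, histories = histories, cross_basis = cb,
       true_beta = beta, true_log_irr = true_log_irr,
       exposure_grid = exposure_grid, lag_grid = lag_grid,
       linpred = unname(linpred), config = config)
}

#' One-call synthetic study
#'
#' [generate_prevalence_panel()] then [generate_counts()] under seeds
#' derived from `config$seed`; the result additionally carries the panel.
#'
#' @param config a [sim_config()].
#' @return the [generate_counts()] list plus `panel`.
#' @export
simulate_study <- function(config = sim_config()) {
  panel <- generate_prevalence_panel(config)
  out <- generate_counts(config, panel)
  out$panel <- panel
  out
}
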