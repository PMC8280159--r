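# true coefficient vector of a synthetic study, in the design's dummy
# coding (first sorted level of every factor is the reference, so the
# generator's zero-indexed effects map one-to-one onto the dummies)
true_design_coefficients <- function(sim, design) {
  cfg <- sim$config
  co <- stats::setNames(numeric(ncol(design$X)), colnames(design$X))
  co["(Intercept)"] <- cfg$alpha
  co[design$cb_idx] <- sim$true_beta
  bands <- outcome_age_bands()
  co[paste0("age_", bands[-1])] <- cfg$age_effects[-1]
  co["gender_M"] <- cfg$gender_effect
  yrs <- sort(unique(sim$strata$outcome_year))
  co[paste0("year_", yrs[-1])] <- cfg$year_effects[-1]
  co[paste0("age_M_", bands[-1])] <- cfg$interaction_effects[-1]
  co
}

test_that("design dummy coding matches the counting oracle", {
  fx <- sl_small_fit()
  strata <- fx$sim$strata
  two <- strata[strata$country %in% c("C01", "C02"), ]
  h <- fx$sim$histories[strata$country %in% c("C01", "C02"), ]
  cb <- cross_basis(h, fx$sim$cross_basis$exposure_spec,
                    fx$sim$cross_basis$lag_spec)
  d <- build_design(two, cb)
  # 1 + 16 + (2-1) + (8-1) + 1 + (3-1) + 7 = 35
  expect_equal(ncol(d$X), 35L)
  d_noint <- build_design(two, cb, interaction = FALSE)
  expect_equal(ncol(d_noint$X), 28L)
  # single-country input: no country dummies
  one <- strata[strata$country == "C01", ]
  cb1 <- cross_basis(fx$sim$histories[strata$country == "C01", ],
                     cb$exposure_spec, cb$lag_spec)
  expect_equal(ncol(build_design(one, cb1)$X), 34L)
  expect_false(any(grepl("^country_", colnames(build_design(one, cb1)$X))))
})

test_that("permuting rows permutes the design identically", {
  fx <- sl_small_fit()
  set.seed(21)
  perm <- sample(nrow(fx$sim$strata))
  cbp <- fx$sim$cross_basis
  cbp$matrix <- cbp$matrix[perm, ]
  dp <- build_design(fx$sim$strata[perm, ], cbp)
  expect_equal(unname(dp$X), unname(fx$design$X[perm, ]))
  expect_equal(dp$offset, fx$design$offset[perm])
})

test_that("rank deficiency is reported with the aliased columns", {
  fx <- sl_small_fit()
  strata <- fx$sim$strata
  strata$gender <- "F"  # gender aliased with nothing -> dropped, fine
  expect_silent(d <- build_design(strata, fx$sim$cross_basis))
  expect_false("gender_M" %in% colnames(d$X))
  # age band and gender perfectly confounded -> aliased dummies, named
  set.seed(22)
  n <- 24L
  strata2 <- data.frame(
    country = "A", registry = rep(c("A-1", "A-2"), n / 2),
    age_group = rep(c("40-44", "45-49"), each = n / 2),
    gender = rep(c("F", "M"), each = n / 2),
    outcome_year = rep(2010:2012, n / 3),
    cases = rpois(n, 20), population = 1e5, stringsAsFactors = FALSE)
  h2 <- matrix(runif(n * 31, 10, 70), n)
  cb2 <- cross_basis(h2, fx$sim$cross_basis$exposure_spec,
                     fx$sim$cross_basis$lag_spec)
  expect_error(build_design(strata2, cb2), "aliased")
})

test_that("the NB fit attains the Poisson limit on equidispersed data", {
  fx <- sl_small_fit()
  set.seed(23)
  strata <- fx$sim$strata
  strata$cases <- rpois(nrow(strata), exp(fx$sim$linpred))
  d <- build_design(strata, fx$sim$cross_basis)
  f <- fit_negbin(d)
  pg <- stats::glm.fit(d$X, d$y, family = stats::poisson(),
                       offset = d$offset,
                       control = list(epsilon = 1e-12, maxit = 100))
  expect_gt(f$theta, 1e4)
  expect_lt(max(abs(f$coefficients - pg$coefficients)), 1e-4)
})

test_that("the fit matches MASS::glm.nb and maximises the likelihood", {
  fx <- sl_small_fit()
  d <- fx$design; f <- fx$fit
  expect_true(f$converged)
  df <- data.frame(y = d$y, off = d$offset)
  Xn <- d$X[, -1, drop = FALSE]
  oracle <- MASS::glm.nb(y ~ Xn + offset(off), data = df,
                         control = stats::glm.control(epsilon = 1e-12,
                                                      maxit = 100))
  expect_lt(max(abs(unname(coef(oracle)) - unname(f$coefficients))), 1e-5)
  expect_equal(f$theta, oracle$theta, tolerance = 1e-6)
  expect_equal(f$loglik, as.numeric(logLik(oracle)), tolerance = 1e-10)
  # ML dominance: fitted likelihood >= likelihood at the generating truth
  truth <- true_design_coefficients(fx$sim, d)
  # country effects are random; plug in the fitted ones so the comparison
  # penalises only the structural parameters
  truth[grep("^country_", names(truth))] <-
    f$coefficients[grep("^country_", names(f$coefficients))]
  mu_true <- exp(d$offset + drop(d$X %*% truth))
  expect_gte(f$loglik, smokelag:::nb_loglik(d$y, mu_true, fx$sim$config$theta))
  # score ~ 0 at the optimum
  u <- (d$y - f$fitted) * f$theta / (f$fitted + f$theta)
  expect_lt(max(abs(crossprod(d$X, u))), 1e-6 * nrow(d$X))
})

test_that("rescaling the population only shifts the intercept", {
  fx <- sl_small_fit()
  strata <- fx$sim$strata
  strata$population <- strata$population * 10
  f2 <- fit_negbin(build_design(strata, fx$sim$cross_basis), tol = 1e-12)
  delta <- f2$coefficients - fx$fit$coefficients
  expect_equal(unname(delta["(Intercept)"]), -log(10), tolerance = 1e-6)
  expect_lt(max(abs(delta[-1])), 1e-6)
  expect_equal(f2$theta, fx$fit$theta, tolerance = 1e-4)
})

test_that("theta and the surface are recovered from synthetic data", {
  errs <- numeric(2); thetas <- numeric(2)
  for (k in 1:2) {
    sim <- simulate_study(sim_config(n_countries = 14L,
                                     registries_per_country = 3L,
                                     seed = 700L + k))
    d <- build_design(sim$strata, sim$cross_basis)
    f <- fit_negbin(d)
    s <- predict_surface(f, sim$cross_basis)
    errs[k] <- mean(abs(s$log_irr - sim$true_log_irr))
    thetas[k] <- f$theta
    # every cross-basis coefficient within 4 standard errors of its truth
    se <- sqrt(diag(f$vcov))[d$cb_idx]
    expect_lt(max(abs(f$coefficients[d$cb_idx] - sim$true_beta) / se), 4)
  }
  expect_lt(mean(abs(thetas - 5) / 5), 0.2)
  expect_lt(mean(errs), 0.05)
})

test_that("AIC bookkeeping is reproducible and guarded", {
  fx <- sl_small_fit()
  f <- fx$fit
  expect_equal(f$aic, -2 * f$loglik + 2 * (f$n_par + 1))
  tab <- compare_aic(list(a = f, b = f))
  expect_equal(tab$delta_aic, c(0, 0))
  other <- f
  other$fingerprint["sum_y"] <- other$fingerprint["sum_y"] + 1
  expect_error(compare_aic(list(f, other)), "different response")
})

test_that("the candidate preset fits four comparable models", {
  fx <- sl_small_fit()
  cs <- fit_candidate_set(fx$sim$strata, fx$sim$histories)
  expect_named(cs$fits, c("full", "no_interaction", "df3",
                          "df3_no_interaction"))
  expect_equal(nrow(cs$aic_table), 4L)
  expect_equal(cs$aic_table$delta_aic[1], 0)
  expect_true(all(diff(cs$aic_table$aic) >= 0))
})
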