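test_that("IRR is exactly 1 at the reference and at lag 0", {
  s <- sl_small_fit()$surface
  ref_row <- match(50, s$exposure_grid)
  expect_lt(max(abs(s$log_irr[ref_row, ])), 1e-10)
  expect_lt(max(abs(s$log_irr[, 1])), 1e-10)   # lag 0 column
  # degenerate CIs there: a null contrast has zero delta-method variance
  expect_lt(max(s$se[ref_row, ]), 1e-10)
  expect_equal(unname(s$irr_low[ref_row, ]), rep(1, ncol(s$irr)),
               tolerance = 1e-9)
  expect_lt(max(s$se[, 1]), 1e-10)
})

test_that("surface entries match a from-scratch contrast computation", {
  fx <- sl_small_fit()
  s <- fx$surface; f <- fx$fit; cb <- fx$sim$cross_basis
  beta <- f$coefficients[f$cb_idx]
  V <- fx$robust$matrix[f$cb_idx, f$cb_idx]
  # raw spline evaluations, assembled independently of point_basis
  xs <- cb$exposure_spec; ls <- cb$lag_spec
  raw <- function(x, l) {
    bx <- drop(splines::ns(x, knots = xs$interior_knots,
                           Boundary.knots = xs$boundary_knots))
    bl <- drop(splines::ns(l, knots = ls$interior_knots,
                           Boundary.knots = ls$boundary_knots)) -
      drop(splines::ns(0, knots = ls$interior_knots,
                       Boundary.knots = ls$boundary_knots))
    as.numeric(t(outer(bx, bl)))  # exposure-major flattening
  }
  for (pt in list(c(20, 5), c(65, 10), c(81, 16), c(35, 28))) {
    cvec <- raw(pt[1], pt[2]) - raw(50, pt[2])
    i <- match(pt[1], s$exposure_grid); j <- match(pt[2], s$lag_grid)
    expect_equal(s$log_irr[i, j], sum(cvec * beta), tolerance = 1e-10,
                 ignore_attr = TRUE)
    expect_equal(s$se[i, j], sqrt(drop(t(cvec) %*% V %*% cvec)),
                 tolerance = 1e-10, ignore_attr = TRUE)
  }
})

test_that("cumulative IRR obeys the product and null identities", {
  s <- sl_small_fit()$surface
  L <- max(s$lag_grid)
  for (x in c(10, 40, 73)) {
    i <- match(x, s$exposure_grid)
    out <- cumulative_irr(s, x, L)
    expect_equal(out$irr_cum, prod(s$irr[i, ]), tolerance = 1e-10)
  }
  h0 <- cumulative_irr(s, 30, 0)
  expect_equal(h0$irr_cum, 1, tolerance = 1e-12)   # lag-0 constraint
  ref <- cumulative_irr(s, 50, 17)
  expect_equal(ref$irr_cum, 1, tolerance = 1e-12)
  expect_lt(ref$se, 1e-12)
  expect_error(cumulative_irr(s, 40.5, 10), "exposure grid")
  expect_error(cumulative_irr(s, 40, 31), "lag grid")
})

test_that("interval ordering and exp/log consistency hold everywhere", {
  s <- sl_small_fit()$surface
  expect_equal(s$irr, exp(s$log_irr))
  expect_true(all(s$irr_low <= s$irr & s$irr <= s$irr_high))
  expect_true(all(s$irr_cum_low <= s$irr_cum & s$irr_cum <= s$irr_cum_high))
  expect_equal(s$cum_log_irr[, ncol(s$cum_log_irr)],
               rowSums(s$log_irr), tolerance = 1e-12)
  tidy <- as.data.frame(s)
  expect_equal(nrow(tidy), length(s$exposure_grid) * length(s$lag_grid))
  i <- match(60, s$exposure_grid); j <- match(12, s$lag_grid)
  expect_equal(tidy$irr[tidy$exposure == 60 & tidy$lag == 12], s$irr[i, j])
})

test_that("scenario tables reduce to cumulative IRRs and guard their input", {
  fx <- sl_small_fit()
  f <- fx$fit; cb <- fx$sim$cross_basis; rv <- fx$robust
  # no-change scenario: all ones with degenerate intervals
  none <- scenario_irr_cum(f, cb, 50, 50, horizon = 12, vcov = rv)
  expect_equal(none$irr_cum, rep(1, 13), tolerance = 1e-12)
  expect_equal(none$low, rep(1, 13), tolerance = 1e-9)
  # constant path at 40%: year h equals cumulative_irr(40, h)
  tab <- scenario_irr_cum(f, cb, 50, 40, horizon = 10, vcov = rv)
  for (h in c(0, 3, 10)) {
    ci <- cumulative_irr(fx$surface, 40, h)
    expect_equal(tab$irr_cum[h + 1], ci$irr_cum, tolerance = 1e-10)
    expect_equal(tab$low[h + 1], ci$low, tolerance = 1e-10)
  }
  # a genuinely time-varying path differs from any constant one
  ramp <- scenario_irr_cum(f, cb, 50, seq(50, 30, length.out = 11),
                           horizon = 10, vcov = rv)
  expect_gt(max(abs(ramp$irr_cum - tab$irr_cum)), 1e-6)
  expect_error(scenario_irr_cum(f, cb, 50, rep(40, 13), horizon = 10),
               "length")
  expect_error(scenario_irr_cum(f, cb, 50, 140, horizon = 10), "\\[0, 100\\]")
  expect_error(scenario_irr_cum(f, cb, 50, 40, horizon = 40), "horizon")
})

test_that("a reference outside the boundary knots warns but predicts", {
  fx <- sl_small_fit()
  hi <- fx$sim$cross_basis$exposure_spec$boundary_knots[2]
  expect_warning(
    s <- predict_surface(fx$fit, fx$sim$cross_basis,
                         exposure_grid = c(20, 50, ceiling(hi) + 5),
                         reference = ceiling(hi) + 5),
    "linear tails")
  expect_true(all(is.finite(s$log_irr)))
})

test_that("the fit bundle reproduces predictions after a YAML round trip", {
  fx <- sl_small_fit()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_fit_bundle(path, fx$fit, fx$sim$cross_basis, fx$robust)
  b <- read_fit_bundle(path)
  expect_equal(b$fit$coefficients, fx$fit$coefficients, tolerance = 1e-12)
  expect_equal(b$robust$matrix, fx$robust$matrix, tolerance = 1e-12)
  s2 <- predict_surface(b$fit, b$cb, vcov = b$robust)
  expect_equal(s2$log_irr, fx$surface$log_irr, tolerance = 1e-10)
  expect_equal(s2$cum_se, fx$surface$cum_se, tolerance = 1e-10)
  tab <- scenario_irr_cum(b$fit, b$cb, 50, 40, 10, vcov = b$robust)
  tab0 <- scenario_irr_cum(fx$fit, fx$sim$cross_basis, 50, 40, 10,
                           vcov = fx$robust)
  expect_equal(tab, tab0, tolerance = 1e-10)
})
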