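# Backward-perspective IRR prediction. For exposure x at lag l the
# log-IRR relative to a reference prevalence x0 is c' beta with contrast
# c = point_basis(x, l) - point_basis(x0, l); delta-method standard errors
# come from the cross-basis block of the (preferably cluster-robust)
# covariance. Cumulative IRRs sum log-IRRs over lags 0..h and use the
# summed contrast for the variance (full delta method, not a sum of
# variances).

z_level <- function(level) stats::qnorm(1 - (1 - level) / 2)

beta_block <- function(fit, vcov_full) {
  idx <- fit$cb_idx
  list(beta = fit$coefficients[idx],
       V = vcov_full[idx, idx, drop = FALSE])
}

#' Predict the exposure-lag IRR surface
#'
#' @param fit a [fit_negbin()] result.
#' @param cb the [cross_basis()] the model was fitted with (metadata only).
#' @param vcov covariance to use: a [cluster_sandwich()] result, a plain
#'   matrix, or `NULL` for the model-based covariance.
#' @param exposure_grid exposure (% prevalence) grid; default 1..81 by 1.
#' @param lag_grid lag grid (years), subset of `0:lag_max`.
#' @param reference reference prevalence (%); IRR = 1 there at every lag.
#'   A reference outside the exposure-basis boundary knots triggers a
#'   warning (predictions remain defined through the linear tails).
#' @param level confidence level of the normal-approximation intervals.
#' @return object of class `"effect_surface"`: matrices (`exposure_grid` x
#'   `lag_grid`) `log_irr`, `se`, `irr`, `irr_low`, `irr_high`, and the
#'   lag-cumulative analogues `cum_log_irr`, `cum_se`, `irr_cum`,
#'   `irr_cum_low`, `irr_cum_high`.
#' @export
predict_surface <- function(fit, cb, vcov = NULL,
                            exposure_grid = 1:81,
                            lag_grid = 0:cb$lag_max,
                            reference = 50, level = 0.95) {
  stopifnot(inherits(fit, "nb_fit"), inherits(cb, "cross_basis"))
  if (any(lag_grid < 0 | lag_grid > cb$lag_max)) {
    stop("lag_grid outside [0, lag_max]", call. = FALSE)
  }
  bk <- cb$exposure_spec$boundary_knots
  if (reference < bk[1] || reference > bk[2]) {
    warning(sprintf(
      "reference %g%% lies outside the exposure boundary knots [%g, %g]; %s",
      reference, bk[1], bk[2],
      "predictions use the linear tails"), call. = FALSE)
  }
  bb <- beta_block(fit, resolve_vcov(vcov, fit))
  z <- z_level(level)
  nx <- length(exposure_grid); nl <- length(lag_grid)
  p <- length(bb$beta)
  log_irr <- se <- cum_log <- cum_se <- matrix(0, nx, nl,
    dimnames = list(paste0("x", exposure_grid), paste0("lag", lag_grid)))
  wsum <- matrix(0, nx, p)
  for (j in seq_len(nl)) {
    l <- lag_grid[j]
    C <- point_basis_matrix(exposure_grid, l, cb) -
      point_basis_matrix(rep(reference, nx), l, cb)
    log_irr[, j] <- drop(C %*% bb$beta)
    se[, j] <- sqrt(pmax(rowSums((C %*% bb$V) * C), 0))
    wsum <- wsum + C
    cum_log[, j] <- if (j == 1L) log_irr[, j] else cum_log[, j - 1L] + log_irr[, j]
    cum_se[, j] <- sqrt(pmax(rowSums((wsum %*% bb$V) * wsum), 0))
  }
  structure(list(
    exposure_grid = exposure_grid, lag_grid = lag_grid,
    reference = reference, level = level,
    log_irr = log_irr, se = se,
    irr = exp(log_irr),
    irr_low = exp(log_irr - z * se), irr_high = exp(log_irr + z * se),
    cum_log_irr = cum_log, cum_se = cum_se,
    irr_cum = exp(cum_log),
    irr_cum_low = exp(cum_log - z * cum_se),
    irr_cum_high = exp(cum_log + z * cum_se)),
    class = "effect_surface")
}

#' @export
print.effect_surface <- function(x, ...) {
  cat(sprintf(
    "IRR surface: exposure %g..%g%% (%d) x lag %g..%g (%d), reference %g%%\n",
    min(x$exposure_grid), max(x$exposure_grid), length(x$exposure_grid),
    min(x$lag_grid), max(x$lag_grid), length(x$lag_grid), x$reference))
  i <- which(x$log_irr == min(x$log_irr), arr.ind = TRUE)[1L, ]
  j <- which(x$log_irr == max(x$log_irr), arr.ind = TRUE)[1L, ]
  cat(sprintf("  min IRR %.3f at %g%% / lag %g; max IRR %.3f at %g%% / lag %g\n",
              exp(min(x$log_irr)), x$exposure_grid[i[1]], x$lag_grid[i[2]],
              exp(max(x$log_irr)), x$exposure_grid[j[1]], x$lag_grid[j[2]]))
  invisible(x)
}

#' Tidy a surface into a long data frame
#'
#' @param x an [predict_surface()] result.
#' @param ... unused.
#' @return data frame with one row per (exposure, lag) cell.
#' @export
as.data.frame.effect_surface <- function(x, ...) {
  grid <- expand.grid(lag = x$lag_grid, exposure = x$exposure_grid,
                      KEEP.OUT.ATTRS = FALSE)[, c("exposure", "lag")]
  tr <- function(m) as.numeric(t(m))
  data.frame(grid,
             log_irr = tr(x$log_irr), se = tr(x$se), irr = tr(x$irr),
             irr_low = tr(x$irr_low), irr_high = tr(x$irr_high),
             irr_cum = tr(x$irr_cum), irr_cum_low = tr(x$irr_cum_low),
             irr_cum_high = tr(x$irr_cum_high))
}

#' Cumulative IRR at one exposure level
#'
#' exp of the summed log-IRRs over lags 0..`horizon` on the surface's lag
#' grid, with the full delta-method interval.
#'
#' @param surface an [predict_surface()] result.
#' @param x exposure level, must be on the surface's exposure grid.
#' @param horizon lag horizon (years), must be on the surface's lag grid.
#' @return list with `irr_cum`, `low`, `high`, `log_irr_cum`, `se`.
#' @export
cumulative_irr <- function(surface, x, horizon) {
  stopifnot(inherits(surface, "effect_surface"))
  i <- match(x, surface$exposure_grid)
  j <- match(horizon, surface$lag_grid)
  if (is.na(i)) stop("x is not on the surface's exposure grid", call. = FALSE)
  if (is.na(j)) stop("horizon is not on the surface's lag grid", call. = FALSE)
  list(irr_cum = surface$irr_cum[i, j],
       low = surface$irr_cum_low[i, j], high = surface$irr_cum_high[i, j],
       log_irr_cum = surface$cum_log_irr[i, j], se = surface$cum_se[i, j])
}

#' "What-if" prevalence scenario
#'
#' Cumulative IRR of moving a population from the reference prevalence to a
#' new prevalence path, year by year. In scenario year h the exposure at
#' lag l is the path value h - l years after the change (the reference for
#' l > h, which contributes nothing), so a constant path reproduces
#' [cumulative_irr()] at each horizon. Example question: what does reducing
#' prevalence from 50% to 40% sustained for 10 years do to the incidence
#' rate?
#'
#' @param fit a [fit_negbin()] result.
#' @param cb the model's [cross_basis()].
#' @param reference reference prevalence (%).
#' @param new_prevalence scalar (% held constant) or a vector of length
#'   `horizon + 1` giving the prevalence in scenario years 0..horizon.
#' @param horizon last scenario year; at most `lag_max`.
#' @param vcov covariance (see [predict_surface()]).
#' @param level confidence level.
#' @return data frame (year, prevalence, irr_cum, low, high).
#' @export
scenario_irr_cum <- function(fit, cb, reference, new_prevalence, horizon,
                             vcov = NULL, level = 0.95) {
  stopifnot(inherits(fit, "nb_fit"), inherits(cb, "cross_basis"))
  if (horizon < 0 || horizon > cb$lag_max) {
    stop("horizon must lie in [0, lag_max]", call. = FALSE)
  }
  path <- as.numeric(new_prevalence)
  if (length(path) == 1L) path <- rep(path, horizon + 1L)
  if (length(path) != horizon + 1L) {
    stop("new_prevalence must be a scalar or a path of length horizon + 1",
         call. = FALSE)
  }
  if (any(path < 0 | path > 100)) {
    stop("prevalence path values must lie in [0, 100]", call. = FALSE)
  }
  bb <- beta_block(fit, resolve_vcov(vcov, fit))
  z <- z_level(level)
  out <- data.frame(year = 0:horizon, prevalence = path,
                    irr_cum = NA_real_, low = NA_real_, high = NA_real_)
  for (h in 0:horizon) {
    w <- 0
    for (l in 0:h) {
      w <- w + point_basis(path[h - l + 1L], l, cb) -
        point_basis(reference, l, cb)
    }
    est <- sum(w * bb$beta)
    se <- sqrt(max(drop(t(w) %*% bb$V %*% w), 0))
    out$irr_cum[h + 1L] <- exp(est)
    out$low[h + 1L] <- exp(est - z * se)
    out$high[h + 1L] <- exp(est + z * se)
  }
  out
}

# ---- fit bundle serialisation ------------------------------------------

mat_to_list <- function(m) {
  list(dim = dim(m), dimnames = dimnames(m)[[1]], values = as.numeric(m))
}

mat_from_list <- function(x) {
  m <- matrix(unlist(x$values), x$dim[[1]], x$dim[[2]])
  if (!is.null(x$dimnames)) dimnames(m) <- list(unlist(x$dimnames),
                                                unlist(x$dimnames))
  m
}

#' Save / load a fitted model bundle
#'
#' A YAML bundle holding everything needed to reproduce predictions:
#' coefficients, dispersion, model-based and (optionally) robust
#' covariance, cross-basis specification (knots, df, lag range, column
#' order) and dummy reference levels.
#'
#' @param path YAML file path.
#' @param fit a [fit_negbin()] result.
#' @param cb the model's [cross_basis()].
#' @param robust optional [cluster_sandwich()] result.
#' @return `write_fit_bundle`: the path, invisibly. `read_fit_bundle`: a
#'   list with elements `fit` (an `nb_fit` without fitted values), `cb`
#'   (a matrix-free `cross_basis`) and `robust`.
#' @export
write_fit_bundle <- function(path, fit, cb, robust = NULL) {
  stopifnot(inherits(fit, "nb_fit"), inherits(cb, "cross_basis"))
  bundle <- list(
    package = "smokelag",
    coefficients = as.list(fit$coefficients),
    theta = fit$theta, loglik = fit$loglik, aic = fit$aic,
    converged = fit$converged, n = fit$n,
    cb_idx = fit$cb_idx,
    reference_levels = fit$reference_levels,
    vcov = mat_to_list(fit$vcov),
    robust_vcov = if (!is.null(robust)) {
      c(mat_to_list(robust$matrix),
        list(n_clusters = robust$n_clusters, correction = robust$correction))
    },
    cross_basis = cb_to_list(cb),
    fingerprint = as.list(fit$fingerprint))
  yaml::write_yaml(bundle, path, precision = 17)
  invisible(path)
}

#' @rdname write_fit_bundle
#' @export
read_fit_bundle <- function(path) {
  b <- yaml::read_yaml(path)
  fit <- structure(list(
    coefficients = unlist(b$coefficients),
    theta = b$theta, loglik = b$loglik, aic = b$aic,
    converged = b$converged, n = b$n,
    cb_idx = as.integer(unlist(b$cb_idx)),
    reference_levels = b$reference_levels,
    vcov = mat_from_list(b$vcov),
    n_par = length(b$coefficients),
    fingerprint = unlist(b$fingerprint)),
    class = "nb_fit")
  robust <- NULL
  if (!is.null(b$robust_vcov)) {
    robust <- structure(list(matrix = mat_from_list(b$robust_vcov),
                             n_clusters = b$robust_vcov$n_clusters,
                             correction = b$robust_vcov$correction),
                        class = "robust_vcov")
  }
  list(fit = fit, cb = cb_from_list(b$cross_basis), robust = robust)
}
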