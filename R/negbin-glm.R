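# Negative binomial (NB2) GLM with log link and population offset, fitted
# by full maximum likelihood: IRLS for the coefficients at fixed dispersion
# theta, alternated with univariate ML for theta, until the log-likelihood
# stabilises. var(Y) = mu + mu^2 / theta.

#' Build the model design matrix
#'
#' Assembles the fixed-effect design of the incidence model: intercept,
#' cross-basis block, country dummies, age-group dummies, a male indicator
#' (1 = male), outcome-year dummies and (optionally) the age x gender
#' interaction block, together with the response (cases) and the offset
#' log(population). Dummy coding drops the first level in sorted order;
#' reference levels are recorded in the result.
#'
#' @param strata a validated strata table.
#' @param cb a [cross_basis()] whose rows align with `strata`.
#' @param interaction include the age-group x gender interaction block?
#' @return object of class `"nb_design"`: `X`, `y`, `offset`, `cb_idx`
#'   (columns of the cross-basis block), `cluster` (registry labels),
#'   `stratum_id`, `reference_levels`, `fingerprint`.
#' @export
build_design <- function(strata, cb, interaction = TRUE) {
  stopifnot(inherits(cb, "cross_basis"), !is.null(cb$matrix))
  if (nrow(cb$matrix) != nrow(strata)) {
    stop("cross-basis rows and strata rows are not aligned", call. = FALSE)
  }
  n <- nrow(strata)
  dummies <- function(values, prefix) {
    lev <- sort(unique(as.character(values)))
    if (length(lev) < 2L) {
      return(list(m = matrix(numeric(0), n, 0L), ref = lev))
    }
    m <- sapply(lev[-1L], function(v) as.numeric(values == v))
    colnames(m) <- paste0(prefix, lev[-1L])
    list(m = m, ref = lev[1L])
  }
  cty <- dummies(strata$country, "country_")
  age <- dummies(strata$age_group, "age_")
  yr <- dummies(strata$outcome_year, "year_")
  male <- as.numeric(strata$gender == "M")
  gcol <- if (length(unique(strata$gender)) > 1L) {
    matrix(male, n, 1L, dimnames = list(NULL, "gender_M"))
  } else matrix(numeric(0), n, 0L)
  X <- cbind("(Intercept)" = rep(1, n), cb$matrix, cty$m, age$m, gcol, yr$m)
  if (interaction && ncol(age$m) && ncol(gcol)) {
    inter <- age$m * male
    colnames(inter) <- sub("^age_", "age_M_", colnames(age$m))
    X <- cbind(X, inter)
  }
  rownames(X) <- NULL
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("design matrix is rank deficient; aliased column(s): ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }
  off <- log(strata$population)
  structure(list(
    X = X, y = as.numeric(strata$cases), offset = off,
    cb_idx = 1L + seq_len(ncol(cb$matrix)),
    cluster = as.character(strata$registry),
    stratum_id = stratum_id(strata),
    interaction = isTRUE(interaction),
    reference_levels = list(country = cty$ref, age_group = age$ref,
                            gender = "F", outcome_year = yr$ref),
    fingerprint = design_fingerprint(strata$cases, off)),
    class = "nb_design")
}

design_fingerprint <- function(y, off) {
  c(n = length(y), sum_y = sum(y), sum_off = round(sum(off), 8))
}

nb_loglik <- function(y, mu, theta) {
  sum(stats::dnbinom(y, mu = mu, size = theta, log = TRUE))
}

# one IRLS pass to convergence at fixed theta (theta = Inf gives Poisson)
irls_negbin <- function(X, y, off, theta, beta = NULL, max_iter = 60L,
                        eps = 1e-12) {
  if (is.null(beta)) {
    eta <- log(pmax(y, 0.5)) - off
    beta <- qr.coef(qr(X), eta)
  }
  for (i in seq_len(max_iter)) {
    eta <- off + drop(X %*% beta)
    eta <- pmin(eta, 700)
    mu <- exp(eta)
    if (any(!is.finite(mu))) {
      stop("overflow in fitted means (possible separation); check the design",
           call. = FALSE)
    }
    w <- if (is.finite(theta)) mu * theta / (mu + theta) else mu
    z <- (eta - off) + (y - mu) / mu
    fit <- stats::lm.wfit(X, z, w)
    delta <- max(abs(fit$coefficients - beta))
    beta <- fit$coefficients
    if (delta < eps * (1 + max(abs(beta)))) break
  }
  beta
}

#' Fit the negative binomial incidence model
#'
#' Full maximum likelihood for the NB2 log-link GLM with offset: coefficient
#' IRLS at fixed dispersion alternates with univariate ML for theta (on the
#' log scale) until the relative log-likelihood change drops below `tol`.
#' Initialisation is a Poisson fit. The model-based covariance is the
#' inverse observed information for the coefficients at the fitted theta.
#'
#' @param design an [build_design()] result.
#' @param init optional starting coefficient vector.
#' @param tol relative log-likelihood convergence tolerance.
#' @param max_iter maximal number of outer (IRLS + theta) cycles;
#'   non-convergence is flagged, not an error.
#' @return object of class `"nb_fit"`: `coefficients`, `theta`, `vcov`
#'   (model-based), `loglik`, `aic` (theta counted as a parameter),
#'   `converged`, `n_iter`, `fitted` (means), plus bookkeeping copied from
#'   the design (`cb_idx`, `reference_levels`, `fingerprint`).
#' @export
fit_negbin <- function(design, init = NULL, tol = 1e-8, max_iter = 50L) {
  stopifnot(inherits(design, "nb_design"))
  X <- design$X; y <- design$y; off <- design$offset
  theta_grid <- c(log(1e-3), log(1e8))
  beta <- irls_negbin(X, y, off, Inf, beta = init)   # Poisson start
  mu <- exp(off + drop(X %*% beta))
  num <- sum((y - mu)^2 - mu)
  theta <- if (num > 0) max(0.01, sum(mu^2) / num) else 1e8
  ll <- nb_loglik(y, mu, theta)
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    beta <- irls_negbin(X, y, off, theta, beta = beta)
    mu <- exp(off + drop(X %*% beta))
    opt <- stats::optimize(function(lt) nb_loglik(y, mu, exp(lt)),
                           interval = theta_grid, maximum = TRUE,
                           tol = 1e-10)
    theta <- exp(opt$maximum)
    ll_new <- opt$objective
    if (abs(ll_new - ll) < tol * (abs(ll_new) + 1)) {
      ll <- ll_new
      converged <- TRUE
      break
    }
    ll <- ll_new
  }
  w_obs <- mu * theta * (theta + y) / (mu + theta)^2
  info <- crossprod(X * sqrt(w_obs))
  vc <- chol2inv(chol(info))
  dimnames(vc) <- list(colnames(X), colnames(X))
  p <- ncol(X)
  structure(list(
    coefficients = stats::setNames(beta, colnames(X)),
    theta = theta, vcov = vc, loglik = ll,
    aic = -2 * ll + 2 * (p + 1),
    converged = converged, n_iter = iter,
    fitted = mu, cb_idx = design$cb_idx,
    reference_levels = design$reference_levels,
    n = length(y), n_par = p,
    fingerprint = design$fingerprint),
    class = "nb_fit")
}

#' @export
print.nb_fit <- function(x, ...) {
  cat(sprintf(
    "negative binomial fit: %d strata, %d coefficients + theta\n", x$n, x$n_par))
  cat(sprintf("  theta = %.4g, logLik = %.3f, AIC = %.2f%s\n",
              x$theta, x$loglik, x$aic,
              if (x$converged) "" else "  [NOT converged]"))
  invisible(x)
}

#' @export
logLik.nb_fit <- function(object, ...) {
  structure(object$loglik, df = object$n_par + 1, class = "logLik")
}

#' @export
vcov.nb_fit <- function(object, ...) object$vcov

#' Rank candidate models by AIC
#'
#' All fits must be on the same response and offset (checked by a data
#' fingerprint). AIC counts the dispersion parameter.
#'
#' @param fits named list of [fit_negbin()] results.
#' @return data frame (model, n_par, loglik, aic, delta_aic) sorted by AIC.
#' @export
compare_aic <- function(fits) {
  stopifnot(length(fits) >= 1L)
  if (is.null(names(fits)) || any(names(fits) == "")) {
    names(fits) <- paste0("model", seq_along(fits))
  }
  fps <- lapply(fits, `[[`, "fingerprint")
  if (!all(vapply(fps, function(f) isTRUE(all.equal(f, fps[[1L]])), TRUE))) {
    stop("AIC comparison across different response/offset data", call. = FALSE)
  }
  out <- data.frame(
    model = names(fits),
    n_par = vapply(fits, function(f) f$n_par + 1, 0),
    loglik = vapply(fits, `[[`, 0, "loglik"),
    aic = vapply(fits, `[[`, 0, "aic"),
    row.names = NULL)
  out <- out[order(out$aic), ]
  out$delta_aic <- out$aic - out$aic[1L]
  rownames(out) <- NULL
  out
}

#' Fit the pre-specified candidate model set
#'
#' The four candidates compared in the analysis: the full model (df 4
#' splines on both cross-basis axes, age x gender interaction), the same
#' without the interaction, the full structure with df 3 splines, and df 3
#' without the interaction.
#'
#' @param strata strata table.
#' @param histories exposure-history matrix from [exposure_histories()].
#' @param df_full,df_reduced spline df of the full and reduced cross-bases.
#' @param lag_knot_scale knot scale of the lag basis (see [default_knots()]).
#' @return list with `fits` (named list of `nb_fit`), `aic_table`,
#'   `cross_bases` (per df), and `designs`.
#' @export
fit_candidate_set <- function(strata, histories, df_full = 4L,
                              df_reduced = 3L, lag_knot_scale = "log-lag") {
  lag_max <- ncol(histories) - 1L
  make_cb <- function(df) {
    cross_basis(histories,
                default_knots(as.numeric(histories), df),
                default_knots(0:lag_max, df, scale = lag_knot_scale))
  }
  cbs <- list(full = make_cb(df_full), reduced = make_cb(df_reduced))
  spec <- list(
    full            = list(cb = "full",    interaction = TRUE),
    no_interaction  = list(cb = "full",    interaction = FALSE),
    df3             = list(cb = "reduced", interaction = TRUE),
    df3_no_interaction = list(cb = "reduced", interaction = FALSE))
  designs <- lapply(spec, function(s) {
    build_design(strata, cbs[[s$cb]], interaction = s$interaction)
  })
  fits <- lapply(designs, fit_negbin)
  list(fits = fits, aic_table = compare_aic(fits),
       cross_bases = cbs, designs = designs)
}
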