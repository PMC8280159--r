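# Simulation-based scaled (quantile) residuals. For each stratum the
# observed count is placed within n_sim draws from its fitted negative
# binomial distribution, with the rank randomised across ties so the
# residuals are Uniform(0, 1) under a correctly specified model.

# deterministic 31-bit polynomial hash keying a stratum's RNG sub-stream
hash_seed <- function(seed, id) {
  h <- 17
  for (b in utf8ToInt(paste0(seed, ":", id))) {
    h <- (h * 31 + b) %% 2147483629
  }
  as.integer(h)
}

#' Simulated scaled quantile residuals
#'
#' For stratum i, draws `n_sim` counts from NB(mu_i, theta) and returns the
#' randomised empirical-CDF position of the observed count among the draws
#' (randomised probability integral transform). Each stratum uses an RNG
#' sub-stream keyed by (seed, stratum id), so the residual vector is
#' reproducible and invariant to row order.
#'
#' @param fit a converged [fit_negbin()] result.
#' @param design the [build_design()] object the fit came from.
#' @param n_sim simulated draws per stratum (>= 100).
#' @param seed integer seed.
#' @return object of class `"scaled_residuals"`: numeric vector in (0, 1)
#'   named by stratum id, with attributes `n_sim` and `seed`.
#' @export
simulate_scaled_residuals <- function(fit, design, n_sim = 250L, seed = 1L) {
  stopifnot(inherits(fit, "nb_fit"), inherits(design, "nb_design"))
  if (!isTRUE(fit$converged)) {
    stop("refusing to diagnose a non-converged fit", call. = FALSE)
  }
  if (n_sim < 100L) stop("n_sim must be >= 100", call. = FALSE)
  if (exists(".Random.seed", globalenv())) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, globalenv()))
  }
  ids <- design$stratum_id
  mu <- fit$fitted
  y <- design$y
  n <- length(y)
  vals <- numeric(n)
  for (i in seq_len(n)) {
    set.seed(hash_seed(seed, ids[i]))
    sims <- stats::rnbinom(n_sim, mu = mu[i], size = fit$theta)
    vals[i] <- (sum(sims < y[i]) + stats::runif(1) * (1 + sum(sims == y[i]))) /
      (n_sim + 1)
  }
  structure(stats::setNames(vals, ids), n_sim = as.integer(n_sim),
            seed = as.integer(seed), class = "scaled_residuals")
}

#' QQ table for scaled residuals
#'
#' Sorted residuals paired with uniform plotting positions (i - 0.5) / n;
#' a correctly specified model puts the points on the 1:1 line.
#'
#' @param res a [simulate_scaled_residuals()] result (or numeric vector in
#'   `[0, 1]`).
#' @return data frame (expected, observed).
#' @export
residual_plot_data <- function(res) {
  v <- sort(as.numeric(res))
  data.frame(expected = (seq_along(v) - 0.5) / length(v), observed = v)
}

#' Kolmogorov-Smirnov uniformity check
#'
#' @param res scaled residuals.
#' @return the `stats::ks.test` result against Uniform(0, 1).
#' @export
residual_ks_test <- function(res) {
  suppressWarnings(stats::ks.test(as.numeric(res), "punif"))
}
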