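# Cluster-robust sandwich covariance. Registries observe the same
# populations across age bands, genders and outcome years, so their strata
# are correlated; clustering on registry makes the standard errors robust
# to that autocorrelation and to heteroskedasticity.

#' Cluster-robust sandwich covariance
#'
#' bread %*% meat %*% bread with bread = the model-based covariance
#' (inverse observed information) and meat = the sum over clusters of the
#' outer products of cluster-summed scores, times the CR1 small-sample
#' factor G / (G - 1). Scores are evaluated at the fitted coefficients with
#' the dispersion theta treated as fixed.
#'
#' @param fit a [fit_negbin()] result.
#' @param design the [build_design()] object the fit came from.
#' @param cluster cluster labels aligned with the design rows; defaults to
#'   the design's registry labels.
#' @return object of class `"robust_vcov"`: `matrix`, `n_clusters`,
#'   `correction` (`"CR1"`).
#' @export
cluster_sandwich <- function(fit, design, cluster = design$cluster) {
  stopifnot(inherits(fit, "nb_fit"), inherits(design, "nb_design"))
  cluster <- as.character(cluster)
  if (length(cluster) != nrow(design$X)) {
    stop("cluster labels not aligned with design rows", call. = FALSE)
  }
  if (anyNA(cluster) || any(!nzchar(cluster))) {
    stop("empty or missing cluster labels", call. = FALSE)
  }
  g <- length(unique(cluster))
  if (g < 2L) stop("need at least 2 clusters", call. = FALSE)
  mu <- fit$fitted
  theta <- fit$theta
  # d loglik_i / d eta_i for NB2 with log link
  u <- (design$y - mu) * theta / (mu + theta)
  scores <- design$X * u
  sg <- rowsum(scores, cluster)
  meat <- crossprod(sg)
  bread <- fit$vcov
  v <- bread %*% meat %*% bread * g / (g - 1)
  v <- (v + t(v)) / 2
  dimnames(v) <- dimnames(fit$vcov)
  structure(list(matrix = v, n_clusters = g, correction = "CR1"),
            class = "robust_vcov")
}

#' @export
print.robust_vcov <- function(x, ...) {
  cat(sprintf("cluster-robust (%s) covariance, %d clusters, dim %d\n",
              x$correction, x$n_clusters, ncol(x$matrix)))
  invisible(x)
}

# accept either a robust_vcov, a plain matrix, or NULL (-> model-based)
resolve_vcov <- function(vcov, fit) {
  if (is.null(vcov)) return(fit$vcov)
  if (inherits(vcov, "robust_vcov")) return(vcov$matrix)
  if (is.matrix(vcov)) return(vcov)
  stop("vcov must be NULL, a matrix, or a robust_vcov", call. = FALSE)
}
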