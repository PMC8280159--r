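# Exposure-lag cross-basis: the tensor product of a natural-spline basis
# over exposure values and one over lags. The row for a stratum sums the
# tensor contributions over its whole lagged exposure history, so the
# coefficient vector beta describes a smooth bidimensional exposure-lag
# surface.
#
# Lag-0 constraint: the lag basis carries no intercept (no lag-constant
# effect exists) and every lag-basis column is additionally anchored to
# evaluate to 0 at lag 0. Anchoring only shifts each column by a constant
# (absorbed by the model intercept) but makes the predicted log-IRR
# identically 0 at lag 0 for every exposure level - the "no same-year
# effect" assumption holds exactly rather than approximately.

#' Build an exposure-lag cross-basis
#'
#' @param histories numeric matrix (or list of [exposure_history()]s), one
#'   row per stratum, columns = exposure at lag 0..L.
#' @param exposure_spec [basis_spec()] for the exposure axis.
#' @param lag_spec [basis_spec()] for the lag axis; must have
#'   `intercept = FALSE`.
#' @return object of class `"cross_basis"`: the N x (df_x * df_lag) matrix
#'   plus the metadata needed to rebuild single-point bases. Column order is
#'   exposure-major: column (j - 1) * df_lag + k pairs exposure-basis column
#'   j with lag-basis column k.
#' @export
cross_basis <- function(histories, exposure_spec, lag_spec) {
  stopifnot(inherits(exposure_spec, "basis_spec"),
            inherits(lag_spec, "basis_spec"))
  if (lag_spec$intercept) {
    stop("the lag basis must exclude the intercept (lag-0 constraint)",
         call. = FALSE)
  }
  if (exposure_spec$intercept) {
    stop("the exposure basis must exclude the intercept", call. = FALSE)
  }
  if (is.list(histories)) histories <- do.call(rbind, lapply(histories, as.numeric))
  histories <- as.matrix(histories)
  lag_max <- ncol(histories) - 1L
  if (lag_max < 1L) stop("histories must cover at least lags 0 and 1",
                         call. = FALSE)
  dfx <- exposure_spec$df
  dfl <- lag_spec$df
  blag <- lag_basis_anchored(0:lag_max, lag_spec)
  n <- nrow(histories)
  m <- matrix(0, n, dfx * dfl)
  ex_idx <- rep(seq_len(dfx), each = dfl)
  for (l in 0:lag_max) {
    bx <- ns_basis(histories[, l + 1L], exposure_spec)
    # exposure-major flattening of bx[, j] * blag[l + 1, k]
    m <- m + bx[, ex_idx, drop = FALSE] *
      matrix(rep(blag[l + 1L, ], dfx), n, dfx * dfl, byrow = TRUE)
  }
  if (any(!is.finite(m))) stop("non-finite cross-basis entries", call. = FALSE)
  colnames(m) <- cb_colnames(dfx, dfl)
  rownames(m) <- rownames(histories)
  structure(list(matrix = m, exposure_spec = exposure_spec,
                 lag_spec = lag_spec, lag_max = lag_max,
                 df_x = dfx, df_lag = dfl),
            class = "cross_basis")
}

cb_colnames <- function(dfx, dfl) {
  paste0("cb_x", rep(seq_len(dfx), each = dfl), "l", rep(seq_len(dfl), dfx))
}

# lag basis with every column shifted to be 0 at lag 0
lag_basis_anchored <- function(l, lag_spec) {
  b <- ns_basis(l, lag_spec)
  b0 <- ns_basis(0, lag_spec)
  sweep(b, 2L, as.numeric(b0), "-")
}

#' Single-point cross-basis vector
#'
#' The flattened outer product B_x(x) (x) B_lag(l), in the same
#' exposure-major column order as [cross_basis()]. Summing `point_basis`
#' over a stratum's history reproduces that stratum's cross-basis row
#' exactly; differences of point bases are the contrast vectors behind all
#' IRR predictions.
#'
#' @param x exposure value (% prevalence), scalar.
#' @param l lag in years, scalar in `[0, lag_max]`.
#' @param cb a [cross_basis()] (its matrix may be absent; only the
#'   specification is used).
#' @return numeric vector of length `df_x * df_lag`.
#' @export
point_basis <- function(x, l, cb) {
  stopifnot(inherits(cb, "cross_basis"), length(x) == 1L, length(l) == 1L)
  if (l < 0 || l > cb$lag_max) {
    stop(sprintf("lag %g outside [0, %d]", l, cb$lag_max), call. = FALSE)
  }
  drop(point_basis_matrix(x, l, cb))
}

# rows = one (x) each, at common lag l; vectorised over x
point_basis_matrix <- function(x, l, cb) {
  bx <- ns_basis(x, cb$exposure_spec)              # n x dfx
  bl <- as.numeric(lag_basis_anchored(l, cb$lag_spec))  # dfl
  out <- bx[, rep(seq_len(cb$df_x), each = cb$df_lag), drop = FALSE] *
    matrix(rep(bl, cb$df_x), nrow(bx), cb$df_x * cb$df_lag, byrow = TRUE)
  colnames(out) <- cb_colnames(cb$df_x, cb$df_lag)
  out
}

#' @export
print.cross_basis <- function(x, ...) {
  cat(sprintf(
    "cross-basis: %s x %d cols (df_x %d * df_lag %d), lags 0..%d\n",
    if (is.null(x$matrix)) "<no rows>" else nrow(x$matrix),
    x$df_x * x$df_lag, x$df_x, x$df_lag, x$lag_max))
  invisible(x)
}

cb_to_list <- function(cb) {
  list(exposure_spec = spec_to_list(cb$exposure_spec),
       lag_spec = spec_to_list(cb$lag_spec),
       lag_max = cb$lag_max, df_x = cb$df_x, df_lag = cb$df_lag,
       column_order = "exposure-major: (j-1)*df_lag + k")
}

cb_from_list <- function(x) {
  structure(list(matrix = NULL,
                 exposure_spec = spec_from_list(x$exposure_spec),
                 lag_spec = spec_from_list(x$lag_spec),
                 lag_max = as.integer(x$lag_max),
                 df_x = as.integer(x$df_x), df_lag = as.integer(x$df_lag)),
            class = "cross_basis")
}
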