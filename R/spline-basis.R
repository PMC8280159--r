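# Restricted cubic (natural) spline bases.
#
# With k knots in total (2 boundary + k-2 interior) a natural cubic spline
# contributes k - 1 free parameters besides the intercept, and is linear
# beyond the boundary knots. The basis itself is the standard B-spline
# projected natural spline (splines::ns); equivalence of the spanned column
# space, not bit-identity of the parameterisation, is the contract.

#' Spline basis specification
#'
#' @param df number of basis columns (excluding any intercept); with k total
#'   knots, df = k - 1.
#' @param interior_knots sorted numeric vector of df - 1 interior knots.
#' @param boundary_knots length-2 numeric; the spline is linear outside.
#' @param intercept include a constant column? The lag basis of a cross-basis
#'   must use `FALSE` (the lag-0 constraint removes any lag-constant term).
#' @param scale how [default_knots()] placed the interior knots: `"identity"`
#'   (quantiles of the observed values) or `"log-lag"` (equally spaced in
#'   log(lag + 1), concentrating flexibility at short lags).
#' @return an object of class `"basis_spec"`.
#' @export
basis_spec <- function(df, interior_knots = numeric(0), boundary_knots,
                       intercept = FALSE, scale = "identity") {
  df <- as.integer(df)
  interior_knots <- as.numeric(interior_knots)
  boundary_knots <- as.numeric(boundary_knots)
  stopifnot(df >= 1L, length(boundary_knots) == 2L,
            boundary_knots[1] < boundary_knots[2],
            length(interior_knots) == df - 1L)
  if (length(interior_knots) &&
      (is.unsorted(interior_knots) ||
       min(interior_knots) <= boundary_knots[1] ||
       max(interior_knots) >= boundary_knots[2])) {
    stop("interior knots must be sorted strictly inside the boundary knots",
         call. = FALSE)
  }
  structure(list(df = df, interior_knots = interior_knots,
                 boundary_knots = boundary_knots,
                 intercept = isTRUE(intercept),
                 scale = match.arg(scale, c("identity", "log-lag"))),
            class = "basis_spec")
}

#' Default knot placement
#'
#' Boundary knots at the observed minimum and maximum. Interior knots:
#' `"identity"` scale places the df - 1 interior knots at equally spaced
#' quantiles of `values`; `"log-lag"` scale places them equally spaced on
#' the log(x + 1) axis between the boundaries, the conventional choice for
#' a lag basis where flexibility should concentrate at short lags.
#'
#' @inheritParams basis_spec
#' @param values observed values of the variable the basis is for.
#' @return a [basis_spec()].
#' @export
default_knots <- function(values, df, scale = c("identity", "log-lag"),
                          intercept = FALSE) {
  scale <- match.arg(scale)
  values <- as.numeric(values[is.finite(values)])
  rng <- range(values)
  if (!(rng[1] < rng[2])) {
    stop("cannot place knots: values have a degenerate (constant) range",
         call. = FALSE)
  }
  df <- as.integer(df)
  stopifnot(df >= 1L)
  interior <- numeric(0)
  if (df > 1L) {
    if (scale == "identity") {
      interior <- stats::quantile(values, probs = seq_len(df - 1L) / df,
                                  names = FALSE, type = 7)
    } else {
      g <- seq(log1p(rng[1]), log1p(rng[2]), length.out = df + 1L)
      interior <- expm1(g[2:df])
    }
    if (anyDuplicated(interior) || min(interior) <= rng[1] ||
        max(interior) >= rng[2]) {
      stop("degenerate interior knots (tied quantiles); reduce df",
           call. = FALSE)
    }
  }
  basis_spec(df, interior, rng, intercept = intercept, scale = scale)
}

#' Evaluate a natural spline basis
#'
#' Each column is a cubic spline with continuous first and second
#' derivatives, constrained to zero second derivative outside the boundary
#' knots; evaluation beyond the boundaries is the linear extension.
#'
#' @param x numeric vector of evaluation points.
#' @param spec a [basis_spec()].
#' @return numeric matrix, `length(x)` rows and `spec$df`
#'   (+1 if `spec$intercept`) columns.
#' @export
ns_basis <- function(x, spec) {
  stopifnot(inherits(spec, "basis_spec"))
  kn <- if (length(spec$interior_knots)) spec$interior_knots else NULL
  b <- splines::ns(as.numeric(x), knots = kn,
                   Boundary.knots = spec$boundary_knots,
                   intercept = spec$intercept)
  m <- matrix(as.numeric(b), nrow = length(x))
  colnames(m) <- paste0("b", seq_len(ncol(m)))
  m
}

#' @export
print.basis_spec <- function(x, ...) {
  cat(sprintf(
    "natural spline basis: df %d, boundary [%g, %g], interior {%s}, %s%s\n",
    x$df, x$boundary_knots[1], x$boundary_knots[2],
    paste(signif(x$interior_knots, 4), collapse = ", "), x$scale,
    if (x$intercept) ", with intercept" else ""))
  invisible(x)
}

# serialisable form (YAML round-trip of a fitted model's configuration)
spec_to_list <- function(spec) {
  list(df = spec$df, interior_knots = as.numeric(spec$interior_knots),
       boundary_knots = as.numeric(spec$boundary_knots),
       intercept = spec$intercept, scale = spec$scale)
}

spec_from_list <- function(x) {
  basis_spec(x$df, unlist(x$interior_knots), unlist(x$boundary_knots),
             intercept = isTRUE(x$intercept), scale = x$scale)
}
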