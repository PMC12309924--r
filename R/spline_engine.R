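# Penalized cubic smoothing spline engine.
#
# The fit minimizes
#     sum_i w_i (y_i - f(x_i))^2  +  lambda * int f''(t)^2 dt
# over natural cubic splines with knots at every distinct age, with ages
# rescaled to [0, 1] before fitting.  The minimizer is represented in the
# cubic B-spline basis on the rescaled knots; the penalty matrix is the
# exact Gram matrix of second derivatives (Simpson's rule per inter-knot
# interval, exact because the integrands are piecewise quadratic).

#' Map the scale-free smoothing parameter to the penalty weight
#'
#' The smoothing spline is tuned through the scale-free parameter `spar`
#' rather than the penalty weight directly.  The mapping is
#' \deqn{\lambda = r \cdot 256^{3\,\mathrm{spar} - 1}}
#' where \eqn{r} is the ratio of the trace of the weighted basis
#' cross-product \eqn{X^\top W X} to the trace of the second-derivative
#' penalty matrix \eqn{\Omega}, both computed on the design with ages
#' rescaled to the unit interval.  Traces are taken over the interior
#' basis functions (the convention of the reference environment in which
#' `spar = 0.8` is the customary conservative choice for these data), so
#' a given `spar` yields comparable smoothness across designs and
#' response scales.  At `spar = 1/3` the exponent vanishes and
#' \eqn{\lambda = r} exactly.
#'
#' @param spar Scale-free smoothing parameter (real; larger is smoother).
#' @param trace_design Trace of the weighted basis cross-product on the
#'   rescaled design (must be positive).
#' @param trace_penalty Trace of the penalty matrix on the rescaled
#'   design (must be positive).
#' @return The penalty weight `lambda` (nonnegative scalar).
#' @seealso [design_traces()] to obtain the two traces for a set of ages.
#' @export
#' @examples
#' tr <- design_traces(c(20, 35, 50, 65, 80))
#' spar_to_lambda(0.8, tr[["design"]], tr[["penalty"]])
spar_to_lambda <- function(spar, trace_design, trace_penalty) {
  stopifnot(is.numeric(spar), length(spar) == 1L, is.finite(spar))
  if (!is.finite(trace_design) || !is.finite(trace_penalty) ||
      trace_design <= 0 || trace_penalty <= 0) {
    stop_immunospline("degenerate_design",
      "both design traces must be positive (degenerate design)")
  }
  (trace_design / trace_penalty) * 256^(3 * spar - 1)
}

#' Design traces for the spar-to-lambda mapping
#'
#' Forms the B-spline basis and exact second-derivative penalty matrix on
#' the rescaled design and returns the two (interior) traces entering
#' [spar_to_lambda()].
#'
#' @param age Numeric vector of ages (at least 4 distinct values).
#' @param weights Optional nonnegative observation weights (multiplicity
#'   semantics; accumulated over duplicate ages).
#' @param tol Duplicate-age tolerance; ages closer than `tol` are
#'   collapsed.  Default `1e-6 * diff(range(age))`.
#' @return Named numeric vector with elements `design` and `penalty`.
#' @export
design_traces <- function(age, weights = NULL, tol = NULL) {
  d <- collapse_duplicate_ages(age, rep(0, length(age)), weights, tol)
  b <- spline_basis_design(d$age)
  XtWX <- crossprod(b$X, d$weights * b$X)
  idx <- trace_index(ncol(b$X))
  c(design = sum(diag(XtWX)[idx]), penalty = sum(diag(b$Omega)[idx]))
}

# interior basis-function window over which the traces are summed
trace_index <- function(nb) 3:(nb - 3L)

#' Fit a cubic smoothing spline to (age, count) data
#'
#' Fits the penalized least-squares natural cubic spline with knots at
#' every distinct age.  Exactly one of `spar` or `lambda` may be given;
#' with neither, the conservative default `spar = 0.8` is used.
#' Duplicate ages are collapsed to a single knot carrying the weighted
#' mean response and the summed weight, which is equivalent to fitting
#' the raw data.
#'
#' @param age,count Numeric vectors of equal length; ages in years,
#'   counts in cells/uL (finite, at least 4 distinct ages).
#' @param spar Scale-free smoothing parameter (see [spar_to_lambda()]).
#' @param lambda Penalty weight, as an alternative to `spar`.
#' @param weights Optional nonnegative observation weights.
#' @param tol Duplicate-age tolerance (see [design_traces()]).
#' @param compute_edf Compute the effective degrees of freedom (trace of
#'   the smoother matrix)?  Skipped inside bootstrap refits for speed.
#' @return An object of class `smoothing_spline_fit`: a list with the
#'   knot ages, B-spline coefficients of the piecewise cubic, `lambda`,
#'   `spar`, the age rescaling map, collapsed weights, fitted values at
#'   the knots, and (optionally) `edf`.
#' @export
#' @examples
#' set.seed(1)
#' age <- sample(19:93, 60, replace = TRUE)
#' count <- 500 * exp(-0.01 * (age - 19)) * exp(rnorm(60, 0, 0.3))
#' fit <- fit_smoothing_spline(age, count, spar = 0.8)
#' fit
fit_smoothing_spline <- function(age, count, spar = NULL, lambda = NULL,
                                 weights = NULL, tol = NULL,
                                 compute_edf = TRUE) {
  if (!is.null(spar) && !is.null(lambda)) {
    stop_immunospline("bad_argument", "supply exactly one of `spar` and `lambda`")
  }
  if (is.null(spar) && is.null(lambda)) spar <- 0.8
  stopifnot(length(age) == length(count))
  if (!all(is.finite(age)) || !all(is.finite(count))) {
    stop_immunospline("bad_argument", "ages and counts must be finite")
  }
  if (!is.null(weights) && any(weights < 0)) {
    stop_immunospline("bad_argument", "weights must be nonnegative")
  }

  d <- collapse_duplicate_ages(age, count, weights, tol)
  if (length(d$age) < 4L) {
    stop_immunospline("insufficient_data", sprintf(
      "need at least 4 distinct ages to fit a cubic smoothing spline (got %d)",
      length(d$age)))
  }
  b <- spline_basis_design(d$age)
  XtWX <- crossprod(b$X, d$weights * b$X)
  idx <- trace_index(ncol(b$X))
  tr_d <- sum(diag(XtWX)[idx])
  tr_p <- sum(diag(b$Omega)[idx])
  r <- tr_d / tr_p
  if (is.null(lambda)) {
    lambda <- spar_to_lambda(spar, tr_d, tr_p)
  } else {
    if (lambda < 0) stop_immunospline("bad_argument", "lambda must be nonnegative")
    # invert the mapping so the fit always records both parameterizations
    spar <- if (lambda > 0) (log(lambda / r, base = 256) + 1) / 3 else -Inf
  }

  rhs <- crossprod(b$X, d$weights * d$count)
  if (lambda > 0) {
    A <- XtWX + lambda * b$Omega
    R <- chol(A)
    beta <- backsolve(R, forwardsolve(t(R), rhs))
    edf <- if (isTRUE(compute_edf)) {
      # tr(S) with S = X (X'WX + lambda*Omega)^{-1} X'W
      sum(diag(backsolve(R, forwardsolve(t(R), XtWX))))
    }
  } else {
    # lambda = 0: the basis has two more functions than knots, so the
    # interpolation problem is solved in its smoothest-limit form --
    # minimize the roughness beta' Omega beta subject to exact fit
    # (the natural interpolating spline, the lambda -> 0+ limit)
    nb <- ncol(b$X); nu <- nrow(b$X)
    kkt <- rbind(cbind(2 * b$Omega, t(b$X)),
                 cbind(b$X, matrix(0, nu, nu)))
    sol <- solve(kkt, c(rep(0, nb), d$count))
    beta <- sol[seq_len(nb)]
    edf <- if (isTRUE(compute_edf)) as.numeric(nu)
  }
  fitted <- drop(b$X %*% beta)

  structure(list(
    knots = d$age,
    coefficients = drop(beta),
    knot_vector = b$kv,
    lambda = lambda,
    spar = spar,
    x_scale = c(offset = d$age[1L], range = diff(range(d$age))),
    weights = d$weights,
    y = d$count,
    fitted = fitted,
    n_obs = length(age),
    edf = edf
  ), class = "smoothing_spline_fit")
}

#' @export
print.smoothing_spline_fit <- function(x, ...) {
  cat("Cubic smoothing spline fit\n")
  cat(sprintf("  observations: %d (%d distinct ages, %.1f-%.1f years)\n",
              x$n_obs, length(x$knots), min(x$knots), max(x$knots)))
  cat(sprintf("  spar = %.4g, lambda = %.4g", x$spar, x$lambda))
  if (!is.null(x$edf)) cat(sprintf(", edf = %.2f", x$edf))
  cat("\n")
  invisible(x)
}

#' Evaluate a fitted smoothing spline
#'
#' `evaluate_curve()` evaluates the fitted mean curve
#' \eqn{\hat E(Y \mid \mathrm{Age})}; `evaluate_first_derivative()`
#' evaluates its exact analytic first derivative (a quadratic on each
#' knot interval, continuous across knots), chain-rule corrected for the
#' internal age rescaling so units are counts per year of age.
#'
#' Ages outside the observed span are refused by default; with
#' `extrapolate = TRUE` the natural spline is extended linearly (its
#' second derivative vanishes at and beyond the boundary knots).
#'
#' @param fit A `smoothing_spline_fit`.
#' @param ages Numeric vector of evaluation ages.
#' @param extrapolate Allow linear extrapolation beyond the knot span?
#' @return Numeric vector of curve values (cells/uL) or derivative
#'   values (cells/uL per year).
#' @export
evaluate_curve <- function(fit, ages, extrapolate = FALSE) {
  eval_spline_fit(fit, ages, deriv = 0L, extrapolate = extrapolate)
}

#' @rdname evaluate_curve
#' @export
evaluate_first_derivative <- function(fit, ages, extrapolate = FALSE) {
  eval_spline_fit(fit, ages, deriv = 1L, extrapolate = extrapolate)
}

eval_spline_fit <- function(fit, ages, deriv = 0L, extrapolate = FALSE) {
  stopifnot(inherits(fit, "smoothing_spline_fit"), is.numeric(ages))
  lo <- fit$x_scale[["offset"]]
  sc <- fit$x_scale[["range"]]
  hi <- lo + sc
  inside <- ages >= lo & ages <= hi
  if (!extrapolate && !all(inside)) {
    stop_immunospline("extrapolation", sprintf(
      "evaluation ages outside the observed span [%.4g, %.4g]; set extrapolate = TRUE for linear extension",
      lo, hi))
  }
  out <- numeric(length(ages))
  if (any(inside)) {
    xs <- (ages[inside] - lo) / sc
    D <- splines::splineDesign(fit$knot_vector, xs,
                               derivs = rep(deriv, length(xs)))
    out[inside] <- drop(D %*% fit$coefficients) / sc^deriv
  }
  if (any(!inside)) {
    bnd <- ifelse(ages[!inside] < lo, lo, hi)
    xs <- (bnd - lo) / sc
    D0 <- splines::splineDesign(fit$knot_vector, xs, derivs = rep(0L, length(xs)))
    D1 <- splines::splineDesign(fit$knot_vector, xs, derivs = rep(1L, length(xs)))
    v0 <- drop(D0 %*% fit$coefficients)
    v1 <- drop(D1 %*% fit$coefficients) / sc
    out[!inside] <- switch(as.character(deriv),
      "0" = v0 + v1 * (ages[!inside] - bnd),
      "1" = v1,
      0)
  }
  out
}

#' Export a fit summary as JSON
#'
#' @param fit A `smoothing_spline_fit`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  jsonlite::write_json(list(
    knots = fit$knots, coefficients = fit$coefficients,
    lambda = fit$lambda, spar = fit$spar, edf = fit$edf,
    n_obs = fit$n_obs
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# ---- internal numerics -------------------------------------------------

# Collapse (near-)duplicate ages to weighted means.  Weights are taken
# as given (multiplicity semantics: default weight 1 per observation)
# and summed within tie groups, so fitting duplicated rows is identical
# to fitting collapsed rows with multiplicity weights.
collapse_duplicate_ages <- function(age, count, weights = NULL, tol = NULL) {
  n <- length(age)
  if (is.null(weights)) weights <- rep(1, n)
  o <- order(age)
  age <- age[o]; count <- count[o]; weights <- weights[o]
  span <- age[n] - age[1L]
  if (is.null(tol)) tol <- 1e-6 * max(span, 1)
  grp <- cumsum(c(TRUE, diff(age) > tol))
  w <- drop(rowsum(weights, grp, reorder = TRUE))
  wy <- drop(rowsum(weights * count, grp, reorder = TRUE))
  wx <- drop(rowsum(weights * age, grp, reorder = TRUE))
  keep <- w > 0
  # zero-weight groups keep their age but cannot define the knot mean
  ux <- ifelse(keep, wx / pmax(w, .Machine$double.eps), age[!duplicated(grp)])
  uy <- ifelse(keep, wy / pmax(w, .Machine$double.eps), count[!duplicated(grp)])
  list(age = unname(ux), count = unname(uy), weights = unname(w))
}

# B-spline design at the rescaled distinct ages plus the exact
# second-derivative Gram (penalty) matrix.
spline_basis_design <- function(ux) {
  sc <- ux[length(ux)] - ux[1L]
  xs <- (ux - ux[1L]) / sc
  xs[length(xs)] <- 1  # guard rounding
  kv <- c(rep(0, 3L), xs, rep(1, 3L))
  X <- splines::splineDesign(kv, xs)
  list(X = X, Omega = penalty_matrix(kv), kv = kv, xs = xs)
}

# Exact Gram matrix of second derivatives of the cubic B-spline basis.
# On each inter-knot interval the product of two second derivatives is a
# quadratic, so Simpson's rule is exact.
penalty_matrix <- function(kv) {
  br <- unique(kv)
  a <- br[-length(br)]; b <- br[-1L]
  h <- b - a; m <- (a + b) / 2
  pts <- c(a, m, b)
  w <- c(h, 4 * h, h) / 6
  G2 <- splines::splineDesign(kv, pts, derivs = rep(2L, length(pts)),
                              outer.ok = TRUE)
  crossprod(G2, w * G2)
}

# Fast combined evaluation of curve and derivative on one grid (a single
# basis call); used in the bootstrap hot path.  Always extrapolates
# linearly outside the knot span.
evaluate_curve_deriv <- function(fit, grid) {
  lo <- fit$x_scale[["offset"]]; sc <- fit$x_scale[["range"]]; hi <- lo + sc
  G <- length(grid)
  clamped <- pmin(pmax(grid, lo), hi)
  xs <- (clamped - lo) / sc
  D <- splines::splineDesign(fit$knot_vector, c(xs, xs),
                             derivs = rep(c(0L, 1L), each = G))
  v <- drop(D %*% fit$coefficients)
  curve <- v[seq_len(G)]
  deriv <- v[G + seq_len(G)] / sc
  out <- grid < lo | grid > hi
  if (any(out)) curve[out] <- curve[out] + deriv[out] * (grid[out] - clamped[out])
  c(curve, deriv)
}

stop_immunospline <- function(class, message, ...) {
  stop(structure(class = c(paste0("immunospline_", class), "error", "condition"),
                 list(message = message, call = sys.call(-1), ...)))
}
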