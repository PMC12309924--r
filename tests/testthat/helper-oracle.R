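# Independent brute-force oracles.
#
# The penalized-least-squares oracle forms the B-spline basis and the
# second-derivative Gram matrix explicitly and solves the dense normal
# equations with base solve().  The Gram integral uses two-point
# Gauss-Legendre quadrature per inter-knot interval (exact for the
# piecewise-quadratic integrand), a different exact rule than the
# engine's, so the two computations share no code path beyond the basis
# evaluator.

oracle_penalty <- function(kv) {
  br <- unique(kv)
  a <- br[-length(br)]; b <- br[-1]
  h <- b - a; m <- (a + b) / 2
  off <- h / (2 * sqrt(3))
  p1 <- m - off; p2 <- m + off
  d2 <- function(p) splines::splineDesign(kv, p, derivs = rep(2L, length(p)))
  (crossprod(d2(p1), h * d2(p1)) + crossprod(d2(p2), h * d2(p2))) / 2
}

# Dense penalized-normal-equations solve; duplicate ages must already be
# collapsed (tests use distinct ages).  Returns fitted values at the
# knots plus the trace-ratio pieces of the spar mapping.
oracle_spline <- function(age, count, lambda = NULL, spar = NULL,
                          weights = NULL) {
  stopifnot(!is.unsorted(age), !anyDuplicated(age))
  if (is.null(weights)) weights <- rep(1, length(age))
  sc <- diff(range(age))
  xs <- (age - min(age)) / sc
  kv <- c(rep(0, 3), xs, rep(1, 3))
  X <- splines::splineDesign(kv, xs)
  Om <- oracle_penalty(kv)
  nb <- ncol(X)
  idx <- 3:(nb - 3)
  XtWX <- crossprod(X, weights * X)
  r <- sum(diag(XtWX)[idx]) / sum(diag(Om)[idx])
  if (is.null(lambda)) lambda <- r * 256^(3 * spar - 1)
  beta <- solve(XtWX + lambda * Om, crossprod(X, weights * count))
  list(fitted = drop(X %*% beta), lambda = lambda, ratio = r,
       trace_design = sum(diag(XtWX)[idx]), trace_penalty = sum(diag(Om)[idx]))
}

# A bootstrap_band built directly from given vectors (for region tests).
make_band <- function(grid, lower, upper, estimate = (lower + upper) / 2,
                      statistic = "derivative", level = 0.95) {
  structure(list(grid = grid, estimate = estimate, lower = lower,
                 upper = upper, level = level, n_boot = 0L,
                 statistic = statistic, seed = NA_integer_,
                 interval_type = "percentile", n_redrawn = 0L,
                 n_dropped = 0L, replicates = NULL),
            class = "bootstrap_band")
}

# Small noisy test datasets on integer ages.
toy_pairs <- function(n, seed, level = 500, sigma = 0.4) {
  set.seed(seed)
  age <- sort(sample(19:93, n))
  count <- level * exp(stats::rnorm(n, 0, sigma) - sigma^2 / 2)
  tibble::tibble(age = age, count = count)
}

toy_cohort <- function(n_per_sex = 30, seed = 1, level = 500, sigma = 0.3) {
  set.seed(seed)
  tibble::tibble(
    participant_id = sprintf("P%03d", seq_len(2 * n_per_sex)),
    age = as.numeric(sample(19:93, 2 * n_per_sex, replace = TRUE)),
    sex = rep(c("female", "male"), each = n_per_sex),
    counts = level * exp(stats::rnorm(2 * n_per_sex, 0, sigma))
  ) |> cohort_table(populations = "counts")
}
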