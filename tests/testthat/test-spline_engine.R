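# The spline engine: penalized fit, spar mapping, evaluation,
# derivatives.

test_that("linear data are reproduced exactly for any penalty", {
  age <- c(20, 31, 45, 58, 66, 80, 92)
  count <- 2 * age + 1
  for (lam in c(0, 1e-4, 1, 1e4)) {
    fit <- fit_smoothing_spline(age, count, lambda = lam)
    g <- seq(20, 92, by = 0.5)
    expect_equal(evaluate_curve(fit, g), 2 * g + 1, tolerance = 1e-8)
    expect_equal(evaluate_first_derivative(fit, g), rep(2, length(g)),
                 tolerance = 1e-8)
  }
})

test_that("constant data give a flat curve with zero derivative", {
  age <- c(19, 30, 44, 61, 77, 93)
  fit <- fit_smoothing_spline(age, rep(420, 6), spar = 0.8)
  g <- 19:93
  expect_equal(evaluate_curve(fit, g), rep(420, length(g)), tolerance = 1e-8)
  expect_equal(max(abs(evaluate_first_derivative(fit, g))), 0,
               tolerance = 1e-8)
})

test_that("fitted knot values match the brute-force penalized solve", {
  worst <- 0
  for (seed in 1:20) {
    pairs <- toy_pairs(n = sample(6:20, 1), seed = seed)
    fit <- fit_smoothing_spline(pairs$age, pairs$count, spar = 0.8)
    ora <- oracle_spline(pairs$age, pairs$count, lambda = fit$lambda)
    rel <- max(abs(fit$fitted - ora$fitted)) / max(abs(ora$fitted))
    worst <- max(worst, rel)
  }
  expect_lt(worst, 1e-8)
})

test_that("lambda -> 0 approaches interpolation; lambda -> Inf the LS line", {
  pairs <- toy_pairs(8, seed = 3)
  lo <- fit_smoothing_spline(pairs$age, pairs$count, lambda = 1e-12)
  expect_equal(lo$fitted, pairs$count, tolerance = 1e-4)
  # 1e5 is far beyond the data-driven lambda scale (~1e-3 here); pushing
  # lambda orders of magnitude further only erodes conditioning
  hi <- fit_smoothing_spline(pairs$age, pairs$count, lambda = 1e5)
  line <- stats::lm(count ~ age, data = pairs)
  expect_equal(hi$fitted, unname(stats::fitted(line)), tolerance = 1e-4)
})

test_that("spar mapping follows the trace-ratio formula", {
  pairs <- toy_pairs(10, seed = 7)
  tr <- design_traces(pairs$age)
  # spar = 1/3: exponent vanishes, lambda equals the trace ratio exactly
  expect_identical(spar_to_lambda(1 / 3, tr[["design"]], tr[["penalty"]]),
                   tr[["design"]] / tr[["penalty"]])
  # explicit-matrix oracle
  ora <- oracle_spline(pairs$age, pairs$count, spar = 0.8)
  expect_equal(spar_to_lambda(0.8, tr[["design"]], tr[["penalty"]]),
               ora$lambda, tolerance = 1e-10)
  expect_equal(unname(tr), c(ora$trace_design, ora$trace_penalty),
               tolerance = 1e-10)
  # monotone in spar
  lams <- vapply(seq(0.2, 1.4, by = 0.2), spar_to_lambda, numeric(1),
                 tr[["design"]], tr[["penalty"]])
  expect_true(all(diff(lams) > 0))
  expect_error(spar_to_lambda(0.8, -1, 2), class = "immunospline_degenerate_design")
})

test_that("fit at spar = 0.8 agrees with the reference implementation", {
  # smooth.spline's internal quadrature differs slightly from the exact
  # penalty, so agreement is expected at ~1e-4, not machine precision
  pairs <- toy_pairs(40, seed = 11)
  fit <- fit_smoothing_spline(pairs$age, pairs$count, spar = 0.8)
  ref <- stats::smooth.spline(pairs$age, pairs$count, spar = 0.8,
                              all.knots = TRUE, cv = NA)
  expect_equal(fit$lambda, ref$lambda, tolerance = 0.01)
  expect_equal(fit$fitted, ref$y, tolerance = 1e-3)
  g <- 25:85
  expect_equal(evaluate_first_derivative(fit, g),
               stats::predict(ref, g, deriv = 1)$y, tolerance = 1e-2)
})

test_that("effective degrees of freedom are non-increasing in spar", {
  pairs <- toy_pairs(50, seed = 5)
  edfs <- vapply(seq(0.2, 1.5, by = 0.1), function(s)
    fit_smoothing_spline(pairs$age, pairs$count, spar = s)$edf, numeric(1))
  expect_true(all(diff(edfs) <= 1e-8))
})

test_that("curve evaluation matches knot fitted values and is C2", {
  pairs <- toy_pairs(15, seed = 9)
  fit <- fit_smoothing_spline(pairs$age, pairs$count, spar = 0.7)
  expect_equal(evaluate_curve(fit, fit$knots), fit$fitted, tolerance = 1e-10)
  # natural boundary conditions: second derivative ~ 0 at the boundary
  d2 <- function(a, h = 1e-3) {
    (evaluate_first_derivative(fit, a + h) -
       evaluate_first_derivative(fit, a - h)) / (2 * h)
  }
  scale2 <- max(abs(d2(seq(min(fit$knots) + 1, max(fit$knots) - 1, by = 1))))
  expect_lt(abs(d2(min(fit$knots) + 1e-3)), 1e-3 * max(scale2, 1))
  expect_lt(abs(d2(max(fit$knots) - 1e-3)), 1e-3 * max(scale2, 1))
})

test_that("analytic first derivative matches central finite differences", {
  for (seed in c(2, 4, 6)) {
    pairs <- toy_pairs(30, seed = seed)
    fit <- fit_smoothing_spline(pairs$age, pairs$count, spar = 0.8)
    g <- seq(min(pairs$age) + 1, max(pairs$age) - 1, by = 1)
    h <- 1e-4
    fd <- (evaluate_curve(fit, g + h) - evaluate_curve(fit, g - h)) / (2 * h)
    expect_lt(max(abs(fd - evaluate_first_derivative(fit, g))), 1e-5)
  }
})

test_that("duplicate ages collapse to weighted means", {
  age <- c(20, 20, 35, 50, 50, 50, 65, 90)
  count <- c(100, 140, 200, 300, 320, 340, 260, 150)
  fit_dup <- fit_smoothing_spline(age, count, spar = 0.8)
  # equivalent collapsed problem
  ua <- c(20, 35, 50, 65, 90)
  uy <- c(120, 200, 320, 260, 150)
  w <- c(2, 1, 3, 1, 1)
  fit_col <- fit_smoothing_spline(ua, uy, spar = 0.8, weights = w)
  expect_equal(fit_dup$fitted, fit_col$fitted, tolerance = 1e-10)
  expect_equal(fit_dup$lambda, fit_col$lambda, tolerance = 1e-10)
})

test_that("evaluation outside the span is refused unless extrapolating", {
  pairs <- toy_pairs(10, seed = 13)
  fit <- fit_smoothing_spline(pairs$age, pairs$count, spar = 0.8)
  hi <- max(pairs$age)
  expect_error(evaluate_curve(fit, hi + 5), class = "immunospline_extrapolation")
  # linear extension: value and slope continue the boundary tangent
  v <- evaluate_curve(fit, hi + 5, extrapolate = TRUE)
  expect_equal(v, evaluate_curve(fit, hi) +
                 5 * evaluate_first_derivative(fit, hi), tolerance = 1e-8)
  expect_equal(evaluate_first_derivative(fit, hi + 5, extrapolate = TRUE),
               evaluate_first_derivative(fit, hi), tolerance = 1e-8)
})

test_that("degenerate inputs raise typed errors", {
  expect_error(fit_smoothing_spline(c(20, 30, 40), c(1, 2, 3), spar = 0.8),
               class = "immunospline_insufficient_data")
  expect_error(fit_smoothing_spline(rep(50, 10), rnorm(10), spar = 0.8),
               class = "immunospline_insufficient_data")
  expect_error(fit_smoothing_spline(19:28, rnorm(10), spar = 0.8,
                                    weights = c(-1, rep(1, 9))),
               class = "immunospline_bad_argument")
  expect_error(fit_smoothing_spline(19:28, rnorm(10), spar = 0.8, lambda = 1),
               class = "immunospline_bad_argument")
})
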