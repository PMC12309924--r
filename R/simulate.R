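# Synthetic cross-sectional cohorts with known age trajectories, sex
# effects and interactions, giving every inference stage a ground truth.
#
# The generator mirrors the design of the motivating cohort: 117 women
# and 114 men, integer ages drawn uniformly on 19..93 years (survey ages
# are whole years), one column of absolute counts (cells/uL) per
# population, and overdispersed strictly-positive count noise
# (mean-one lognormal multiplicative with sigma = 0.4 by default, a
# realistic right-skew for cytometry counts).

# ---- trajectories ------------------------------------------------------

new_trajectory <- function(fun, form, params) {
  structure(list(fun = fun, form = form, params = params),
            class = "trajectory")
}

#' Trajectory constructors for synthetic cohorts
#'
#' A trajectory gives the true mean count (cells/uL) as a smooth or
#' piecewise function of age; optionally one sex gets its own parameter
#' set via [traj_by_sex()].
#'
#' * `traj_constant(level)` — flat mean.
#' * `traj_linear(level, slope, ref_age)` — `level + slope * (age - ref_age)`.
#' * `traj_logistic_decline(from, to, midpoint, width)` — sigmoidal
#'   decline from `from` to `to`, centred at `midpoint`, width in years.
#' * `traj_piecewise_linear(ages, values)` — linear interpolation
#'   through the given points, constant outside.
#' * `traj_gaussian_bump(baseline, height, center, width)` — localized
#'   excursion.
#' * `traj_sum(...)` — pointwise sum of trajectories.
#'
#' @param level,slope,ref_age,from,to,midpoint,width,ages,values,baseline,height,center
#'   Form-specific parameters; levels in cells/uL, slopes in cells/uL
#'   per year, ages in years.
#' @param ... Trajectories to sum.
#' @return A `trajectory` object.
#' @name trajectories
NULL

#' @rdname trajectories
#' @export
traj_constant <- function(level) {
  new_trajectory(function(age) rep(level, length(age)), "constant",
                 list(level = level))
}

#' @rdname trajectories
#' @export
traj_linear <- function(level, slope, ref_age = 19) {
  new_trajectory(function(age) level + slope * (age - ref_age), "linear",
                 list(level = level, slope = slope, ref_age = ref_age))
}

#' @rdname trajectories
#' @export
traj_logistic_decline <- function(from, to, midpoint, width) {
  new_trajectory(function(age) to + (from - to) / (1 + exp((age - midpoint) / width)),
                 "logistic_decline",
                 list(from = from, to = to, midpoint = midpoint, width = width))
}

#' @rdname trajectories
#' @export
traj_piecewise_linear <- function(ages, values) {
  stopifnot(length(ages) == length(values), !is.unsorted(ages))
  new_trajectory(function(age) stats::approx(ages, values, xout = age,
                                             rule = 2)$y,
                 "piecewise_linear", list(ages = ages, values = values))
}

#' @rdname trajectories
#' @export
traj_gaussian_bump <- function(baseline, height, center, width) {
  new_trajectory(function(age) baseline + height * exp(-((age - center) / width)^2 / 2),
                 "gaussian_bump",
                 list(baseline = baseline, height = height, center = center,
                      width = width))
}

#' @rdname trajectories
#' @export
traj_sum <- function(...) {
  parts <- list(...)
  stopifnot(all(vapply(parts, inherits, logical(1), "trajectory")))
  new_trajectory(function(age) Reduce(`+`, lapply(parts, function(p) p$fun(age))),
                 "sum", list(parts = parts))
}

#' Sex-specific trajectory override
#'
#' @param female,male Trajectories for each sex.
#' @return A `sex_trajectory` usable wherever a trajectory is expected.
#' @export
traj_by_sex <- function(female, male) {
  stopifnot(inherits(female, "trajectory"), inherits(male, "trajectory"))
  structure(list(female = female, male = male), class = "sex_trajectory")
}

#' Evaluate a trajectory's true mean at given ages
#'
#' @param traj A `trajectory` or `sex_trajectory`.
#' @param age Numeric ages.
#' @param sex `"female"` or `"male"`; required only for sex-specific
#'   trajectories (either label works for shared ones).
#' @return True mean counts at `age`.
#' @export
traj_eval <- function(traj, age, sex = "female") {
  if (inherits(traj, "sex_trajectory")) traj <- traj[[sex]]
  stopifnot(inherits(traj, "trajectory"))
  traj$fun(age)
}

# Central-difference derivative of the true mean (cells/uL per year).
traj_deriv <- function(traj, age, sex = "female", h = 0.005) {
  (traj_eval(traj, age + h, sex) - traj_eval(traj, age - h, sex)) / (2 * h)
}

# ---- noise -------------------------------------------------------------

new_noise <- function(fun, family, dispersion) {
  structure(list(fun = fun, family = family, dispersion = dispersion),
            class = "noise_spec")
}

#' Count-noise families for synthetic cohorts
#'
#' All families generate nonnegative counts around a given mean:
#'
#' * `noise_lognormal(sigma)` — mean-one multiplicative lognormal,
#'   `mu * exp(sigma * Z - sigma^2 / 2)`; the default (`sigma = 0.4`)
#'   gives right-skewed counts with a coefficient of variation of about
#'   42%.
#' * `noise_nbinom(size)` — negative binomial with mean `mu` and
#'   dispersion `size` (variance `mu + mu^2 / size`).
#' * `noise_truncnorm(cv)` — Gaussian with sd `cv * mu`, truncated at
#'   zero by resampling (slight upward mean bias when `cv` is large).
#'
#' @param sigma,size,cv Family-specific dispersion (> 0; `sigma = 0` or
#'   `cv = 0` degenerate to exactly the mean).
#' @return A `noise_spec`.
#' @name noise
NULL

#' @rdname noise
#' @export
noise_lognormal <- function(sigma = 0.4) {
  stopifnot(sigma >= 0)
  new_noise(function(mu) mu * exp(stats::rnorm(length(mu), 0, sigma) - sigma^2 / 2),
            "lognormal-multiplicative", sigma)
}

#' @rdname noise
#' @export
noise_nbinom <- function(size = 10) {
  stopifnot(size > 0)
  new_noise(function(mu) stats::rnbinom(length(mu), mu = mu, size = size),
            "negative-binomial", size)
}

#' @rdname noise
#' @export
noise_truncnorm <- function(cv = 0.3) {
  stopifnot(cv >= 0)
  new_noise(function(mu) {
    x <- stats::rnorm(length(mu), mu, cv * mu)
    while (any(neg <- x < 0)) x[neg] <- stats::rnorm(sum(neg), mu[neg], cv * mu[neg])
    x
  }, "gaussian-truncated-at-zero", cv)
}

# ---- cohort configuration and simulation -------------------------------

#' Configuration for a synthetic cohort
#'
#' @param populations Named list; each element is `list(trajectory = ,
#'   noise = )` with a [trajectories] object (or [traj_by_sex()]) and a
#'   [noise] spec.
#' @param n_female,n_male Group sizes (defaults mirror the motivating
#'   study: 117 women, 114 men).
#' @param age_range Integer age span, default 19–93 years.
#' @param age_distribution `"uniform"` (integer-uniform over the span)
#'   or `"empirical"` (middle-weighted, mimicking sparse age tails).
#' @param seed Integer seed recorded with the cohort.
#' @return A `cohort_config`.
#' @export
cohort_config <- function(populations, n_female = 117, n_male = 114,
                          age_range = c(19, 93),
                          age_distribution = c("uniform", "empirical"),
                          seed = 1) {
  age_distribution <- match.arg(age_distribution)
  stopifnot(n_female >= 4, n_male >= 4, is.list(populations),
            length(populations) >= 1, !is.null(names(populations)))
  fine <- seq(age_range[1], age_range[2], by = 0.01)
  for (nm in names(populations)) {
    p <- populations[[nm]]
    stopifnot(inherits(p$trajectory, c("trajectory", "sex_trajectory")),
              inherits(p$noise, "noise_spec"))
    for (sx in c("female", "male")) {
      mu <- traj_eval(p$trajectory, fine, sx)
      if (any(!is.finite(mu)) || any(mu < 0)) {
        stop_immunospline("config", sprintf(
          "trajectory for population '%s' (%s) yields negative or non-finite means",
          nm, sx))
      }
    }
  }
  structure(list(populations = populations, n_female = n_female,
                 n_male = n_male, age_range = age_range,
                 age_distribution = age_distribution, seed = seed),
            class = "cohort_config")
}

#' Simulate a cohort with known ground truth
#'
#' Draws ages per sex from the configured distribution, evaluates each
#' population's true mean trajectory at each participant's age and sex,
#' and applies the population's noise.  The ground truth (true curves,
#' true derivatives, and their exact sign regions, all tabulated on a
#' 0.01-year grid independent of any fitting) is returned alongside the
#' cohort.  Fully reproducible from the config seed.
#'
#' @param config A [cohort_config()].
#' @return A list with elements `cohort` (a [cohort_table()]), `truth`
#'   (a `ground_truth`), and `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed)
  n <- c(female = config$n_female, male = config$n_male)
  ages <- sexes <- NULL
  for (sx in c("female", "male")) {
    a <- draw_ages(n[[sx]], config$age_range, config$age_distribution)
    ages <- c(ages, a); sexes <- c(sexes, rep(sx, n[[sx]]))
  }
  data <- tibble::tibble(
    participant_id = sprintf("P%04d", seq_along(ages)),
    age = as.numeric(ages), sex = sexes)
  for (nm in names(config$populations)) {
    p <- config$populations[[nm]]
    mu <- numeric(length(ages))
    for (sx in c("female", "male")) {
      i <- sexes == sx
      mu[i] <- traj_eval(p$trajectory, ages[i], sx)
    }
    data[[nm]] <- p$noise$fun(mu)
  }
  cohort <- cohort_table(data, populations = names(config$populations))
  list(cohort = cohort, truth = ground_truth(config), config = config)
}

draw_ages <- function(n, age_range, distribution) {
  span <- age_range[1]:age_range[2]
  prob <- if (distribution == "empirical") {
    # sparse tails: few participants near 20 and above 90
    w <- stats::dnorm(span, mean = 55, sd = 18); w / sum(w)
  } else NULL
  for (try in 1:100) {
    a <- sample(span, n, replace = TRUE, prob = prob)
    if (length(unique(a)) >= min(4L, length(span))) return(a)
  }
  stop_immunospline("config", "could not draw 4 distinct ages")
}

# Tabulated ground truth on a fine (0.01-year) grid.
ground_truth <- function(config) {
  fine <- seq(config$age_range[1], config$age_range[2], by = 0.01)
  pops <- lapply(config$populations, function(p) {
    curves <- lapply(c(female = "female", male = "male"),
                     function(sx) traj_eval(p$trajectory, fine, sx))
    derivs <- lapply(c(female = "female", male = "male"),
                     function(sx) traj_deriv(p$trajectory, fine, sx))
    list(curve = curves, derivative = derivs,
         derivative_difference = derivs$female - derivs$male,
         trajectory = p$trajectory)
  })
  structure(list(ages = fine, populations = pops,
                 age_range = config$age_range), class = "ground_truth")
}

#' Exact sign regions of a true statistic
#'
#' Run-extraction on the tabulated ground truth (zero, within a small
#' numerical tolerance, counts as non-significant), encoded exactly like
#' the regions produced by [extract_significant_regions()] so detected
#' and true regions can be compared with [region_jaccard()].
#'
#' @param truth A `ground_truth` from [simulate_cohort()].
#' @param grid Evaluation ages (coarser than or equal to the tabulation).
#' @param statistic `"derivative"` (per sex) or `"derivative-difference"`.
#' @param population Population name (default the first).
#' @param sex Sex for the per-sex derivative (default `"female"`).
#' @param tol Values within `tol` of zero count as zero.
#' @return A region tibble (`statistic`, `start_age`, `end_age`,
#'   `direction`).
#' @export
true_significant_regions <- function(truth, grid,
                                     statistic = c("derivative",
                                                   "derivative-difference"),
                                     population = NULL, sex = "female",
                                     tol = 1e-8) {
  statistic <- match.arg(statistic)
  stopifnot(inherits(truth, "ground_truth"))
  if (is.null(population)) population <- names(truth$populations)[1]
  p <- truth$populations[[population]]
  if (is.null(p)) stop_immunospline("lookup",
                                    paste0("unknown population: ", population))
  vals_fine <- switch(statistic,
    "derivative" = p$derivative[[sex]],
    "derivative-difference" = p$derivative_difference)
  v <- stats::approx(truth$ages, vals_fine, xout = grid, rule = 2)$y
  state <- ifelse(v > tol, 1L, ifelse(v < -tol, -1L, 0L))
  labels <- if (statistic == "derivative") c("increase", "decrease")
            else c("group1-higher", "group2-higher")
  runs <- rle(state)
  ends <- cumsum(runs$lengths); starts <- ends - runs$lengths + 1L
  keep <- runs$values != 0L
  tibble::tibble(statistic = rep(statistic, sum(keep)),
                 start_age = grid[starts[keep]],
                 end_age = grid[ends[keep]],
                 direction = as.character(
                   ifelse(runs$values[keep] > 0L, labels[1L], labels[2L])))
}

#' Write a simulated cohort with its ground-truth sidecar
#'
#' The cohort goes out in the package's TSV dialect; a JSON sidecar
#' (`<path>.truth.json`) records the seed, cohort sizes and the true
#' curves and derivatives tabulated on a 1-year grid.
#'
#' @param sim Result of [simulate_cohort()].
#' @param path TSV output path.
#' @return `path`, invisibly.
#' @export
write_simulated_cohort <- function(sim, path) {
  write_cohort(sim$cohort, path)
  grid <- seq(sim$config$age_range[1], sim$config$age_range[2], by = 1)
  tab <- lapply(sim$truth$populations, function(p) list(
    curve = lapply(p$curve, function(v)
      stats::approx(sim$truth$ages, v, xout = grid)$y),
    derivative = lapply(p$derivative, function(v)
      stats::approx(sim$truth$ages, v, xout = grid)$y)))
  jsonlite::write_json(list(
    seed = sim$config$seed, n_female = sim$config$n_female,
    n_male = sim$config$n_male, age_range = sim$config$age_range,
    grid = grid, truth = tab
  ), paste0(path, ".truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# ---- scenario library --------------------------------------------------

#' Built-in simulation scenarios
#'
#' Each scenario returns a ready [cohort_config()] at the default cohort
#' size (117 women, 114 men, integer ages 19–93, mean-one lognormal
#' noise with `sigma = 0.4`) containing a single population named after
#' the scenario:
#'
#' * `scenario_null()` — flat truth at `level`; nothing should be
#'   flagged beyond the nominal false-positive rate.
#' * `scenario_logistic_decline()` — smooth sigmoidal decline (600 to
#'   300 cells/uL, centred at 55, width 8 years), the coverage
#'   benchmark.
#' * `scenario_decline()` — piecewise-linear decline at `slope` over
#'   `[onset, end]`, flat elsewhere; true decrease region `[onset, end]`.
#' * `scenario_sex_shift()` — female counts shifted by `delta` on
#'   `[from, to]` (2-year ramps), male flat; a level difference with no
#'   derivative difference outside the ramps.
#' * `scenario_interaction()` — female counts decline at `slope` over
#'   `[from, to]`, male flat: equal slopes outside the window, so the
#'   true derivative-difference region is exactly `[from, to]`.
#'
#' @param level,from,to,midpoint,width,onset,end,slope,delta Scenario
#'   parameters (cells/uL, years, cells/uL per year).
#' @param sigma Lognormal noise dispersion (default 0.4).
#' @param n_female,n_male Group sizes.
#' @param seed Seed recorded in the config.
#' @return A `cohort_config`.
#' @name scenarios
NULL

scenario_config <- function(name, trajectory, sigma, n_female, n_male, seed) {
  pops <- list(list(trajectory = trajectory, noise = noise_lognormal(sigma)))
  names(pops) <- name
  cohort_config(pops, n_female = n_female, n_male = n_male, seed = seed)
}

#' @rdname scenarios
#' @export
scenario_null <- function(level = 500, sigma = 0.4, n_female = 117,
                          n_male = 114, seed = 1) {
  scenario_config("flat", traj_constant(level), sigma, n_female, n_male, seed)
}

#' @rdname scenarios
#' @export
scenario_logistic_decline <- function(from = 600, to = 300, midpoint = 55,
                                      width = 8, sigma = 0.4, n_female = 117,
                                      n_male = 114, seed = 1) {
  scenario_config("logistic_decline",
                  traj_logistic_decline(from, to, midpoint, width),
                  sigma, n_female, n_male, seed)
}

#' @rdname scenarios
#' @export
scenario_decline <- function(level = 600, onset = 40, end = 75, slope = -8,
                             sigma = 0.4, n_female = 117, n_male = 114,
                             seed = 1) {
  lo <- level + slope * (end - onset)
  traj <- traj_piecewise_linear(c(19, onset, end, 93),
                                c(level, level, lo, lo))
  scenario_config("declining", traj, sigma, n_female, n_male, seed)
}

#' @rdname scenarios
#' @export
scenario_sex_shift <- function(level = 500, delta = 200, from = 40, to = 70,
                               sigma = 0.4, n_female = 117, n_male = 114,
                               seed = 1) {
  female <- traj_piecewise_linear(
    c(19, from, from + 2, to - 2, to, 93),
    c(level, level, level + delta, level + delta, level, level))
  scenario_config("sex_shift", traj_by_sex(female, traj_constant(level)),
                  sigma, n_female, n_male, seed)
}

#' @rdname scenarios
#' @export
scenario_interaction <- function(level = 700, slope = -8, from = 20, to = 60,
                                 sigma = 0.4, n_female = 117, n_male = 114,
                                 seed = 1) {
  lo <- level + slope * (to - from)
  female <- traj_piecewise_linear(c(19, from, to, 93), c(level, level, lo, lo))
  scenario_config("interaction", traj_by_sex(female, traj_constant(level)),
                  sigma, n_female, n_male, seed)
}

#' Synthetic multi-population panel
#'
#' A deterministic panel of `n_populations` populations cycling through
#' the trajectory forms with varied levels, onsets and slopes, at the
#' default cohort size and noise — a stand-in for a full 35-subset
#' leukocyte panel when exercising the whole pipeline.
#'
#' @param n_populations Number of populations (default 35).
#' @inheritParams scenarios
#' @return A `cohort_config`.
#' @export
scenario_panel <- function(n_populations = 35, sigma = 0.4, n_female = 117,
                           n_male = 114, seed = 1) {
  pops <- list()
  for (i in seq_len(n_populations)) {
    level <- 200 + 40 * (i %% 7)
    traj <- switch((i %% 4) + 1L,
      traj_constant(level),
      traj_logistic_decline(level + 200, level, 35 + (i %% 5) * 10, 6 + i %% 4),
      traj_piecewise_linear(c(19, 30 + i %% 20, 70, 93),
                            c(level + 150, level + 150, level, level)),
      traj_by_sex(traj_piecewise_linear(c(19, 25, 60, 93),
                                        c(level + 160, level + 160,
                                          level, level)),
                  traj_constant(level + 160)))
    pops[[sprintf("pop%02d", i)]] <- list(trajectory = traj,
                                          noise = noise_lognormal(sigma))
  }
  cohort_config(pops, n_female = n_female, n_male = n_male, seed = seed)
}
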