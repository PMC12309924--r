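# Synthetic cohorts: trajectories, noise, ground truth.

test_that("simulation is byte-identical under a fixed seed", {
  cfg <- scenario_interaction(seed = 123)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(as.data.frame(a$cohort), as.data.frame(b$cohort))
})

test_that("default cohort mirrors the study design", {
  sim <- simulate_cohort(scenario_null(seed = 2))
  expect_equal(sum(sim$cohort$sex == "female"), 117L)
  expect_equal(sum(sim$cohort$sex == "male"), 114L)
  expect_true(all(sim$cohort$age >= 19 & sim$cohort$age <= 93))
  expect_true(all(sim$cohort$age == round(sim$cohort$age)))
})

test_that("degenerate noise reproduces the trajectory exactly", {
  cfg <- cohort_config(
    list(popA = list(trajectory = traj_logistic_decline(600, 300, 55, 8),
                     noise = noise_lognormal(0))),
    n_female = 20, n_male = 20, seed = 5)
  sim <- simulate_cohort(cfg)
  mu <- traj_eval(cfg$populations$popA$trajectory, sim$cohort$age)
  expect_equal(sim$cohort$popA, mu, tolerance = 1e-12)
})

test_that("noise families are mean-preserving at fixed age", {
  mu <- rep(traj_eval(traj_logistic_decline(600, 300, 55, 8), 50), 20000)
  set.seed(11)
  for (noise in list(noise_lognormal(0.4), noise_nbinom(10))) {
    x <- noise$fun(mu)
    expect_true(all(x >= 0))
    se <- stats::sd(x) / sqrt(length(x))
    expect_lt(abs(mean(x) - mu[1]), 3 * se)
  }
})

test_that("negative trajectory means are refused before sampling", {
  expect_error(
    cohort_config(list(bad = list(trajectory = traj_linear(10, -5),
                                  noise = noise_lognormal()))),
    class = "immunospline_config")
})

test_that("true regions come from sign runs of the tabulated truth", {
  # constant trajectory: no regions
  flat <- simulate_cohort(scenario_null(seed = 1))
  expect_equal(nrow(true_significant_regions(flat$truth, 19:93, "derivative",
                                             population = "flat")), 0L)
  # piecewise linear decline on [40, 75]
  dec <- simulate_cohort(scenario_decline(onset = 40, end = 75, seed = 1))
  r <- true_significant_regions(dec$truth, 19:93, "derivative",
                                population = "declining")
  expect_equal(nrow(r), 1L)
  expect_equal(r$direction, "decrease")
  expect_lte(abs(r$start_age - 40), 1)
  expect_lte(abs(r$end_age - 75), 1)
  # interaction scenario: difference of derivatives is negative on [20, 60]
  int <- simulate_cohort(scenario_interaction(from = 20, to = 60, seed = 1))
  rd <- true_significant_regions(int$truth, 19:93, "derivative-difference",
                                 population = "interaction")
  expect_equal(nrow(rd), 1L)
  expect_equal(rd$direction, "group2-higher")
  expect_lte(abs(rd$start_age - 20), 1)
  expect_lte(abs(rd$end_age - 60), 1)
})

test_that("thresholded true regions match an independent root solve", {
  # ages where the logistic decline is steeper than 1 cell/uL/year
  cfg <- scenario_logistic_decline(seed = 1)
  sim <- simulate_cohort(cfg)
  traj <- cfg$populations$logistic_decline$trajectory
  r <- true_significant_regions(sim$truth, 19:93, "derivative", tol = 1)
  dfun <- function(a) {
    h <- 1e-4
    (traj_eval(traj, a + h) - traj_eval(traj, a - h)) / (2 * h) + 1
  }
  lo <- stats::uniroot(dfun, c(19, 55))$root
  hi <- stats::uniroot(dfun, c(55, 93))$root
  expect_equal(nrow(r), 1L)
  expect_lte(abs(r$start_age - ceiling(lo)), 1)
  expect_lte(abs(r$end_age - floor(hi)), 1)
})

test_that("a noiseless cohort recovers the true region through the pipeline", {
  cfg <- scenario_decline(onset = 40, end = 75, sigma = 0, seed = 31)
  sim <- simulate_cohort(cfg)
  pairs <- cohort_subset(sim$cohort, "declining")
  # noiseless data need little smoothing; a light spar keeps the
  # smoothing halo around the kinks inside one or two grid steps
  band <- bootstrap_band(pairs, "derivative", spar = 0.4, n_boot = 100,
                         seed = 7)
  det <- extract_significant_regions(band)
  det <- det[det$direction == "decrease", ]
  tru <- true_significant_regions(sim$truth, band$grid, "derivative",
                                  population = "declining")
  expect_gt(region_jaccard(det, tru), 0.8)
})

test_that("cohorts write with a ground-truth sidecar and read back", {
  sim <- simulate_cohort(scenario_sex_shift(seed = 77))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_simulated_cohort(sim, path)
  back <- read_cohort(path)
  expect_equal(as.data.frame(back), as.data.frame(sim$cohort),
               tolerance = 1e-12)
  side <- jsonlite::read_json(paste0(path, ".truth.json"),
                              simplifyVector = TRUE)
  expect_equal(side$seed, 77L)
  expect_equal(side$grid, 19:93)
  expect_equal(
    side$truth$sex_shift$curve$female - side$truth$sex_shift$curve$male,
    traj_eval(sim$truth$populations$sex_shift$trajectory, 19:93, "female") -
      traj_eval(sim$truth$populations$sex_shift$trajectory, 19:93, "male"),
    tolerance = 1e-8)
})

test_that("the empirical age distribution thins the tails", {
  cfg <- scenario_null(seed = 3)
  cfg$age_distribution <- "empirical"
  sim <- simulate_cohort(cfg)
  ages <- sim$cohort$age
  expect_gt(mean(ages >= 40 & ages <= 70), mean(ages < 30 | ages > 80))
})
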