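# Case resampling, bootstrap bands, significant-region extraction.

test_that("case resampling keeps size, pairing and determinism", {
  pairs <- tibble::tibble(age = c(20, 30, 40), count = c(1, 2, 3))
  one <- pairs[2, ]
  expect_identical(case_bootstrap_resample(one), one)
  set.seed(99); a <- case_bootstrap_resample(pairs)
  set.seed(99); b <- case_bootstrap_resample(pairs)
  expect_identical(a, b)
  expect_equal(nrow(a), 3L)
  # resampled rows are whole records from the input
  expect_true(all(paste(a$age, a$count) %in% paste(pairs$age, pairs$count)))
  expect_error(case_bootstrap_resample(pairs[0, ]),
               class = "immunospline_domain")
})

test_that("selection frequencies are uniform across elements", {
  pairs <- tibble::tibble(age = 1:5, count = 1:5)
  set.seed(7)
  picks <- tabulate(replicate(10000, case_bootstrap_resample(pairs)$age[1]),
                    nbins = 5)
  p <- picks / 10000
  se <- sqrt(0.2 * 0.8 / 10000)
  expect_true(all(abs(p - 0.2) < 3 * se + 1e-12))
})

test_that("zero-noise linear data give a degenerate derivative band", {
  age <- rep(seq(20, 90, by = 5), 2)
  pairs <- tibble::tibble(age = age, count = 3 * age + 10)
  band <- bootstrap_band(pairs, "derivative", n_boot = 50, seed = 1)
  expect_lt(max(band$upper - band$lower), 1e-8)
  expect_equal(band$estimate, rep(3, length(band$grid)), tolerance = 1e-8)
})

test_that("bands at higher levels enclose bands at lower levels", {
  pairs <- toy_pairs(60, seed = 21)
  b95 <- bootstrap_band(pairs, "derivative", n_boot = 200, seed = 5,
                        level = 0.95)
  b80 <- bootstrap_band(pairs, "derivative", n_boot = 200, seed = 5,
                        level = 0.80)
  # same seed -> same replicate set, so nesting must hold elementwise
  expect_true(all(b95$lower <= b80$lower + 1e-12))
  expect_true(all(b95$upper >= b80$upper - 1e-12))
})

test_that("the default replicate count is 2000", {
  expect_equal(formals(bootstrap_band)$n_boot, 2000)
  expect_equal(formals(sex_contrast)$n_boot, 2000)
})

test_that("bands are reproducible and worker-count independent", {
  pairs <- toy_pairs(40, seed = 31)
  b1 <- bootstrap_band(pairs, "curve", n_boot = 60, seed = 17)
  b2 <- bootstrap_band(pairs, "curve", n_boot = 60, seed = 17)
  expect_identical(b1[c("estimate", "lower", "upper")],
                   b2[c("estimate", "lower", "upper")])
  b3 <- bootstrap_band(pairs, "curve", n_boot = 60, seed = 17, workers = 2L)
  expect_identical(b1[c("estimate", "lower", "upper")],
                   b3[c("estimate", "lower", "upper")])
})

test_that("basic intervals reflect percentile intervals about the estimate", {
  pairs <- toy_pairs(40, seed = 8)
  bp <- bootstrap_band(pairs, "curve", n_boot = 100, seed = 2,
                       interval_type = "percentile")
  bb <- bootstrap_band(pairs, "curve", n_boot = 100, seed = 2,
                       interval_type = "basic")
  expect_equal(bb$lower, 2 * bp$estimate - bp$upper, tolerance = 1e-12)
  expect_equal(bb$upper, 2 * bp$estimate - bp$lower, tolerance = 1e-12)
})

test_that("replicates with too few distinct ages are redrawn and counted", {
  pairs <- tibble::tibble(age = c(20, 40, 60, 80), count = c(1, 2, 3, 4))
  band <- bootstrap_band(pairs, "curve", n_boot = 100, seed = 3)
  # with n = 4, most resamples have < 4 distinct ages and must be redrawn
  expect_gt(band$n_redrawn, 0)
  expect_true(all(is.finite(band$lower)))
})

test_that("region extraction is a run-length encoding of band sign", {
  g <- 1:7
  # sign pattern +, +, 0, -, -, 0, +
  band <- make_band(g,
                    lower = c(1, 1, -1, -3, -3, -1, 2),
                    upper = c(2, 2, 1, -1, -1, 1, 3))
  r <- extract_significant_regions(band)
  expect_equal(nrow(r), 3L)
  expect_equal(r$start_age, c(1, 4, 7))
  expect_equal(r$end_age, c(2, 5, 7))
  expect_equal(r$direction, c("increase", "decrease", "increase"))
  # a band that always overlaps zero yields no regions
  null_band <- make_band(g, lower = rep(-1, 7), upper = rep(1, 7))
  expect_equal(nrow(extract_significant_regions(null_band)), 0L)
  # a band above zero everywhere yields one full-span region
  pos <- make_band(g, lower = rep(0.5, 7), upper = rep(1, 7))
  rp <- extract_significant_regions(pos)
  expect_equal(rp[, c("start_age", "end_age", "direction")],
               tibble::tibble(start_age = 1, end_age = 7,
                              direction = "increase"))
  # deterministic: recomputation yields identical regions
  expect_identical(extract_significant_regions(band),
                   extract_significant_regions(band))
})

test_that("difference statistics get group-difference direction labels", {
  band <- make_band(1:3, lower = c(1, 1, 1), upper = c(2, 2, 2),
                    statistic = "derivative-difference")
  expect_equal(unique(extract_significant_regions(band)$direction),
               "group1-higher")
})

test_that("region Jaccard uses grid-age sets", {
  a <- tibble::tibble(start_age = 40, end_age = 59)
  b <- tibble::tibble(start_age = 50, end_age = 69)
  # 10 shared ages of 30 in the union
  expect_equal(region_jaccard(a, b), 10 / 30)
  expect_equal(region_jaccard(a, a), 1)
  expect_equal(region_jaccard(a[0, ], a[0, ]), 1)
  expect_equal(region_jaccard(a[0, ], b), 0)
  # a single-grid-point region has size one
  p <- tibble::tibble(start_age = 63, end_age = 63)
  expect_equal(region_jaccard(p, p), 1)
})
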