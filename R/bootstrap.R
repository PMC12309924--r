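# Nonparametric case bootstrap of the spline fit: pointwise confidence
# bands for the fitted curve and its first derivative, and extraction of
# the age ranges where a band excludes a reference value.
#
# Resampling is at the participant level: whole (age, count) records are
# drawn with replacement and the spline refit with the SAME spar on each
# replicate (no per-replicate smoothing selection).  Bands are pointwise
# empirical percentile intervals across replicates by default.

#' Resample (age, count) pairs with replacement
#'
#' Participant-level (case) resampling: whole records are drawn with
#' replacement, preserving the pairing of age and count and hence any
#' heteroscedasticity in the counts.
#'
#' @param pairs A data frame with columns `age` and `count`.
#' @return A data frame of the same size drawn with replacement.
#' @export
case_bootstrap_resample <- function(pairs) {
  if (NROW(pairs) == 0L) {
    stop_immunospline("domain", "cannot resample an empty set of pairs")
  }
  pairs[sample.int(NROW(pairs), replace = TRUE), , drop = FALSE]
}

#' Pointwise bootstrap confidence band for a spline statistic
#'
#' Fits the smoothing spline to the full sample, then refits it to
#' `n_boot` case resamples (same `spar`, same evaluation grid) and forms
#' elementwise empirical percentile intervals across replicates.
#' Replicates whose resample has fewer than 4 distinct ages are redrawn
#' (up to `max_redraw` attempts, then dropped and counted).
#'
#' @param pairs Data frame with columns `age` and `count`.
#' @param statistic `"curve"` for the fitted mean, `"derivative"` for
#'   its first derivative.
#' @param spar Scale-free smoothing parameter held fixed in every
#'   replicate (default 0.8).
#' @param grid Evaluation ages; default 1-year steps over the observed
#'   span.
#' @param level Nominal pointwise coverage (default 0.95).
#' @param n_boot Number of bootstrap replicates (default 2000).
#' @param seed Integer seed; every replicate gets its own deterministic
#'   substream, so results do not depend on execution order or worker
#'   count.
#' @param interval_type `"percentile"` (default) or `"basic"`
#'   (reflected) intervals.
#' @param workers Number of forked workers for the replicate loop.
#' @param keep_replicates Retain the replicate-by-grid matrix?
#' @return A `bootstrap_band`: list with `grid`, `estimate`, `lower`,
#'   `upper`, `level`, `n_boot`, `statistic`, `seed`, `n_redrawn`,
#'   `n_dropped`.
#' @export
bootstrap_band <- function(pairs, statistic = c("curve", "derivative"),
                           spar = 0.8, grid = NULL, level = 0.95,
                           n_boot = 2000, seed = 1,
                           interval_type = c("percentile", "basic"),
                           workers = 1L, keep_replicates = FALSE) {
  statistic <- match.arg(statistic)
  interval_type <- match.arg(interval_type)
  core <- trajectory_replicates(pairs, spar = spar, grid = grid,
                                n_boot = n_boot, seed = seed,
                                workers = workers)
  band_from_replicates(core$grid, core$estimates[[statistic]],
                       core$replicates[[statistic]], level = level,
                       statistic = statistic, seed = seed,
                       interval_type = interval_type,
                       n_redrawn = core$n_redrawn, n_dropped = core$n_dropped,
                       keep_replicates = keep_replicates)
}

# Shared bootstrap core: one replicate set, both statistics evaluated on
# the same grid, so curve and derivative panels are mutually consistent.
trajectory_replicates <- function(pairs, spar = 0.8, grid = NULL,
                                  n_boot = 2000, seed = 1, workers = 1L,
                                  min_distinct = 4L, max_redraw = 100L) {
  age <- pairs$age; count <- pairs$count
  if (length(age) < 1L) stop_immunospline("domain", "no observations")
  if (n_boot < 2L) stop_immunospline("bad_argument", "n_boot must be >= 2")
  full <- fit_smoothing_spline(age, count, spar = spar, compute_edf = FALSE)
  if (is.null(grid)) grid <- default_grid(age)
  est <- list(curve = evaluate_curve(full, grid, extrapolate = TRUE),
              derivative = evaluate_first_derivative(full, grid,
                                                     extrapolate = TRUE))
  rseeds <- replicate_seeds(seed, n_boot)
  one <- function(b) {
    set.seed(rseeds[b])
    n <- length(age)
    for (try in seq_len(max_redraw)) {
      idx <- sample.int(n, replace = TRUE)
      if (n_distinct_ages(age[idx]) >= min_distinct) {
        f <- fit_smoothing_spline(age[idx], count[idx], spar = spar,
                                  compute_edf = FALSE)
        return(c(evaluate_curve_deriv(f, grid), try - 1L))
      }
    }
    rep(NA_real_, 2L * length(grid) + 1L)  # dropped replicate
  }
  res <- run_replicates(one, n_boot, workers)
  res <- do.call(rbind, res)
  G <- length(grid)
  curve_reps <- res[, seq_len(G), drop = FALSE]
  deriv_reps <- res[, G + seq_len(G), drop = FALSE]
  redraws <- res[, 2L * G + 1L]
  list(grid = grid, estimates = est,
       replicates = list(curve = curve_reps, derivative = deriv_reps),
       n_redrawn = sum(redraws, na.rm = TRUE),
       n_dropped = sum(is.na(redraws)))
}

run_replicates <- function(fun, n_boot, workers) {
  if (workers > 1L) {
    parallel::mclapply(seq_len(n_boot), fun, mc.cores = workers,
                       mc.preschedule = TRUE)
  } else {
    lapply(seq_len(n_boot), fun)
  }
}

# Deterministic per-replicate seed schedule derived from the master seed.
replicate_seeds <- function(seed, n, streams = 1L) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  matrix(sample.int(.Machine$integer.max, n * streams), nrow = n)
}

n_distinct_ages <- function(age, tol = NULL) {
  if (is.null(tol)) tol <- 1e-6 * max(diff(range(age)), 1)
  sum(diff(sort(age)) > tol) + 1L
}

default_grid <- function(age, step = 1) {
  seq(ceiling(min(age) / step) * step, floor(max(age) / step) * step, by = step)
}

band_from_replicates <- function(grid, estimate, reps, level, statistic, seed,
                                 interval_type = "percentile",
                                 n_redrawn = 0L, n_dropped = 0L,
                                 keep_replicates = FALSE) {
  stopifnot(level > 0, level < 1)
  probs <- c((1 - level) / 2, (1 + level) / 2)
  q <- apply(reps, 2L, stats::quantile, probs = probs, na.rm = TRUE,
             names = FALSE)
  if (interval_type == "percentile") {
    lower <- q[1L, ]; upper <- q[2L, ]
  } else {  # basic / reflected intervals
    lower <- 2 * estimate - q[2L, ]
    upper <- 2 * estimate - q[1L, ]
  }
  structure(list(
    grid = grid, estimate = estimate, lower = lower, upper = upper,
    level = level, n_boot = nrow(reps), statistic = statistic, seed = seed,
    interval_type = interval_type, n_redrawn = n_redrawn,
    n_dropped = n_dropped,
    replicates = if (keep_replicates) reps else NULL
  ), class = "bootstrap_band")
}

#' @export
print.bootstrap_band <- function(x, ...) {
  cat(sprintf("Bootstrap %s band (%.0f%%, %d replicates, %s intervals)\n",
              x$statistic, 100 * x$level, x$n_boot, x$interval_type))
  cat(sprintf("  grid: %g-%g (%d ages); dropped replicates: %d\n",
              min(x$grid), max(x$grid), length(x$grid), x$n_dropped))
  invisible(x)
}

#' @export
as.data.frame.bootstrap_band <- function(x, ...) {
  data.frame(age = x$grid, statistic = x$statistic, estimate = x$estimate,
             lower = x$lower, upper = x$upper)
}

#' Coerce a bootstrap band to a tibble
#' @param band A `bootstrap_band`.
#' @return A tibble with columns `age`, `statistic`, `estimate`,
#'   `lower`, `upper`.
#' @export
band_tibble <- function(band) tibble::as_tibble(as.data.frame(band))

#' Age ranges where a band excludes a reference value
#'
#' Scans the band along its grid and returns the maximal runs of
#' consecutive grid ages where `lower > reference` (first direction
#' label) or `upper < reference` (second label).  Single-grid-point runs
#' are reported; for the derivative statistic the direction encodes
#' significant increase vs. decrease of the cell counts.
#'
#' @param band A `bootstrap_band`.
#' @param reference Reference value the band must exclude (default 0).
#' @param labels Length-2 direction labels (above, below).  Defaults
#'   depend on the band's statistic: `increase`/`decrease` for curve and
#'   derivative bands, `group1-higher`/`group2-higher` for difference
#'   bands.
#' @return A tibble with columns `statistic`, `start_age`, `end_age`,
#'   `direction`; zero rows when the band always overlaps the
#'   reference.  Regions are disjoint and maximal.
#' @export
extract_significant_regions <- function(band, reference = 0, labels = NULL) {
  stopifnot(inherits(band, "bootstrap_band"))
  if (is.null(labels)) {
    labels <- if (grepl("difference", band$statistic)) {
      c("group1-higher", "group2-higher")
    } else {
      c("increase", "decrease")
    }
  }
  state <- ifelse(band$lower > reference, 1L,
                  ifelse(band$upper < reference, -1L, 0L))
  runs <- rle(state)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- runs$values != 0L
  tibble::tibble(
    statistic = rep(band$statistic, sum(keep)),
    start_age = band$grid[starts[keep]],
    end_age = band$grid[ends[keep]],
    direction = as.character(ifelse(runs$values[keep] > 0L, labels[1L],
                                    labels[2L]))
  )
}

#' Jaccard overlap between two region sets
#'
#' Regions are compared as sets of grid ages (each region `[start, end]`
#' contributes the ages `seq(start, end, by = step)`), so a
#' single-grid-point region has size one rather than length zero.
#'
#' @param regions,truth Data frames with `start_age` and `end_age`
#'   columns (only rows of one direction should be passed when the
#'   direction matters).
#' @param step Grid step in years (default 1).
#' @return Jaccard index in \[0, 1\]; 1 when both are empty.
#' @export
region_jaccard <- function(regions, truth, step = 1) {
  ages <- function(r) {
    if (!NROW(r)) return(numeric())
    unique(unlist(Map(function(a, b) seq(a, b, by = step),
                      r$start_age, r$end_age)))
  }
  a <- ages(regions); b <- ages(truth)
  if (!length(a) && !length(b)) return(1)
  length(intersect(a, b)) / length(union(a, b))
}
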