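# Sex-stratified fits and between-group contrasts.
#
# Two contrast statistics are computed on a shared grid restricted to
# the age interval covered by BOTH groups:
#   * level difference:       E_g1(Y|Age) - E_g2(Y|Age)
#   * derivative difference:  f'_g1(Age)  - f'_g2(Age)
# The derivative difference is the age-by-group interaction on the
# rate-of-change scale: a nonzero value at an age means the two groups'
# cell counts are changing at different rates there.
#
# Bootstrap resampling is stratified: each replicate resamples
# participants with replacement WITHIN each group, preserving group
# sizes.  All per-group and difference bands for one call come from the
# same replicate set, so the three interaction-figure panels (two
# group-specific derivative bands plus the difference band) are mutually
# consistent.  Per-replicate seeds are keyed by the group LABEL (in
# sorted label order), so swapping the order of `groups` negates the
# difference statistics exactly.

#' Sex-stratified smoothing-spline fits on a shared grid
#'
#' @param cohort A `cohort_table`.
#' @param population Population name.
#' @param spar Smoothing parameter applied to both groups.
#' @param groups The two group labels (default the cohort's sex labels).
#' @param grid_step Grid step in years (default 1).
#' @return A list with `fits` (named per group), `grid` (1-year steps
#'   over the intersection of the group age spans) and `data` (the
#'   per-group (age, count) tibbles).
#' @export
fit_by_group <- function(cohort, population, spar = 0.8, groups = NULL,
                         grid_step = 1) {
  stopifnot(inherits(cohort, "cohort_table"))
  if (is.null(groups)) groups <- attr(cohort, "sex_labels")
  stopifnot(length(groups) == 2L)
  data <- lapply(groups, function(g) cohort_subset(cohort, population, sex = g))
  names(data) <- groups
  fits <- vector("list", 2L); names(fits) <- groups
  for (g in groups) {
    nd <- if (nrow(data[[g]])) n_distinct_ages(data[[g]]$age) else 0L
    if (nd < 4L) {
      stop_immunospline("insufficient_data", sprintf(
        "group '%s' has %d distinct ages for population '%s' (need >= 4)",
        g, nd, population))
    }
    fits[[g]] <- fit_smoothing_spline(data[[g]]$age, data[[g]]$count,
                                      spar = spar)
  }
  lo <- max(vapply(data, function(d) min(d$age), numeric(1)))
  hi <- min(vapply(data, function(d) max(d$age), numeric(1)))
  if (lo > hi) {
    stop_immunospline("insufficient_data",
                      "the two groups' age spans do not overlap")
  }
  grid <- seq(ceiling(lo / grid_step) * grid_step,
              floor(hi / grid_step) * grid_step, by = grid_step)
  list(fits = fits, grid = grid, data = data)
}

#' Group contrast with stratified bootstrap bands
#'
#' Fits both groups, then builds -- from a single stratified replicate
#' set -- pointwise bands for each group's curve and derivative and for
#' the two contrast statistics (level difference and derivative
#' difference, both `groups[1] - groups[2]`), together with their
#' significant regions.
#'
#' @inheritParams fit_by_group
#' @inheritParams bootstrap_band
#' @param groups The two group labels, in (group1, group2) order; the
#'   difference statistics are group1 minus group2.
#' @return A `group_contrast`: list with `population`, `groups`, `grid`,
#'   `fits`, `bands` (named list: `curve_<g>`, `derivative_<g>`,
#'   `curve-difference`, `derivative-difference`) and `regions` (one
#'   tibble with a `group` column).
#' @export
sex_contrast <- function(cohort, population, groups = NULL, spar = 0.8,
                         grid_step = 1, level = 0.95, n_boot = 2000,
                         seed = 1, interval_type = c("percentile", "basic"),
                         workers = 1L, keep_replicates = FALSE) {
  interval_type <- match.arg(interval_type)
  if (is.null(groups)) groups <- attr(cohort, "sex_labels")
  fg <- fit_by_group(cohort, population, spar = spar, groups = groups,
                     grid_step = grid_step)
  grid <- fg$grid
  G <- length(grid)
  est <- lapply(fg$fits, function(f) list(
    curve = evaluate_curve(f, grid, extrapolate = TRUE),
    derivative = evaluate_first_derivative(f, grid, extrapolate = TRUE)))

  # per-replicate, per-group seeds keyed by sorted group label
  smat <- replicate_seeds(seed, n_boot, streams = 2L)
  colnames(smat) <- sort(groups)
  one <- function(b) {
    out <- vector("list", 2L); names(out) <- groups
    for (g in groups) {
      d <- fg$data[[g]]
      set.seed(smat[b, g])
      n <- nrow(d)
      val <- NULL
      for (try in 1:100) {
        idx <- sample.int(n, replace = TRUE)
        if (n_distinct_ages(d$age[idx]) >= 4L) {
          f <- fit_smoothing_spline(d$age[idx], d$count[idx], spar = spar,
                                    compute_edf = FALSE)
          val <- evaluate_curve_deriv(f, grid)
          break
        }
      }
      out[[g]] <- val %||% rep(NA_real_, 2L * G)
    }
    c(out[[groups[1L]]], out[[groups[2L]]])
  }
  res <- do.call(rbind, run_replicates(one, n_boot, workers))
  reps <- list()
  reps[[paste0("curve_", groups[1L])]] <- res[, seq_len(G), drop = FALSE]
  reps[[paste0("derivative_", groups[1L])]] <- res[, G + seq_len(G), drop = FALSE]
  reps[[paste0("curve_", groups[2L])]] <- res[, 2L * G + seq_len(G), drop = FALSE]
  reps[[paste0("derivative_", groups[2L])]] <- res[, 3L * G + seq_len(G), drop = FALSE]
  reps[["curve-difference"]] <-
    reps[[paste0("curve_", groups[1L])]] - reps[[paste0("curve_", groups[2L])]]
  reps[["derivative-difference"]] <-
    reps[[paste0("derivative_", groups[1L])]] -
    reps[[paste0("derivative_", groups[2L])]]

  ests <- list()
  for (g in groups) {
    ests[[paste0("curve_", g)]] <- est[[g]]$curve
    ests[[paste0("derivative_", g)]] <- est[[g]]$derivative
  }
  ests[["curve-difference"]] <- est[[groups[1L]]]$curve - est[[groups[2L]]]$curve
  ests[["derivative-difference"]] <-
    est[[groups[1L]]]$derivative - est[[groups[2L]]]$derivative

  stat_of <- function(nm) {
    if (nm %in% c("curve-difference", "derivative-difference")) nm
    else sub("_.*$", "", nm)
  }
  bands <- lapply(names(reps), function(nm) {
    band_from_replicates(grid, ests[[nm]], reps[[nm]], level = level,
                         statistic = stat_of(nm), seed = seed,
                         interval_type = interval_type,
                         keep_replicates = keep_replicates)
  })
  names(bands) <- names(reps)

  diff_labels <- paste0(groups, "-higher")
  regions <- dplyr::bind_rows(lapply(names(bands), function(nm) {
    grp <- if (grepl("difference", nm)) "contrast" else sub("^[^_]*_", "", nm)
    labs <- if (grepl("difference", nm)) diff_labels else NULL
    r <- extract_significant_regions(bands[[nm]], labels = labs)
    if (nrow(r)) r$group <- grp else r$group <- character()
    r
  }))

  structure(list(population = population, groups = groups, grid = grid,
                 fits = fg$fits, bands = bands, regions = regions,
                 level = level, n_boot = n_boot, seed = seed, spar = spar),
            class = "group_contrast")
}

#' @export
print.group_contrast <- function(x, ...) {
  cat(sprintf("Group contrast for '%s': %s - %s\n", x$population,
              x$groups[1], x$groups[2]))
  cat(sprintf("  grid %g-%g, %d bootstrap replicates, %.0f%% bands\n",
              min(x$grid), max(x$grid), x$n_boot, 100 * x$level))
  sig <- x$regions[x$regions$group == "contrast", ]
  if (nrow(sig)) {
    cat("  significant contrast regions:\n")
    for (i in seq_len(nrow(sig))) {
      cat(sprintf("    %s %g-%g: %s\n", sig$statistic[i], sig$start_age[i],
                  sig$end_age[i], sig$direction[i]))
    }
  } else cat("  no significant contrast regions\n")
  invisible(x)
}
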