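# Orchestration: run the full analysis set over a cohort (read from disk
# or simulated), write band/region tables, the sex-comparison matrix and
# publication-style figures, with a structured log.
#
# Every output table carries a header comment with the resolved config
# hash and seed.  All analyses are deterministic given the seed,
# regardless of worker count, because every bootstrap replicate owns a
# pre-assigned seed.

#' Pipeline configuration
#'
#' @param input Path to a cohort TSV/CSV, or `NULL` to simulate.
#' @param scenario A [cohort_config()], or the name of a built-in
#'   scenario (`"null"`, `"logistic_decline"`, `"decline"`,
#'   `"sex_shift"`, `"interaction"`, `"panel"`); used when `input` is
#'   `NULL`.
#' @param populations Populations to analyze; default all.
#' @param analyses Subset of `c("overall", "within-sex",
#'   "sex-comparison", "interaction")`.
#' @param spar Smoothing parameter (default 0.8).
#' @param level Band coverage (default 0.95).
#' @param n_boot Bootstrap replicates (default 2000).
#' @param grid_step Grid step in years (default 1).
#' @param seed Master seed (default 1).
#' @param out_dir Output directory.
#' @param interval_type `"percentile"` or `"basic"` intervals.
#' @param workers Forked workers for replicate loops.
#' @param make_plots Write figures? (Analyses never depend on them;
#'   plotting failures are logged, not fatal.)
#' @param col_map Column mapping passed to [read_cohort()].
#' @return A `pipeline_config`.
#' @export
pipeline_config <- function(input = NULL, scenario = NULL, populations = NULL,
                            analyses = c("overall", "within-sex",
                                         "sex-comparison", "interaction"),
                            spar = 0.8, level = 0.95, n_boot = 2000,
                            grid_step = 1, seed = 1, out_dir = "results",
                            interval_type = "percentile", workers = 1L,
                            make_plots = TRUE, col_map = NULL) {
  analyses <- match.arg(analyses, several.ok = TRUE)
  stopifnot(!is.null(input) || !is.null(scenario))
  structure(list(input = input, scenario = scenario,
                 populations = populations, analyses = analyses, spar = spar,
                 level = level, n_boot = n_boot, grid_step = grid_step,
                 seed = seed, out_dir = out_dir,
                 interval_type = interval_type, workers = workers,
                 make_plots = make_plots, col_map = col_map),
            class = "pipeline_config")
}

resolve_scenario <- function(scenario, seed) {
  if (inherits(scenario, "cohort_config")) return(scenario)
  switch(scenario,
    "null" = scenario_null(seed = seed),
    "logistic_decline" = scenario_logistic_decline(seed = seed),
    "decline" = scenario_decline(seed = seed),
    "sex_shift" = scenario_sex_shift(seed = seed),
    "interaction" = scenario_interaction(seed = seed),
    "panel" = scenario_panel(seed = seed),
    stop_immunospline("config", paste0("unknown scenario: ", scenario)))
}

#' Run the full analysis pipeline
#'
#' Per population: the overall curve and derivative bands with their
#' significant regions ("overall"); sex-specific derivative bands
#' ("within-sex"); the female-minus-male level-difference band
#' ("sex-comparison"); and the derivative-difference (age-by-sex
#' interaction) band ("interaction").  The three sex analyses share one
#' stratified replicate set per population.  Writes `bands.tsv`,
#' `regions.tsv`, `regions.json`, `comparison_matrix.tsv`, the resolved
#' config (`config.json`), a log, and figures.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the per-population results, the band
#'   and region tibbles, and output paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  t_start <- proc.time()[["elapsed"]]
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$out_dir, "pipeline.log")
  logf <- function(fmt, ...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                    sprintf(fmt, ...))
    message(line)
    cat(line, "\n", file = log_path, append = TRUE)
  }

  truth <- NULL
  if (!is.null(config$input)) {
    cohort <- read_cohort(config$input, col_map = config$col_map)
    logf("read cohort: %s (%d participants)", config$input, nrow(cohort))
  } else {
    sc <- resolve_scenario(config$scenario, config$seed)
    sim <- simulate_cohort(sc)
    cohort <- sim$cohort
    truth <- sim$truth
    logf("simulated cohort: %d participants, %d populations, seed %d",
         nrow(cohort), length(attr(cohort, "populations")), sc$seed)
  }
  pops <- config$populations %||% attr(cohort, "populations")
  sexes <- attr(cohort, "sex_labels")
  resolved <- config
  resolved$populations <- pops
  # the hash covers the scientific configuration only, never execution
  # details (workers, plotting, paths), so identical analyses hash alike
  sci <- resolved[c("analyses", "spar", "level", "n_boot", "grid_step",
                    "seed", "interval_type", "populations")]
  sci$input <- resolved$input
  sci$scenario <- if (inherits(resolved$scenario, "cohort_config")) {
    sc0 <- resolved$scenario
    list(populations = names(sc0$populations), n_female = sc0$n_female,
         n_male = sc0$n_male, age_range = sc0$age_range,
         age_distribution = sc0$age_distribution, seed = sc0$seed)
  } else resolved$scenario
  cfg_hash <- rlang::hash(as.character(jsonlite::toJSON(sci,
    auto_unbox = TRUE, digits = NA)))
  cfg_json <- jsonlite::toJSON(
    c(sci, resolved[c("workers", "make_plots", "out_dir")],
      list(config_hash = cfg_hash)),
    auto_unbox = TRUE, digits = NA)
  writeLines(as.character(cfg_json), file.path(config$out_dir, "config.json"))

  need_sex <- any(c("within-sex", "sex-comparison", "interaction") %in%
                    config$analyses)
  band_rows <- list(); region_rows <- list(); results <- list()
  failed <- character()
  for (pop in pops) {
    t_pop <- proc.time()[["elapsed"]]
    res <- tryCatch({
      out <- list()
      if ("overall" %in% config$analyses) {
        pairs <- cohort_subset(cohort, pop)
        core <- trajectory_replicates(pairs, spar = config$spar,
                                      grid = default_grid(pairs$age,
                                                          config$grid_step),
                                      n_boot = config$n_boot,
                                      seed = config$seed,
                                      workers = config$workers)
        for (st in c("curve", "derivative")) {
          b <- band_from_replicates(core$grid, core$estimates[[st]],
                                    core$replicates[[st]],
                                    level = config$level, statistic = st,
                                    seed = config$seed,
                                    interval_type = config$interval_type,
                                    n_redrawn = core$n_redrawn,
                                    n_dropped = core$n_dropped)
          out$overall[[st]] <- b
          band_rows[[length(band_rows) + 1L]] <- dplyr::mutate(
            band_tibble(b), population = pop, group = "all", .before = 1)
          r <- extract_significant_regions(b)
          if (nrow(r)) {
            region_rows[[length(region_rows) + 1L]] <- dplyr::mutate(
              r, population = pop, group = "all", .before = 1)
          }
        }
        out$data <- pairs
        logf("population %s: overall bands done (dropped %d)", pop,
             core$n_dropped)
      }
      if (need_sex) {
        ctr <- sex_contrast(cohort, pop, groups = sexes, spar = config$spar,
                            grid_step = config$grid_step,
                            level = config$level, n_boot = config$n_boot,
                            seed = config$seed,
                            interval_type = config$interval_type,
                            workers = config$workers)
        out$contrast <- ctr
        keep_stats <- c(
          if ("within-sex" %in% config$analyses)
            c(paste0("curve_", sexes), paste0("derivative_", sexes)),
          if ("sex-comparison" %in% config$analyses) "curve-difference",
          if ("interaction" %in% config$analyses) "derivative-difference")
        for (nm in intersect(names(ctr$bands), keep_stats)) {
          b <- ctr$bands[[nm]]
          grp <- if (grepl("difference", nm)) "contrast" else sub("^[^_]*_", "", nm)
          band_rows[[length(band_rows) + 1L]] <- dplyr::mutate(
            band_tibble(b), population = pop, group = grp, .before = 1)
        }
        keep_groups <- c(if ("within-sex" %in% config$analyses) sexes,
                         "contrast")
        reg <- ctr$regions
        reg <- reg[reg$group %in% keep_groups, ]
        if (!"sex-comparison" %in% config$analyses) {
          reg <- reg[reg$statistic != "curve-difference", ]
        }
        if (!"interaction" %in% config$analyses) {
          reg <- reg[reg$statistic != "derivative-difference", ]
        }
        if (!"within-sex" %in% config$analyses) {
          reg <- reg[reg$group == "contrast", ]
        }
        if (nrow(reg)) {
          region_rows[[length(region_rows) + 1L]] <- dplyr::mutate(
            reg, population = pop, .before = 1)
        }
        logf("population %s: sex contrast done", pop)
      }
      out
    }, error = function(e) {
      logf("population %s FAILED: %s", pop, conditionMessage(e))
      failed <<- c(failed, pop)
      NULL
    })
    results[[pop]] <- res
    logf("population %s finished in %.1f s", pop,
         proc.time()[["elapsed"]] - t_pop)
  }

  bands <- if (length(band_rows)) dplyr::bind_rows(band_rows) else
    tibble::tibble(population = character(), group = character(),
                   age = numeric(), statistic = character(),
                   estimate = numeric(), lower = numeric(), upper = numeric())
  bands <- bands[, c("population", "group", "statistic", "age", "estimate",
                     "lower", "upper")]
  regions <- if (length(region_rows)) dplyr::bind_rows(region_rows) else
    empty_regions()
  regions <- regions[, c("population", "group", "statistic", "start_age",
                         "end_age", "direction")]

  hdr <- sprintf("# immunospline config_hash=%s seed=%d", cfg_hash, config$seed)
  paths <- list(
    bands = write_band_table(bands, file.path(config$out_dir, "bands.tsv"), hdr),
    regions = write_region_table(regions,
                                 file.path(config$out_dir, "regions.tsv"), hdr),
    regions_json = file.path(config$out_dir, "regions.json"),
    config = file.path(config$out_dir, "config.json"))
  jsonlite::write_json(list(config_hash = cfg_hash, seed = config$seed,
                            regions = regions),
                       paths$regions_json, auto_unbox = TRUE, digits = NA)

  if ("sex-comparison" %in% config$analyses) {
    paths$matrix <- render_comparison_matrix(
      regions, pops, grid = sort(unique(bands$age[bands$group == "contrast"])),
      sexes = sexes, out_dir = config$out_dir, header = hdr,
      make_plot = config$make_plots)
  }
  if (config$make_plots) {
    render_figures(results, config, sexes, logf)
  }
  if (length(failed)) {
    logf("%d population(s) failed: %s", length(failed),
         paste(failed, collapse = ", "))
  }
  logf("pipeline finished in %.1f s",
       proc.time()[["elapsed"]] - t_start)
  out <- invisible(list(results = results, bands = bands, regions = regions,
                        truth = truth, paths = paths, failed = failed,
                        config_hash = cfg_hash))
  if (length(failed) == length(pops)) {
    stop_immunospline("pipeline", "every population failed; see pipeline.log")
  }
  out
}

empty_regions <- function() {
  tibble::tibble(population = character(), group = character(),
                 statistic = character(), start_age = numeric(),
                 end_age = numeric(), direction = character())
}

#' Write / read band and region tables
#'
#' Stable column order, ages on the grid, a `# immunospline` header
#' comment carrying the config hash and seed.  The readers skip comment
#' lines, so tables round-trip unchanged.
#'
#' @param bands,regions Tibbles as produced by [run_pipeline()].
#' @param path Output path.
#' @param header Optional comment line (without trailing newline).
#' @return `path` (writers, invisibly) or a tibble (readers).
#' @name band_tables
NULL

#' @rdname band_tables
#' @export
write_band_table <- function(bands, path, header = NULL) {
  if (!is.null(header)) writeLines(header, path)
  readr::write_tsv(bands, path, append = !is.null(header), col_names = TRUE,
                   progress = FALSE)
  invisible(path)
}

#' @rdname band_tables
#' @export
write_region_table <- function(regions, path, header = NULL) {
  if (!is.null(header)) writeLines(header, path)
  readr::write_tsv(regions, path, append = !is.null(header), col_names = TRUE,
                   progress = FALSE)
  invisible(path)
}

#' @rdname band_tables
#' @export
read_region_table <- function(path) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                  progress = FALSE)
}

#' @rdname band_tables
#' @export
read_band_table <- function(path) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                  progress = FALSE)
}

#' Sex-comparison matrix (population x age)
#'
#' Three-valued cells: `<group1>-higher`, `<group2>-higher`, or `ns`,
#' from the level-difference significant regions — the heatmap-style
#' summary of where women's and men's mean counts differ.  Written as a
#' TSV matrix and (optionally) a tile plot.
#'
#' @param regions Region tibble from [run_pipeline()].
#' @param populations Row order.
#' @param grid Column ages.
#' @param sexes The two group labels.
#' @param out_dir Output directory.
#' @param header Comment line for the TSV.
#' @param make_plot Also render a PNG tile plot?
#' @return Path to the TSV, invisibly.
#' @export
render_comparison_matrix <- function(regions, populations, grid, sexes,
                                     out_dir, header = NULL,
                                     make_plot = TRUE) {
  if (!length(grid)) return(invisible(NULL))
  lev <- regions[regions$statistic == "curve-difference", ]
  m <- matrix("ns", nrow = length(populations), ncol = length(grid),
              dimnames = list(populations, as.character(grid)))
  for (i in seq_len(nrow(lev))) {
    ages <- as.character(seq(lev$start_age[i], lev$end_age[i]))
    ages <- intersect(ages, colnames(m))
    m[lev$population[i], ages] <- lev$direction[i]
  }
  tab <- tibble::as_tibble(cbind(population = populations,
                                 as.data.frame(m, check.names = FALSE)))
  path <- file.path(out_dir, "comparison_matrix.tsv")
  if (!is.null(header)) writeLines(header, path)
  readr::write_tsv(tab, path, append = !is.null(header), col_names = TRUE,
                   progress = FALSE)
  if (make_plot) {
    long <- tidyr::pivot_longer(tab, -"population", names_to = "age",
                                values_to = "difference")
    long$age <- as.numeric(long$age)
    long$population <- factor(long$population, levels = rev(populations))
    pal <- stats::setNames(c("#1b9e77", "#7570b3", "grey92"),
                           c(paste0(sexes, "-higher"), "ns"))
    p <- ggplot2::ggplot(long, ggplot2::aes(.data$age, .data$population,
                                            fill = .data$difference)) +
      ggplot2::geom_tile() +
      ggplot2::scale_fill_manual(values = pal, name = NULL) +
      ggplot2::labs(x = "Age (years)", y = NULL,
                    title = "Significant sex differences in mean count") +
      ggplot2::theme_minimal(base_size = 9)
    try_plot(p, file.path(out_dir, "comparison_matrix.png"),
             width = 8, height = max(2, 0.25 * length(populations) + 1))
  }
  invisible(path)
}

# Curve-over-scatter plus derivative panel for each population, and the
# three-panel interaction figure where a contrast was run.
render_figures <- function(results, config, sexes, logf) {
  fig_dir <- file.path(config$out_dir, "figures")
  dir.create(fig_dir, showWarnings = FALSE)
  for (pop in names(results)) {
    res <- results[[pop]]
    if (is.null(res)) next
    if (!is.null(res$overall)) {
      p <- plot_trajectory(res$overall$curve, res$overall$derivative,
                           data = res$data, population = pop)
      try_plot(p, file.path(fig_dir, paste0(pop, "_trajectory.png")),
               width = 6, height = 6, logf = logf)
    }
    if (!is.null(res$contrast)) {
      p <- plot_interaction(res$contrast)
      try_plot(p, file.path(fig_dir, paste0(pop, "_interaction.png")),
               width = 10, height = 3.5, logf = logf)
    }
  }
}

try_plot <- function(plot, path, width, height, logf = NULL) {
  ok <- tryCatch({
    ggplot2::ggsave(path, plot, width = width, height = height, dpi = 120)
    TRUE
  }, error = function(e) {
    msg <- sprintf("figure %s not written: %s", basename(path),
                   conditionMessage(e))
    if (!is.null(logf)) logf("%s", msg) else message(msg)
    FALSE
  })
  invisible(ok)
}

#' Two-panel trajectory figure
#'
#' Upper panel: observed counts with the fitted curve and its band.
#' Lower panel: the first-derivative band; ages where it excludes zero
#' are the significant changes.
#'
#' @param curve_band,derivative_band `bootstrap_band`s on a shared grid.
#' @param data Optional tibble with `age`, `count` for the scatter.
#' @param population Title label.
#' @return A patchwork object.
#' @export
plot_trajectory <- function(curve_band, derivative_band, data = NULL,
                            population = "") {
  cb <- band_tibble(curve_band)
  db <- band_tibble(derivative_band)
  p1 <- ggplot2::ggplot(cb, ggplot2::aes(.data$age, .data$estimate))
  if (!is.null(data)) {
    p1 <- p1 + ggplot2::geom_point(data = data,
                                   ggplot2::aes(.data$age, .data$count),
                                   alpha = 0.35, size = 0.8, colour = "grey40")
  }
  p1 <- p1 +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
                         fill = "#d7301f", alpha = 0.25) +
    ggplot2::geom_line(colour = "#d7301f") +
    ggplot2::labs(y = "Absolute count (cells/µL)", x = NULL,
                  title = population) +
    ggplot2::theme_minimal(base_size = 10)
  p2 <- ggplot2::ggplot(db, ggplot2::aes(.data$age, .data$estimate)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
                         fill = "grey20", alpha = 0.25) +
    ggplot2::geom_line(colour = "grey20") +
    ggplot2::labs(x = "Age (years)", y = "Rate of change (cells/µL/year)") +
    ggplot2::theme_minimal(base_size = 10)
  patchwork::wrap_plots(p1, p2, ncol = 1, heights = c(2, 1))
}

#' Three-panel interaction figure
#'
#' Sex-specific first-derivative bands (left, middle) and the
#' derivative-difference band (right) whose zero-exclusion ranges are
#' the significant age-by-sex interactions.
#'
#' @param contrast A `group_contrast` from [sex_contrast()].
#' @return A patchwork object.
#' @export
plot_interaction <- function(contrast) {
  g <- contrast$groups
  panel <- function(band, title, colour) {
    ggplot2::ggplot(band_tibble(band), ggplot2::aes(.data$age, .data$estimate)) +
      ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
      ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower,
                                        ymax = .data$upper),
                           fill = colour, alpha = 0.25) +
      ggplot2::geom_line(colour = colour) +
      ggplot2::labs(x = "Age (years)",
                    y = "Rate of change (cells/µL/year)",
                    title = title) +
      ggplot2::theme_minimal(base_size = 10)
  }
  patchwork::wrap_plots(
    panel(contrast$bands[[paste0("derivative_", g[1])]], g[1], "#1b9e77"),
    panel(contrast$bands[[paste0("derivative_", g[2])]], g[2], "#7570b3"),
    panel(contrast$bands[["derivative-difference"]],
          sprintf("interaction (%s - %s)", g[1], g[2]), "#d95f02"),
    ncol = 3)
}
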