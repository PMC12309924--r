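# Per-participant cohort tables: reading, validation, reshaping.
#
# A cohort table is a tibble with one row per participant: an opaque
# participant id, age in years, sex (two labels, "female"/"male" by
# default), and one numeric column of absolute counts (cells/uL) per
# leukocyte population.  Missing counts are allowed per participant and
# population; that participant is simply excluded from that population's
# fit.

#' Construct a cohort table
#'
#' @param data A data frame with columns `participant_id`, `age`, `sex`
#'   and one numeric column per population.
#' @param populations Character vector naming the population columns.
#'   Defaults to every column other than the three mandatory ones.
#' @param sex_labels The two admissible sex labels, in (group1, group2)
#'   order.
#' @param age_range Admissible age range in years.
#' @return A `cohort_table` (a tibble with a `populations` attribute).
#' @export
cohort_table <- function(data, populations = NULL,
                         sex_labels = c("female", "male"),
                         age_range = c(18, 100)) {
  data <- tibble::as_tibble(data)
  mandatory <- c("participant_id", "age", "sex")
  missing_cols <- setdiff(mandatory, names(data))
  if (length(missing_cols)) {
    stop_immunospline("format", paste0("missing mandatory column(s): ",
                                       paste(missing_cols, collapse = ", ")))
  }
  if (is.null(populations)) populations <- setdiff(names(data), mandatory)
  if (!length(populations)) {
    stop_immunospline("format", "no population columns found")
  }
  if (anyDuplicated(populations)) {
    stop_immunospline("format", "population names must be unique")
  }
  absent <- setdiff(populations, names(data))
  if (length(absent)) {
    stop_immunospline("format", paste0("population column(s) not in data: ",
                                       paste(absent, collapse = ", ")))
  }
  data$participant_id <- as.character(data$participant_id)
  data$sex <- as.character(data$sex)

  report <- validate_cohort_rows(data, populations, sex_labels, age_range)
  if (nrow(report)) {
    msg <- paste0("cohort validation failed for ", length(unique(report$row)),
                  " row(s):\n",
                  paste(utils::head(sprintf("  row %d [%s]: %s", report$row,
                                            report$participant_id,
                                            report$problem), 10L),
                        collapse = "\n"))
    cond <- structure(
      class = c("immunospline_validation", "immunospline_integrity",
                "error", "condition"),
      list(message = msg, call = sys.call(-1), report = report))
    stop(cond)
  }
  data <- data[, c(mandatory, populations)]
  structure(data, populations = populations, sex_labels = sex_labels,
            class = c("cohort_table", class(data)))
}

# Row-level validation report: one row per (row, problem).
validate_cohort_rows <- function(data, populations, sex_labels, age_range) {
  probs <- list()
  note <- function(rows, what) {
    if (length(rows)) {
      probs[[length(probs) + 1L]] <<- tibble::tibble(
        row = rows, participant_id = data$participant_id[rows], problem = what)
    }
  }
  note(which(is.na(data$participant_id) | data$participant_id == ""),
       "empty participant_id")
  dup <- data$participant_id[duplicated(data$participant_id)]
  note(which(data$participant_id %in% dup), "duplicate participant_id")
  age <- suppressWarnings(as.numeric(data$age))
  note(which(is.na(age)), "unparseable or missing age")
  note(which(!is.na(age) & (age < age_range[1] | age > age_range[2])),
       sprintf("age outside admissible range [%g, %g]", age_range[1], age_range[2]))
  note(which(!(data$sex %in% sex_labels)),
       sprintf("sex label not in {%s}", paste(sex_labels, collapse = ", ")))
  for (p in populations) {
    v <- data[[p]]
    if (!is.numeric(v)) {
      vnum <- suppressWarnings(as.numeric(v))
      note(which(is.na(vnum) & !is.na(v) & v != ""),
           sprintf("unparseable count for '%s'", p))
      v <- vnum
    }
    note(which(!is.na(v) & (v < 0 | is.infinite(v))),
         sprintf("negative or non-finite count for '%s'", p))
  }
  if (!length(probs)) {
    return(tibble::tibble(row = integer(), participant_id = character(),
                          problem = character()))
  }
  dplyr::arrange(dplyr::bind_rows(probs), .data$row)
}

#' Validate a cohort data frame without constructing a table
#'
#' @inheritParams cohort_table
#' @return A tibble with one row per problem (`row`, `participant_id`,
#'   `problem`); zero rows when the data are valid.
#' @export
validate_cohort <- function(data, populations = NULL,
                            sex_labels = c("female", "male"),
                            age_range = c(18, 100)) {
  data <- tibble::as_tibble(data)
  if (is.null(populations)) {
    populations <- setdiff(names(data), c("participant_id", "age", "sex"))
  }
  validate_cohort_rows(data, populations, sex_labels, age_range)
}

#' @export
print.cohort_table <- function(x, ...) {
  pops <- attr(x, "populations")
  cat(sprintf("Cohort table: %d participants, %d populations\n", nrow(x),
              length(pops)))
  tab <- table(factor(x$sex, levels = attr(x, "sex_labels")))
  cat(sprintf("  sex: %s\n",
              paste(sprintf("%s = %d", names(tab), tab), collapse = ", ")))
  cat(sprintf("  age: %.0f-%.0f years\n", min(x$age), max(x$age)))
  NextMethod()
}

#' Read a cohort table from delimited text
#'
#' Reads a wide per-participant table (one row per participant, one
#' column per population), renames columns according to `col_map`, and
#' validates.  Rows failing validation are rejected with a per-row
#' report attached to the error condition (field `report`), never
#' silently dropped.
#'
#' @param path Path to a CSV or TSV file (delimiter inferred from the
#'   extension unless `delim` is given).
#' @param delim Field delimiter; `NULL` to infer.
#' @param col_map Named list/character mapping the mandatory fields to
#'   file column names, e.g. `list(participant_id = "ID", age = "Age",
#'   sex = "Sex")`.  May also be the path to a YAML or JSON file holding
#'   such a mapping (optionally with `populations`, `sex_labels`,
#'   `age_range` entries).
#' @param populations File columns holding counts; default all unmapped
#'   columns.
#' @inheritParams cohort_table
#' @return A `cohort_table`.
#' @export
read_cohort <- function(path, delim = NULL, col_map = NULL, populations = NULL,
                        sex_labels = c("female", "male"),
                        age_range = c(18, 100)) {
  if (!file.exists(path)) {
    stop_immunospline("format", paste0("file not found: ", path))
  }
  if (is.character(col_map) && length(col_map) == 1L && file.exists(col_map)) {
    cfg <- read_config_file(col_map)
    col_map <- cfg$col_map
    populations <- populations %||% cfg$populations
    sex_labels <- cfg$sex_labels %||% sex_labels
    if (!is.null(cfg$age_range)) age_range <- unlist(cfg$age_range)
  }
  if (is.null(delim)) {
    delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  }
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE, comment = "#")
  if (!is.null(col_map)) {
    col_map <- unlist(col_map)
    absent <- setdiff(unname(col_map), names(raw))
    if (length(absent)) {
      stop_immunospline("format", paste0("mapped column(s) absent from file: ",
                                         paste(absent, collapse = ", ")))
    }
    names(raw)[match(unname(col_map), names(raw))] <- names(col_map)
  }
  cohort_table(raw, populations = populations, sex_labels = sex_labels,
               age_range = age_range)
}

read_config_file <- function(path) {
  if (grepl("\\.(ya?ml)$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop_immunospline("format", "YAML config requires the 'yaml' package")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}

#' Write a cohort table as TSV
#'
#' @param cohort A `cohort_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "cohort_table"))
  readr::write_tsv(as.data.frame(cohort), path, progress = FALSE)
  invisible(path)
}

#' Convert population frequencies to absolute counts
#'
#' Absolute counts (cells/uL of blood) are the product of each
#' population's frequency among intact leukocytes and the participant's
#' total leukocyte concentration.
#'
#' @param frequencies Numeric vector, matrix or data frame of fractions
#'   in \[0, 1\] (rows = participants when matrix-like).
#' @param total_leukocytes Total leukocyte concentration (cells/uL);
#'   scalar, or one value per row of `frequencies`.
#' @return Absolute counts with the same shape and names as
#'   `frequencies`.
#' @export
#' @examples
#' frequencies_to_absolute_counts(c(naive_CD8_T = 0.10), 6000)
frequencies_to_absolute_counts <- function(frequencies, total_leukocytes) {
  fr <- if (is.data.frame(frequencies)) as.matrix(frequencies) else frequencies
  if (any(!is.finite(fr)) || any(fr < 0) || any(fr > 1)) {
    stop_immunospline("domain", "frequencies must lie in [0, 1]")
  }
  if (any(!is.finite(total_leukocytes)) || any(total_leukocytes < 0)) {
    stop_immunospline("domain", "total_leukocytes must be nonnegative")
  }
  out <- fr * total_leukocytes
  if (is.data.frame(frequencies)) out <- tibble::as_tibble(as.data.frame(out))
  out
}

#' Extract the (age, count) pairs for one population
#'
#' @param cohort A `cohort_table`.
#' @param population Population name.
#' @param sex Optional sex label to filter on.
#' @return A tibble with columns `age` and `count`, rows with missing
#'   counts dropped, sorted by age ascending.
#' @export
cohort_subset <- function(cohort, population, sex = NULL) {
  stopifnot(inherits(cohort, "cohort_table"))
  pops <- attr(cohort, "populations")
  if (!population %in% pops) {
    stop_immunospline("lookup", paste0("unknown population: ", population))
  }
  if (!is.null(sex)) {
    labs <- attr(cohort, "sex_labels")
    if (!sex %in% labs) {
      stop_immunospline("lookup", paste0("unknown sex label: ", sex))
    }
  }
  d <- tibble::tibble(age = cohort$age, sex = cohort$sex,
                      count = cohort[[population]])
  if (!is.null(sex)) d <- d[d$sex == sex, ]
  d <- d[!is.na(d$count), c("age", "count")]
  d[order(d$age), ]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
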