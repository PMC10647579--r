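CANONICAL_COLUMNS <- c("id", "age", "sex", "bmi", "waist", "sbp", "dbp", "map",
                       "pp", "pwv", "cavi", "cavi0",
                       "hypertension", "diabetes", "dyslipidemia", "smoking")

#' Write a cohort table to CSV
#'
#' Deterministic, diffable output: canonical column order (known columns
#' first, extras after, in their original order), UTF-8, "." decimal,
#' doubles formatted to 6 significant digits. Writing the same table twice
#' yields byte-identical files.
#'
#' @param data A cohort data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(data, path) {
  data <- tibble::as_tibble(data)
  ord <- c(intersect(CANONICAL_COLUMNS, names(data)),
           setdiff(names(data), CANONICAL_COLUMNS))
  data <- data[ord]
  formatted <- dplyr::mutate(data, dplyr::across(
    dplyr::where(is.double),
    function(x) trimws(formatC(x, digits = 6, format = "g"))
  ))
  readr::write_csv(formatted, path, eol = "\n")
  invisible(path)
}

#' Read and validate a cohort CSV
#'
#' Reads a delimited cohort table, checks that the required columns are
#' present, and enforces the pressure invariant `sbp > dbp > 0` row by row:
#' offending rows are reported with their file line numbers and dropped.
#'
#' @param path CSV file path with a header row.
#' @param required Columns that must be present.
#' @return A validated cohort tibble.
#' @export
read_cohort_csv <- function(path, required = c("age", "sbp", "dbp")) {
  if (!file.exists(path)) {
    abort(paste0("File not found: ", path), class = "cavindex_io_error")
  }
  data <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  require_columns(data, required)
  if (all(c("sbp", "dbp") %in% names(data))) {
    bad <- which(!(data$sbp > data$dbp & data$dbp > 0))
    if (length(bad)) {
      warn(paste0(
        "Dropping ", length(bad), " row(s) violating sbp > dbp > 0 at file line(s): ",
        paste(bad + 1L, collapse = ", ")
      ))
      data <- data[-bad, , drop = FALSE]
    }
  }
  data
}

#' Read a run configuration from YAML
#'
#' The file mirrors [generator_config()] field names under a `generator`
#' key, with optional top-level `analysis` options (`threshold`,
#' `permutations`, `extra_terms`) and `output_dir`.
#'
#' @param path YAML file path.
#' @return A list with elements `generator` (a `generator_config`),
#'   `analysis` and `output_dir`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  gl <- raw$generator
  if (!is.null(gl)) {
    # YAML 1.1 reads a bare `n` key as boolean FALSE; map it back
    names(gl)[names(gl) %in% c("FALSE", "no")] <- "n"
  }
  if (is.null(gl) || is.null(gl$n)) {
    abort("Config must provide `generator` with at least `n`.",
          class = "cavindex_config_error")
  }
  gen <- do.call(generator_config, gl)
  analysis <- raw$analysis %||% list()
  list(
    generator = gen,
    analysis = list(
      threshold = analysis$threshold %||% 70,
      permutations = analysis$permutations %||% 999,
      extra_terms = analysis$extra_terms %||% c("sbp", "sex", "bmi")
    ),
    output_dir = raw$output_dir
  )
}

#' Run the full generation-to-report pipeline
#'
#' Generates (or accepts) a cohort and runs the complete analysis: the
#' stratified descriptive comparison, the three-term and extended
#' interaction models for both indexes (with permutation inference), the
#' CAVI0 crossover, the decade-strata trends (DBP-adjusted and not) and the
#' prediction grid for the predicted-value figure. The bundle is stamped
#' with the seed and a hash of the configuration; identical configurations
#' produce identical bundles.
#'
#' @param generator A [generator_config()] describing the cohort, or `NULL`
#'   if `cohort` is supplied directly.
#' @param cohort An existing cohort tibble (optional; overrides generation).
#' @param threshold Age threshold for the descriptive comparison.
#' @param permutations Permutation count for the regression models
#'   (0 disables permutation inference; otherwise must be >= 99).
#' @param extra_terms Extra terms for the extended models.
#' @param out_dir Optional directory; when given, every result table is
#'   written there as a deterministic CSV.
#' @param quiet Suppress per-stage progress messages?
#' @return An object of class `reproduction_report` (a named list of result
#'   tables plus `seed` and `config_hash`).
#' @examples
#' rep <- run_reproduction(generator_config(n = 191, seed = 1),
#'                         permutations = 0, quiet = TRUE)
#' rep$crossover
#' @export
run_reproduction <- function(generator = NULL,
                             cohort = NULL,
                             threshold = 70,
                             permutations = 999,
                             extra_terms = c("sbp", "sex", "bmi"),
                             out_dir = NULL,
                             quiet = FALSE) {
  if (permutations != 0 && permutations < 99) {
    abort("`permutations` must be 0 or at least 99.",
          class = "cavindex_config_error")
  }
  say <- function(...) if (!quiet) message("[cavindex] ", sprintf(...))
  if (is.null(cohort)) {
    if (is.null(generator)) {
      abort("Provide either `generator` or `cohort`.",
            class = "cavindex_config_error")
    }
    say("generating %s-mode cohort, n = %d, seed = %d",
        generator$mode, generator$n, as.integer(generator$seed))
    cohort <- generate_cohort(generator)
  }
  seed <- if (!is.null(generator)) generator$seed else NA_integer_

  say("descriptive comparison at threshold %g years", threshold)
  table1 <- describe_by_age_group(cohort, threshold = threshold)

  say("interaction models (permutations = %d)", permutations)
  fit_one <- function(resp, extras) {
    fit_interaction_model(cohort, resp, extra_terms = extras,
                          permutations = permutations,
                          perm_seed = if (is.na(seed)) 1 else as.integer(seed))
  }
  fits <- list(
    cavi0_base = fit_one("cavi0", NULL),
    cavi0_extended = fit_one("cavi0", extra_terms),
    cavi_base = fit_one("cavi", NULL),
    cavi_extended = fit_one("cavi", extra_terms)
  )

  say("crossover and trends")
  cross <- crossover(fits$cavi0_base)
  trends <- list(
    cavi0 = trend_across_strata(cohort, "cavi0"),
    cavi0_adjusted = trend_across_strata(cohort, "cavi0", adjust_for_dbp = TRUE),
    cavi = trend_across_strata(cohort, "cavi"),
    cavi_adjusted = trend_across_strata(cohort, "cavi", adjust_for_dbp = TRUE)
  )
  grid <- prediction_grid(fits$cavi0_base)

  cfg_hash <- rlang::hash(list(
    generator = if (!is.null(generator)) unclass(generator),
    threshold = threshold, permutations = permutations,
    extra_terms = extra_terms
  ))
  report <- structure(
    list(
      cohort = cohort,
      table1 = table1,
      fits = fits,
      crossover = cross,
      trends = trends,
      prediction_grid = grid,
      threshold = threshold,
      permutations = permutations,
      seed = seed,
      config_hash = cfg_hash
    ),
    class = "reproduction_report"
  )
  if (!is.null(out_dir)) {
    say("writing report tables to %s", out_dir)
    write_report_bundle(report, out_dir)
  }
  report
}

#' @export
print.reproduction_report <- function(x, ...) {
  cat(sprintf("<reproduction_report> n = %d, seed = %s, config %s\n",
              nrow(x$cohort), format(x$seed), x$config_hash))
  cat(sprintf("  CAVI0 crossover: age %.1f years, value %.2f\n",
              x$crossover$crossover_age, x$crossover$crossover_value))
  for (nm in names(x$fits)) {
    g <- glance(x$fits[[nm]])
    cat(sprintf("  %-15s R2 = %.3f\n", nm, g$r_squared))
  }
  invisible(x)
}

write_report_bundle <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(name) file.path(out_dir, name)
  write_cohort_csv(report$cohort, out("cohort.csv"))
  write_table_csv(report$table1$continuous, out("table1_continuous.csv"))
  write_table_csv(report$table1$binary, out("table1_binary.csv"))
  for (nm in names(report$fits)) {
    write_table_csv(tidy(report$fits[[nm]]), out(paste0("fit_", nm, ".csv")))
  }
  write_table_csv(report$crossover, out("crossover.csv"))
  for (nm in names(report$trends)) {
    write_table_csv(report$trends[[nm]]$stratum_means,
                    out(paste0("trend_", nm, "_means.csv")))
    write_table_csv(report$trends[[nm]]$trend, out(paste0("trend_", nm, ".csv")))
  }
  write_table_csv(report$prediction_grid, out("prediction_grid.csv"))
  meta <- tibble::tibble(seed = report$seed, config_hash = report$config_hash,
                         threshold = report$threshold,
                         permutations = report$permutations)
  write_table_csv(meta, out("run_meta.csv"))
  invisible(out_dir)
}

# deterministic formatting shared by every emitted result table
write_table_csv <- function(data, path) {
  formatted <- dplyr::mutate(tibble::as_tibble(data), dplyr::across(
    dplyr::where(is.double),
    function(x) trimws(formatC(x, digits = 6, format = "g"))
  ))
  readr::write_csv(formatted, path, eol = "\n")
  invisible(path)
}
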