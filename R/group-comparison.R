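#' Two-sample Student t test
#'
#' Pooled-variance Student t test for unpaired samples (the study's default
#' parametric comparison); set `var_equal = FALSE` for the Welch variant.
#' Two-sided.
#'
#' @param x,y Numeric samples of size >= 2.
#' @param var_equal Pool the variances (classic Student test)?
#' @return A one-row tibble: `estimate` (mean difference x - y),
#'   `statistic`, `df`, `p_value`.
#' @examples
#' student_t_test(c(1, 2, 3), c(2, 3, 4))
#' @export
student_t_test <- function(x, y, var_equal = TRUE) {
  if (length(x) < 2 || length(y) < 2) {
    abort("Each sample needs at least 2 observations.",
          class = "cavindex_degenerate_sample")
  }
  if (var(x) == 0 && var(y) == 0) {
    abort("Zero pooled variance: the t statistic is undefined.",
          class = "cavindex_degenerate_sample")
  }
  ht <- t.test(x, y, var.equal = var_equal)
  tibble::tibble(
    estimate = mean(x) - mean(y),
    statistic = unname(ht$statistic),
    df = unname(ht$parameter),
    p_value = ht$p.value
  )
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum comparison. For combined sample sizes up to 20 with no
#' ties the exact enumeration p-value is used; otherwise the normal
#' approximation with tie and continuity corrections. The reported statistic
#' is the U statistic for the first sample (number of (x, y) pairs with
#' x > y, ties counting one half).
#'
#' @param x,y Numeric samples (non-empty).
#' @param exact Force (`TRUE`)/suppress (`FALSE`) exact enumeration;
#'   default `NULL` applies the rule above.
#' @return A one-row tibble: `statistic` (U), `p_value`, `exact`.
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6)) # U = 0, exact p = 0.1
#' @export
mann_whitney_u <- function(x, y, exact = NULL) {
  if (length(x) < 1 || length(y) < 1) {
    abort("Both samples must be non-empty.", class = "cavindex_degenerate_sample")
  }
  ties <- anyDuplicated(c(x, y)) > 0
  if (is.null(exact)) exact <- (length(x) + length(y) <= 20) && !ties
  ht <- suppressWarnings(
    wilcox.test(x, y, exact = exact, correct = TRUE)
  )
  p <- ht$p.value
  # complete ties degenerate the normal approximation (0/0); no evidence
  # against the null either way
  if (is.nan(p)) p <- 1
  tibble::tibble(
    statistic = unname(ht$statistic),
    p_value = p,
    exact = exact && !ties
  )
}

#' Yates-corrected chi-square test for a 2x2 table
#'
#' Pearson chi-square on the table `rbind(c(a, b), c(c, d))` with the Yates
#' continuity correction (clamped at |O - E| so small tables cannot
#' overshoot), one degree of freedom, two-sided.
#'
#' @param a,b First row counts (e.g. exposed / not exposed in group 1).
#' @param c,d Second row counts.
#' @return A one-row tibble: `statistic`, `df`, `p_value`.
#' @examples
#' chisq_2x2_yates(74, 26, 53, 38) # p = 0.031
#' @export
chisq_2x2_yates <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(!is.finite(counts)) || any(counts < 0)) {
    abort("Counts must be non-negative.", class = "cavindex_contract_error")
  }
  m <- matrix(counts, nrow = 2, byrow = TRUE)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    abort("A zero margin makes the chi-square test undefined.",
          class = "cavindex_undefined_table")
  }
  ht <- suppressWarnings(chisq.test(m, correct = TRUE))
  tibble::tibble(
    statistic = unname(ht$statistic),
    df = unname(ht$parameter),
    p_value = ht$p.value
  )
}

#' Pearson correlation with t-based p-value
#'
#' @param x,y Numeric samples of equal length >= 3 with positive variance.
#' @return A one-row tibble: `estimate` (r), `statistic` (t with n - 2 df),
#'   `df`, `p_value` (two-sided).
#' @examples
#' pearson_correlation(c(1, 2, 3), c(1, 3, 2)) # r = 0.5
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    abort("Need paired samples of length >= 3.", class = "cavindex_degenerate_sample")
  }
  if (var(x) == 0 || var(y) == 0) {
    abort("Zero variance: correlation undefined.",
          class = "cavindex_degenerate_sample")
  }
  ht <- cor.test(x, y, method = "pearson")
  tibble::tibble(
    estimate = unname(ht$estimate),
    statistic = unname(ht$statistic),
    df = unname(ht$parameter),
    p_value = ht$p.value
  )
}

#' Stratified descriptive comparison of a cohort
#'
#' Splits the cohort at an age threshold and summarises every continuous
#' variable (mean, SD, median, quartiles per stratum, plus Student-t and
#' Mann-Whitney p-values) and every binary variable (count, percentage per
#' stratum, plus the Yates chi-square p-value), in the layout of a clinical
#' "Table 1".
#'
#' @param data A cohort data frame with an `age` column.
#' @param threshold Age cut (years); strata are `age < threshold` and
#'   `age >= threshold`. Both must be non-empty.
#' @param continuous_vars,binary_vars Character vectors of column names;
#'   defaults pick all numeric non-flag columns (except `id`) and the 0/1
#'   flag columns plus a male-sex indicator derived from `sex`.
#' @param quartile_type Quantile algorithm passed to [stats::quantile()]
#'   (default 7, the R convention used in the source analyses).
#' @return An object of class `cohort_comparison`: a list with tibbles
#'   `continuous` and `binary`, plus `threshold` and stratum sizes.
#' @examples
#' cohort <- generate_cohort(generator_config(n = 120, seed = 3))
#' describe_by_age_group(cohort)
#' @export
describe_by_age_group <- function(data, threshold = 70,
                                  continuous_vars = NULL,
                                  binary_vars = NULL,
                                  quartile_type = 7) {
  require_columns(data, "age")
  data <- tibble::as_tibble(data)
  old <- data$age >= threshold
  if (all(old) || !any(old)) {
    abort("Both age strata must be non-empty at this threshold.",
          class = "cavindex_stratification_error")
  }
  flags <- intersect(c("hypertension", "diabetes", "dyslipidemia", "smoking"),
                     names(data))
  if (is.null(continuous_vars)) {
    continuous_vars <- setdiff(
      names(data)[vapply(data, is.numeric, logical(1))],
      c("id", flags)
    )
  }
  if (is.null(binary_vars)) {
    if ("sex" %in% names(data)) {
      data$male <- as.integer(data$sex == "male")
      binary_vars <- c("male", flags)
    } else {
      binary_vars <- flags
    }
  }

  summarise_one <- function(v) {
    xy <- data[[v]][!old]
    xo <- data[[v]][old]
    q_y <- quantile(xy, c(0.25, 0.5, 0.75), type = quartile_type, names = FALSE)
    q_o <- quantile(xo, c(0.25, 0.5, 0.75), type = quartile_type, names = FALSE)
    tibble::tibble(
      variable = v,
      mean_young = mean(xy), sd_young = sd(xy),
      median_young = q_y[2], q1_young = q_y[1], q3_young = q_y[3],
      mean_old = mean(xo), sd_old = sd(xo),
      median_old = q_o[2], q1_old = q_o[1], q3_old = q_o[3],
      p_ttest = student_t_test(xy, xo)$p_value,
      p_mannwhitney = mann_whitney_u(xy, xo)$p_value
    )
  }
  binary_one <- function(v) {
    cy <- sum(data[[v]][!old]); ny <- sum(!old)
    co <- sum(data[[v]][old]); no <- sum(old)
    tibble::tibble(
      variable = v,
      count_young = cy, pct_young = 100 * cy / ny,
      count_old = co, pct_old = 100 * co / no,
      p_chisq = chisq_2x2_yates(cy, ny - cy, co, no - co)$p_value
    )
  }

  structure(
    list(
      continuous = purrr::map_dfr(continuous_vars, summarise_one),
      binary = purrr::map_dfr(binary_vars, binary_one),
      threshold = threshold,
      n_young = sum(!old),
      n_old = sum(old)
    ),
    class = "cohort_comparison"
  )
}

#' @export
print.cohort_comparison <- function(x, ...) {
  cat(sprintf("<cohort_comparison> split at %g years: n = %d (< %g) vs %d (>= %g)\n\n",
              x$threshold, x$n_young, x$threshold, x$n_old, x$threshold))
  cat("Continuous variables:\n")
  print(x$continuous, n = Inf)
  cat("\nBinary variables:\n")
  print(x$binary, n = Inf)
  invisible(x)
}

#' @rdname describe_by_age_group
#' @param x A `cohort_comparison` object.
#' @param which `"continuous"` or `"binary"` table to return.
#' @param ... Unused.
#' @method tidy cohort_comparison
#' @export
tidy.cohort_comparison <- function(x, which = c("continuous", "binary"), ...) {
  x[[match.arg(which)]]
}
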