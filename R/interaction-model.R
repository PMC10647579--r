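#' Fit the age-by-DBP interaction model for a stiffness index
#'
#' Ordinary least squares of a stiffness index on age, DBP and their
#' product, optionally extended with SBP, sex and BMI -- the model used to
#' ask whether age modifies the DBP slope (effect modification). Standard
#' errors come from the classical covariance estimator and two-sided
#' p-values from the t distribution with n - p degrees of freedom;
#' Freedman-Lane permutation p-values can be attached by setting
#' `permutations`.
#'
#' @param data A cohort data frame with `age`, `dbp` and the response
#'   column (plus `sbp`, `sex`, `bmi` if requested).
#' @param response Name of the response column, `"cavi0"` or `"cavi"` (any
#'   numeric column is accepted).
#' @param extra_terms Character vector from `c("sbp", "sex", "bmi")` to
#'   append to the three-term model, or `NULL`.
#' @param permutations Number of permutations for [permutation_test()]
#'   (0 = none, otherwise >= 99).
#' @param perm_seed Seed for the permutation stream.
#' @param perm_method Permutation scheme, see [permutation_test()].
#' @return An object of class `stiffness_fit` wrapping the [stats::lm] fit,
#'   with [tidy()], [glance()], [sequential_anova()], [predict_index()],
#'   [crossover()] and [autoplot()] methods.
#' @examples
#' cohort <- generate_cohort(generator_config(n = 191, seed = 1))
#' fit <- fit_interaction_model(cohort, "cavi0")
#' tidy(fit)
#' glance(fit)
#' @export
fit_interaction_model <- function(data, response = c("cavi0", "cavi"),
                                  extra_terms = NULL,
                                  permutations = 0,
                                  perm_seed = 1,
                                  perm_method = c("freedman_lane", "response")) {
  response <- if (is.character(response) && length(response) == 1 &&
                  !response %in% c("cavi0", "cavi")) response else match.arg(response)
  if (!is.null(extra_terms)) {
    bad <- setdiff(extra_terms, c("sbp", "sex", "bmi"))
    if (length(bad)) {
      abort(paste0("Unsupported extra term(s): ", paste(bad, collapse = ", ")),
            class = "cavindex_contract_error")
    }
  }
  require_columns(data, c("age", "dbp", response, extra_terms))
  data <- tibble::as_tibble(data)
  if ("sex" %in% extra_terms) {
    data$sex <- factor(data$sex, levels = c("female", "male"))
  }
  rhs <- paste(c("age", "dbp", "age:dbp", extra_terms), collapse = " + ")
  form <- as.formula(paste(response, "~", rhs))
  n_terms <- 4L + length(extra_terms)
  if (nrow(data) <= n_terms) {
    abort("Need more observations than model terms.",
          class = "cavindex_contract_error")
  }
  fit <- lm(form, data = data)
  if (fit$rank < length(coef(fit))) {
    aliased <- names(coef(fit))[is.na(coef(fit))]
    abort(paste0("Design matrix is rank deficient; collinear term(s): ",
                 paste(aliased, collapse = ", ")),
          class = "cavindex_collinearity_error")
  }
  out <- structure(
    list(
      lm = fit,
      response = response,
      extra_terms = extra_terms,
      n = nrow(data),
      permutations = NULL
    ),
    class = "stiffness_fit"
  )
  if (permutations > 0) {
    pt <- permutation_test(out, B = permutations, seed = perm_seed,
                           method = match.arg(perm_method))
    out$permutations <- pt
  }
  out
}

#' @export
print.stiffness_fit <- function(x, ...) {
  cat(sprintf("<stiffness_fit> %s ~ age * dbp%s, n = %d\n",
              x$response,
              if (length(x$extra_terms)) paste0(" + ", paste(x$extra_terms, collapse = " + ")) else "",
              x$n))
  print(tidy(x), n = Inf)
  g <- glance(x)
  cat(sprintf("R-squared %.4f (adj. %.4f), residual SD %.4f\n",
              g$r_squared, g$adj_r_squared, g$sigma))
  invisible(x)
}

#' Coefficient table of a stiffness-index fit
#'
#' @param x A `stiffness_fit`.
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`, `std_error`,
#'   `statistic`, `p_value` and, when permutation inference was run,
#'   `p_perm`.
#' @method tidy stiffness_fit
#' @export
tidy.stiffness_fit <- function(x, ...) {
  s <- summary(x$lm)$coefficients
  out <- tibble::tibble(
    term = rownames(s),
    estimate = unname(s[, "Estimate"]),
    std_error = unname(s[, "Std. Error"]),
    statistic = unname(s[, "t value"]),
    p_value = unname(s[, "Pr(>|t|)"])
  )
  if (!is.null(x$permutations)) {
    out <- dplyr::left_join(out,
                            dplyr::select(x$permutations, "term", "p_perm"),
                            by = "term")
  }
  out
}

#' Model-level summary of a stiffness-index fit
#'
#' @param x A `stiffness_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `r_squared`, `adj_r_squared`, `sigma`,
#'   `statistic` (overall F), `p_value`, `df`, `df_residual`, `n`.
#' @method glance stiffness_fit
#' @export
glance.stiffness_fit <- function(x, ...) {
  s <- summary(x$lm)
  f <- s$fstatistic
  tibble::tibble(
    r_squared = s$r.squared,
    adj_r_squared = s$adj.r.squared,
    sigma = s$sigma,
    statistic = unname(f[1]),
    p_value = unname(pf_upper(f[1], f[2], f[3])),
    df = unname(f[2]),
    df_residual = unname(f[3]),
    n = x$n
  )
}

pf_upper <- function(f, df1, df2) stats::pf(f, df1, df2, lower.tail = FALSE)

#' Sequential (type I) analysis of variance for a stiffness-index fit
#'
#' Nested-model F tests in the order the terms enter the model.
#'
#' @param fit A `stiffness_fit`.
#' @return A tibble with `term`, `df`, `sum_sq`, `mean_sq`, `statistic`,
#'   `p_value`.
#' @export
sequential_anova <- function(fit) {
  stopifnot(inherits(fit, "stiffness_fit"))
  a <- anova(fit$lm)
  tibble::tibble(
    term = rownames(a),
    df = a$Df,
    sum_sq = a$`Sum Sq`,
    mean_sq = a$`Mean Sq`,
    statistic = a$`F value`,
    p_value = a$`Pr(>F)`
  )
}

#' Permutation inference for the coefficients of a stiffness-index fit
#'
#' Distribution-free per-coefficient p-values. The default Freedman-Lane
#' scheme tests each term by fitting the reduced model without it, permuting
#' the reduced-model residuals, rebuilding pseudo-responses, refitting the
#' full model and comparing the permuted |t| statistics to the observed one;
#' `p = (1 + #(|t*| >= |t_obs|)) / (B + 1)`. The simpler `"response"` scheme
#' permutes the response wholesale. Results are deterministic given `seed`.
#'
#' @param fit A `stiffness_fit`.
#' @param B Number of permutations (>= 99 so the attainable p resolution is
#'   at worst 0.01).
#' @param seed Integer seed for the permutation stream.
#' @param method `"freedman_lane"` (default) or `"response"`.
#' @return A tibble with `term`, `statistic` (observed t), `p_perm`,
#'   `permutations`, `method`.
#' @examples
#' cohort <- generate_cohort(generator_config(n = 191, seed = 1))
#' fit <- fit_interaction_model(cohort, "cavi0")
#' permutation_test(fit, B = 199, seed = 42)
#' @export
permutation_test <- function(fit, B = 999, seed = 1,
                             method = c("freedman_lane", "response")) {
  stopifnot(inherits(fit, "stiffness_fit"))
  method <- match.arg(method)
  if (B < 99) {
    abort("`B` must be at least 99 (p-value resolution would be too coarse).",
          class = "cavindex_config_error")
  }
  X <- model.matrix(fit$lm)
  y <- model.response(model.frame(fit$lm))
  n <- nrow(X)
  p <- ncol(X)
  qr_full <- qr(X)
  # diag of (X'X)^-1: fixed across permutations, so permuted t statistics
  # need only the permuted coefficients and residual SDs
  xtx_inv_diag <- diag(chol2inv(qr.R(qr_full)))
  t_obs <- summary(fit$lm)$coefficients[, "t value"]

  perm_t <- function(Ystar, j) {
    cf <- qr.coef(qr_full, Ystar)
    res <- qr.resid(qr_full, Ystar)
    s2 <- colSums(res^2) / (n - p)
    cf[j, ] / sqrt(s2 * xtx_inv_diag[j])
  }

  withr::with_seed(seed, {
    perms <- replicate(B, sample.int(n))
    p_perm <- numeric(p)
    if (method == "response") {
      for (j in seq_len(p)) {
        Ystar <- matrix(y[perms], nrow = n)
        p_perm[j] <- (1 + sum(abs(perm_t(Ystar, j)) >= abs(t_obs[j]))) / (B + 1)
      }
    } else {
      for (j in seq_len(p)) {
        qz <- qr(X[, -j, drop = FALSE])
        e <- qr.resid(qz, y)
        f <- y - e
        Ystar <- f + matrix(e[perms], nrow = n)
        p_perm[j] <- (1 + sum(abs(perm_t(Ystar, j)) >= abs(t_obs[j]))) / (B + 1)
      }
    }
    tibble::tibble(
      term = colnames(X),
      statistic = unname(t_obs),
      p_perm = p_perm,
      permutations = B,
      method = method
    )
  })
}

# reference covariate values for terms other than age/dbp: numeric extras at
# their sample mean, sex at the reference level (female)
reference_newdata <- function(fit, age, dbp) {
  nd <- tibble::tibble(age = age, dbp = dbp)
  mf <- model.frame(fit$lm)
  for (v in fit$extra_terms) {
    nd[[v]] <- if (v == "sex") factor("female", levels = levels(mf$sex)) else mean(mf[[v]])
  }
  nd
}

#' Predicted stiffness index at given age and DBP
#'
#' Evaluates the fitted linear predictor at the supplied covariate points,
#' with any extra model terms fixed at reference values (numeric extras at
#' their sample mean, sex at female).
#'
#' @param fit A `stiffness_fit`.
#' @param age,dbp Covariate values (recycled to a common length).
#' @return A numeric vector of predicted index values.
#' @examples
#' cohort <- generate_cohort(generator_config(n = 191, seed = 1))
#' fit <- fit_interaction_model(cohort, "cavi0")
#' predict_index(fit, age = 70, dbp = c(50, 110))
#' @export
predict_index <- function(fit, age, dbp) {
  stopifnot(inherits(fit, "stiffness_fit"))
  k <- max(length(age), length(dbp))
  nd <- reference_newdata(fit, rep_len(age, k), rep_len(dbp, k))
  unname(stats::predict(fit$lm, newdata = nd))
}

#' Prediction grid over age and DBP
#'
#' Tabulates [predict_index()] over the cross of selected ages and a DBP
#' range, the data behind a predicted-value figure (one line per age).
#'
#' @param fit A `stiffness_fit`.
#' @param ages Ages (years) at which to draw lines.
#' @param dbp_range DBP interval (mmHg) to span.
#' @param n_dbp Number of grid points across `dbp_range`.
#' @return A tibble with columns `age`, `dbp`, `predicted`.
#' @export
prediction_grid <- function(fit, ages = seq(40, 90, by = 10),
                            dbp_range = c(50, 110), n_dbp = 61) {
  grid <- tidyr::expand_grid(
    age = ages,
    dbp = seq(dbp_range[1], dbp_range[2], length.out = n_dbp)
  )
  grid$predicted <- predict_index(fit, grid$age, grid$dbp)
  grid
}

#' Crossover age at which the DBP effect vanishes
#'
#' In the interaction model the partial DBP slope is
#' `b_dbp + b_int * age`; it is zero at `age = -b_dbp / b_int`, where the
#' predicted index is independent of DBP. Returns that age and the
#' DBP-independent predicted value there.
#'
#' @param object A `stiffness_fit`, or a named coefficient vector with
#'   names `(Intercept)`, `age`, `dbp`, `age:dbp` (e.g. printed estimates).
#' @param ... Unused.
#' @return A one-row tibble: `crossover_age` (years), `crossover_value`
#'   (index units).
#' @examples
#' crossover(c(`(Intercept)` = -30.301, age = 0.682,
#'             dbp = 0.306, `age:dbp` = -0.005))
#' @export
crossover <- function(object, ...) UseMethod("crossover")

#' @export
crossover.stiffness_fit <- function(object, ...) {
  cf <- coef(object$lm)
  res <- crossover_from_coefs(cf["dbp"], cf["age:dbp"])
  # evaluate through the fit so extra terms sit at their reference values
  val <- predict_index(object, res$age, dbp = 100)
  tibble::tibble(crossover_age = res$age, crossover_value = val)
}

#' @export
crossover.numeric <- function(object, ...) {
  needed <- c("(Intercept)", "age", "dbp", "age:dbp")
  if (!all(needed %in% names(object))) {
    abort("Coefficient vector needs names (Intercept), age, dbp, age:dbp.",
          class = "cavindex_contract_error")
  }
  res <- crossover_from_coefs(object[["dbp"]], object[["age:dbp"]])
  tibble::tibble(
    crossover_age = res$age,
    crossover_value = object[["(Intercept)"]] + object[["age"]] * res$age
  )
}

crossover_from_coefs <- function(b_dbp, b_int) {
  if (!is.finite(b_int) || b_int == 0) {
    abort("Interaction coefficient is zero: the DBP slope never crosses zero.",
          class = "cavindex_no_crossover")
  }
  list(age = unname(-b_dbp / b_int))
}

#' Trend of a stiffness index across age strata
#'
#' Bins subjects into decade strata (40-49, ..., 80-89, 90+), regresses the
#' index on the ordinal stratum score (optionally adjusting for DBP) and
#' reports the score slope with its p-value, plus per-stratum means for
#' plotting.
#'
#' @param data A cohort data frame with `age`, `dbp` and the index column.
#' @param index `"cavi0"` or `"cavi"`.
#' @param adjust_for_dbp Add DBP as a covariate?
#' @param breaks Left edges of the strata; the last stratum is open-ended.
#' @return An object of class `strata_trend`: list with `trend` (one-row
#'   tibble: `estimate`, `std_error`, `statistic`, `p_value`),
#'   `stratum_means` (tibble: `stratum`, `n`, `mean`, `se`), `index`,
#'   `adjusted`.
#' @examples
#' cohort <- generate_cohort(generator_config(n = 300, seed = 2))
#' trend_across_strata(cohort, "cavi0", adjust_for_dbp = TRUE)
#' @export
trend_across_strata <- function(data, index = c("cavi0", "cavi"),
                                adjust_for_dbp = FALSE,
                                breaks = seq(40, 90, by = 10)) {
  index <- match.arg(index)
  require_columns(data, c("age", index, if (adjust_for_dbp) "dbp"))
  edges <- c(breaks, Inf)
  labels <- c(paste(breaks[-length(breaks)], breaks[-1] - 1, sep = "-"),
              paste0(breaks[length(breaks)], "+"))
  stratum <- cut(data$age, edges, labels = labels, right = FALSE,
                 include.lowest = TRUE)
  keep <- !is.na(stratum)
  stratum <- droplevels(stratum[keep])
  if (nlevels(stratum) < 3) {
    abort("Need at least 3 populated age strata for a trend.",
          class = "cavindex_trend_undefined")
  }
  df <- tibble::tibble(
    y = data[[index]][keep],
    score = as.integer(stratum),
    stratum = stratum
  )
  if (adjust_for_dbp) df$dbp <- data$dbp[keep]
  form <- if (adjust_for_dbp) y ~ score + dbp else y ~ score
  s <- summary(lm(form, data = df))$coefficients
  means <- df |>
    dplyr::group_by(.data$stratum) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean(.data$y),
      se = sd(.data$y) / sqrt(dplyr::n()),
      .groups = "drop"
    )
  structure(
    list(
      trend = tibble::tibble(
        estimate = s["score", "Estimate"],
        std_error = s["score", "Std. Error"],
        statistic = s["score", "t value"],
        p_value = s["score", "Pr(>|t|)"]
      ),
      stratum_means = means,
      index = index,
      adjusted = adjust_for_dbp
    ),
    class = "strata_trend"
  )
}

#' @export
print.strata_trend <- function(x, ...) {
  cat(sprintf("<strata_trend> %s across decade strata%s\n", x$index,
              if (x$adjusted) " (DBP-adjusted)" else ""))
  print(x$trend)
  print(x$stratum_means, n = Inf)
  invisible(x)
}

#' @rdname trend_across_strata
#' @param x A `strata_trend` object.
#' @param ... Unused.
#' @method tidy strata_trend
#' @export
tidy.strata_trend <- function(x, ...) x$trend
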