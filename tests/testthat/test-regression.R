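test_that("OLS fit equals the explicit normal-equations oracle", {
  tab <- tibble::tibble(
    age = c(45, 52, 61, 68, 77, 83, 88, 59),
    dbp = c(92, 88, 85, 80, 74, 70, 66, 83),
    cavi0 = c(10.2, 11.1, 12.4, 13.9, 16.8, 18.2, 20.5, 12.0)
  )
  fit <- fit_interaction_model(tab, "cavi0")
  X <- cbind(1, tab$age, tab$dbp, tab$age * tab$dbp)
  oracle <- ols_oracle(X, tab$cavi0)
  td <- tidy(fit)
  expect_equal(td$estimate, unname(oracle$coef), tolerance = 1e-9)
  expect_equal(td$std_error, unname(oracle$se), tolerance = 1e-9)
})

test_that("noiseless cohorts are recovered exactly, with R-squared one", {
  cfg <- generator_config(n = 400, seed = 6, cavi0_noise_sd = 0, cavi_noise_sd = 0)
  tab <- generate_cohort(cfg)
  fit <- fit_interaction_model(tab, "cavi0")
  # summary.lm flags the perfect fit; that is the point of the check
  td <- suppressWarnings(tidy(fit))
  expect_equal(td$estimate, unname(cfg$cavi0_coefficients), tolerance = 1e-8)
  expect_equal(suppressWarnings(glance(fit))$r_squared, 1, tolerance = 1e-12)
  # predictions equal the generating plane everywhere
  expect_equal(predict_index(fit, 70, 50), 15.239, tolerance = 1e-8)
  expect_equal(predict_index(fit, c(40, 90), c(100, 60)),
               -30.301 + 0.682 * c(40, 90) + 0.306 * c(100, 60) -
                 0.005 * c(40, 90) * c(100, 60),
               tolerance = 1e-8)
})

test_that("rank deficiency is reported with the offending term", {
  # constant pulse pressure makes sbp an exact copy of dbp plus a constant
  tab <- tibble::tibble(
    age = c(45, 52, 61, 68, 77, 83, 88, 59),
    dbp = c(92, 88, 85, 80, 74, 70, 66, 83),
    sex = rep(c("male", "female"), 4),
    bmi = c(31, 29, 33, 26, 24, 27, 25, 30),
    cavi0 = c(10.2, 11.1, 12.4, 13.9, 16.8, 18.2, 20.5, 12.0)
  )
  tab$sbp <- tab$dbp + 55
  expect_error(fit_interaction_model(tab, "cavi0", extra_terms = "sbp"),
               regexp = "sbp", class = "cavindex_collinearity_error")
  expect_error(fit_interaction_model(tab, "cavi0", extra_terms = "height"),
               class = "cavindex_contract_error")
  expect_error(fit_interaction_model(tab[1:4, ], "cavi0"),
               class = "cavindex_contract_error")
})

test_that("extended models expose extra terms with sex coded male = 1", {
  tab <- generate_cohort(generator_config(n = 300, seed = 12))
  fit <- fit_interaction_model(tab, "cavi0", extra_terms = c("sbp", "sex", "bmi"))
  expect_setequal(tidy(fit)$term,
                  c("(Intercept)", "age", "dbp", "age:dbp", "sbp", "sexmale", "bmi"))
  av <- sequential_anova(fit)
  expect_equal(av$term[1:3], c("age", "dbp", "sbp"))
  expect_true(all(av$p_value[!is.na(av$p_value)] >= 0 &
                    av$p_value[!is.na(av$p_value)] <= 1))
})

test_that("crossover arithmetic matches the printed-coefficient oracle", {
  printed <- c(`(Intercept)` = -30.301, age = 0.682, dbp = 0.306, `age:dbp` = -0.005)
  res <- crossover(printed)
  expect_equal(res$crossover_age, 61.2)
  expect_equal(res$crossover_value, 11.4374, tolerance = 1e-4)
  res2 <- crossover(c(`(Intercept)` = 0, age = 1, dbp = 1, `age:dbp` = -0.01))
  expect_equal(res2$crossover_age, 100)
  expect_equal(res2$crossover_value, 100)
  expect_error(crossover(c(`(Intercept)` = 0, age = 1, dbp = 1, `age:dbp` = 0)),
               class = "cavindex_no_crossover")
  expect_error(crossover(c(age = 1, dbp = 1)), class = "cavindex_contract_error")
})

test_that("predictions at the fitted crossover age are DBP-independent", {
  tab <- generate_cohort(generator_config(n = 5000, seed = 13))
  fit <- fit_interaction_model(tab, "cavi0")
  res <- crossover(fit)
  p50 <- predict_index(fit, res$crossover_age, 50)
  p110 <- predict_index(fit, res$crossover_age, 110)
  expect_lt(abs(p50 - p110), 1e-9)
  expect_equal(p50, res$crossover_value, tolerance = 1e-9)
})

test_that("prediction grids evaluate the linear predictor over age x DBP", {
  tab <- generate_cohort(generator_config(n = 1000, seed = 14))
  fit <- fit_interaction_model(tab, "cavi0")
  grid <- prediction_grid(fit, ages = c(40, 70), dbp_range = c(50, 110), n_dbp = 7)
  expect_equal(nrow(grid), 14)
  cf <- coef(fit$lm)
  manual <- cf[1] + cf["age"] * grid$age + cf["dbp"] * grid$dbp +
    cf["age:dbp"] * grid$age * grid$dbp
  expect_equal(grid$predicted, unname(manual), tolerance = 1e-10)
})

test_that("permutation inference is valid, reproducible and bounded below", {
  tab <- generate_cohort(generator_config(n = 191, seed = 15))
  fit <- fit_interaction_model(tab, "cavi0")
  expect_error(permutation_test(fit, B = 10), class = "cavindex_config_error")

  p1 <- permutation_test(fit, B = 199, seed = 7)
  p2 <- permutation_test(fit, B = 199, seed = 7)
  expect_identical(p1, p2)
  expect_true(all(p1$p_perm >= 1 / 200 & p1$p_perm <= 1))
  # on weak-signal data, different permutation streams give different p-values
  weak <- withr::with_seed(41, tibble::tibble(
    age = rnorm(40), dbp = rnorm(40),
    cavi0 = rnorm(40) + 0.2 * rnorm(40)
  ))
  wfit <- fit_interaction_model(weak, "cavi0")
  expect_false(identical(permutation_test(wfit, B = 199, seed = 7)$p_perm,
                         permutation_test(wfit, B = 199, seed = 8)$p_perm))

  # an overwhelming true effect attains the lower bound 1/(B+1)
  strong <- tibble::tibble(age = seq(40, 90, length.out = 60),
                           dbp = rep(c(70, 90), 30))
  strong$cavi0 <- 5 + 1 * strong$age + 0.01 * strong$dbp +
    0.0001 * strong$age * strong$dbp +
    withr::with_seed(3, rnorm(60, 0, 0.01))
  sfit <- fit_interaction_model(strong, "cavi0")
  sp <- permutation_test(sfit, B = 999, seed = 5)
  expect_equal(sp$p_perm[sp$term == "age"], 1 / 1000)

  # the simple response-permutation scheme is also available
  rp <- permutation_test(fit, B = 99, seed = 1, method = "response")
  expect_true(all(rp$p_perm >= 1 / 100 & rp$p_perm <= 1))
  expect_equal(unique(rp$method), "response")

  # fits can carry permutation p-values in their coefficient table
  pf <- fit_interaction_model(tab, "cavi0", permutations = 99, perm_seed = 2)
  expect_true("p_perm" %in% names(tidy(pf)))
})

test_that("decade-strata trends detect monotone aging and need 3 strata", {
  tab <- tibble::tibble(age = seq(40, 95, length.out = 120), dbp = 80)
  tab$cavi0 <- tab$age / 10
  tr <- trend_across_strata(tab, "cavi0")
  expect_gt(tr$trend$estimate, 0)
  expect_lt(tr$trend$p_value, 1e-6)
  expect_equal(nrow(tr$stratum_means), 6)

  expect_error(
    trend_across_strata(tibble::tibble(age = c(41, 42, 55), dbp = 80,
                                       cavi0 = 1:3), "cavi0"),
    class = "cavindex_trend_undefined"
  )

  # the mechanistic cohort shows a positive DBP-adjusted trend for both indexes
  mech <- generate_cohort(generator_config(n = 3000, seed = 16, mode = "mechanistic"))
  for (idx in c("cavi0", "cavi")) {
    tr <- trend_across_strata(mech, idx, adjust_for_dbp = TRUE)
    expect_gt(tr$trend$estimate, 0)
    expect_lt(tr$trend$p_value, 1e-6)
  }
})
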