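test_that("slope and noise calibrations follow their closed forms", {
  expect_identical(calibrate_dbp_slope(0, 9, 14.4), 0)
  expect_equal(calibrate_dbp_slope(-0.464, 9.0, 14.4), -0.3274, tolerance = 1e-4)
  expect_error(calibrate_dbp_slope(1, 9, 14.4), class = "cavindex_config_error")
  expect_error(calibrate_dbp_slope(-1.2, 9, 14.4), class = "cavindex_config_error")

  expect_equal(calibrate_noise_sd(0.5, 1), 1.0)
  expect_equal(calibrate_noise_sd(0.508, 4), 1.9683, tolerance = 1e-4)
  expect_equal(calibrate_noise_sd(0.99, 1), 0.1005, tolerance = 1e-3)
  expect_error(calibrate_noise_sd(0, 1), class = "cavindex_config_error")
  expect_error(calibrate_noise_sd(1, 1), class = "cavindex_config_error")
  expect_error(calibrate_noise_sd(0.5, -1), class = "cavindex_config_error")
})

test_that("truncated-normal moments match a large Monte-Carlo sample", {
  m <- truncnorm_moments(68.3, 14.4, 40, 96)
  x <- withr::with_seed(5, qnorm(runif(2e5, pnorm((40 - 68.3) / 14.4),
                                       pnorm((96 - 68.3) / 14.4))) * 14.4 + 68.3)
  expect_equal(m$mean, mean(x), tolerance = 5e-3)
  expect_equal(m$sd, sd(x), tolerance = 1e-2)
})

test_that("configuration validation rejects inconsistent settings", {
  expect_error(generator_config(n = 0), class = "cavindex_config_error")
  expect_error(generator_config(n = 10, age_range = c(96, 40)),
               class = "cavindex_config_error")
  expect_error(generator_config(n = 10, sex_male_prob = c(0.5, 1.2)),
               class = "cavindex_config_error")
  expect_error(
    generator_config(n = 10, cavi0_target_r2 = 0.5, cavi0_noise_sd = 1),
    class = "cavindex_config_error"
  )
})

test_that("cohorts are deterministic given the seed and respect invariants", {
  cfg <- generator_config(n = 2000, seed = 42)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)
  expect_false(identical(a, generate_cohort(generator_config(n = 2000, seed = 43))))

  expect_false(anyNA(a))
  expect_true(all(a$age >= 40 & a$age <= 96))
  expect_true(all(a$dbp >= 55 & a$dbp <= 109))
  expect_true(all(a$sbp > a$dbp & a$dbp > 0))
  expect_true(all(a$dbp < a$map & a$map < a$sbp))
  expect_true(all(a$sex %in% c("male", "female")))
  flags <- c("hypertension", "diabetes", "dyslipidemia", "smoking")
  expect_true(all(unlist(a[flags]) %in% 0:1))
})

test_that("degenerate DBP settings produce a constant column", {
  cfg <- generator_config(n = 5, seed = 9, dbp_noise_sd = 0, dbp_slope = 0,
                          dbp_intercept = 80)
  expect_true(all(sample_covariates(cfg)$dbp == 80))
})

test_that("covariates reproduce the configured stratum structure", {
  cfg <- generator_config(n = 20000, seed = 11)
  tab <- sample_covariates(cfg)
  young <- tab$age < 70
  ref_c <- study_population_reference("continuous")
  for (v in c("bmi", "waist")) {
    for (s in c("young", "old")) {
      sel <- if (s == "young") young else !young
      ref <- ref_c[ref_c$variable == v & ref_c$stratum == s, ]
      se <- ref$sd / sqrt(sum(sel))
      expect_lt(abs(mean(tab[[v]][sel]) - ref$mean), 4 * se)
    }
  }
  # comorbidity prevalences per stratum within 4 binomial SEs
  for (flag in names(cfg$comorbidity_prev)) {
    for (k in 1:2) {
      sel <- if (k == 1) young else !young
      p <- cfg$comorbidity_prev[[flag]][k]
      se <- sqrt(p * (1 - p) / sum(sel))
      expect_lt(abs(mean(tab[[flag]][sel]) - p), 4 * se)
    }
  }
  # calibrated marginal moments of DBP and its correlation with age
  # (range clipping trims ~1% of draws, shaving about 1% off the SD)
  expect_equal(mean(tab$dbp), 81.2, tolerance = 0.01)
  expect_equal(sd(tab$dbp), 10.7, tolerance = 0.02)
  expect_equal(cor(tab$dbp, tab$age), -0.464, tolerance = 0.015)
})

test_that("regression mode draws indexes from the configured planes", {
  # noiseless cohorts sit exactly on the generating planes
  cfg0 <- generator_config(n = 400, seed = 3, cavi0_noise_sd = 0, cavi_noise_sd = 0)
  tab <- generate_cohort(cfg0)
  plane0 <- -30.301 + 0.682 * tab$age + 0.306 * tab$dbp - 0.005 * tab$age * tab$dbp
  planec <- -4.16 + 0.175 * tab$age + 0.072 * tab$dbp - 0.001 * tab$age * tab$dbp
  expect_equal(tab$cavi0, plane0, tolerance = 1e-12)
  expect_equal(tab$cavi, planec, tolerance = 1e-12)

  # with calibrated noise, a large-sample refit recovers the generating
  # coefficients within Monte-Carlo error
  tab2 <- generate_cohort(generator_config(n = 50000, seed = 4))
  fit <- fit_interaction_model(tab2, "cavi0")
  td <- tidy(fit)
  se <- td$std_error
  expect_lt(abs(td$estimate[td$term == "age"] - 0.682), 3 * se[td$term == "age"])
  expect_lt(abs(td$estimate[td$term == "dbp"] - 0.306), 3 * se[td$term == "dbp"])
  expect_lt(abs(td$estimate[td$term == "age:dbp"] + 0.005),
            3 * se[td$term == "age:dbp"])
})

test_that("mechanistic mode routes PWV through the formula chain", {
  cfg <- generator_config(n = 300, seed = 8, mode = "mechanistic",
                          pwv_intercept = 4, pwv_slope = 0.05, pwv_noise_sd = 0)
  tab <- generate_cohort(cfg)
  expect_equal(tab$pwv, 4 + 0.05 * tab$age, tolerance = 1e-12)
  expect_equal(tab$cavi, cavi_from_pwv(tab$sbp, tab$dbp, tab$pwv), tolerance = 1e-12)
  expect_equal(tab$cavi0, cavi0_from_pwv(tab$dbp, tab$pwv), tolerance = 1e-12)
  # a 60-year-old subject would have pwv = 7 under this model
  expect_equal(unique(round(tab$pwv - 0.05 * tab$age, 10)), 4)

  # seed reproducibility in mechanistic mode
  cfg2 <- generator_config(n = 500, seed = 21, mode = "mechanistic")
  expect_identical(generate_cohort(cfg2), generate_cohort(cfg2))

  # a PWV model aimed at negative speeds warns and clips
  bad <- generator_config(n = 50, seed = 2, mode = "mechanistic",
                          pwv_intercept = -20, pwv_slope = 0.01,
                          pwv_noise_sd = 0.1)
  expect_warning(tabbad <- generate_cohort(bad), "clipped")
  expect_true(all(tabbad$pwv >= 0))
})

test_that("regression and mechanistic modes share covariates at equal seeds", {
  covars <- c("id", "age", "sex", "bmi", "waist", "sbp", "dbp", "map", "pp")
  r <- generate_cohort(generator_config(n = 100, seed = 77))
  m <- generate_cohort(generator_config(n = 100, seed = 77, mode = "mechanistic"))
  expect_identical(r[covars], m[covars])
})
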