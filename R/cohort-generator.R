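#' Moments of a truncated normal distribution
#'
#' Analytic mean and standard deviation of a Normal(mean, sd) truncated to
#' `[lower, upper]`. Used to calibrate the DBP-versus-age model against the
#' truncated age distribution of the generator.
#'
#' @param mean,sd Moments of the parent normal.
#' @param lower,upper Truncation bounds.
#' @return A list with elements `mean` and `sd`.
#' @examples
#' truncnorm_moments(68.3, 14.4, 40, 96)
#' @export
truncnorm_moments <- function(mean, sd, lower, upper) {
  a <- (lower - mean) / sd
  b <- (upper - mean) / sd
  z <- pnorm(b) - pnorm(a)
  m <- mean + sd * (dnorm(a) - dnorm(b)) / z
  v <- sd^2 * (1 + (a * dnorm(a) - b * dnorm(b)) / z -
                 ((dnorm(a) - dnorm(b)) / z)^2)
  list(mean = m, sd = sqrt(v))
}

# inverse-CDF sampler for the truncated normal (single runif draw per value,
# keeps the generator's RNG stream layout simple and stable)
rtruncnorm <- function(n, mean, sd, lower, upper) {
  plo <- pnorm((lower - mean) / sd)
  phi <- pnorm((upper - mean) / sd)
  qnorm(runif(n, plo, phi)) * sd + mean
}

#' Calibrate the DBP-on-age slope for a target correlation
#'
#' In the generating model `DBP = alpha0 + alpha1 * age + eps` with
#' `eps ~ Normal(0, sigma_eps)`, the population correlation between DBP and
#' age is determined by the slope; the closed form
#' `alpha1 = r * sigma_eps / (sigma_age * sqrt(1 - r^2))`
#' yields exactly the requested correlation.
#'
#' @param target_r Target Pearson correlation, strictly inside (-1, 1).
#' @param sigma_eps Residual SD of the DBP model (mmHg).
#' @param sigma_age SD of the age distribution actually sampled (years); for
#'   a truncated normal age model use the truncated SD
#'   (see [truncnorm_moments()]).
#' @return The slope `alpha1` in mmHg per year.
#' @examples
#' calibrate_dbp_slope(-0.464, 9.0, 14.4) # -0.3274
#' @export
calibrate_dbp_slope <- function(target_r, sigma_eps, sigma_age) {
  if (!is.finite(target_r) || abs(target_r) >= 1) {
    abort("`target_r` must lie strictly inside (-1, 1).",
          class = "cavindex_config_error")
  }
  if (sigma_eps < 0 || sigma_age <= 0) {
    abort("`sigma_eps` must be >= 0 and `sigma_age` > 0.",
          class = "cavindex_config_error")
  }
  target_r * sigma_eps / (sigma_age * sqrt(1 - target_r^2))
}

#' Calibrate the response noise SD for a target R-squared
#'
#' For a linear generating model with linear-predictor variance `Var(mu)`,
#' Gaussian noise with `sigma^2 = Var(mu) * (1 - R2) / R2` yields a
#' population coefficient of determination of exactly `R2`.
#'
#' @param target_r2 Target R-squared, strictly inside (0, 1).
#' @param linear_predictor_variance Variance of the noiseless linear
#'   predictor over the covariate distribution (estimate it on a large
#'   covariate sample).
#' @return Noise standard deviation in response units.
#' @examples
#' calibrate_noise_sd(0.5, 1)    # 1
#' calibrate_noise_sd(0.508, 4)  # 1.9683
#' @export
calibrate_noise_sd <- function(target_r2, linear_predictor_variance) {
  if (!is.finite(target_r2) || target_r2 <= 0 || target_r2 >= 1) {
    abort("`target_r2` must lie strictly inside (0, 1).",
          class = "cavindex_config_error")
  }
  if (linear_predictor_variance <= 0) {
    abort("`linear_predictor_variance` must be positive.",
          class = "cavindex_config_error")
  }
  sqrt(linear_predictor_variance * (1 - target_r2) / target_r2)
}

#' Configuration for the synthetic cohort generator
#'
#' Defines every distribution, coefficient and noise level of the synthetic
#' cohort. Defaults emulate the 191-patient geriatric study population on
#' which the package is calibrated: ages 40-96 with pooled mean 68.3 (SD
#' 14.4), DBP declining with age so that corr(DBP, age) = -0.464 with a
#' marginal DBP SD of 10.7 mmHg clipped to the observed 55-109 mmHg range,
#' pulse pressure, sex, BMI, waist and comorbidity prevalences matched to
#' the under-70 / 70-plus strata, and stiffness indexes generated either
#' from the study's fitted regression planes (`mode = "regression"`) or
#' mechanistically from a PWV-versus-age model pushed through the formula
#' chain (`mode = "mechanistic"`).
#'
#' The DBP slope, intercept and noise SD are derived from
#' (`dbp_mean`, `dbp_sd`, `dbp_age_r`) via [calibrate_dbp_slope()] using the
#' analytic truncated-age moments, unless overridden explicitly. Per-index
#' noise is specified either as a target R-squared (calibrated via
#' [calibrate_noise_sd()] on the realized linear-predictor variance) or as
#' an explicit SD -- exactly one of the two; when neither is given the
#' defaults `target R2 = 0.508` (CAVI0) and `0.49` (CAVI) apply.
#'
#' @param n Number of subjects (> 0).
#' @param seed Integer seed; the whole cohort is a deterministic function of
#'   the configuration and this seed.
#' @param mode `"regression"` or `"mechanistic"`.
#' @param age_mean,age_sd,age_range Parent mean/SD (years) and truncation
#'   range of the age distribution.
#' @param dbp_mean,dbp_sd Target marginal mean and SD of DBP (mmHg).
#' @param dbp_age_r Target Pearson correlation between DBP and age.
#' @param dbp_intercept,dbp_slope,dbp_noise_sd Optional explicit overrides
#'   of the derived DBP model parameters.
#' @param dbp_range Clipping range for DBP (mmHg); the observed study range.
#' @param clip_dbp Clip DBP to `dbp_range`? Clipping is mild (about 1% of
#'   draws) and its effect on the calibrated correlation is negligible.
#' @param pp_anchor_ages,pp_anchor_means,pp_anchor_sds Two age anchors (the
#'   stratum mean ages) with pulse-pressure means/SDs (mmHg); PP is drawn
#'   normal with mean and SD linearly interpolated in age through these
#'   anchors, independent of DBP.
#' @param pp_min Lower clip for pulse pressure (mmHg) so that SBP > DBP.
#' @param stratum_threshold Age (years) splitting the two strata used for
#'   stratum-specific covariates.
#' @param sex_male_prob,bmi_mean,bmi_sd,waist_mean,waist_sd Length-2 vectors
#'   (young stratum, old stratum).
#' @param comorbidity_prev Named list of length-2 prevalence vectors for the
#'   binary flags `hypertension`, `diabetes`, `dyslipidemia`, `smoking`.
#' @param cavi0_coefficients,cavi_coefficients Named generating coefficients
#'   `(intercept, age, dbp, age_dbp)` of the regression-mode planes.
#' @param cavi0_target_r2,cavi_target_r2 Target model R-squared per index
#'   (regression mode), or `NULL`.
#' @param cavi0_noise_sd,cavi_noise_sd Explicit noise SD per index, or
#'   `NULL`. Supplying both an SD and a target R2 for the same index is an
#'   error.
#' @param pwv_intercept,pwv_slope,pwv_noise_sd Mechanistic PWV model
#'   `pwv = c0 + c1 * age + Normal(0, sigma)` (m/s); defaults are calibrated
#'   so the implied CAVI matches the stratum means and spreads of the study
#'   population (these are synthetic calibration values, not estimates).
#' @param constants [hemo_constants()] used by the mechanistic mode.
#'
#' @return A validated object of class `generator_config`.
#' @examples
#' cfg <- generator_config(n = 100, seed = 1)
#' cohort <- generate_cohort(cfg)
#' @export
generator_config <- function(n,
                             seed = 1,
                             mode = c("regression", "mechanistic"),
                             age_mean = 68.3,
                             age_sd = 14.4,
                             age_range = c(40, 96),
                             dbp_mean = 81.2,
                             dbp_sd = 10.7,
                             dbp_age_r = -0.464,
                             dbp_intercept = NULL,
                             dbp_slope = NULL,
                             dbp_noise_sd = NULL,
                             dbp_range = c(55, 109),
                             clip_dbp = TRUE,
                             pp_anchor_ages = c(56.86, 80.79),
                             pp_anchor_means = c(54.9, 60.07),
                             pp_anchor_sds = c(13.18, 14.53),
                             pp_min = 10,
                             stratum_threshold = 70,
                             sex_male_prob = c(0.28, 0.44),
                             bmi_mean = c(31.38, 25.84),
                             bmi_sd = c(4.82, 5.68),
                             waist_mean = c(103.6, 97.18),
                             waist_sd = c(13.88, 15.19),
                             comorbidity_prev = list(
                               hypertension = c(0.62, 0.78),
                               diabetes     = c(0.21, 0.29),
                               dyslipidemia = c(0.74, 0.58),
                               smoking      = c(0.24, 0.35)
                             ),
                             cavi0_coefficients = c(intercept = -30.301, age = 0.682,
                                                    dbp = 0.306, age_dbp = -0.005),
                             cavi_coefficients = c(intercept = -4.16, age = 0.175,
                                                   dbp = 0.072, age_dbp = -0.001),
                             cavi0_target_r2 = NULL,
                             cavi_target_r2 = NULL,
                             cavi0_noise_sd = NULL,
                             cavi_noise_sd = NULL,
                             pwv_intercept = 5.502,
                             pwv_slope = 0.0334,
                             pwv_noise_sd = 0.5,
                             constants = hemo_constants()) {
  mode <- match.arg(mode)
  if (!is.numeric(n) || length(n) != 1 || !is.finite(n) || n < 1) {
    abort("`n` must be a positive count.", class = "cavindex_config_error")
  }
  n <- as.integer(n)
  if (!is.numeric(seed) || length(seed) != 1 || !is.finite(seed)) {
    abort("`seed` must be a single integer.", class = "cavindex_config_error")
  }
  if (age_range[1] >= age_range[2]) {
    abort("`age_range` must be increasing.", class = "cavindex_config_error")
  }
  if (age_sd <= 0 || dbp_sd <= 0) {
    abort("`age_sd` and `dbp_sd` must be positive.", class = "cavindex_config_error")
  }
  prev <- unlist(comorbidity_prev)
  if (any(prev < 0) || any(prev > 1) || any(sex_male_prob < 0) || any(sex_male_prob > 1)) {
    abort("Prevalences and sex probabilities must lie in [0, 1].",
          class = "cavindex_config_error")
  }
  if (any(c(pp_anchor_sds, bmi_sd, waist_sd, pwv_noise_sd) < 0)) {
    abort("Standard deviations must be non-negative.", class = "cavindex_config_error")
  }
  for (cf in list(cavi0_coefficients, cavi_coefficients)) {
    if (!all(c("intercept", "age", "dbp", "age_dbp") %in% names(cf))) {
      abort("Generating coefficients need names intercept, age, dbp, age_dbp.",
            class = "cavindex_config_error")
    }
  }
  if (!is.null(cavi0_target_r2) && !is.null(cavi0_noise_sd)) {
    abort("Give either `cavi0_target_r2` or `cavi0_noise_sd`, not both.",
          class = "cavindex_config_error")
  }
  if (!is.null(cavi_target_r2) && !is.null(cavi_noise_sd)) {
    abort("Give either `cavi_target_r2` or `cavi_noise_sd`, not both.",
          class = "cavindex_config_error")
  }
  if (is.null(cavi0_target_r2) && is.null(cavi0_noise_sd)) cavi0_target_r2 <- 0.508
  if (is.null(cavi_target_r2) && is.null(cavi_noise_sd)) cavi_target_r2 <- 0.49

  # derive the DBP-versus-age model from the marginal targets unless the
  # user pins its parameters directly
  age_trunc <- truncnorm_moments(age_mean, age_sd, age_range[1], age_range[2])
  if (is.null(dbp_noise_sd)) dbp_noise_sd <- dbp_sd * sqrt(1 - dbp_age_r^2)
  if (is.null(dbp_slope)) {
    dbp_slope <- calibrate_dbp_slope(dbp_age_r, dbp_noise_sd, age_trunc$sd)
  }
  if (is.null(dbp_intercept)) dbp_intercept <- dbp_mean - dbp_slope * age_trunc$mean

  structure(
    list(
      n = n, seed = seed, mode = mode,
      age_mean = age_mean, age_sd = age_sd, age_range = age_range,
      age_trunc = age_trunc,
      dbp_mean = dbp_mean, dbp_sd = dbp_sd, dbp_age_r = dbp_age_r,
      dbp_intercept = dbp_intercept, dbp_slope = dbp_slope,
      dbp_noise_sd = dbp_noise_sd, dbp_range = dbp_range, clip_dbp = clip_dbp,
      pp_anchor_ages = pp_anchor_ages, pp_anchor_means = pp_anchor_means,
      pp_anchor_sds = pp_anchor_sds, pp_min = pp_min,
      stratum_threshold = stratum_threshold,
      sex_male_prob = sex_male_prob,
      bmi_mean = bmi_mean, bmi_sd = bmi_sd,
      waist_mean = waist_mean, waist_sd = waist_sd,
      comorbidity_prev = comorbidity_prev,
      cavi0_coefficients = cavi0_coefficients,
      cavi_coefficients = cavi_coefficients,
      cavi0_target_r2 = cavi0_target_r2, cavi_target_r2 = cavi_target_r2,
      cavi0_noise_sd = cavi0_noise_sd, cavi_noise_sd = cavi_noise_sd,
      pwv_intercept = pwv_intercept, pwv_slope = pwv_slope,
      pwv_noise_sd = pwv_noise_sd,
      constants = constants
    ),
    class = "generator_config"
  )
}

#' @export
print.generator_config <- function(x, ...) {
  cat(sprintf("<generator_config> n = %d, seed = %d, mode = %s\n",
              x$n, as.integer(x$seed), x$mode))
  cat(sprintf("  age ~ truncN(%g, %g) on [%g, %g]\n",
              x$age_mean, x$age_sd, x$age_range[1], x$age_range[2]))
  cat(sprintf("  dbp = %.3f %+.4f * age + N(0, %.3f), target r = %.3f\n",
              x$dbp_intercept, x$dbp_slope, x$dbp_noise_sd, x$dbp_age_r))
  invisible(x)
}

# linear interpolation in age through the two stratum anchors (straight
# line, extrapolated linearly outside the anchor ages)
interp_anchor <- function(age, anchor_ages, anchor_values) {
  slope <- (anchor_values[2] - anchor_values[1]) / (anchor_ages[2] - anchor_ages[1])
  anchor_values[1] + slope * (age - anchor_ages[1])
}

#' Sample the covariate block of a synthetic cohort
#'
#' Draws ages from the truncated normal model, DBP from the calibrated
#' linear-in-age model (clipped to the observed range), pulse pressure from
#' the age-interpolated model (independent of DBP), and sex, BMI, waist and
#' comorbidity flags per age stratum. Column generation order is fixed (age,
#' DBP, PP, sex, BMI, waist, hypertension, diabetes, dyslipidemia, smoking)
#' on a single RNG stream, so cohorts are reproducible given the seed.
#'
#' @param config A [generator_config()].
#' @return A tibble with columns `id`, `age`, `sex`, `bmi`, `waist`, `sbp`,
#'   `dbp`, `map`, `pp` and the four 0/1 comorbidity flags.
#' @export
sample_covariates <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  withr::with_seed(config$seed, sample_covariates_impl(config))
}

sample_covariates_impl <- function(config) {
  n <- config$n
  age <- rtruncnorm(n, config$age_mean, config$age_sd,
                    config$age_range[1], config$age_range[2])
  dbp <- config$dbp_intercept + config$dbp_slope * age +
    rnorm(n, 0, config$dbp_noise_sd)
  if (config$clip_dbp) {
    dbp <- pmin(pmax(dbp, config$dbp_range[1]), config$dbp_range[2])
  }
  pp <- rnorm(n,
              interp_anchor(age, config$pp_anchor_ages, config$pp_anchor_means),
              interp_anchor(age, config$pp_anchor_ages, config$pp_anchor_sds))
  pp <- pmax(pp, config$pp_min)
  old <- age >= config$stratum_threshold
  idx <- ifelse(old, 2L, 1L)
  sex <- ifelse(rbinom(n, 1, config$sex_male_prob[idx]) == 1, "male", "female")
  bmi <- pmax(rnorm(n, config$bmi_mean[idx], config$bmi_sd[idx]), 13)
  waist <- pmax(rnorm(n, config$waist_mean[idx], config$waist_sd[idx]), 50)
  flags <- lapply(config$comorbidity_prev, function(p) rbinom(n, 1, p[idx]))
  tibble::tibble(
    id = seq_len(n),
    age = age,
    sex = sex,
    bmi = bmi,
    waist = waist,
    sbp = dbp + pp,
    dbp = dbp,
    map = dbp + pp / 3,
    pp = pp,
    hypertension = flags$hypertension,
    diabetes = flags$diabetes,
    dyslipidemia = flags$dyslipidemia,
    smoking = flags$smoking
  )
}

# variance of a vector with the denominator n (population form); the noise
# calibration targets the population R2, not the n-1 sample estimator
var_pop <- function(x) mean((x - mean(x))^2)

FLAG_COLUMNS <- c("hypertension", "diabetes", "dyslipidemia", "smoking")

#' Generate a synthetic cohort
#'
#' Draws the covariate block with [sample_covariates()] and then the
#' stiffness indexes according to `config$mode`:
#'
#' * **regression**: `cavi0` and `cavi` are drawn from the configured
#'   generating planes `intercept + b_age*age + b_dbp*dbp + b_int*age*dbp`
#'   plus Gaussian noise whose SD is either given explicitly or calibrated
#'   to the target R-squared on the realized linear-predictor variance.
#' * **mechanistic**: a heart-ankle PWV is drawn from the linear aging model
#'   (independent of DBP given age, clipped at zero with a warning if the
#'   model produces negative speeds) and `cavi`/`cavi0` are computed through
#'   [cavi_from_pwv()] and [cavi0_from_pwv()]; the `pwv` column is kept.
#'
#' The full table is a deterministic function of the configuration,
#' including the seed.
#'
#' @param config A [generator_config()].
#' @return A cohort tibble (one row per subject).
#' @examples
#' cohort <- generate_cohort(generator_config(n = 50, seed = 7))
#' dplyr::glimpse(cohort)
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  withr::with_seed(config$seed, {
    tab <- sample_covariates_impl(config)
    if (config$mode == "regression") {
      mu0 <- eval_plane(config$cavi0_coefficients, tab$age, tab$dbp)
      muc <- eval_plane(config$cavi_coefficients, tab$age, tab$dbp)
      sd0 <- config$cavi0_noise_sd %||%
        calibrate_noise_sd(config$cavi0_target_r2, var_pop(mu0))
      sdc <- config$cavi_noise_sd %||%
        calibrate_noise_sd(config$cavi_target_r2, var_pop(muc))
      tab$cavi0 <- mu0 + rnorm(config$n, 0, sd0)
      tab$cavi <- muc + rnorm(config$n, 0, sdc)
      tab <- tab[c(setdiff(names(tab), c("cavi", "cavi0", FLAG_COLUMNS)),
                   "cavi", "cavi0", FLAG_COLUMNS)]
    } else {
      pwv <- config$pwv_intercept + config$pwv_slope * tab$age +
        rnorm(config$n, 0, config$pwv_noise_sd)
      if (any(pwv < 0)) {
        warn(sprintf("PWV model produced %d negative speed(s); clipped to 0.",
                     sum(pwv < 0)))
        pwv <- pmax(pwv, 0)
      }
      tab$pwv <- pwv
      tab$cavi <- cavi_from_pwv(tab$sbp, tab$dbp, pwv, config$constants)
      tab$cavi0 <- cavi0_from_pwv(tab$dbp, pwv,
                                  rho = config$constants$rho,
                                  pref = config$constants$pref)
      tab <- tab[c(setdiff(names(tab), c("pwv", "cavi", "cavi0", FLAG_COLUMNS)),
                   "pwv", "cavi", "cavi0", FLAG_COLUMNS)]
    }
    tab
  })
}

eval_plane <- function(coefs, age, dbp) {
  coefs[["intercept"]] + coefs[["age"]] * age + coefs[["dbp"]] * dbp +
    coefs[["age_dbp"]] * age * dbp
}
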