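#' Device and physical constants for stiffness-index formulas
#'
#' Bundles the constants entering the CAVI formula chain: the proprietary
#' device scale `a` and offset `b` that map the Bramwell-Hill stiffness
#' parameter beta onto the CAVI scale, the blood density `rho`, and the
#' reference pressure `pref` anchoring CAVI0. The device vendor does not
#' publish `a` and `b`; the defaults `a = 1`, `b = 0` therefore work on the
#' raw beta scale. All cross-formula identities (conversion, inversion)
#' hold for any valid `(a, b)`.
#'
#' @param scale_a Dimensionless scale applied to beta. Must be > 0.
#' @param offset_b Dimensionless offset added after scaling.
#' @param rho Blood density in kg/m^3. Default 1050.
#' @param pref Reference pressure in mmHg anchoring CAVI0. Default 100.
#'
#' @return An object of class `hemo_constants` (a validated list).
#' @examples
#' hemo_constants()
#' hemo_constants(scale_a = 0.7, offset_b = 3)
#' @export
hemo_constants <- function(scale_a = 1, offset_b = 0, rho = 1050, pref = 100) {
  if (!is.numeric(scale_a) || length(scale_a) != 1 || !is.finite(scale_a) || scale_a <= 0) {
    abort("`scale_a` must be a single positive number.", class = "cavindex_config_error")
  }
  if (!is.numeric(offset_b) || length(offset_b) != 1 || !is.finite(offset_b)) {
    abort("`offset_b` must be a single finite number.", class = "cavindex_config_error")
  }
  if (!is.numeric(rho) || length(rho) != 1 || !is.finite(rho) || rho <= 0) {
    abort("`rho` must be a single positive number (kg/m^3).", class = "cavindex_config_error")
  }
  if (!is.numeric(pref) || length(pref) != 1 || !is.finite(pref) || pref <= 0) {
    abort("`pref` must be a single positive pressure (mmHg).", class = "cavindex_config_error")
  }
  structure(
    list(scale_a = scale_a, offset_b = offset_b, rho = rho, pref = pref),
    class = "hemo_constants"
  )
}

#' @export
print.hemo_constants <- function(x, ...) {
  cat("<hemo_constants>\n")
  cat(sprintf("  scale a:  %g\n  offset b: %g\n  rho:      %g kg/m^3\n  Pref:     %g mmHg\n",
              x$scale_a, x$offset_b, x$rho, x$pref))
  invisible(x)
}

#' Convert pressure from mmHg to pascal
#'
#' Pressures are measured by cuff in mmHg but enter the stiffness formulas
#' in SI units; 1 mmHg = 133.322 Pa. Negative inputs are permitted so that
#' pressure differences can be converted.
#'
#' @param p Pressure(s) in mmHg.
#' @return Pressure(s) in Pa.
#' @examples
#' mmhg_to_pa(100) # 13332.2
#' @export
mmhg_to_pa <- function(p) {
  if (!is.numeric(p)) abort("`p` must be numeric.", class = "cavindex_contract_error")
  p * MMHG_TO_PA
}

#' Pressure summaries for a systolic/diastolic pair
#'
#' Derives pulse pressure `pp = sbp - dbp`, mean arterial pressure
#' (by default the sphygmomanometric convention `dbp + pp/3`; the fraction
#' is configurable) and the pressure difference in Pa used by the formula
#' chain. Enforces the pressure-pair invariant `sbp > dbp > 0`.
#'
#' @param sbp,dbp Systolic and diastolic pressures (mmHg), vectorised.
#' @param pp_fraction Fraction of pulse pressure added to DBP for MAP.
#' @return A tibble with columns `sbp`, `dbp`, `pp`, `map`, `delta_p_pa`.
#' @examples
#' pressure_summary(140, 80)
#' @export
pressure_summary <- function(sbp, dbp, pp_fraction = 1 / 3) {
  check_pressure_pair(sbp, dbp)
  pp <- sbp - dbp
  tibble::tibble(
    sbp = sbp, dbp = dbp, pp = pp,
    map = dbp + pp_fraction * pp,
    delta_p_pa = mmhg_to_pa(pp)
  )
}

# shared validation of the sbp > dbp > 0 invariant; sbp == dbp is the
# degenerate 0/0 case of the Bramwell-Hill bracket and is always an error
check_pressure_pair <- function(sbp, dbp) {
  if (!is.numeric(sbp) || !is.numeric(dbp)) {
    abort("Pressures must be numeric.", class = "cavindex_contract_error")
  }
  if (any(!is.finite(sbp)) || any(!is.finite(dbp))) {
    abort("Pressures must be finite.", class = "cavindex_invalid_pressure")
  }
  if (any(dbp <= 0)) {
    abort("DBP must be strictly positive.", class = "cavindex_invalid_pressure")
  }
  if (any(sbp == dbp)) {
    abort("SBP equal to DBP: the stiffness formulas are degenerate (0/0).",
          class = "cavindex_degenerate_pressure")
  }
  if (any(sbp < dbp)) {
    abort("SBP must exceed DBP.", class = "cavindex_invalid_pressure")
  }
  invisible(TRUE)
}

#' Heart-ankle pulse wave velocity from transit times
#'
#' The device measures the time from the second heart sound to the brachial
#' dicrotic notch (`tb`) and from the brachial to the ankle pulse wave
#' (`tba`); the heart-ankle PWV is the path length from the aortic valve to
#' the ankle divided by their sum.
#'
#' @param path_length Aortic valve to ankle distance in metres.
#' @param tb,tba Transit-time components in seconds.
#' @return PWV in m/s.
#' @examples
#' heart_ankle_pwv(1.3, 0.06, 0.10) # 8.125
#' @export
heart_ankle_pwv <- function(path_length, tb, tba) {
  if (any(path_length <= 0)) {
    abort("`path_length` must be positive.", class = "cavindex_invalid_timing")
  }
  if (any(tb < 0) || any(tba < 0)) {
    abort("Transit times must be non-negative.", class = "cavindex_invalid_timing")
  }
  t_total <- tb + tba
  if (any(t_total <= 0)) {
    abort("Total transit time must be positive.", class = "cavindex_invalid_timing")
  }
  path_length / t_total
}

#' Bramwell-Hill stiffness parameter beta from PWV
#'
#' `beta = 2 rho PWV^2 ln(SBP/DBP) / (SBP - DBP)` with the pressure
#' difference in Pa. This is the bracketed quantity inside the CAVI formula
#' and coincides with the diameter-based stiffness parameter under the
#' Bramwell-Hill substitution.
#'
#' @inheritParams pressure_summary
#' @param pwv Pulse wave velocity in m/s (non-negative).
#' @param rho Blood density in kg/m^3.
#' @return Dimensionless beta.
#' @examples
#' beta_from_pwv(140, 80, 8) # 9.402
#' @export
beta_from_pwv <- function(sbp, dbp, pwv, rho = 1050) {
  check_pressure_pair(sbp, dbp)
  if (any(pwv < 0)) abort("`pwv` must be non-negative.", class = "cavindex_contract_error")
  2 * rho * pwv^2 * log(sbp / dbp) / mmhg_to_pa(sbp - dbp)
}

#' CAVI from pulse wave velocity
#'
#' `CAVI = a * beta + b` where beta is the Bramwell-Hill stiffness
#' parameter and `(a, b)` the device constants.
#'
#' @inheritParams beta_from_pwv
#' @param constants A [hemo_constants()] object.
#' @return Dimensionless CAVI.
#' @examples
#' cavi_from_pwv(140, 80, 8) # 9.402 on the raw beta scale
#' cavi_from_pwv(140, 80, 8, hemo_constants(scale_a = 0.7, offset_b = 3))
#' @export
cavi_from_pwv <- function(sbp, dbp, pwv, constants = hemo_constants()) {
  stopifnot(inherits(constants, "hemo_constants"))
  constants$scale_a * beta_from_pwv(sbp, dbp, pwv, rho = constants$rho) + constants$offset_b
}

#' CAVI0 from pulse wave velocity
#'
#' The pressure-referenced index
#' `CAVI0 = 2 rho PWV^2 / DBP_Pa - ln(DBP / Pref)`, which depends on the
#' diastolic pressure alone and decreases strictly in DBP at fixed PWV --
#' the mechanistic root of its behaviour in older, low-DBP subjects.
#'
#' @param dbp Diastolic pressure in mmHg (positive).
#' @param pwv Pulse wave velocity in m/s.
#' @param rho Blood density in kg/m^3.
#' @param pref Reference pressure in mmHg.
#' @return Dimensionless CAVI0.
#' @examples
#' cavi0_from_pwv(100, 8) # 10.081 (log term vanishes at DBP = Pref)
#' cavi0_from_pwv(80, 8)  # 12.824
#' @export
cavi0_from_pwv <- function(dbp, pwv, rho = 1050, pref = 100) {
  if (any(!is.finite(dbp)) || any(dbp <= 0)) {
    abort("DBP must be positive and finite.", class = "cavindex_invalid_pressure")
  }
  if (any(pref <= 0)) abort("`pref` must be positive.", class = "cavindex_invalid_pressure")
  if (any(pwv < 0)) abort("`pwv` must be non-negative.", class = "cavindex_contract_error")
  2 * rho * pwv^2 / mmhg_to_pa(dbp) - log(dbp / pref)
}

#' Convert CAVI to CAVI0
#'
#' Algebraic conversion that undoes the device scaling and re-references the
#' index to `Pref`:
#' `CAVI0 = ((CAVI - b)/a) * (SBP/DBP - 1) / ln(SBP/DBP) - ln(DBP/Pref)`.
#' It is exactly the composition of the PWV implied by CAVI with the direct
#' CAVI0 formula, so its output does not depend on `(a, b)` when the input
#' CAVI was produced with the same constants.
#'
#' @param cavi CAVI value(s).
#' @inheritParams pressure_summary
#' @param constants A [hemo_constants()] object.
#' @return Dimensionless CAVI0.
#' @examples
#' cavi0_from_cavi(9.402, 140, 80) # 12.824
#' @export
cavi0_from_cavi <- function(cavi, sbp, dbp, constants = hemo_constants()) {
  stopifnot(inherits(constants, "hemo_constants"))
  check_pressure_pair(sbp, dbp)
  beta <- (cavi - constants$offset_b) / constants$scale_a
  ratio <- sbp / dbp
  beta * (ratio - 1) / log(ratio) - log(dbp / constants$pref)
}

#' Pressure-normalised stiffness parameter beta0
#'
#' `beta0 = beta - ln(DBP / Pref)`: re-references beta to the standard
#' pressure so that subjects are comparable across diastolic pressures.
#'
#' @param beta Stiffness parameter beta.
#' @param dbp Diastolic pressure in mmHg (positive).
#' @param pref Reference pressure in mmHg.
#' @return Dimensionless beta0.
#' @examples
#' beta0_from_beta(9.402, 80) # 9.625
#' @export
beta0_from_beta <- function(beta, dbp, pref = 100) {
  if (any(!is.finite(dbp)) || any(dbp <= 0) || any(pref <= 0)) {
    abort("`dbp` and `pref` must be positive.", class = "cavindex_invalid_pressure")
  }
  beta - log(dbp / pref)
}

#' Pulse wave velocity implied by a CAVI value
#'
#' Inverse of [cavi_from_pwv()]: recovers the PWV whose CAVI (under the
#' supplied constants and pressures) equals the input. Used by the
#' mechanistic cohort generator and by round-trip checks.
#'
#' @inheritParams cavi0_from_cavi
#' @return PWV in m/s.
#' @examples
#' pwv_from_cavi(9.402, 140, 80) # 8
#' @export
pwv_from_cavi <- function(cavi, sbp, dbp, constants = hemo_constants()) {
  stopifnot(inherits(constants, "hemo_constants"))
  check_pressure_pair(sbp, dbp)
  beta <- (cavi - constants$offset_b) / constants$scale_a
  if (any(beta < 0)) {
    abort("CAVI below the device offset implies a negative beta.",
          class = "cavindex_negative_beta")
  }
  sqrt(beta * mmhg_to_pa(sbp - dbp) / (2 * constants$rho * log(sbp / dbp)))
}

#' Add stiffness indexes to a cohort table from PWV
#'
#' Computes `cavi` and `cavi0` columns from `sbp`, `dbp` and `pwv` columns,
#' returning the table with the new columns appended.
#'
#' @param data A data frame with numeric `sbp`, `dbp` and `pwv` columns.
#' @param constants A [hemo_constants()] object.
#' @return A tibble with `cavi` and `cavi0` columns added.
#' @export
add_indices_from_pwv <- function(data, constants = hemo_constants()) {
  require_columns(data, c("sbp", "dbp", "pwv"))
  dplyr::mutate(
    tibble::as_tibble(data),
    cavi = cavi_from_pwv(.data$sbp, .data$dbp, .data$pwv, constants),
    cavi0 = cavi0_from_pwv(.data$dbp, .data$pwv,
                           rho = constants$rho, pref = constants$pref)
  )
}

#' Add a CAVI0 column converted from CAVI
#'
#' Table-level wrapper around [cavi0_from_cavi()].
#'
#' @param data A data frame with numeric `cavi`, `sbp`, `dbp` columns.
#' @param constants A [hemo_constants()] object matching the device that
#'   produced the `cavi` column.
#' @return A tibble with a `cavi0` column added (overwritten if present).
#' @export
add_cavi0_from_cavi <- function(data, constants = hemo_constants()) {
  require_columns(data, c("cavi", "sbp", "dbp"))
  dplyr::mutate(
    tibble::as_tibble(data),
    cavi0 = cavi0_from_cavi(.data$cavi, .data$sbp, .data$dbp, constants)
  )
}

require_columns <- function(data, cols) {
  missing <- setdiff(cols, names(data))
  if (length(missing)) {
    abort(paste0("Missing required column(s): ", paste(missing, collapse = ", ")),
          class = "cavindex_schema_error")
  }
  invisible(TRUE)
}
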