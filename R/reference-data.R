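#' Reference stratum summary of the calibration study population
#'
#' The published stratum-level summary (split at 70 years; n = 100 under 70,
#' n = 91 at or over) of the 191-patient geriatric cohort against which the
#' synthetic generator's defaults are calibrated. `"continuous"` returns
#' per-variable mean/SD/median/quartiles per stratum; `"binary"` returns the
#' comorbidity and sex counts.
#'
#' @param which `"continuous"` or `"binary"`.
#' @return A tibble.
#' @examples
#' study_population_reference("binary")
#' @export
study_population_reference <- function(which = c("continuous", "binary")) {
  which <- match.arg(which)
  path <- system.file("extdata",
                      paste0("study_summary_", which, ".csv"),
                      package = "cavindex", mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}
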