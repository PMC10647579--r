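#' Predicted-index surface plot
#'
#' One line of predicted index values against DBP per selected age -- the
#' standard display of the age-by-DBP interaction: lines fan out and cross
#' where the DBP slope changes sign with age.
#'
#' @param object A `stiffness_fit`.
#' @param ages Ages (years) at which to draw lines.
#' @param dbp_range DBP interval (mmHg).
#' @param ... Unused.
#' @return A ggplot object.
#' @examples
#' cohort <- generate_cohort(generator_config(n = 191, seed = 1))
#' autoplot(fit_interaction_model(cohort, "cavi0"))
#' @method autoplot stiffness_fit
#' @export
autoplot.stiffness_fit <- function(object, ages = seq(40, 90, by = 10),
                                   dbp_range = c(50, 110), ...) {
  grid <- prediction_grid(object, ages = ages, dbp_range = dbp_range)
  ggplot2::ggplot(grid, ggplot2::aes(x = .data$dbp, y = .data$predicted,
                                     colour = factor(.data$age),
                                     group = .data$age)) +
    ggplot2::geom_line(linewidth = 0.7) +
    ggplot2::labs(
      x = "DBP (mmHg)",
      y = paste("Predicted", toupper(object$response)),
      colour = "Age (years)"
    ) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.stiffness_fit
#' @param fit A `stiffness_fit`.
#' @export
plot_prediction_surface <- function(fit, ages = seq(40, 90, by = 10),
                                    dbp_range = c(50, 110)) {
  autoplot.stiffness_fit(fit, ages = ages, dbp_range = dbp_range)
}

#' Stratum-mean plot for a trend object
#'
#' Per-decade means with standard-error bars for the index underlying a
#' [trend_across_strata()] result.
#'
#' @param object A `strata_trend`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot strata_trend
#' @export
autoplot.strata_trend <- function(object, ...) {
  m <- object$stratum_means
  ggplot2::ggplot(m, ggplot2::aes(x = .data$stratum, y = .data$mean, group = 1)) +
    ggplot2::geom_line(colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean - .data$se,
                                          ymax = .data$mean + .data$se)) +
    ggplot2::labs(x = "Age stratum (years)",
                  y = paste("Mean", toupper(object$index)),
                  subtitle = if (object$adjusted) "DBP-adjusted trend" else NULL) +
    ggplot2::theme_minimal()
}

#' Index means by decade for both stiffness indexes
#'
#' Displays CAVI and CAVI0 decade means side by side, the display in which
#' CAVI0 visibly pulls away from CAVI in the oldest strata.
#'
#' @param data A cohort data frame with `age`, `cavi`, `cavi0`.
#' @param breaks Left edges of the decade strata.
#' @return A ggplot object.
#' @export
plot_indexes_by_stratum <- function(data, breaks = seq(40, 90, by = 10)) {
  require_columns(data, c("age", "cavi", "cavi0"))
  edges <- c(breaks, Inf)
  labels <- c(paste(breaks[-length(breaks)], breaks[-1] - 1, sep = "-"),
              paste0(breaks[length(breaks)], "+"))
  long <- data |>
    dplyr::mutate(stratum = cut(.data$age, edges, labels = labels,
                                right = FALSE, include.lowest = TRUE)) |>
    dplyr::filter(!is.na(.data$stratum)) |>
    tidyr::pivot_longer(c("cavi", "cavi0"), names_to = "index",
                        values_to = "value") |>
    dplyr::group_by(.data$stratum, .data$index) |>
    dplyr::summarise(
      mean = mean(.data$value),
      se = sd(.data$value) / sqrt(dplyr::n()),
      .groups = "drop"
    )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$stratum, y = .data$mean,
                                     colour = toupper(.data$index),
                                     group = .data$index)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean - .data$se,
                                          ymax = .data$mean + .data$se)) +
    ggplot2::labs(x = "Age stratum (years)", y = "Mean index value",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
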