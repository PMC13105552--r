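#' Plot state occupancy of a cohort run
#'
#' Stacked-area chart of the cohort mass per health-state class over age.
#'
#' @param object A `crc_outcome`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot crc_outcome
#' @export
autoplot.crc_outcome <- function(object, ...) {
  states <- health_states()
  long <- object$trace |>
    tidyr::pivot_longer(-"age", names_to = "state", values_to = "mass") |>
    dplyr::left_join(states[, c("state", "class")], by = "state") |>
    dplyr::group_by(.data$age, .data$class) |>
    dplyr::summarise(mass = sum(.data$mass), .groups = "drop")
  ggplot2::ggplot(long, ggplot2::aes(.data$age, .data$mass,
                                     fill = .data$class)) +
    ggplot2::geom_area() +
    ggplot2::labs(x = "Cohort mean age (years)",
                  y = "Cohort proportion", fill = "State class",
                  title = paste0("State occupancy: ",
                                 object$strategy$frequency, " from age ",
                                 object$strategy$entry_age)) +
    ggplot2::theme_minimal()
}

#' Plot the cost-effectiveness plane of a strategy comparison
#'
#' @param object A `crc_cea` from [rank_and_compare()].
#' @param ... Unused.
#' @return A ggplot object: incremental QALYs vs incremental cost versus
#'   the baseline, path drawn in QALY order.
#' @method autoplot crc_cea
#' @export
autoplot.crc_cea <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(.data$inc_qaly_vs_none,
                               .data$inc_cost_vs_none / 1e3,
                               label = .data$strategy)) +
    ggplot2::geom_path(colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::geom_text(vjust = -0.6, size = 3) +
    ggplot2::labs(x = "Incremental QALYs vs no screening",
                  y = "Incremental cost vs no screening (thousand USD)") +
    ggplot2::theme_minimal()
}

#' Plot cost-effectiveness acceptability curves
#'
#' @param object A `crc_ceac` from [ceac()].
#' @param what `"p_optimal"` (default) or `"p_ce"`.
#' @param ... Unused.
#' @return A ggplot object, one panel per entry age.
#' @method autoplot crc_ceac
#' @export
autoplot.crc_ceac <- function(object, what = c("p_optimal", "p_ce"), ...) {
  what <- match.arg(what)
  ggplot2::ggplot(object,
                  ggplot2::aes(.data$wtp, .data[[what]],
                               colour = .data$strategy)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(ggplot2::vars(.data$entry_age)) +
    ggplot2::labs(x = "Willingness to pay (USD/QALY)",
                  y = if (what == "p_optimal") "Probability optimal"
                  else "Probability cost-effective",
                  colour = "Strategy") +
    ggplot2::theme_minimal()
}

#' Plot the PSA cloud on the cost-effectiveness plane
#'
#' @param object A `crc_psa`.
#' @param ... Unused.
#' @return A ggplot object: per-draw incremental cost vs incremental QALYs
#'   versus no screening, coloured by strategy.
#' @method autoplot crc_psa
#' @export
autoplot.crc_psa <- function(object, ...) {
  base <- object$draws |>
    dplyr::filter(.data$strategy == "none") |>
    dplyr::select("draw", "entry_age", base_qalys = "qalys",
                  base_cost = "cost")
  pts <- object$draws |>
    dplyr::filter(.data$strategy != "none") |>
    dplyr::left_join(base, by = c("draw", "entry_age"))
  ggplot2::ggplot(pts,
                  ggplot2::aes(.data$qalys - .data$base_qalys,
                               (.data$cost - .data$base_cost) / 1e3,
                               colour = .data$strategy)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.7) +
    ggplot2::facet_wrap(ggplot2::vars(.data$entry_age)) +
    ggplot2::labs(x = "Incremental QALYs vs no screening",
                  y = "Incremental cost (thousand USD)",
                  colour = "Strategy") +
    ggplot2::theme_minimal()
}
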