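#' Override a parameter's base value
#'
#' Sets the base-case value of every row of `name` (all age bands for
#' banded parameters, unless `age` selects one band). Used by one-way
#' sweeps and scenario analyses.
#'
#' @param params A `crc_param_set`.
#' @param name Parameter name.
#' @param value New base value.
#' @param age Optional age selecting a single band.
#' @return The modified `crc_param_set`.
#' @export
set_param <- function(params, name, value, age = NULL) {
  rows <- params$name == name
  if (!any(rows)) stop("unknown parameter: ", name, call. = FALSE)
  if (!is.null(age)) {
    rows <- rows & !is.na(params$age_low) & params$age_low <= age &
      age <= params$age_high
    if (!any(rows)) stop("no band of '", name, "' covers age ", age,
                         call. = FALSE)
  }
  params$base[rows] <- value
  params
}

#' One-way deterministic sensitivity sweep
#'
#' Re-runs the strategy grid once per candidate value of a single
#' parameter, holding every other parameter at base case, and reports each
#' strategy's outcomes and ICER versus no screening, plus whether the
#' QALY ranking of strategies changed relative to the base case.
#'
#' @param params A `crc_param_set` (base case).
#' @param name Parameter to vary (all age bands move together).
#' @param values Numeric vector of values; each must lie in the parameter's
#'   support (`[0, 1]` for probabilities and utilities, non-negative for
#'   costs). Set `limit_to_ui = TRUE` to additionally require values inside
#'   the row's 95% uncertainty interval.
#' @param entry_ages,frequencies Strategy grid (defaults: entry age 42 with
#'   all six frequencies).
#' @param limit_to_ui Restrict values to the row's uncertainty interval
#'   (default `FALSE`: published sweeps vary adherence well beyond it).
#' @param ... Passed to [run_cohort()].
#' @return A `crc_oneway` tibble: one row per (value, entry age, strategy)
#'   with `qalys`, `cost`, `deaths_averted`, `icer_vs_none`, `status`, and
#'   `ranking_changed`.
#' @export
one_way_sweep <- function(params, name, values,
                          entry_ages = 42L,
                          frequencies = c("once", "every_10y", "every_5y",
                                          "every_3y", "every_2y", "annual"),
                          limit_to_ui = FALSE, ...) {
  rows <- params[params$name == name, ]
  if (nrow(rows) == 0) stop("unknown parameter: ", name, call. = FALSE)
  if (rows$units[1] %in% c("probability", "utility") &&
      (any(values < 0) || any(values > 1))) {
    stop("sweep values outside [0, 1] for a probability/utility parameter",
         call. = FALSE)
  }
  if (rows$units[1] == "USD" && any(values < 0)) {
    stop("negative sweep values for a cost parameter", call. = FALSE)
  }
  if (limit_to_ui &&
      (any(values < min(rows$ui_low)) || any(values > max(rows$ui_high)))) {
    stop("sweep values outside the parameter's uncertainty interval",
         call. = FALSE)
  }
  base_rank <- NULL
  out <- purrr::map_dfr(values, function(v) {
    p <- set_param(params, name, v)
    grid <- run_strategy_grid(p, entry_ages = entry_ages,
                              frequencies = frequencies, ...)
    cea <- grid |>
      dplyr::group_by(.data$entry_age) |>
      dplyr::group_modify(~ rank_and_compare(.x)) |>
      dplyr::ungroup()
    cea$value <- v
    cea
  })
  base_order <- out |>
    dplyr::filter(.data$value == values[1]) |>
    dplyr::arrange(.data$entry_age, .data$qalys) |>
    dplyr::pull(.data$strategy)
  out <- out |>
    dplyr::group_by(.data$value) |>
    dplyr::mutate(ranking_changed = {
      ord <- .data$strategy[order(.data$entry_age, .data$qalys)]
      !identical(ord, base_order)
    }) |>
    dplyr::ungroup() |>
    dplyr::relocate("value")
  class(out) <- c("crc_oneway", class(out))
  out
}

#' Probabilistic sensitivity analysis
#'
#' Monte-Carlo re-evaluation of the strategy grid: per draw, one joint
#' parameter sample (every parameter drawn independently from its declared
#' distribution, age-banded families independently per band) and a full
#' grid run. Per-draw seeds are derived deterministically from the master
#' seed, so a given draw index always sees the same parameters regardless
#' of how many draws are requested.
#'
#' @param params A `crc_param_set`.
#' @param n_draws Number of Monte-Carlo draws (the published analysis used
#'   10,000; scaled-down runs are routine for testing).
#' @param seed Master seed.
#' @param entry_ages,frequencies Strategy grid (default: entry age 42, all
#'   six frequencies).
#' @param ... Passed to [run_cohort()].
#' @return A `crc_psa`: list with `draws` (tibble draw x entry_age x
#'   strategy with `qalys`, `cost`), `base` (base-case grid), `n_draws`,
#'   `seed`.
#' @export
run_psa <- function(params, n_draws, seed,
                    entry_ages = 42L,
                    frequencies = c("once", "every_10y", "every_5y",
                                    "every_3y", "every_2y", "annual"),
                    ...) {
  stopifnot(n_draws >= 1)
  draws <- purrr::map_dfr(seq_len(n_draws), function(i) {
    draw_seed <- (as.integer(seed) + 104729L * i) %% .Machine$integer.max
    p <- sample_parameter_draw(params, draw_seed)
    grid <- run_strategy_grid(p, entry_ages = entry_ages,
                              frequencies = frequencies, ...)
    tibble::tibble(draw = i, entry_age = grid$entry_age,
                   strategy = grid$strategy, qalys = grid$qalys,
                   cost = grid$cost)
  })
  base <- run_strategy_grid(params, entry_ages = entry_ages,
                            frequencies = frequencies, ...)
  structure(
    list(draws = draws,
         base = tibble::as_tibble(base)[, c("entry_age", "strategy",
                                            "qalys", "cost")],
         n_draws = n_draws, seed = seed),
    class = "crc_psa"
  )
}

#' Summarise a PSA: uncertainty intervals and cost-effectiveness
#' probabilities
#'
#' @param object A `crc_psa`.
#' @param wtp Willingness-to-pay threshold for the cost-effectiveness
#'   probability (default three times per-capita GDP).
#' @param ... Unused.
#' @return Tibble per (entry age, strategy): 2.5/50/97.5 percentiles of
#'   QALYs, costs and of the per-draw ICER versus no screening, and
#'   `p_ce`, the fraction of draws with non-negative net monetary benefit
#'   versus no screening at `wtp`.
#' @export
summary.crc_psa <- function(object, wtp = ce_thresholds()$three_gdp, ...) {
  draws <- object$draws
  base <- draws |>
    dplyr::filter(.data$strategy == "none") |>
    dplyr::select("draw", "entry_age", base_qalys = "qalys",
                  base_cost = "cost")
  draws |>
    dplyr::filter(.data$strategy != "none") |>
    dplyr::left_join(base, by = c("draw", "entry_age")) |>
    dplyr::mutate(
      dq = .data$qalys - .data$base_qalys,
      dc = .data$cost - .data$base_cost,
      icer = ifelse(.data$dq > 0, .data$dc / .data$dq, NA_real_),
      nmb = wtp * .data$dq - .data$dc
    ) |>
    dplyr::group_by(.data$entry_age, .data$strategy) |>
    dplyr::summarise(
      qalys_lo = stats::quantile(.data$qalys, 0.025),
      qalys_med = stats::median(.data$qalys),
      qalys_hi = stats::quantile(.data$qalys, 0.975),
      cost_lo = stats::quantile(.data$cost, 0.025),
      cost_med = stats::median(.data$cost),
      cost_hi = stats::quantile(.data$cost, 0.975),
      icer_lo = stats::quantile(.data$icer, 0.025, na.rm = TRUE),
      icer_med = stats::median(.data$icer, na.rm = TRUE),
      icer_hi = stats::quantile(.data$icer, 0.975, na.rm = TRUE),
      p_ce = mean(.data$nmb >= 0),
      .groups = "drop"
    )
}

#' Cost-effectiveness acceptability curves
#'
#' At each willingness-to-pay value, a strategy is cost-effective versus
#' the no-screening baseline when its net monetary benefit
#' `wtp * dQALY - dCost` is non-negative, and optimal when it attains the
#' maximum net monetary benefit among all strategies of its entry age
#' (including no screening). Probabilities are fractions of PSA draws.
#'
#' @param psa A `crc_psa`.
#' @param wtp_grid Willingness-to-pay grid in USD/QALY (default 0 to
#'   106,470 — twice the 3x-GDP threshold — in 500-USD steps).
#' @return A `crc_ceac` tibble: `wtp`, `entry_age`, `strategy`, `p_ce`,
#'   `p_optimal`; at each `wtp` the per-entry-age `p_optimal` values sum
#'   to 1.
#' @export
ceac <- function(psa, wtp_grid = seq(0, 106470, by = 500)) {
  stopifnot(inherits(psa, "crc_psa"), nrow(psa$draws) > 0)
  draws <- psa$draws
  base <- draws |>
    dplyr::filter(.data$strategy == "none") |>
    dplyr::select("draw", "entry_age", base_qalys = "qalys",
                  base_cost = "cost")
  aug <- draws |>
    dplyr::left_join(base, by = c("draw", "entry_age")) |>
    dplyr::mutate(dq = .data$qalys - .data$base_qalys,
                  dc = .data$cost - .data$base_cost)
  out <- purrr::map_dfr(wtp_grid, function(lambda) {
    aug |>
      dplyr::mutate(nmb = lambda * .data$dq - .data$dc) |>
      dplyr::group_by(.data$draw, .data$entry_age) |>
      dplyr::mutate(optimal = .data$nmb == max(.data$nmb)) |>
      # ties (e.g. identical schedules) are split evenly so probabilities
      # still sum to one
      dplyr::mutate(optimal = .data$optimal / sum(.data$optimal)) |>
      dplyr::ungroup() |>
      dplyr::group_by(.data$entry_age, .data$strategy) |>
      dplyr::summarise(
        p_ce = mean(.data$nmb >= 0),
        p_optimal = mean(.data$optimal),
        .groups = "drop"
      ) |>
      dplyr::mutate(wtp = lambda, .before = 1L)
  })
  class(out) <- c("crc_ceac", class(out))
  out
}
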