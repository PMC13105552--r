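#' Willingness-to-pay thresholds
#'
#' The programme's benchmarks: three times the 2023 per-capita GDP (USD
#' 53,235 per QALY) and the chronic-disease threshold of 1.76 times
#' per-capita GDP.
#'
#' @param gdp_per_capita Per-capita GDP in USD (default 17,745, i.e. one
#'   third of 53,235).
#' @return One-row tibble: `per_capita_gdp`, `chronic` (1.76x), `three_gdp`
#'   (3x).
#' @export
ce_thresholds <- function(gdp_per_capita = 17745) {
  stopifnot(gdp_per_capita > 0)
  tibble::tibble(
    per_capita_gdp = gdp_per_capita,
    chronic = 1.76 * gdp_per_capita,
    three_gdp = 3 * gdp_per_capita
  )
}

# round half away from zero, the convention of the printed tables
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Incremental cost-effectiveness ratio
#'
#' @param delta_cost Incremental cost in USD (vectorised).
#' @param delta_qaly Incremental QALYs.
#' @return Tibble with `delta_cost`, `delta_qaly`, `icer` (USD per QALY,
#'   rounded to the nearest dollar; `NA` when not meaningful) and `status`:
#'   `"ok"`, `"dominated"` (QALY loss at non-negative cost), `"dominant"`
#'   (QALY gain at non-positive cost) or `"undefined"` (both deltas zero).
#' @export
#' @examples
#' compute_icer(12233000, 1821)
compute_icer <- function(delta_cost, delta_qaly) {
  stopifnot(length(delta_cost) == length(delta_qaly))
  status <- dplyr::case_when(
    delta_cost == 0 & delta_qaly == 0 ~ "undefined",
    delta_qaly <= 0 & delta_cost >= 0 ~ "dominated",
    delta_qaly > 0 & delta_cost <= 0 ~ "dominant",
    TRUE ~ "ok"
  )
  icer <- ifelse(status == "ok",
                 round_half_up(delta_cost / delta_qaly), NA_real_)
  if (any(status == "undefined")) {
    warning("ICER undefined where both deltas are zero", call. = FALSE)
  }
  tibble::tibble(delta_cost = delta_cost, delta_qaly = delta_qaly,
                 icer = icer, status = status)
}

# coerce rank_and_compare inputs to a (strategy, qalys, cost) tibble
as_outcome_table <- function(outcomes) {
  if (inherits(outcomes, "crc_outcome")) outcomes <- list(outcomes)
  if (is.list(outcomes) && !is.data.frame(outcomes) &&
      all(purrr::map_lgl(outcomes, inherits, "crc_outcome"))) {
    outcomes <- purrr::map_dfr(outcomes, ~ .x$summary)
  }
  stopifnot(is.data.frame(outcomes),
            all(c("strategy", "qalys", "cost") %in% names(outcomes)))
  tibble::as_tibble(outcomes)
}

#' Rank strategies and compute incremental comparisons
#'
#' Orders the strategies of one entry age by ascending QALYs (ties broken
#' by ascending cost) and attaches, per strategy, the incremental QALYs,
#' costs and ICER versus the no-screening baseline and versus the
#' next-most-effective strategy (its predecessor in the QALY ordering, the
#' baseline for the least effective). No dominance pruning is applied here;
#' see [ce_frontier()] for strict and extended dominance.
#'
#' @param outcomes A tibble with columns `strategy`, `qalys`, `cost` (one
#'   row per strategy), or a list of `crc_outcome` objects.
#' @param baseline The comparator: a one-row tibble or `crc_outcome`. If
#'   `NULL`, the row with `strategy == "none"` is used.
#' @return A `crc_cea` tibble ordered by ascending QALYs with incremental
#'   columns and `icer_vs_none`, `icer_vs_next` plus their status columns.
#' @export
rank_and_compare <- function(outcomes, baseline = NULL) {
  tab <- as_outcome_table(outcomes)
  if (is.null(baseline)) {
    base_row <- tab[tab$strategy == "none", ]
    if (nrow(base_row) != 1) {
      stop("no baseline supplied and no unique 'none' row found",
           call. = FALSE)
    }
    tab <- tab[tab$strategy != "none", ]
  } else {
    base_row <- as_outcome_table(baseline)
    stopifnot(nrow(base_row) == 1)
  }
  if (anyDuplicated(tab$strategy)) {
    stop("duplicate strategy labels", call. = FALSE)
  }
  tab <- dplyr::arrange(tab, .data$qalys, .data$cost)
  prev_qaly <- dplyr::lag(tab$qalys, default = base_row$qalys)
  prev_cost <- dplyr::lag(tab$cost, default = base_row$cost)

  vs_none <- compute_icer(tab$cost - base_row$cost,
                          tab$qalys - base_row$qalys)
  vs_next <- compute_icer(tab$cost - prev_cost, tab$qalys - prev_qaly)

  out <- tab |>
    dplyr::mutate(
      inc_qaly_vs_none = vs_none$delta_qaly,
      inc_cost_vs_none = vs_none$delta_cost,
      icer_vs_none = vs_none$icer,
      status_vs_none = vs_none$status,
      inc_qaly_vs_next = vs_next$delta_qaly,
      inc_cost_vs_next = vs_next$delta_cost,
      icer_vs_next = vs_next$icer,
      status_vs_next = vs_next$status
    )
  attr(out, "baseline") <- base_row
  class(out) <- c("crc_cea", class(out))
  out
}

#' Flag strategies against willingness-to-pay thresholds
#'
#' A strategy is cost-effective at a threshold when its ICER versus the
#' baseline is at most the threshold (boundary included) or when it is
#' dominant; dominated strategies are never cost-effective.
#'
#' @param rows A `crc_cea` tibble from [rank_and_compare()].
#' @param thresholds A [ce_thresholds()] row.
#' @return `rows` with logical columns `ce_at_chronic`, `ce_at_three_gdp`;
#'   the attribute `"summary"` holds the maximum defined ICER and whether
#'   all strategies pass each threshold.
#' @export
classify_against_threshold <- function(rows, thresholds = ce_thresholds()) {
  ce_at <- function(lambda) {
    dplyr::case_when(
      rows$status_vs_none == "dominant" ~ TRUE,
      rows$status_vs_none == "ok" ~ rows$icer_vs_none <= lambda,
      TRUE ~ FALSE
    )
  }
  rows$ce_at_chronic <- ce_at(thresholds$chronic)
  rows$ce_at_three_gdp <- ce_at(thresholds$three_gdp)
  attr(rows, "summary") <- tibble::tibble(
    max_icer_vs_none = suppressWarnings(max(rows$icer_vs_none, na.rm = TRUE)),
    all_ce_at_chronic = all(rows$ce_at_chronic),
    all_ce_at_three_gdp = all(rows$ce_at_three_gdp)
  )
  rows
}

#' Cost-effectiveness frontier with strict and extended dominance
#'
#' General-purpose frontier construction: strategies dominated strictly
#' (another option has at least the QALYs at no more cost) or by extension
#' (a blend of two other options does) are flagged.
#'
#' @param outcomes Tibble with `strategy`, `qalys`, `cost` (the baseline may
#'   be included as a row).
#' @return The input with logical columns `dominated`,
#'   `extendedly_dominated`, `on_frontier`, and frontier ICERs
#'   (`icer_frontier`, versus the previous frontier point).
#' @export
ce_frontier <- function(outcomes) {
  tab <- as_outcome_table(outcomes) |>
    dplyr::arrange(.data$cost, dplyr::desc(.data$qalys))
  n <- nrow(tab)
  dominated <- logical(n)
  for (i in seq_len(n)) {
    dominated[i] <- any(tab$qalys >= tab$qalys[i] & tab$cost <= tab$cost[i] &
                          seq_len(n) != i &
                          (tab$qalys > tab$qalys[i] | tab$cost < tab$cost[i]))
  }
  ext <- logical(n)
  repeat {
    idx <- which(!dominated & !ext)
    cand <- tab[idx, ]
    if (nrow(cand) < 3) break
    icers <- diff(cand$cost) / diff(cand$qalys)
    viol <- which(diff(icers) < 0)
    if (length(viol) == 0) break
    ext[idx[viol[1] + 1L]] <- TRUE
  }
  tab$dominated <- dominated
  tab$extendedly_dominated <- ext
  tab$on_frontier <- !dominated & !ext
  tab$icer_frontier <- NA_real_
  fr <- which(tab$on_frontier)
  if (length(fr) > 1) {
    tab$icer_frontier[fr[-1]] <-
      round_half_up(diff(tab$cost[fr]) / diff(tab$qalys[fr]))
  }
  tab
}

#' Published strategy-comparison table of the programme evaluation
#'
#' The programme's published per-100,000 cohort comparison: discounted
#' QALYs, costs (thousand USD) and ICERs versus no screening and versus the
#' next-most-effective strategy, for seven initiation ages and up to six
#' frequencies, as printed.
#'
#' @return Tibble with one row per (entry age, strategy).
#' @export
pccsp_cea_table <- function() {
  readr::read_csv(
    system.file("extdata", "pccsp_cea_table.csv", package = "crcscreen",
                mustWork = TRUE),
    col_types = readr::cols(
      entry_age = readr::col_integer(),
      age_group = readr::col_character(),
      strategy = readr::col_character(),
      .default = readr::col_double()
    ),
    progress = FALSE
  )
}

#' Internal-consistency check of a printed comparison table
#'
#' Recomputes each ICER versus no screening from the table's own printed
#' incremental costs (thousand USD) and QALYs and reports the deviation from
#' the printed ICER. Printed tables round increments before printing, so
#' small deviations can appear; rows deviating by more than `tol` USD/QALY
#' are flagged as discrepancies rather than silently matched.
#'
#' @param table A table shaped like [pccsp_cea_table()] (default).
#' @param tol Flagging tolerance in USD per QALY (default 1).
#' @return Tibble of non-baseline rows with `icer_recomputed`, `deviation`
#'   and `consistent`.
#' @export
icer_consistency <- function(table = pccsp_cea_table(), tol = 1) {
  rows <- table[table$strategy != "none", ]
  recomputed <- round_half_up(rows$inc_cost_vs_none * 1000 /
                                rows$inc_qaly_vs_none)
  tibble::tibble(
    entry_age = rows$entry_age,
    age_group = rows$age_group,
    strategy = rows$strategy,
    icer_printed = rows$icer_vs_none,
    icer_recomputed = recomputed,
    deviation = recomputed - rows$icer_vs_none,
    consistent = abs(recomputed - rows$icer_vs_none) <= tol
  )
}
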