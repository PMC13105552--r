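#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a cohort run into its per-cycle ledger
#'
#' @param x A `crc_outcome`.
#' @param ... Unused.
#' @return The per-cycle ledger tibble (events, costs, QALYs, discounted
#'   and undiscounted).
#' @method tidy crc_outcome
#' @export
tidy.crc_outcome <- function(x, ...) x$ledger

#' One-row summary of a cohort run
#'
#' @param x A `crc_outcome`.
#' @param ... Unused.
#' @return One-row tibble with discounted QALYs/costs, lifetime CRC
#'   deaths, colonoscopies and detections.
#' @method glance crc_outcome
#' @export
glance.crc_outcome <- function(x, ...) x$summary

#' @method tidy crc_cea
#' @export
tidy.crc_cea <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "crc_cea")
  tibble::as_tibble(out)
}

#' @method glance crc_cea
#' @export
glance.crc_cea <- function(x, ...) {
  s <- attr(x, "summary")
  if (!is.null(s)) return(s)
  tibble::tibble(
    n_strategies = nrow(x),
    max_icer_vs_none = suppressWarnings(max(x$icer_vs_none, na.rm = TRUE)),
    top_strategy = x$strategy[which.max(x$qalys)]
  )
}

#' @method tidy crc_psa
#' @export
tidy.crc_psa <- function(x, ...) x$draws

#' @method glance crc_psa
#' @export
glance.crc_psa <- function(x, ...) {
  tibble::tibble(n_draws = x$n_draws, seed = x$seed,
                 n_strategies = dplyr::n_distinct(x$draws$strategy),
                 n_entry_ages = dplyr::n_distinct(x$draws$entry_age))
}

#' @method tidy crc_calibration
#' @export
tidy.crc_calibration <- function(x, ...) x$estimates

#' @method glance crc_calibration
#' @export
glance.crc_calibration <- function(x, ...) {
  tibble::tibble(objective = x$objective,
                 objective_start = x$objective_start,
                 converged = x$convergence == 0L,
                 n_parameters = nrow(x$estimates))
}

#' @method tidy crc_ceac
#' @export
tidy.crc_ceac <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "crc_ceac")
  tibble::as_tibble(out)
}

#' @method tidy crc_yield
#' @export
tidy.crc_yield <- function(x, ...) x$report

#' @method glance crc_yield
#' @export
glance.crc_yield <- function(x, ...) {
  dplyr::bind_cols(
    x$rates, x$nns,
    tibble::tibble(
      n_discrepancies = if (is.null(x$discrepancies)) NA_integer_
      else sum(!x$discrepancies$consistent)
    )
  )
}
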