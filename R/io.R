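#' Read a strategy-grid configuration
#'
#' YAML (or JSON-equivalent) config with fields `entry_ages`,
#' `frequencies`, optional `stop_age`, `discount`, `adherence_decay`.
#'
#' @param path Path to a YAML file.
#' @return Named list with validated fields and defaults filled in.
#' @export
read_strategy_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("reading YAML configs requires the 'yaml' package", call. = FALSE)
  }
  cfg <- yaml::read_yaml(path)
  cfg$entry_ages <- as.integer(cfg$entry_ages %||%
                                 c(42L, 47L, 52L, 57L, 62L, 67L, 72L))
  cfg$frequencies <- cfg$frequencies %||%
    c("once", "every_10y", "every_5y", "every_3y", "every_2y", "annual")
  cfg$stop_age <- as.integer(cfg$stop_age %||% 74L)
  cfg$adherence_decay <- cfg$adherence_decay %||% 1
  bad <- setdiff(cfg$frequencies, names(.frequency_intervals()))
  if (length(bad) > 0) {
    stop("unknown frequency in config: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Export the per-cycle trace of a cohort run
#'
#' Writes one CSV row per cycle: age, the 21 state masses and, where
#' available, the ledger columns.
#'
#' @param outcome A `crc_outcome`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(outcome, path) {
  stopifnot(inherits(outcome, "crc_outcome"))
  tab <- dplyr::left_join(outcome$trace, outcome$ledger, by = "age")
  readr::write_csv(tab, path)
  invisible(path)
}
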