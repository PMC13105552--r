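#' Load a model parameter table
#'
#' Reads a delimited parameter table (one row per parameter, or per parameter
#' x age band for age-dependent quantities) and validates it into a parameter
#' set usable by every other function in the package. The packaged default
#' table carries the base case of the province-wide screening programme the
#' model was built for: screening performance, adherence, age-banded
#' natural-history transition probabilities, symptom-detection and recurrence
#' rates, utilities, stage-specific five-year survival, background mortality,
#' unit costs in 2023 USD and the annual discount rate, each with its 95%
#' uncertainty interval and the distribution family used in probabilistic
#' sensitivity analysis.
#'
#' @param source Path to a CSV with columns `name`, `age_low`, `age_high`,
#'   `base`, `ui_low`, `ui_high`, `distribution`, `units`, `source`. Defaults
#'   to the packaged base-case table.
#' @return A `crc_param_set`: a tibble of validated parameter rows.
#' @export
#' @examples
#' params <- load_parameter_table()
#' param_value(params, "participation")
load_parameter_table <- function(source = NULL) {
  if (is.null(source)) {
    source <- system.file("extdata", "model_parameters.csv",
                          package = "crcscreen", mustWork = TRUE)
  }
  tab <- readr::read_csv(
    source,
    col_types = readr::cols(
      name = readr::col_character(),
      age_low = readr::col_integer(),
      age_high = readr::col_integer(),
      base = readr::col_double(),
      ui_low = readr::col_double(),
      ui_high = readr::col_double(),
      distribution = readr::col_character(),
      units = readr::col_character(),
      source = readr::col_character()
    ),
    progress = FALSE
  )
  as_param_set(tab)
}

#' Validate a parameter tibble into a parameter set
#'
#' @param tab Tibble with the columns described in [load_parameter_table()].
#' @return The validated tibble with class `crc_param_set`.
#' @export
as_param_set <- function(tab) {
  required <- c("name", "base", "ui_low", "ui_high", "distribution", "units")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols) > 0) {
    stop("parameter table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!"age_low" %in% names(tab)) tab$age_low <- NA_integer_
  if (!"age_high" %in% names(tab)) tab$age_high <- NA_integer_
  if (!"source" %in% names(tab)) tab$source <- NA_character_

  known <- c("triangular", "gamma", "beta", "uniform", "fixed")
  bad_dist <- setdiff(unique(tab$distribution), known)
  if (length(bad_dist) > 0) {
    stop("unknown distribution family: ", paste(bad_dist, collapse = ", "),
         call. = FALSE)
  }
  if (any(tab$ui_low > tab$base | tab$base > tab$ui_high)) {
    off <- tab$name[tab$ui_low > tab$base | tab$base > tab$ui_high]
    stop("base value outside its uncertainty interval for: ",
         paste(off, collapse = ", "), call. = FALSE)
  }
  unit_bounded <- tab$units %in% c("probability", "utility")
  if (any(unit_bounded & (tab$base < 0 | tab$base > 1))) {
    off <- tab$name[unit_bounded & (tab$base < 0 | tab$base > 1)]
    stop("probability/utility outside [0, 1] for: ",
         paste(off, collapse = ", "), call. = FALSE)
  }
  if (any(tab$units == "USD" & tab$base < 0)) {
    stop("negative cost parameter", call. = FALSE)
  }
  banded <- !is.na(tab$age_low)
  if (any(banded & tab$age_low > tab$age_high)) {
    stop("age band with lower bound above upper bound", call. = FALSE)
  }
  dup <- tab |>
    dplyr::count(.data$name, .data$age_low) |>
    dplyr::filter(.data$n > 1L)
  if (nrow(dup) > 0) {
    stop("duplicated parameter rows: ",
         paste(unique(dup$name), collapse = ", "), call. = FALSE)
  }

  mandatory <- .mandatory_parameters()
  absent <- setdiff(mandatory, unique(tab$name))
  if (length(absent) > 0) {
    stop("missing mandatory parameter(s): ", paste(absent, collapse = ", "),
         call. = FALSE)
  }

  tab <- tibble::as_tibble(tab)
  class(tab) <- c("crc_param_set", class(tab))
  tab
}

.mandatory_parameters <- function() {
  c(
    "cost_preparation", "cost_initial_screen", "cost_colonoscopy",
    "cost_treat_naa", "cost_treat_aa",
    paste0("cost_treat_crc", 1:4),
    "cost_diagnosis", "cost_followup",
    "participation", "sens_initial_lesion", "sens_initial_crc",
    "spec_initial", "compliance_colonoscopy",
    "sens_colo_naa", "sens_colo_aa", "sens_colo_crc", "spec_colo",
    "p_normal_naa", "p_naa_aa", "p_aa_crc1",
    "p_crc1_crc2", "p_crc2_crc3", "p_crc3_crc4",
    "symptom_naa", "symptom_aa", paste0("symptom_crc", 1:4),
    "treat_compliance_naa", "treat_compliance_aa",
    paste0("treat_compliance_crc", 1:4),
    "recur_naa", "recur_aa", paste0("recur_crc", 1:4),
    "utility_general", "utility_aa", paste0("utility_crc", 1:4),
    paste0("surv5_crc", 1:4),
    "bg_mort", "discount_rate"
  )
}

#' Look up a scalar parameter value
#'
#' @param params A `crc_param_set`.
#' @param name Parameter name.
#' @param age Integer age (years); required for age-banded parameters.
#' @return The base-case value for `name` (at `age` if banded).
#' @export
param_value <- function(params, name, age = NULL) {
  rows <- params[params$name == name, ]
  if (nrow(rows) == 0) stop("unknown parameter: ", name, call. = FALSE)
  if (nrow(rows) == 1 && is.na(rows$age_low[1])) return(rows$base[1])
  if (is.null(age)) {
    stop("parameter '", name, "' is age-banded; supply `age`", call. = FALSE)
  }
  hit <- which(rows$age_low <= age & age <= rows$age_high)
  if (length(hit) != 1) {
    stop("no age band of '", name, "' covers age ", age, call. = FALSE)
  }
  rows$base[hit]
}

#' Write a parameter set to CSV
#'
#' Values round-trip exactly: re-loading the written file reproduces the
#' parameter set.
#'
#' @param params A `crc_param_set`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_parameter_table <- function(params, path) {
  readr::write_csv(tibble::as_tibble(params), path)
  invisible(path)
}

#' Draw one joint parameter sample for probabilistic sensitivity analysis
#'
#' Every parameter is drawn independently from the distribution family
#' declared in its table row (age-banded members of one family are drawn
#' independently per band, as each band has its own uncertainty interval).
#' `fixed` rows -- background mortality -- keep their base value.
#'
#' @param params A `crc_param_set`.
#' @param seed Integer seed; equal seeds give identical draws.
#' @return A new `crc_param_set` whose `base` column holds the draw.
#' @export
sample_parameter_draw <- function(params, seed) {
  stopifnot(length(seed) == 1, is.finite(seed))
  old <- globalenv()$.Random.seed
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  drawn <- purrr::pmap_dbl(
    list(params$base, params$ui_low, params$ui_high, params$distribution),
    function(base, lo, hi, family) {
      draw_distribution(build_distribution(base, lo, hi, family), 1L)
    }
  )
  out <- params
  out$base <- drawn
  out
}
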