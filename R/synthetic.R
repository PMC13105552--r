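#' Synthetic age-specific initial health-state distribution
#'
#' The programme's age-specific initial distribution of CRC-related health
#' states (observed at first screen) is not published; this generator
#' emulates it by running the package's own unscreened natural history from
#' age 40 under a stored parameter set and, optionally, perturbing the
#' resulting band prevalences with multiplicative log-normal noise. Two
#' structural properties of such data are enforced by construction:
#' prevalence is non-decreasing with age band and decreasing with lesion
#' severity (NAA >= AA >= CRC) in every band. With zero noise the output is
#' exactly the model's own prevalence, so calibration against it recovers
#' the generating transition probabilities.
#'
#' @param seed Integer seed.
#' @param bands Tibble `age_low`, `age_high` (default: 5-year bands
#'   40-44 ... 70-74).
#' @param params Generating `crc_param_set` (default: packaged base case).
#' @param noise_sd Standard deviation of the log-normal multiplicative
#'   noise (0 = noise-free).
#' @return Tibble `age_low`, `age_high`, `naa`, `aa`, `crc`; the generating
#'   parameter set is attached as attribute `"generator_params"`.
#' @export
synth_initial_distribution <- function(seed, bands = default_age_bands(),
                                       params = load_parameter_table(),
                                       noise_sd = 0) {
  prev <- prevalence_by_band(params, bands)
  if (noise_sd > 0) {
    old <- globalenv()$.Random.seed
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
    for (cls in c("naa", "aa", "crc")) {
      prev[[cls]] <- prev[[cls]] *
        exp(stats::rnorm(nrow(prev), 0, noise_sd))
    }
  }
  # structural guarantees: monotone in age, decreasing in severity
  prev$naa <- pmin(cummax(prev$naa), 1)
  prev$aa <- pmin(cummax(prev$aa), prev$naa)
  prev$crc <- pmin(cummax(prev$crc), prev$aa)
  attr(prev, "generator_params") <- params
  prev
}

#' Default 5-year age bands of the screening programme
#' @return Tibble `age_low`, `age_high` for bands 40-44 through 70-74.
#' @export
default_age_bands <- function() {
  tibble::tibble(age_low = seq(40L, 70L, by = 5L),
                 age_high = seq(44L, 74L, by = 5L))
}

#' Synthetic registry-style incidence and mortality curves
#'
#' Emulates the cancer-registry reference curves used for external
#' validation: the model's own age-specific CRC incidence and mortality per
#' 100,000 (unscreened cohort entering at age 40) plus additive Gaussian
#' noise. The generator guarantees non-negative rates and mortality no
#' greater than incidence at every age. Noise-free output therefore gives a
#' perfect goodness-of-fit (R-squared 1, RMSE 0) against the model.
#'
#' @param seed Integer seed.
#' @param params Generating `crc_param_set`.
#' @param noise_sd Additive noise standard deviation, per 100,000
#'   (default 15, the order of the discrepancy registry comparisons show).
#' @param from_age,to_age Age range of the curves.
#' @return Tibble `age`, `incidence`, `mortality` (observed, noisy) and
#'   `incidence_true`, `mortality_true` (the model's own curves).
#' @export
synth_registry_curves <- function(seed, params = load_parameter_table(),
                                  noise_sd = 15, from_age = 40L,
                                  to_age = 82L) {
  proj <- project_natural_history(params, from_age = from_age,
                                  to_age = to_age)
  old <- globalenv()$.Random.seed
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  inc <- pmax(proj$crc_incidence + stats::rnorm(nrow(proj), 0, noise_sd), 0)
  mort <- pmax(proj$crc_mortality + stats::rnorm(nrow(proj), 0, noise_sd), 0)
  mort <- pmin(mort, inc)
  tibble::tibble(
    age = proj$age,
    incidence = inc,
    mortality = mort,
    incidence_true = proj$crc_incidence,
    mortality_true = proj$crc_mortality
  )
}

#' Synthetic programme cascade counts
#'
#' Draws a binomial screening cascade — completers, screen positives,
#' colonoscopies, detections per lesion class — for a hypothetical
#' programme of `n_invitees`. Cascade probabilities default to the model's
#' base case: participation and colonoscopy compliance from the parameter
#' table, positivity and per-colonoscopy detection rates derived from the
#' unscreened state mix over the programme's 50-74 age range combined with
#' initial-screen sensitivity/specificity and colonoscopy sensitivity.
#' Expected counts equal the closed-form products of `n_invitees` with the
#' cascade probabilities.
#'
#' @param seed Integer seed.
#' @param n_invitees Programme target population size.
#' @param params Generating `crc_param_set` (ignored when `probs` given).
#' @param probs Optional named list overriding the cascade probabilities:
#'   `participation`, `positivity`, `compliance`, `det_naa`, `det_aa`,
#'   `det_crc`.
#' @return One-row tibble shaped like [pccsp_counts()] (cost components
#'   from the parameter table's unit costs; `crc_deaths_averted` is `NA` —
#'   deaths averted are a model output, not a cascade draw). The cascade
#'   probabilities used are attached as attribute `"probs"`.
#' @export
synth_program_counts <- function(seed, n_invitees,
                                 params = load_parameter_table(),
                                 probs = NULL) {
  stopifnot(n_invitees >= 1)
  if (is.null(probs)) probs <- derive_cascade_probs(params)
  old <- globalenv()$.Random.seed
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  completers <- stats::rbinom(1, n_invitees, probs$participation)
  positives <- stats::rbinom(1, completers, probs$positivity)
  colonoscopies <- stats::rbinom(1, positives, probs$compliance)
  det_naa <- stats::rbinom(1, colonoscopies, probs$det_naa)
  det_aa <- stats::rbinom(1, colonoscopies, probs$det_aa)
  det_crc <- stats::rbinom(1, colonoscopies, probs$det_crc)
  cost <- param_value(params, "cost_preparation") +
    completers * param_value(params, "cost_initial_screen") +
    colonoscopies * param_value(params, "cost_colonoscopy")
  out <- tibble::tibble(
    stratum = "synthetic",
    invitees = n_invitees,
    completers = completers,
    positives = positives,
    colonoscopies = colonoscopies,
    detected_naa = det_naa,
    detected_aa = det_aa,
    detected_crc = det_crc,
    total_cost_usd = cost,
    crc_deaths_averted = NA_real_
  )
  attr(out, "probs") <- probs
  out
}

# positivity and per-colonoscopy detection rates implied by the unscreened
# state mix over the programme age range and the test characteristics
derive_cascade_probs <- function(params) {
  cp <- compile_params(params)
  prev <- prevalence_by_band(
    params, tibble::tibble(age_low = 50L, age_high = 74L))
  p_free <- 1 - prev$naa - prev$aa - prev$crc
  sc <- cp$screen
  p_pos <- prev$naa * sc[["sens_lesion"]] + prev$aa * sc[["sens_lesion"]] +
    prev$crc * sc[["sens_crc"]] + p_free * (1 - sc[["spec_initial"]])
  # detection rates are conditional on reaching colonoscopy, i.e. on having
  # screened positive
  list(
    participation = sc[["participation"]],
    positivity = p_pos,
    compliance = sc[["compliance"]],
    det_naa = prev$naa * sc[["sens_lesion"]] * sc[["sens_colo_naa"]] / p_pos,
    det_aa = prev$aa * sc[["sens_lesion"]] * sc[["sens_colo_aa"]] / p_pos,
    det_crc = prev$crc * sc[["sens_crc"]] * sc[["sens_colo_crc"]] / p_pos
  )
}
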