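#' Annual cancer mortality from five-year survival
#'
#' Converts a stage-specific five-year survival proportion into the constant
#' annual probability of cancer death implied by it:
#' `1 - survival^(1/5)`.
#'
#' @param five_year_survival Probability of surviving five years from
#'   diagnosis, in `[0, 1]`. Vectorised.
#' @return Annual probability of CRC death.
#' @export
#' @examples
#' annual_mortality_from_survival(0.916)
annual_mortality_from_survival <- function(five_year_survival) {
  if (any(five_year_survival < 0 | five_year_survival > 1)) {
    stop("five-year survival must lie in [0, 1]", call. = FALSE)
  }
  1 - five_year_survival^(1 / 5)
}

# Flatten a parameter set into the age-indexed vectors and scalars the
# cycle engine reads. Ages are indexed 40..82; age-banded parameters are
# looked up by the cohort's current integer mean age.
compile_params <- function(params) {
  ages <- 40:82
  banded <- function(name) {
    rows <- params[params$name == name, ]
    idx <- vapply(ages, function(a) {
      hit <- which(rows$age_low <= a & a <= rows$age_high)
      if (length(hit) != 1) {
        stop("age bands of '", name, "' do not cover age ", a, call. = FALSE)
      }
      hit
    }, integer(1))
    stats::setNames(rows$base[idx], ages)
  }
  scalar <- function(name) param_value(params, name)

  surv5 <- vapply(paste0("surv5_crc", 1:4), scalar, numeric(1))
  list(
    ages = ages,
    onset = banded("p_normal_naa"),
    p_naa_aa = banded("p_naa_aa"),
    p_aa_crc1 = banded("p_aa_crc1"),
    bg_mort = banded("bg_mort"),
    u_general = banded("utility_general"),
    p_stage = c(scalar("p_crc1_crc2"), scalar("p_crc2_crc3"),
                scalar("p_crc3_crc4")),
    symptom = c(
      naa = scalar("symptom_naa"), aa = scalar("symptom_aa"),
      crc1 = scalar("symptom_crc1"), crc2 = scalar("symptom_crc2"),
      crc3 = scalar("symptom_crc3"), crc4 = scalar("symptom_crc4")
    ),
    treat_comp = c(
      naa = scalar("treat_compliance_naa"), aa = scalar("treat_compliance_aa"),
      crc1 = scalar("treat_compliance_crc1"),
      crc2 = scalar("treat_compliance_crc2"),
      crc3 = scalar("treat_compliance_crc3"),
      crc4 = scalar("treat_compliance_crc4")
    ),
    recur = c(
      naa = scalar("recur_naa"), aa = scalar("recur_aa"),
      crc1 = scalar("recur_crc1"), crc2 = scalar("recur_crc2"),
      crc3 = scalar("recur_crc3"), crc4 = scalar("recur_crc4")
    ),
    crc_mort = annual_mortality_from_survival(unname(surv5)),
    utility = c(
      aa = scalar("utility_aa"),
      crc1 = scalar("utility_crc1"), crc2 = scalar("utility_crc2"),
      crc3 = scalar("utility_crc3"), crc4 = scalar("utility_crc4")
    ),
    screen = c(
      participation = scalar("participation"),
      sens_lesion = scalar("sens_initial_lesion"),
      sens_crc = scalar("sens_initial_crc"),
      spec_initial = scalar("spec_initial"),
      compliance = scalar("compliance_colonoscopy"),
      sens_colo_naa = scalar("sens_colo_naa"),
      sens_colo_aa = scalar("sens_colo_aa"),
      sens_colo_crc = scalar("sens_colo_crc"),
      spec_colo = scalar("spec_colo")
    ),
    cost = c(
      preparation = scalar("cost_preparation"),
      initial_screen = scalar("cost_initial_screen"),
      colonoscopy = scalar("cost_colonoscopy"),
      treat_naa = scalar("cost_treat_naa"),
      treat_aa = scalar("cost_treat_aa"),
      treat_crc1 = scalar("cost_treat_crc1"),
      treat_crc2 = scalar("cost_treat_crc2"),
      treat_crc3 = scalar("cost_treat_crc3"),
      treat_crc4 = scalar("cost_treat_crc4"),
      diagnosis = scalar("cost_diagnosis"),
      followup = scalar("cost_followup")
    ),
    discount = scalar("discount_rate")
  )
}

#' One-cycle transition matrix of the unscreened disease process
#'
#' Builds the 21 x 21 row-stochastic matrix for one annual cycle at a given
#' cohort age. Within the cycle, background mortality is applied first and
#' all other transitions are conditioned on surviving it; diagnosed CRC
#' states (treated and untreated) then face stage-specific cancer mortality
#' derived from five-year survival; survivors undergo symptom detection
#' (undiagnosed states, split by treatment compliance into treated vs
#' diagnosed-untreated), natural-history progression (undiagnosed and
#' diagnosed-untreated compartments) and recurrence (treated states return
#' to the corresponding undiagnosed state). Undiagnosed preclinical CRC is
#' exposed to background mortality only, because survival inputs are
#' conditional on diagnosis.
#'
#' @param age Integer age in years, 40-82.
#' @param params A `crc_param_set` (or a pre-compiled parameter list).
#' @return A 21 x 21 matrix with rows and columns named after
#'   [health_states()].
#' @export
build_transition_matrix <- function(age, params) {
  cp <- if (inherits(params, "crc_param_set")) compile_params(params) else params
  age <- as.integer(age)
  if (age < 40L || age > 82L) {
    stop("age must lie in the model range 40-82", call. = FALSE)
  }
  a <- as.character(age)
  M <- matrix(0, 21L, 21L, dimnames = list(.state_names, .state_names))
  bg <- cp$bg_mort[[a]]
  s <- .S

  alive <- 1:19
  M[alive, s$death_other] <- bg
  surv <- 1 - bg

  # normal epithelium: adenoma onset
  onset <- cp$onset[[a]]
  M[s$normal, s$naa_u] <- surv * onset
  M[s$normal, s$normal] <- surv * (1 - onset)

  # undiagnosed adenomas: symptom detection then progression
  lesion_u <- list(
    list(from = s$naa_u, to_t = s$naa_t, to_du = s$naa_du, to_prog = s$aa_u,
         det = cp$symptom[["naa"]], tc = cp$treat_comp[["naa"]],
         prog = cp$p_naa_aa[[a]]),
    list(from = s$aa_u, to_t = s$aa_t, to_du = s$aa_du, to_prog = s$crc1_u,
         det = cp$symptom[["aa"]], tc = cp$treat_comp[["aa"]],
         prog = cp$p_aa_crc1[[a]])
  )
  for (L in lesion_u) {
    M[L$from, L$to_t] <- surv * L$det * L$tc
    M[L$from, L$to_du] <- surv * L$det * (1 - L$tc)
    M[L$from, L$to_prog] <- surv * (1 - L$det) * L$prog
    M[L$from, L$from] <- surv * (1 - L$det) * (1 - L$prog)
  }

  # undiagnosed preclinical CRC: symptom detection then stage progression
  for (k in 1:4) {
    from <- s$crc1_u + k - 1L
    det <- cp$symptom[[paste0("crc", k)]]
    tc <- cp$treat_comp[[paste0("crc", k)]]
    prog <- if (k < 4) cp$p_stage[k] else 0
    M[from, s$crc1_t + k - 1L] <- surv * det * tc
    M[from, s$crc1_du + k - 1L] <- surv * det * (1 - tc)
    if (k < 4) M[from, from + 1L] <- surv * (1 - det) * prog
    M[from, from] <- surv * (1 - det) * (1 - prog)
  }

  # treated adenomas: recurrence back to the undiagnosed compartment
  M[s$naa_t, s$naa_u] <- surv * cp$recur[["naa"]]
  M[s$naa_t, s$naa_t] <- surv * (1 - cp$recur[["naa"]])
  M[s$aa_t, s$aa_u] <- surv * cp$recur[["aa"]]
  M[s$aa_t, s$aa_t] <- surv * (1 - cp$recur[["aa"]])

  # treated CRC: cancer mortality, then recurrence among survivors
  for (k in 1:4) {
    from <- s$crc1_t + k - 1L
    mu <- cp$crc_mort[k]
    rec <- cp$recur[[paste0("crc", k)]]
    M[from, s$death_crc] <- surv * mu
    M[from, s$crc1_u + k - 1L] <- surv * (1 - mu) * rec
    M[from, from] <- surv * (1 - mu) * (1 - rec)
  }

  # diagnosed-untreated lesions progress with natural-history probabilities
  M[s$naa_du, s$aa_du] <- surv * cp$p_naa_aa[[a]]
  M[s$naa_du, s$naa_du] <- surv * (1 - cp$p_naa_aa[[a]])
  M[s$aa_du, s$crc1_du] <- surv * cp$p_aa_crc1[[a]]
  M[s$aa_du, s$aa_du] <- surv * (1 - cp$p_aa_crc1[[a]])

  # diagnosed-untreated CRC: cancer mortality, then stage progression
  for (k in 1:4) {
    from <- s$crc1_du + k - 1L
    mu <- cp$crc_mort[k]
    prog <- if (k < 4) cp$p_stage[k] else 0
    M[from, s$death_crc] <- surv * mu
    if (k < 4) M[from, from + 1L] <- surv * (1 - mu) * prog
    M[from, from] <- surv * (1 - mu) * (1 - prog)
  }

  M[s$death_crc, s$death_crc] <- 1
  M[s$death_other, s$death_other] <- 1

  if (any(M < -1e-15) || any(abs(rowSums(M) - 1) > 1e-12)) {
    stop("transition matrix is not row-stochastic", call. = FALSE)
  }
  M
}

# attach per-age transition-matrix and utility-vector caches to a compiled
# parameter list; reused across every strategy run under one parameter set
prepare_engine <- function(params) {
  cp <- if (inherits(params, "crc_param_set")) compile_params(params) else params
  if (!is.null(cp$M)) return(cp)
  ages <- 40:81
  cp$M <- lapply(ages, build_transition_matrix, params = cp)
  names(cp$M) <- ages
  cp$U <- lapply(ages, utility_vector, cp = cp)
  names(cp$U) <- ages
  cp
}

#' Project the unscreened natural history of a cohort
#'
#' Runs the disease process with no screening from `from_age`, recording the
#' full state distribution at every age. Used for calibration targets,
#' registry-style validation curves and the synthetic initial-distribution
#' generator.
#'
#' @param params A `crc_param_set`.
#' @param from_age,to_age Integer ages bounding the projection (default the
#'   full model range 40-82).
#' @param init Optional length-21 initial distribution (defaults to all mass
#'   in `normal`).
#' @return A tibble with columns `age`, one column per state, plus
#'   `crc_incidence` and `crc_mortality` (annual flows into diagnosed CRC and
#'   CRC death per person alive at the start of the cycle, per 100,000).
#' @export
project_natural_history <- function(params, from_age = 40L, to_age = 82L,
                                    init = NULL) {
  cp <- prepare_engine(params)
  m <- if (is.null(init)) initial_distribution() else init
  stopifnot(length(m) == 21L, abs(sum(m) - 1) < 1e-8)
  ages <- seq(from_age, to_age - 1L)
  s <- .S
  crc_u <- s$crc1_u:s$crc4_u
  out <- matrix(0, length(ages), 24L,
                dimnames = list(NULL, c("age", .state_names,
                                        "crc_incidence", "crc_mortality")))
  for (i in seq_along(ages)) {
    M <- cp$M[[as.character(ages[i])]]
    m_next <- drop(m %*% M)
    alive <- sum(m[1:19])
    # newly diagnosed CRC this cycle: symptomatic detection flows out of
    # preclinical states
    inc_flow <- sum(m[crc_u] * (M[cbind(crc_u, s$crc1_t + (0:3))] +
                                  M[cbind(crc_u, s$crc1_du + (0:3))]))
    mort_flow <- sum(m[1:19] * M[1:19, s$death_crc])
    out[i, ] <- c(ages[i], m, 1e5 * inc_flow / alive,
                  1e5 * mort_flow / alive)
    m <- m_next
  }
  tibble::as_tibble(out)
}

#' Age-banded lesion prevalence under no screening
#'
#' Summarises a natural-history projection into the prevalence of
#' undiagnosed NAA, AA and (preclinical) CRC among the alive population,
#' averaged over the ages of each band. This is the quantity the calibration
#' matches against age-specific initial health-state distributions observed
#' at first screen.
#'
#' @param params A `crc_param_set`.
#' @param bands Tibble with integer columns `age_low`, `age_high`.
#' @param from_age Age at which the unscreened cohort enters (default 40).
#' @return Tibble `age_low`, `age_high`, `naa`, `aa`, `crc` (proportions).
#' @export
prevalence_by_band <- function(params, bands, from_age = 40L) {
  cp <- if (inherits(params, "crc_param_set")) compile_params(params) else params
  s <- .S
  ages <- seq(from_age, max(bands$age_high))
  prev <- matrix(0, length(ages), 3L,
                 dimnames = list(ages, c("naa", "aa", "crc")))
  m <- initial_distribution()
  for (i in seq_along(ages)) {
    alive <- sum(m[1:19])
    prev[i, ] <- c(m[s$naa_u], m[s$aa_u],
                   sum(m[s$crc1_u:s$crc4_u])) / alive
    m <- drop(m %*% build_transition_matrix(ages[i], cp))
  }
  purrr::pmap_dfr(bands, function(age_low, age_high, ...) {
    sel <- ages >= age_low & ages <= age_high
    tibble::tibble(
      age_low = age_low, age_high = age_high,
      naa = mean(prev[sel, "naa"]),
      aa = mean(prev[sel, "aa"]),
      crc = mean(prev[sel, "crc"])
    )
  })
}

#' Calibrate onset and progression probabilities to prevalence targets
#'
#' Adjusts the calibration-sourced rows of the parameter table -- the
#' age-banded adenoma onset (`p_normal_naa`), NAA-to-AA and AA-to-CRC
#' progression probabilities -- so that the unscreened model's age-banded
#' prevalence of undiagnosed NAA, AA and CRC matches supplied targets in
#' least squares, holding every literature-sourced parameter fixed. Bounded
#' local search (L-BFGS-B) starts from the current base values and respects
#' each row's uncertainty interval.
#'
#' @param targets Tibble `age_low`, `age_high`, `naa`, `aa`, `crc`
#'   (proportions in `[0, 1]`), covering at least three age bands.
#' @param params A `crc_param_set` providing start values and bounds.
#' @param families Character vector of parameter families to calibrate.
#' @param from_age Entry age of the unscreened projection (default 40).
#' @return A `crc_calibration`: list with the calibrated `params`, a tibble
#'   `estimates` (parameter, band, start, fitted, lower, upper), the achieved
#'   `objective`, the starting-point `objective_start` and `convergence`.
#' @export
calibrate_transitions <- function(targets, params,
                                  families = c("p_normal_naa", "p_naa_aa",
                                               "p_aa_crc1"),
                                  from_age = 40L) {
  stopifnot(nrow(targets) >= 3L)
  if (any(unlist(targets[, c("naa", "aa", "crc")]) < 0) ||
      any(unlist(targets[, c("naa", "aa", "crc")]) > 1)) {
    stop("prevalence targets must lie in [0, 1]", call. = FALSE)
  }
  bands <- targets[, c("age_low", "age_high")]
  # only bands that influence the targeted age range are free parameters
  max_age <- max(targets$age_high)
  free <- params$name %in% families & !is.na(params$age_low) &
    params$age_low <= max_age
  idx <- which(free)
  if (length(idx) == 0) stop("no calibratable rows selected", call. = FALSE)

  target_mat <- as.matrix(targets[, c("naa", "aa", "crc")])
  cp0 <- compile_params(params)
  field <- c(p_normal_naa = "onset", p_naa_aa = "p_naa_aa",
             p_aa_crc1 = "p_aa_crc1")
  # ages (as positions in the compiled 40..82 vectors) each free row covers
  cover <- lapply(idx, function(i) {
    which(cp0$ages >= params$age_low[i] & cp0$ages <= params$age_high[i])
  })
  objective <- function(x) {
    cp <- cp0
    for (j in seq_along(idx)) {
      cp[[field[[params$name[idx[j]]]]]][cover[[j]]] <- x[j]
    }
    fit <- prevalence_by_band(cp, bands, from_age = from_age)
    sum((as.matrix(fit[, c("naa", "aa", "crc")]) - target_mat)^2)
  }

  start <- params$base[idx]
  lower <- params$ui_low[idx]
  upper <- params$ui_high[idx]
  f0 <- objective(start)
  opt <- stats::optim(
    start, objective, method = "L-BFGS-B", lower = lower, upper = upper,
    control = list(maxit = 2000L, factr = 1e3,
                   ndeps = rep(1e-6, length(start)))
  )
  fitted <- params
  fitted$base[idx] <- opt$par
  structure(
    list(
      params = fitted,
      estimates = tibble::tibble(
        parameter = params$name[idx],
        age_low = params$age_low[idx],
        age_high = params$age_high[idx],
        start = start, fitted = opt$par, lower = lower, upper = upper
      ),
      objective = opt$value,
      objective_start = f0,
      convergence = opt$convergence,
      message = opt$message
    ),
    class = "crc_calibration"
  )
}

#' Goodness of fit between a model curve and a reference curve
#'
#' @param model_curve,reference_curve Numeric vectors on the same age grid.
#' @return Tibble with `r_squared` (1 - SS_res/SS_tot about the reference
#'   mean) and `rmse` (root mean squared difference).
#' @export
#' @examples
#' goodness_of_fit(c(1, 2), c(1, 4))
goodness_of_fit <- function(model_curve, reference_curve) {
  if (length(model_curve) != length(reference_curve)) {
    stop("curves must share one age grid", call. = FALSE)
  }
  if (length(model_curve) < 2L) {
    stop("at least two points are needed", call. = FALSE)
  }
  ss_res <- sum((model_curve - reference_curve)^2)
  ss_tot <- sum((reference_curve - mean(reference_curve))^2)
  if (ss_tot == 0) {
    stop("reference curve is constant; R-squared is undefined",
         call. = FALSE)
  }
  tibble::tibble(
    r_squared = 1 - ss_res / ss_tot,
    rmse = sqrt(mean((model_curve - reference_curve)^2))
  )
}
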