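#' Define a screening strategy
#'
#' A strategy is an initiation age (the mean age of the entering five-year
#' band), a screening frequency, a stop age (the programme's upper
#' eligibility, 74 by default) and an optional per-round multiplicative
#' adherence decay. Rounds fall at cycle starts: entry, entry + f, entry +
#' 2f, ... while the cohort's mean age is at most `stop_age`; `"once"`
#' schedules exactly one round at entry and `"none"` is the routine-care
#' baseline.
#'
#' @param entry_age Mean age at model entry, one of 42, 47, 52, 57, 62, 67,
#'   72 (other integer ages in 40-81 are accepted for experiments).
#' @param frequency One of `"none"`, `"once"`, `"every_10y"`, `"every_5y"`,
#'   `"every_3y"`, `"every_2y"`, `"annual"`.
#' @param stop_age Last age at which a round may be offered (default 74).
#' @param adherence_decay Multiplicative factor applied to participation and
#'   colonoscopy compliance per completed round (default 1 = constant
#'   adherence).
#' @return A `crc_strategy` list.
#' @export
#' @examples
#' screening_strategy(42, "annual")
screening_strategy <- function(entry_age, frequency,
                               stop_age = 74L, adherence_decay = 1) {
  frequency <- match.arg(frequency, names(.frequency_intervals()))
  entry_age <- as.integer(entry_age)
  if (entry_age < 40L || entry_age > 81L) {
    stop("entry age must lie in 40-81", call. = FALSE)
  }
  if (frequency != "none" && entry_age > stop_age) {
    stop("entry age must not exceed the stop age", call. = FALSE)
  }
  structure(
    list(entry_age = entry_age, frequency = frequency,
         stop_age = as.integer(stop_age),
         adherence_decay = adherence_decay),
    class = "crc_strategy"
  )
}

.frequency_intervals <- function() {
  c(none = NA_integer_, once = 0L, every_10y = 10L, every_5y = 5L,
    every_3y = 3L, every_2y = 2L, annual = 1L)
}

#' Entering state distribution of a cohort at a given age
#'
#' A screening-naive cohort carries prevalent disease when it enters the
#' model. The entering distribution is the unscreened natural history's own
#' state mix at the entry age, accumulated from young adulthood: the
#' process starts all-`normal` at `entry_age - run_in` years (ages below 40
#' reuse the youngest band's transition probabilities, since adenoma onset
#' is slow but not zero before 40), and the resulting mix is conditioned on
#' being alive and free of a CRC diagnosis — mirroring programme
#' eligibility, which excluded residents with diagnosed colorectal
#' malignancy.
#'
#' @param params A `crc_param_set` or compiled parameter list.
#' @param entry_age Integer entry age (40-81).
#' @param run_in Years of pre-entry lesion accumulation (default 22,
#'   i.e. an entry cohort of mean age 42 accumulates from age 20).
#' @return Named length-21 probability vector.
#' @export
entering_distribution <- function(params, entry_age, run_in = 22L) {
  cp <- prepare_engine(params)
  m <- initial_distribution()
  if (run_in > 0L) {
    for (age in seq(entry_age - run_in, entry_age - 1L)) {
      m <- drop(m %*% cp$M[[as.character(max(age, 40L))]])
    }
  }
  names(m) <- .state_names
  s <- .S
  m[c(s$crc1_t:s$crc4_t, s$crc1_du:s$crc4_du,
      s$death_crc, s$death_other)] <- 0
  m / sum(m)
}

# cycle indices (0-based) at which a screening round is offered
screening_schedule <- function(strategy, horizon) {
  f <- .frequency_intervals()[[strategy$frequency]]
  if (is.na(f)) return(integer(0))
  if (f == 0L) return(0L)
  t <- seq(0L, horizon - 1L, by = f)
  t[strategy$entry_age + t <= strategy$stop_age]
}

#' Apply one screening round to a cohort distribution
#'
#' Deterministic proportional flows of the two-step strategy: a
#' participation fraction of every screening-eligible state takes the
#' initial screen (risk questionnaire plus FIT); positives -- true positives
#' by initial-screen sensitivity for lesion or preclinical CRC states, false
#' positives by one minus specificity for lesion-free states -- proceed to
#' colonoscopy at the compliance rate; colonoscopy true positives are
#' diagnosed and split by treatment compliance into treated versus
#' diagnosed-untreated; everyone else returns to their state. Lesion-free
#' colonoscopies are counted as false positives and accrue cost only (those
#' that colonoscopy itself mis-calls, one minus colonoscopy specificity,
#' accrue one extra follow-up visit). Eligible states are all alive states
#' except diagnosed CRC, which stays in clinical follow-up.
#'
#' @param dist Length-21 state distribution (need not be freshly named).
#' @param params A `crc_param_set` or compiled parameter list.
#' @param round_index 0-based index of this round within the strategy, used
#'   by the adherence-decay scenario.
#' @param adherence_decay Per-round multiplicative decay of participation
#'   and colonoscopy compliance (default 1).
#' @return List with `dist` (post-screening distribution), `cost` (per
#'   unit cohort mass) and event counts per unit mass: `screens`,
#'   `positives`, `colonoscopies`, `fp_colonoscopies`, `det_naa`, `det_aa`,
#'   `det_crc`, `treatments`.
#' @export
apply_screening_round <- function(dist, params, round_index = 0L,
                                  adherence_decay = 1) {
  cp <- if (inherits(params, "crc_param_set")) compile_params(params) else params
  s <- .S
  sc <- cp$screen
  decay <- adherence_decay^round_index
  part <- sc[["participation"]] * decay
  comp <- sc[["compliance"]] * decay

  m <- as.numeric(dist)
  new <- m
  cost <- 0
  ev <- c(screens = 0, positives = 0, colonoscopies = 0,
          fp_colonoscopies = 0, det_naa = 0, det_aa = 0, det_crc = 0,
          treatments = 0)

  # state, positivity probability, colonoscopy sensitivity, lesion class,
  # treated / declined destinations (NA for lesion-free states)
  plan <- list(
    list(from = s$normal, p_pos = 1 - sc[["spec_initial"]], lesion = NA),
    list(from = s$naa_t, p_pos = 1 - sc[["spec_initial"]], lesion = NA),
    list(from = s$aa_t, p_pos = 1 - sc[["spec_initial"]], lesion = NA),
    list(from = s$naa_u, p_pos = sc[["sens_lesion"]], lesion = "naa",
         colo_sens = sc[["sens_colo_naa"]], to_t = s$naa_t, to_du = s$naa_du),
    list(from = s$naa_du, p_pos = sc[["sens_lesion"]], lesion = "naa",
         colo_sens = sc[["sens_colo_naa"]], to_t = s$naa_t, to_du = s$naa_du),
    list(from = s$aa_u, p_pos = sc[["sens_lesion"]], lesion = "aa",
         colo_sens = sc[["sens_colo_aa"]], to_t = s$aa_t, to_du = s$aa_du),
    list(from = s$aa_du, p_pos = sc[["sens_lesion"]], lesion = "aa",
         colo_sens = sc[["sens_colo_aa"]], to_t = s$aa_t, to_du = s$aa_du)
  )
  for (k in 1:4) {
    plan[[length(plan) + 1L]] <- list(
      from = s$crc1_u + k - 1L, p_pos = sc[["sens_crc"]],
      lesion = paste0("crc", k), colo_sens = sc[["sens_colo_crc"]],
      to_t = s$crc1_t + k - 1L, to_du = s$crc1_du + k - 1L
    )
  }

  for (p in plan) {
    mass <- m[p$from]
    if (mass == 0) next
    screened <- mass * part
    ev[["screens"]] <- ev[["screens"]] + screened
    cost <- cost + screened * cp$cost[["initial_screen"]]
    positives <- screened * p$p_pos
    ev[["positives"]] <- ev[["positives"]] + positives
    colo <- positives * comp
    ev[["colonoscopies"]] <- ev[["colonoscopies"]] + colo
    cost <- cost + colo * cp$cost[["colonoscopy"]]
    if (is.na(p$lesion[1])) {
      # false-positive colonoscopy: cost only, no state change; the share
      # colonoscopy itself mis-calls gets one extra follow-up visit
      ev[["fp_colonoscopies"]] <- ev[["fp_colonoscopies"]] + colo
      cost <- cost + colo * (1 - sc[["spec_colo"]]) * cp$cost[["followup"]]
    } else {
      detected <- colo * p$colo_sens
      cls <- if (startsWith(p$lesion, "crc")) "det_crc" else
        paste0("det_", p$lesion)
      ev[[cls]] <- ev[[cls]] + detected
      tc <- cp$treat_comp[[p$lesion]]
      treat_cost <- cp$cost[[paste0("treat_", p$lesion)]]
      treated <- detected * tc
      ev[["treatments"]] <- ev[["treatments"]] + treated
      cost <- cost + treated * treat_cost
      new[p$from] <- new[p$from] - detected
      new[p$to_t] <- new[p$to_t] + treated
      new[p$to_du] <- new[p$to_du] + detected - treated
    }
  }

  if (abs(sum(new) - sum(m)) > 1e-10) {
    stop("screening round lost probability mass", call. = FALSE)
  }
  list(dist = new, cost = cost, events = ev)
}

# state utility vector at a given age
utility_vector <- function(age, cp) {
  s <- .S
  u <- numeric(21L)
  gen <- cp$u_general[[as.character(age)]]
  # normal, NAA in all compartments, treated AA and undiagnosed preclinical
  # CRC carry the age-specific general-population utility
  u[c(s$normal, s$naa_u, s$naa_t, s$naa_du, s$aa_t,
      s$crc1_u:s$crc4_u)] <- gen
  u[c(s$aa_u, s$aa_du)] <- cp$utility[["aa"]]
  for (k in 1:4) {
    u[c(s$crc1_t + k - 1L, s$crc1_du + k - 1L)] <-
      cp$utility[[paste0("crc", k)]]
  }
  u
}

#' Run a closed cohort through the model under one strategy
#'
#' Annual cycles from the strategy's entry age until the cohort's mean age
#' reaches 82. Within each cycle the order of events is: (1) the screening
#' round, if one is scheduled; (2) symptom detection with its treatment
#' split; (3) natural-history progression and recurrence; (4) mortality --
#' steps 2-4 are composed in the one-cycle transition matrix with background
#' mortality applied first as a competing risk. Utility and state-based cost
#' accrual use the half-cycle mean of the start- and end-of-cycle
#' distributions; cycle-`t` accruals are discounted by `(1 + r)^(-t)`. The
#' fixed programme preparation cost is charged once at entry for any
#' strategy that screens.
#'
#' @param strategy A `crc_strategy` from [screening_strategy()].
#' @param params A `crc_param_set`.
#' @param init Initial distribution: `NULL` (default) for the age-specific
#'   entering mix of [entering_distribution()], `"normal"` for an
#'   all-`normal` cohort, or a length-21 probability vector.
#' @param cohort_size Persons represented by the unit cohort (default
#'   100,000); all reported totals are scaled to it.
#' @param discount Annual discount rate; defaults to the table's
#'   `discount_rate`.
#' @param accrual `"half"` (half-cycle correction, default), `"start"` or
#'   `"end"` — start/end-of-cycle accrual variants for diagnostics.
#' @return A `crc_outcome`: list with `summary` (one-row tibble: discounted
#'   QALYs and costs, undiscounted counterparts, lifetime CRC deaths, other
#'   deaths, colonoscopies, screen detections by class, symptom detections,
#'   screens), `ledger` (per-cycle tibble), `trace` (per-cycle state
#'   distributions), `strategy`, `cohort_size`, `discount`.
#' @export
#' @examples
#' params <- load_parameter_table()
#' out <- run_cohort(screening_strategy(72, "once"), params)
#' glance(out)
run_cohort <- function(strategy, params, init = NULL, cohort_size = 1e5,
                       discount = NULL, accrual = c("half", "start", "end")) {
  stopifnot(inherits(strategy, "crc_strategy"))
  accrual <- match.arg(accrual)
  cp <- prepare_engine(params)
  r <- if (is.null(discount)) cp$discount else discount
  horizon <- 82L - strategy$entry_age
  if (horizon <= 0L) stop("horizon must be positive", call. = FALSE)

  m <- if (is.null(init)) {
    entering_distribution(cp, strategy$entry_age)
  } else if (identical(init, "normal")) {
    initial_distribution()
  } else {
    as.numeric(init)
  }
  stopifnot(length(m) == 21L)
  rounds <- screening_schedule(strategy, horizon)
  s <- .S
  u_states <- c(s$naa_u, s$aa_u, s$crc1_u:s$crc4_u)
  t_states <- c(s$naa_t, s$aa_t, s$crc1_t:s$crc4_t)
  du_states <- c(s$naa_du, s$aa_du, s$crc1_du:s$crc4_du)
  treat_costs <- cp$cost[paste0("treat_", c("naa", "aa", paste0("crc", 1:4)))]

  ledger_cols <- c("cycle", "age", "screens", "positives", "colonoscopies",
                   "fp_colonoscopies", "det_naa", "det_aa", "det_crc",
                   "screen_treatments", "symptom_detections", "crc_deaths",
                   "other_deaths", "cost", "cost_discounted", "qaly",
                   "qaly_discounted")
  L <- matrix(0, horizon, length(ledger_cols),
              dimnames = list(NULL, ledger_cols))
  trace <- matrix(0, horizon + 1L, 21L,
                  dimnames = list(NULL, .state_names))
  round_index <- 0L

  for (t in seq_len(horizon) - 1L) {
    age <- strategy$entry_age + t
    trace[t + 1L, ] <- m
    cost_screen <- 0
    ev <- c(screens = 0, positives = 0, colonoscopies = 0,
            fp_colonoscopies = 0, det_naa = 0, det_aa = 0, det_crc = 0,
            treatments = 0)
    if (t %in% rounds) {
      sr <- apply_screening_round(m, cp, round_index,
                                  strategy$adherence_decay)
      m <- sr$dist
      cost_screen <- sr$cost
      ev <- sr$events
      round_index <- round_index + 1L
    }
    prep <- if (t == 0L && length(rounds) > 0L) cp$cost[["preparation"]] else 0

    M <- cp$M[[as.character(age)]]
    m_next <- drop(m %*% M)

    # event flows of the natural-history step (per unit mass)
    det_t <- m[u_states] * M[cbind(u_states, t_states)]
    det_du <- m[u_states] * M[cbind(u_states, du_states)]
    sympt_det <- sum(det_t) + sum(det_du)
    cost_event <- sympt_det * cp$cost[["diagnosis"]] +
      sum(det_t * treat_costs)
    crc_deaths <- sum(m[1:19] * M[1:19, s$death_crc])
    other_deaths <- sum(m[1:19] * M[1:19, s$death_other])

    hc <- switch(accrual,
                 half = (m + m_next) / 2,
                 start = m,
                 end = m_next)
    qaly <- sum(cp$U[[as.character(age)]] * hc)
    cost_followup <- sum(hc[t_states]) * cp$cost[["followup"]]

    disc <- (1 + r)^(-t)
    cost_total <- cost_screen + cost_event + cost_followup
    cost_abs <- cost_total * cohort_size + prep
    L[t + 1L, ] <- c(
      t, age,
      ev[["screens"]] * cohort_size,
      ev[["positives"]] * cohort_size,
      ev[["colonoscopies"]] * cohort_size,
      ev[["fp_colonoscopies"]] * cohort_size,
      ev[["det_naa"]] * cohort_size,
      ev[["det_aa"]] * cohort_size,
      ev[["det_crc"]] * cohort_size,
      ev[["treatments"]] * cohort_size,
      sympt_det * cohort_size,
      crc_deaths * cohort_size,
      other_deaths * cohort_size,
      cost_abs,
      cost_abs * disc,
      qaly * cohort_size,
      qaly * cohort_size * disc
    )
    m <- m_next
  }
  trace[horizon + 1L, ] <- m
  ledger <- tibble::as_tibble(L)

  if (any(abs(rowSums(trace) - 1) > 1e-10) || any(trace < -1e-12)) {
    stop("cohort mass not conserved", call. = FALSE)
  }

  label <- strategy$frequency
  entry <- strategy$entry_age
  summary <- tibble::tibble(
    strategy = label,
    entry_age = entry,
    qalys = sum(ledger$qaly_discounted),
    cost = sum(ledger$cost_discounted),
    qalys_undiscounted = sum(ledger$qaly),
    cost_undiscounted = sum(ledger$cost),
    crc_deaths = unname(m[s$death_crc]) * cohort_size,
    other_deaths = unname(m[s$death_other]) * cohort_size,
    screens = sum(ledger$screens),
    colonoscopies = sum(ledger$colonoscopies),
    det_naa = sum(ledger$det_naa),
    det_aa = sum(ledger$det_aa),
    det_crc = sum(ledger$det_crc),
    symptom_detections = sum(ledger$symptom_detections)
  )

  structure(
    list(summary = summary, ledger = ledger,
         trace = tibble::as_tibble(trace) |>
           dplyr::mutate(age = strategy$entry_age + dplyr::row_number() - 1L,
                         .before = 1L),
         strategy = strategy, cohort_size = cohort_size, discount = r),
    class = "crc_outcome"
  )
}

#' @export
print.crc_outcome <- function(x, ...) {
  cat("<crc_outcome> strategy:", x$strategy$frequency,
      "| entry age:", x$strategy$entry_age, "\n")
  print(x$summary)
  invisible(x)
}

#' Deaths averted by a strategy relative to a baseline run
#'
#' @param baseline,strategy `crc_outcome` objects sharing entry age and
#'   parameters; `baseline` is normally the no-screening run.
#' @return One-row tibble: `deaths_averted` (baseline lifetime CRC deaths
#'   minus strategy CRC deaths, in cohort persons), `colonoscopies`, and
#'   `colonoscopies_per_death_averted` (`NA` with a warning when no deaths
#'   are averted).
#' @export
deaths_averted <- function(baseline, strategy) {
  stopifnot(inherits(baseline, "crc_outcome"),
            inherits(strategy, "crc_outcome"))
  if (baseline$strategy$entry_age != strategy$strategy$entry_age) {
    stop("outcomes must share an entry age", call. = FALSE)
  }
  averted <- baseline$summary$crc_deaths - strategy$summary$crc_deaths
  colos <- strategy$summary$colonoscopies
  ratio <- if (averted > 0) colos / averted else {
    warning("no deaths averted; colonoscopies per death averted undefined",
            call. = FALSE)
    NA_real_
  }
  label <- strategy$summary$strategy
  entry <- strategy$summary$entry_age
  tibble::tibble(
    strategy = label,
    entry_age = entry,
    deaths_averted = averted,
    colonoscopies = colos,
    colonoscopies_per_death_averted = ratio
  )
}

#' Run the full strategy grid
#'
#' Evaluates every combination of entry age and frequency (plus the
#' no-screening baseline per entry age) and returns one summary row per
#' run.
#'
#' @param params A `crc_param_set`.
#' @param entry_ages Integer vector of initiation ages.
#' @param frequencies Character vector of screening frequencies (the
#'   baseline `"none"` is always added).
#' @param dedup Drop frequencies whose round schedule duplicates a less
#'   intensive strategy's at that entry age (e.g. "every 10 years" from
#'   age 72 collapses to a single round, identical to "once"); default
#'   `TRUE`, matching how such rows are reported in practice.
#' @param ... Passed to [run_cohort()].
#' @return A tibble of per-strategy summaries with class `crc_grid`; the
#'   full `crc_outcome` objects are attached as attribute `"outcomes"`.
#' @export
run_strategy_grid <- function(params,
                              entry_ages = c(42L, 47L, 52L, 57L, 62L, 67L,
                                             72L),
                              frequencies = c("once", "every_10y",
                                              "every_5y", "every_3y",
                                              "every_2y", "annual"),
                              dedup = TRUE, ...) {
  cp <- prepare_engine(params)
  combos <- tidyr::expand_grid(entry_age = entry_ages,
                               frequency = c("none", frequencies))
  if (dedup) {
    sched_key <- purrr::pmap_chr(combos, function(entry_age, frequency) {
      st <- screening_strategy(entry_age, frequency)
      paste(screening_schedule(st, 82L - entry_age), collapse = ",")
    })
    keep <- !duplicated(cbind(combos["entry_age"], key = sched_key)) |
      combos$frequency == "none"
    combos <- combos[keep, ]
  }
  outcomes <- purrr::pmap(combos, function(entry_age, frequency) {
    run_cohort(screening_strategy(entry_age, frequency), cp, ...)
  })
  grid <- purrr::map_dfr(outcomes, ~ .x$summary)
  baselines <- grid[grid$strategy == "none", c("entry_age", "crc_deaths")]
  names(baselines)[2] <- "baseline_crc_deaths"
  grid <- dplyr::left_join(grid, baselines, by = "entry_age") |>
    dplyr::mutate(
      deaths_averted = .data$baseline_crc_deaths - .data$crc_deaths
    ) |>
    dplyr::select(-"baseline_crc_deaths")
  attr(grid, "outcomes") <- outcomes
  class(grid) <- c("crc_grid", class(grid))
  grid
}
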