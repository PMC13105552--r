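test_that("screening round flows reproduce the composed probabilities", {
  # no participation: a no-op with zero cost
  p0 <- set_param(base_params, "participation", 0)
  dist <- initial_distribution()
  res <- apply_screening_round(dist, p0)
  expect_equal(res$dist, unname(dist))
  expect_equal(res$cost, 0)
  expect_equal(unname(res$events["colonoscopies"]), 0)

  # lesion-free cohort: colonoscopies per screen = (1 - specificity) x
  # colonoscopy compliance
  res <- apply_screening_round(initial_distribution(), base_params)
  expect_equal(res$events[["colonoscopies"]] / res$events[["screens"]],
               (1 - 0.7170) * 0.3892, tolerance = 1e-10)
  expect_equal(res$events[["fp_colonoscopies"]],
               res$events[["colonoscopies"]])
  expect_equal(sum(res$dist), 1, tolerance = 1e-12)

  # unit mass of preclinical stage-I CRC: detected fraction is the product
  # participation x CRC sensitivity x compliance x colonoscopy sensitivity
  m <- stats::setNames(numeric(21), names(initial_distribution()))
  m["crc1_u"] <- 1
  res <- apply_screening_round(m, base_params, round_index = 0L)
  expect_equal(res$events[["det_crc"]], 0.5829 * 0.7778 * 0.3892 * 1.00,
               tolerance = 1e-10)
  # treatment compliance splits detections into treated vs declined
  expect_equal(res$dist[[10]], res$events[["det_crc"]] * 0.95,
               tolerance = 1e-10)
  expect_equal(res$dist[[16]], res$events[["det_crc"]] * 0.05,
               tolerance = 1e-10)

  # adherence decay shrinks later rounds
  r0 <- apply_screening_round(m, base_params, 0L, adherence_decay = 0.9)
  r3 <- apply_screening_round(m, base_params, 3L, adherence_decay = 0.9)
  expect_lt(r3$events[["screens"]], r0$events[["screens"]])
})

test_that("cohort runs conserve mass and are bit-reproducible", {
  out <- run_cohort(screening_strategy(42, "annual"), base_params)
  masses <- rowSums(out$trace[, setdiff(names(out$trace), "age")])
  expect_lt(max(abs(masses - 1)), 1e-10)
  expect_true(all(out$trace[, -1] >= 0))
  out2 <- run_cohort(screening_strategy(42, "annual"), base_params)
  expect_identical(out$summary, out2$summary)
  expect_identical(out$ledger, out2$ledger)
  # totals equal the sum of their ledger entries
  expect_equal(out$summary$cost, sum(out$ledger$cost_discounted))
  expect_equal(out$summary$qalys, sum(out$ledger$qaly_discounted))
  expect_equal(out$summary$crc_deaths, sum(out$ledger$crc_deaths),
               tolerance = 1e-8)
})

test_that("degenerate bookkeeping: no deaths, unit utility, no discounting", {
  out <- run_cohort(screening_strategy(42, "none"), no_mortality_params,
                    init = "normal")
  expect_equal(out$summary$qalys, 1e5 * 40, tolerance = 1e-9)
  expect_equal(out$summary$crc_deaths, 0)
  expect_equal(out$summary$other_deaths, 0)
})

test_that("two-cycle cohort matches hand-computed arithmetic", {
  # entry at 80, no screening, all-normal entry: only onset and background
  # mortality act, so the trace is a closed-form product
  out <- run_cohort(screening_strategy(80, "none"), base_params,
                    init = "normal", discount = 0)
  bg <- 0.06802
  onset <- 0.0606
  m1_normal <- (1 - bg) * (1 - onset)
  m1_naa <- (1 - bg) * onset
  expect_equal(out$trace$normal[2], m1_normal, tolerance = 1e-12)
  expect_equal(out$trace$naa_u[2], m1_naa, tolerance = 1e-12)
  expect_equal(out$trace$death_other[3], 1 - (1 - bg)^2, tolerance = 1e-12)
  # half-cycle utility accrual: mean alive mass x general utility, minus
  # the utility decrement of the advanced-adenoma mass arising in cycle 2
  u <- 0.943
  alive <- c(1, 1 - bg, (1 - bg)^2)
  # progression at age 81 uses the 80+ band's NAA-to-AA probability
  m2_aa <- m1_naa * (1 - bg) * (1 - 0.145) * 0.2445
  qaly_hand <- (u * sum((alive[-3] + alive[-1]) / 2) -
                  (u - 0.83) * m2_aa / 2) * 1e5
  expect_equal(out$summary$qalys, qaly_hand, tolerance = 1e-9)
})

test_that("half-cycle accrual lies between start- and end-of-cycle accrual", {
  st <- screening_strategy(52, "every_5y")
  q <- vapply(c("start", "half", "end"), function(a) {
    run_cohort(st, base_params, accrual = a)$summary$qalys
  }, numeric(1))
  expect_lt(q[["end"]], q[["half"]])
  expect_lt(q[["half"]], q[["start"]])
})

test_that("discounting and screening sensitivities act monotonically", {
  st <- screening_strategy(47, "every_3y")
  hi <- run_cohort(st, base_params, discount = 0.05)
  lo <- run_cohort(st, base_params, discount = 0.03)
  expect_lt(hi$summary$qalys, lo$summary$qalys)
  expect_lt(hi$summary$cost, lo$summary$cost)

  # zero screening sensitivity: health outcomes collapse to baseline,
  # only screening costs remain
  blind <- set_param(set_param(base_params, "sens_initial_lesion", 0),
                     "sens_initial_crc", 0)
  none <- run_cohort(screening_strategy(62, "none"), blind)
  annual <- run_cohort(screening_strategy(62, "annual"), blind)
  expect_equal(annual$summary$crc_deaths, none$summary$crc_deaths,
               tolerance = 1e-10)
  expect_equal(annual$summary$qalys, none$summary$qalys, tolerance = 1e-10)
  expect_gt(annual$summary$cost, none$summary$cost)
})

test_that("deaths averted grow with screening frequency at every entry age", {
  grid <- run_strategy_grid(base_params, entry_ages = c(42L, 62L, 72L))
  for (ea in unique(grid$entry_age)) {
    da <- grid$deaths_averted[grid$entry_age == ea &
                                grid$strategy != "none"]
    colos <- grid$colonoscopies[grid$entry_age == ea &
                                  grid$strategy != "none"]
    expect_true(all(diff(da) > 0))
    expect_true(all(diff(colos) > 0))
    expect_true(all(da > 0))
  }
})

test_that("deaths_averted compares runs and flags the degenerate ratio", {
  none <- run_cohort(screening_strategy(72, "none"), base_params)
  annual <- run_cohort(screening_strategy(72, "annual"), base_params)
  da <- deaths_averted(none, annual)
  expect_gt(da$deaths_averted, 0)
  expect_equal(da$colonoscopies_per_death_averted,
               annual$summary$colonoscopies / da$deaths_averted)
  expect_warning(self <- deaths_averted(none, none), "undefined")
  expect_equal(self$deaths_averted, 0)
  expect_true(is.na(self$colonoscopies_per_death_averted))
  other_age <- run_cohort(screening_strategy(67, "none"), base_params)
  expect_error(deaths_averted(none, other_age), "entry age")
})

test_that("duplicate round schedules are dropped from the grid", {
  grid <- run_strategy_grid(base_params, entry_ages = 72L)
  expect_setequal(grid$strategy, c("none", "once", "every_2y", "annual"))
  grid_all <- run_strategy_grid(base_params, entry_ages = 72L,
                                dedup = FALSE)
  expect_equal(nrow(grid_all), 7L)
})
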