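test_that("a degenerate sweep reproduces the base-case comparison", {
  base_cea <- rank_and_compare(run_strategy_grid(base_params,
                                                 entry_ages = 62L))
  sweep <- one_way_sweep(base_params, "participation", 0.5829,
                         entry_ages = 62L)
  expect_equal(sweep$icer_vs_none, base_cea$icer_vs_none)
  expect_false(any(sweep$ranking_changed))
  expect_error(one_way_sweep(base_params, "not_a_parameter", 0.5),
               "unknown parameter")
  expect_error(one_way_sweep(base_params, "participation", 1.2), "\\[0, 1\\]")
})

test_that("deaths averted rise with colonoscopy compliance", {
  sweep <- one_way_sweep(base_params, "compliance_colonoscopy",
                         c(0.3, 0.5, 0.8), entry_ages = 42L,
                         frequencies = "annual")
  da <- sweep$deaths_averted[sweep$strategy == "annual"]
  expect_equal(length(da), 3L)
  expect_true(all(diff(da) > 0))
})

test_that("QALYs fall monotonically in the discount rate", {
  sweep <- one_way_sweep(base_params, "discount_rate", c(0, 0.05),
                         entry_ages = 52L, frequencies = "every_5y")
  q <- sweep$qalys[sweep$strategy == "every_5y"]
  expect_lt(q[2], q[1])
})

test_that("PSA with fixed distributions equals the base case", {
  psa <- run_psa(fixed_params, n_draws = 1, seed = 5,
                 frequencies = c("once", "annual"))
  joined <- dplyr::left_join(psa$draws, psa$base,
                             by = c("entry_age", "strategy"),
                             suffix = c("", "_base"))
  expect_equal(joined$qalys, joined$qalys_base, tolerance = 1e-12)
  expect_equal(joined$cost, joined$cost_base, tolerance = 1e-12)
})

test_that("PSA is reproducible under a fixed master seed", {
  a <- run_psa(base_params, n_draws = 3, seed = 9,
               frequencies = c("once", "annual"))
  b <- run_psa(base_params, n_draws = 3, seed = 9,
               frequencies = c("once", "annual"))
  c <- run_psa(base_params, n_draws = 3, seed = 10,
               frequencies = c("once", "annual"))
  expect_identical(a$draws, b$draws)
  expect_false(identical(a$draws, c$draws))
  # draw i sees the same parameters regardless of the number of draws
  a1 <- run_psa(base_params, n_draws = 1, seed = 9,
                frequencies = c("once", "annual"))
  expect_identical(a1$draws, a$draws[a$draws$draw == 1, ])
})

test_that("acceptability curves are coherent probabilities", {
  psa <- run_psa(base_params, n_draws = 4, seed = 21,
                 frequencies = c("once", "every_2y", "annual"))
  cc <- ceac(psa, wtp_grid = c(0, 10000, 53235, 1e9))
  expect_true(all(cc$p_ce >= 0 & cc$p_ce <= 1))
  sums <- cc |>
    dplyr::group_by(.data$wtp) |>
    dplyr::summarise(total = sum(.data$p_optimal))
  expect_equal(sums$total, rep(1, 4), tolerance = 1e-12)

  # single-draw probabilities are 0/1
  one <- ceac(run_psa(fixed_params, 1, 1, frequencies = "annual"),
              wtp_grid = c(0, 53235))
  expect_true(all(one$p_optimal %in% c(0, 1)))
  # at zero willingness to pay the cheapest option (no screening) is
  # optimal; as wtp grows without bound the QALY-maximising strategy wins
  expect_equal(one$p_optimal[one$wtp == 0 & one$strategy == "none"], 1)
  fix4 <- ceac(run_psa(fixed_params, 1, 1,
                       frequencies = c("once", "annual")),
               wtp_grid = c(0, 1e12))
  expect_equal(fix4$p_optimal[fix4$wtp == 1e12 &
                                fix4$strategy == "annual"], 1)
})
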