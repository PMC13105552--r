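test_that("synthetic initial distributions are reproducible and structured", {
  a <- synth_initial_distribution(3L, params = base_params, noise_sd = 0.2)
  b <- synth_initial_distribution(3L, params = base_params, noise_sd = 0.2)
  expect_identical(a, b)
  # noise-free output is exactly the model's own prevalence wherever the
  # structural severity clamp does not bind (it binds above age 65, where
  # raw advanced-adenoma prevalence overtakes non-advanced)
  clean <- synth_initial_distribution(1L, params = base_params)
  raw <- prevalence_by_band(base_params, default_age_bands())
  sub <- clean$age_high <= 64
  expect_equal(as.matrix(clean[sub, c("naa", "aa", "crc")]),
               as.matrix(raw[sub, c("naa", "aa", "crc")]),
               tolerance = 1e-12, ignore_attr = TRUE)
  # severity and age orderings hold for any seed, even under heavy noise
  for (seed in 1:10) {
    tab <- synth_initial_distribution(seed, params = base_params,
                                      noise_sd = 0.5)
    expect_true(all(tab$naa >= tab$aa & tab$aa >= tab$crc))
    for (cls in c("naa", "aa", "crc")) {
      expect_true(all(diff(tab[[cls]]) >= 0))
    }
  }
  expect_s3_class(attr(a, "generator_params"), "crc_param_set")
})

test_that("synthetic registry curves carry calibrated noise", {
  clean <- synth_registry_curves(1L, base_params, noise_sd = 0)
  fit <- goodness_of_fit(clean$incidence, clean$incidence_true)
  expect_equal(fit$r_squared, 1)
  expect_equal(fit$rmse, 0)

  rmses <- vapply(1:8, function(seed) {
    cur <- synth_registry_curves(seed, base_params, noise_sd = 15)
    goodness_of_fit(cur$incidence_true, cur$incidence)$rmse
  }, numeric(1))
  expect_true(all(rmses >= 10 & rmses <= 22))

  for (seed in 1:5) {
    cur <- synth_registry_curves(seed, base_params, noise_sd = 25)
    expect_true(all(cur$mortality <= cur$incidence))
    expect_true(all(cur$incidence >= 0))
  }
})

test_that("synthetic cascade counts follow the binomial model", {
  probs1 <- list(participation = 1, positivity = 1, compliance = 1,
                 det_naa = 1, det_aa = 1, det_crc = 1)
  full <- synth_program_counts(1L, 5000, params = base_params,
                               probs = probs1)
  expect_equal(full$completers, 5000)
  expect_equal(full$colonoscopies, 5000)
  expect_equal(full$detected_crc, 5000)

  # sample mean of completers over 200 seeded draws vs binomial expectation
  printed <- list(participation = 0.5829, positivity = 0.1527,
                  compliance = 0.3892, det_naa = 0.2118, det_aa = 0.1155,
                  det_crc = 0.0110)
  comp <- vapply(1:200, function(seed) {
    synth_program_counts(seed, 10000L, params = base_params,
                         probs = printed)$completers
  }, numeric(1))
  se <- sqrt(10000 * 0.5829 * (1 - 0.5829)) / sqrt(200)
  expect_lt(abs(mean(comp) - 10000 * 0.5829), 3 * se)

  # at programme scale one draw is within a fraction of a percent of the
  # published completer count
  prog <- synth_program_counts(11L, 17780462L, params = base_params,
                               probs = printed)
  expect_lt(abs(prog$completers - 10364955) / 10364955, 0.001)
  expect_identical(prog, synth_program_counts(11L, 17780462L,
                                              params = base_params,
                                              probs = printed))
  # model-derived cascade probabilities are valid probabilities
  derived <- attr(synth_program_counts(2L, 1000L, params = base_params),
                  "probs")
  expect_true(all(unlist(derived) >= 0 & unlist(derived) <= 1))
})
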