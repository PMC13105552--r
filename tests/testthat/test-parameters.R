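test_that("packaged table reproduces the programme base case", {
  expect_equal(param_value(base_params, "participation"), 0.5829)
  expect_equal(param_value(base_params, "cost_treat_aa"), 1185)
  expect_equal(param_value(base_params, "compliance_colonoscopy"), 0.3892)
  expect_equal(param_value(base_params, "sens_initial_crc"), 0.7778)
  expect_equal(param_value(base_params, "discount_rate"), 0.03)
  # age-banded lookups
  expect_equal(param_value(base_params, "p_normal_naa", age = 45), 0.0147)
  expect_equal(param_value(base_params, "p_normal_naa", age = 81), 0.0606)
  expect_equal(param_value(base_params, "bg_mort", age = 47), 0.00226)
  expect_equal(param_value(base_params, "utility_general", age = 60), 0.957)
  # banded parameter demands an age
  expect_error(param_value(base_params, "bg_mort"), "age-banded")
})

test_that("validation rejects malformed parameter tables", {
  tab <- tibble::as_tibble(base_params)
  bad <- tab
  bad$base[bad$name == "participation"] <- 1.2
  bad$ui_high[bad$name == "participation"] <- 1.3
  expect_error(as_param_set(bad), "outside \\[0, 1\\]")

  bad <- tab
  bad$base[bad$name == "utility_aa"] <- 0.95  # above its ui_high of 0.90
  expect_error(as_param_set(bad), "outside its uncertainty interval")

  bad <- tab
  bad$distribution[1] <- "cauchy"
  expect_error(as_param_set(bad), "unknown distribution")

  expect_error(as_param_set(tab[tab$name != "participation", ]),
               "missing mandatory")
})

test_that("a parameter set round-trips through CSV exactly", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_parameter_table(base_params, path)
  reloaded <- load_parameter_table(path)
  for (col in c("name", "base", "ui_low", "ui_high", "distribution")) {
    expect_identical(reloaded[[col]], base_params[[col]])
  }
})

test_that("distribution families follow the method-of-moments convention", {
  set.seed(42)
  # beta with mean 0.83 and sd (0.90 - 0.80)/3.92
  d <- build_distribution(0.83, 0.80, 0.90, "beta")
  draws <- draw_distribution(d, 1e4)
  expect_lt(abs(mean(draws) - 0.83), 0.005)
  expect_true(all(draws > 0 & draws < 1))
  expect_equal(dist_mean(d), 0.83)

  # gamma reproduces mean and sd within Monte-Carlo error at 1e5 draws
  g <- build_distribution(1185, 593, 1778, "gamma")
  gd <- draw_distribution(g, 1e5)
  expect_lt(abs(mean(gd) - 1185) / 1185, 0.01)
  expect_lt(abs(stats::sd(gd) - (1778 - 593) / 3.92) / 302, 0.02)

  # triangular support and fixed degeneracy
  tr <- build_distribution(0.3892, 0.2690, 0.5290, "triangular")
  td <- draw_distribution(tr, 1e4)
  expect_true(all(td >= 0.2690 & td <= 0.5290))
  expect_equal(draw_distribution(build_distribution(0.03, 0, 0.05, "fixed"),
                                 5),
               rep(0.03, 5))

  # uniform discount rate: sample mean near (0 + 0.05) / 2
  u <- build_distribution(0.03, 0, 0.05, "uniform")
  expect_lt(abs(mean(draw_distribution(u, 1e4)) - 0.025), 0.001)

  # invalid parameterisations
  expect_error(build_distribution(1.2, 1.0, 1.5, "beta"), "inside \\(0, 1\\)")
  expect_error(build_distribution(0, -1, 1, "gamma"), "positive mean")
  expect_error(build_distribution(0.5, 0.6, 0.9, "uniform"), "inside")
})

test_that("joint parameter draws are reproducible and respect supports", {
  d1 <- sample_parameter_draw(base_params, 101)
  d2 <- sample_parameter_draw(base_params, 101)
  d3 <- sample_parameter_draw(base_params, 102)
  expect_identical(d1$base, d2$base)
  expect_false(identical(d1$base, d3$base))

  for (seed in 1:20) {
    d <- sample_parameter_draw(base_params, seed)
    bounded <- d$units %in% c("probability", "utility")
    expect_true(all(d$base[bounded] >= 0 & d$base[bounded] <= 1))
    expect_true(all(d$base[d$units == "USD"] >= 0))
    interval <- d$distribution %in% c("triangular", "uniform", "fixed")
    expect_true(all(d$base[interval] >= base_params$ui_low[interval] &
                      d$base[interval] <= base_params$ui_high[interval]))
    # background mortality is fixed, never resampled
    expect_identical(d$base[d$name == "bg_mort"],
                     base_params$base[base_params$name == "bg_mort"])
  }
})

test_that("uncertainty intervals of repeated draws bracket the base case", {
  draws <- vapply(1:200, function(s) sample_parameter_draw(base_params,
                                                           s)$base,
                  numeric(nrow(base_params)))
  free <- base_params$distribution != "fixed"
  lo <- apply(draws, 1, stats::quantile, 0.025)
  hi <- apply(draws, 1, stats::quantile, 0.975)
  inside <- base_params$base >= lo & base_params$base <= hi
  expect_gte(mean(inside[free]), 0.9)
})
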