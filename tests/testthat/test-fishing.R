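p <- species_params()

test_that("selectivity: midpoint, hand value, knife-edge limit", {
  # age whose length equals the legal length -> 0.5 exactly
  age_legal <- p$t0 - log(1 - p$legal_length / p$linf) / p$k_growth
  expect_equal(selectivity_at_age(age_legal, p), 0.5, tolerance = 1e-12)
  # L - legal = 10 at steepness 0.2 -> 1/(1+e^-2)
  q <- species_params(legal_length = length_at_age(10, p) - 10)
  expect_equal(selectivity_at_age(10, q, steepness = 0.2),
               1 / (1 + exp(-2)), tolerance = 1e-12)
  # very steep -> knife edge around legal length
  expect_lt(selectivity_at_age(0, p, steepness = 1e4), 1e-10)
  expect_gt(selectivity_at_age(p$max_age, p, steepness = 1e4), 1 - 1e-10)
})

test_that("fishable biomass: sublegal stocks, no-farm identity, farm zeroing", {
  n_age <- p$max_age + 1
  num <- matrix(0, 2, n_age)
  num[, 1] <- 1000                       # age-0 fish only, far below legal
  w <- matrix(1, 2, n_age)
  env <- patch_environment(rep(500, 2))
  s <- population_state(num, w)
  expect_true(all(fishable_biomass(s, env, p, steepness = 1e4) < 1e-6))

  num2 <- matrix(10, 2, n_age)
  s2 <- population_state(num2, w)
  nu <- selectivity_at_age(0:p$max_age, p)
  expect_equal(fishable_biomass(s2, env, p), rep(sum(10 * nu), 2))

  env_farm <- patch_environment(rep(500, 2), is_farm = c(TRUE, FALSE))
  fb <- fishable_biomass(s2, env_farm, p)
  expect_equal(fb[1], 0)
  expect_gt(fb[2], 0)
})

test_that("gravity effort allocation", {
  expect_equal(allocate_effort(0.2, rep(7, 5))$f_by_patch, rep(0.2, 5))
  one <- allocate_effort(0.3, c(0, 0, 9, 0))
  expect_equal(one$f_by_patch, c(0, 0, 0.3, 0))
  g <- allocate_effort(0.3, c(2, 1, 1))
  expect_equal(g$f_by_patch, c(0.45, 0.225, 0.225))
  expect_equal(g$total_effort, 0.9)
})

test_that("farm effort redistribution conserves aggregate effort", {
  n <- 4
  env <- patch_environment(rep(1, n), is_farm = c(TRUE, FALSE, FALSE, FALSE))
  bau <- effort_field(rep(0.25, n))
  fb <- c(0, 3, 2, 1)
  red <- redistribute_for_farm(bau, env, fb)
  expect_equal(red$f_by_patch, 1 * c(0, 3, 2, 1) / 6)
  expect_equal(red$total_effort, bau$total_effort, tolerance = 1e-9)
  # no farms -> identity
  env0 <- patch_environment(rep(1, n))
  expect_equal(redistribute_for_farm(bau, env0, fb)$f_by_patch,
               bau$f_by_patch)
  # half the patches farmed, uniform biomass -> remaining F doubles
  env2 <- patch_environment(rep(1, n), is_farm = c(TRUE, TRUE, FALSE, FALSE))
  red2 <- redistribute_for_farm(bau, env2, c(0, 0, 5, 5))
  expect_equal(red2$f_by_patch, c(0, 0, 0.5, 0.5))
})

test_that("harvest: zero effort, all-catch limit, Baranov hand value", {
  n_age <- p$max_age + 1
  num <- matrix(50, 3, n_age)
  w <- matrix(2, 3, n_age)
  s <- population_state(num, w)
  h0 <- harvest(s, effort_field(rep(0, 3)), p)
  expect_equal(h0$total_catch, 0)
  expect_equal(h0$state$numbers, num * exp(-p$m_nat), ignore_attr = TRUE)

  # M -> 0 with flat selectivity: all deaths are catch
  q <- species_params(m_nat = 1e-12, legal_length = 0)
  hq <- harvest(s, effort_field(rep(0.4, 3)), q, steepness = 0)
  # steepness 0 gives nu = 0.5 for every age
  expect_equal(hq$total_catch,
               sum(num * (1 - exp(-0.4 * 0.5)) * w), tolerance = 1e-6)

  # single patch, single cohort, N = 1000, w = 1, M = 0.2, F = 0.3, nu = 1
  num1 <- matrix(c(0, 1000, 0), 1, 3)
  w1 <- matrix(1, 1, 3)
  s1 <- population_state(num1, w1)
  q1 <- species_params(m_nat = 0.2, max_age = 2, legal_length = 0)
  h1 <- harvest(s1, effort_field(0.3), q1, steepness = 1e6)
  expect_equal(h1$total_catch, (0.3 / 0.5) * 1000 * (1 - exp(-0.5)),
               tolerance = 1e-9)
})

test_that("harvest leaves zero abundance at zero", {
  n_age <- p$max_age + 1
  s <- population_state(matrix(0, 2, n_age), matrix(1, 2, n_age))
  h <- harvest(s, effort_field(rep(0.5, 2)), p)
  expect_equal(h$total_catch, 0)
  expect_true(all(h$state$numbers == 0))
})

test_that("open access effort: price zero and free effort limits", {
  base <- unfished_equilibrium(default_species(range_fraction = 0.2), 50, 5e4)
  q <- default_species(range_fraction = 0.2)
  f0 <- fishery_config("weak_open_access", price = 1e-12,
                       cost_per_effort = 100, max_effort = 100)
  expect_equal(open_access_effort(base$state, base$env, q, f0), 0,
               tolerance = 1e-4)
  f_free <- fishery_config("weak_open_access", price = 10,
                           cost_per_effort = 1e-9, max_effort = 100)
  expect_equal(open_access_effort(base$state, base$env, q, f_free), 100,
               tolerance = 1e-3)
})

test_that("open access maximiser matches a dense scan of the profit curve", {
  base <- unfished_equilibrium(default_species(range_fraction = 0.2), 20, 2e4)
  q <- default_species(range_fraction = 0.2)
  f <- fishery_config("weak_open_access", price = 1, cost_per_effort = 300,
                      max_effort = 40)
  fb <- fishable_biomass(base$state, base$env, q, f$selectivity_steepness)
  profit <- vapply(seq(0, 40, by = 0.05), function(e) {
    eff <- effort_field(e * fb / sum(fb))
    h <- harvest(base$state, eff, q, base$env, 1, f$selectivity_steepness)
    f$price * h$total_catch - f$cost_per_effort * e
  }, numeric(1))
  scan_best <- seq(0, 40, by = 0.05)[which.max(profit)]
  expect_equal(open_access_effort(base$state, base$env, q, f), scan_best,
               tolerance = 0.06)
})
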