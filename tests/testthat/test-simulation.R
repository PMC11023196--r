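# Shared small system: 50 patches keeps these integration tests fast.
params50 <- default_species(range_fraction = 0.2)
params50$sigma_m <- sigma_from_range(0.2, 50)
base50 <- unfished_equilibrium(params50, 50, 5e4)
kern50 <- build_kernel(params50$sigma_m, 50)

test_that("unfished equilibrium is a fixed point of the annual step", {
  s <- step_population(base50$state, base50$env, kern50,
                       effort = effort_field(rep(0, 50)),
                       params = params50)$state
  expect_equal(total_biomass(s), total_biomass(base50$state),
               tolerance = 1e-9)
  expect_equal(patch_biomass(s), patch_biomass(base50$state),
               tolerance = 1e-9)
})

test_that("zero abundance stays zero with zero catch", {
  s0 <- base50$state
  s0$numbers[] <- 0
  out <- step_population(s0, base50$env, kern50,
                         effort = effort_field(rep(0.3, 50)),
                         params = params50)
  expect_equal(out$total_catch, 0)
  expect_true(all(out$state$numbers == 0))
})

test_that("one step equals the manual composition of its six stages", {
  state <- base50$state
  state$numbers <- state$numbers * 0.8   # off equilibrium
  env <- base50$env
  eff <- effort_field(rep(0.1, 50))

  out <- step_population(state, env, kern50, effort = eff, params = params50)

  # stage 1: density-dependent movement
  man <- state
  e_frac <- pmin(1, patch_biomass(man) /
                   (params50$move_threshold * env$k_patch))
  moving <- man$numbers * e_frac
  man$numbers <- move(moving, kern50) + man$numbers - moving
  # stage 2: growth factor
  gf <- pmax(0, 1 - patch_biomass(man) / env$k_patch)
  # stage 3: recruitment
  man$numbers[, 1] <- settle_and_survive(spawn(man, params50), env, params50)
  # stage 5: harvest (stage 4 effort is supplied)
  h <- harvest(man, eff, params50)
  man <- h$state
  # stage 6: aging
  man <- advance_age(man, params50, growth_factor = gf)

  expect_equal(out$state$numbers, man$numbers, tolerance = 1e-12)
  expect_equal(out$state$weight_at_age, man$weight_at_age, tolerance = 1e-12)
  expect_equal(out$total_catch, h$total_catch, tolerance = 1e-12)
})

test_that("strong-management BAU converges to the MSY search optimum", {
  fishery <- default_fishery("strong")
  msy <- find_msy_effort(base50, params50, fishery)
  cfg <- sim_config(params = params50, fishery = fishery, design = NULL,
                    n_patches = 50, total_biomass_target = 5e4)
  run <- run_to_equilibrium(cfg, base = base50, msy_effort = msy$effort)
  expect_true(run$bau$converged)
  expect_equal(run$bau$equilibrium_catch, msy$msy, tolerance = 1e-3)
})

test_that("MSY effort is a local maximum of the yield curve", {
  fishery <- default_fishery("strong")
  msy <- find_msy_effort(base50, params50, fishery)
  y <- function(e) equilibrium_catch_at_effort(e, base50, kern50, params50,
                                               fishery)
  expect_gte(msy$msy * (1 + 1e-6), y(0.9 * msy$effort))
  expect_gte(msy$msy * (1 + 1e-6), y(1.1 * msy$effort))
  expect_equal(y(0), 0)
})

test_that("equilibrium biomass ordering: open access < MSY < unfished", {
  f_strong <- default_fishery("strong")
  # catch scales with system biomass (half the default here), so halve the
  # unit effort cost to keep the same open-access incentives
  f_weak <- default_fishery("weak",
                            cost_per_effort =
                              default_fishery("weak")$cost_per_effort / 2)
  msy <- find_msy_effort(base50, params50, f_strong)
  cfg_s <- sim_config(params = params50, fishery = f_strong,
                      n_patches = 50, total_biomass_target = 5e4)
  run_s <- run_to_equilibrium(cfg_s, base = base50, msy_effort = msy$effort)
  cfg_w <- sim_config(params = params50, fishery = f_weak,
                      n_patches = 50, total_biomass_target = 5e4)
  run_w <- run_to_equilibrium(cfg_w, base = base50)
  expect_lt(run_w$bau$equilibrium_biomass, run_s$bau$equilibrium_biomass)
  expect_lt(run_s$bau$equilibrium_biomass, base50$equilibrium_biomass)
})

test_that("reruns with an identical configuration are bit-identical", {
  fishery <- default_fishery("weak")
  d <- farm_design(0.1, layout = "several_small", attraction = 5)
  cfg <- sim_config(params = params50, fishery = fishery, design = d,
                    n_patches = 50, total_biomass_target = 5e4)
  r1 <- run_to_equilibrium(cfg, base = base50)
  r2 <- run_to_equilibrium(cfg, base = base50)
  expect_identical(r1$farm$biomass_trajectory, r2$farm$biomass_trajectory)
  expect_identical(r1$farm$catch_trajectory, r2$farm$catch_trajectory)
})

test_that("relative outcomes: identity, never-recovering, and crossing cases", {
  mk <- function(catches, biomass = 100) {
    structure(list(biomass_trajectory = rep(biomass, length(catches)),
                   catch_trajectory = catches,
                   equilibrium_biomass = biomass,
                   equilibrium_catch = catches[length(catches)],
                   converged = TRUE, years_run = length(catches)),
              class = "scenario_result")
  }
  bau <- mk(rep(10, 10))
  expect_equal(relative_outcomes(mk(rep(10, 10)), bau),
               list(delta_b = 1, delta_c = 1, recovery_year = 0L),
               ignore_attr = TRUE)
  low <- relative_outcomes(mk(rep(5, 10)), bau)
  expect_equal(low$delta_c, 0.5)
  expect_true(is.na(low$recovery_year))
  crossing <- mk(c(rep(4, 7), rep(12, 3)))
  expect_equal(relative_outcomes(crossing, bau)$recovery_year, 7L)
})
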