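#' One annual time step of the coupled population-fishery model
#'
#' Stages, in fixed order: (1) adult movement through the kernel; (2)
#' computation of the per-patch density-dependent growth factor
#' \code{max(0, 1 - bm/K)}; (3) spawning, uniform larval settlement, and
#' Beverton-Holt recruit survival into the age-0 class; (4) effort
#' determination for the year (a supplied field, a fixed aggregate effort
#' spread by gravity over fishable biomass, or the open-access
#' profit-maximising effort); (5) combined natural and fishing mortality with
#' Baranov catch accounting (the farm mortality multiplier folds into M in
#' farm patches); (6) aging with density-dependent weight growth and the
#' plus group.
#'
#' @param state A [population_state()].
#' @param env A [patch_environment()].
#' @param kernel A movement kernel (attraction-modified for farm scenarios).
#' @param effort An [effort_field()] to use verbatim, or \code{NULL} to
#'   derive effort from \code{fixed_effort} / \code{fishery}.
#' @param params A [species_params()] object.
#' @param fishery A [fishery_config()]; required when \code{effort} and
#'   \code{fixed_effort} are both \code{NULL}.
#' @param fixed_effort Aggregate effort to spread by gravity (used by the
#'   strong regime, where it stays at the MSY level in all scenarios).
#' @param farm_m_multiplier Natural-mortality multiplier in farm patches.
#' @param dd_movement When \code{TRUE} (default), emigration is density
#'   dependent: the fraction of a patch's fish that disperse through the
#'   kernel each year is \code{min(1, c_i / theta)} with crowding
#'   \code{c_i = bm_i / K_i} and \code{theta = params$move_threshold} the
#'   crowding level at which mixing is complete; the rest stay put. Fish emigrate when their patch is near its capacity
#'   and stay when there is room, the same density signal that governs
#'   growth and recruitment. A spatially uniform (no-farm) system has a
#'   uniform emigration fraction, so its equilibrium is identical to the
#'   plain-kernel one; at farms, whose elevated carrying capacity keeps
#'   crowding low, fish are retained until the farm fills, after which
#'   spillover to the surrounding fishery resumes.
#' @return List with the advanced \code{state}, per-patch \code{catch},
#'   \code{total_catch}, and the aggregate \code{effort} applied.
#' @export
step_population <- function(state, env, kernel, effort = NULL, params,
                            fishery = NULL, fixed_effort = NULL,
                            farm_m_multiplier = 1, dd_movement = TRUE) {
  sel_steep <- if (is.null(fishery)) 0.25 else fishery$selectivity_steepness

  # (1) adult movement (optionally density dependent)
  if (dd_movement) {
    theta <- if (!is.null(params$move_threshold)) params$move_threshold else 1
    e_frac <- pmin(1, patch_biomass(state) / (theta * env$k_patch))
    moving <- state$numbers * e_frac
    state$numbers <- move(moving, kernel) + state$numbers - moving
  } else {
    state$numbers <- move(state$numbers, kernel)
  }

  # (2) density-dependent growth factor from post-movement crowding
  bm <- patch_biomass(state)
  gf <- pmax(0, 1 - bm / env$k_patch)

  # (3) larval production, uniform settlement, density-dependent survival
  larvae <- spawn(state, params)
  recruits <- settle_and_survive(larvae, env, params)
  state$numbers[, 1] <- recruits
  state$weight_at_age[, 1] <- weight_at_age_free(0, params)

  # (4) effort for the year
  if (is.null(effort)) {
    if (!is.null(fixed_effort)) {
      fb <- fishable_biomass(state, env, params, sel_steep)
      tot <- sum(fb)
      effort <- if (tot > 0) effort_field(fixed_effort * fb / tot)
                else effort_field(rep(0, nrow(env)))
    } else if (!is.null(fishery) && fishery$regime == "weak_open_access") {
      e_total <- open_access_effort(state, env, params, fishery,
                                    farm_m_multiplier)
      fb <- fishable_biomass(state, env, params, sel_steep)
      tot <- sum(fb)
      effort <- if (tot > 0) effort_field(e_total * fb / tot)
                else effort_field(rep(0, nrow(env)))
    } else {
      stop("supply an effort field, a fixed aggregate effort, or a fishery config")
    }
  }

  # (5) combined mortality and catch
  h <- harvest(state, effort, params, env, farm_m_multiplier, sel_steep)
  state <- h$state

  # (6) aging with density-dependent growth
  state <- advance_age(state, params, growth_factor = gf)

  if (any(!is.finite(state$numbers)) || any(state$numbers < 0))
    stop(sprintf("numerical integrity lost at year %d", state$year))

  list(state = state, catch = h$catch, total_catch = h$total_catch,
       effort = effort$total_effort)
}

#' Simulation scenario configuration
#'
#' @param params A [species_params()] object; when \code{params$range_fraction}
#'   is set, \code{sigma_m} is derived from it via [sigma_from_range()].
#' @param fishery A [fishery_config()].
#' @param design A [farm_design()] or \code{NULL} for a no-farm run.
#' @param n_patches Lattice size (default 100).
#' @param total_biomass_target Unfished equilibrium system biomass the
#'   carrying-capacity calibration aims for.
#' @param max_years Cap on post-introduction years.
#' @param tol Relative-change tolerance for equilibrium detection.
#' @param window Consecutive sub-tolerance years required to declare
#'   equilibrium.
#' @param dd_movement Use density-dependent emigration (see
#'   [step_population()]).
#' @return An object of class \code{sim_config}.
#' @export
sim_config <- function(params = default_species(), fishery = fishery_config(),
                       design = NULL, n_patches = 100,
                       total_biomass_target = 1e5,
                       max_years = 500, tol = 1e-6, window = 10L,
                       dd_movement = TRUE) {
  if (!is.null(params$range_fraction))
    params$sigma_m <- sigma_from_range(params$range_fraction, n_patches)
  structure(list(params = params, fishery = fishery, design = design,
                 n_patches = n_patches,
                 total_biomass_target = total_biomass_target,
                 max_years = max_years, tol = tol, window = as.integer(window),
                 dd_movement = dd_movement),
            class = "sim_config")
}

run_until_stable <- function(state, env, kernel, params, fishery,
                             fixed_effort, farm_m_multiplier,
                             max_years, tol, window, dd_movement = TRUE) {
  b_traj <- numeric(0)
  c_traj <- numeric(0)
  e_traj <- numeric(0)
  prev_b <- total_biomass(state)
  prev_c <- NA_real_
  ok <- 0L
  converged <- FALSE
  for (yr in seq_len(max_years)) {
    out <- step_population(state, env, kernel, effort = NULL, params = params,
                           fishery = fishery, fixed_effort = fixed_effort,
                           farm_m_multiplier = farm_m_multiplier,
                           dd_movement = dd_movement)
    state <- out$state
    cur_b <- total_biomass(state)
    b_traj[yr] <- cur_b
    c_traj[yr] <- out$total_catch
    e_traj[yr] <- out$effort
    rel_b <- abs(cur_b - prev_b) / max(abs(prev_b), 1e-12)
    rel_c <- if (is.na(prev_c)) Inf
             else abs(out$total_catch - prev_c) / max(abs(prev_c), 1e-12)
    if (max(prev_c, out$total_catch, na.rm = TRUE) < 1e-12) rel_c <- 0
    ok <- if (max(rel_b, rel_c) < tol) ok + 1L else 0L
    prev_b <- cur_b
    prev_c <- out$total_catch
    if (ok >= window) { converged <- TRUE; break }
  }
  if (!is.finite(prev_b)) stop("biomass diverged")
  structure(list(biomass_trajectory = b_traj, catch_trajectory = c_traj,
                 effort_trajectory = e_traj,
                 equilibrium_biomass = prev_b, equilibrium_catch = prev_c,
                 converged = converged, years_run = length(b_traj),
                 final_state = state),
            class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  cat(sprintf(
    "<scenario_result> %d years (%s): equilibrium biomass %.4g, catch %.4g\n",
    x$years_run, if (x$converged) "converged" else "NOT converged",
    x$equilibrium_biomass, x$equilibrium_catch))
  invisible(x)
}

#' Run a scenario to equilibrium, with its no-farm baseline
#'
#' The business-as-usual (BAU) system - same species, same management, no
#' farms - is burnt in from the unfished equilibrium until biomass and catch
#' stabilise. If the configuration includes a farm design with positive
#' area, farms are then introduced instantaneously into the BAU equilibrium
#' state and the run continues until a new equilibrium (or
#' \code{max_years}).
#'
#' @param config A [sim_config()].
#' @param base Optional pre-computed calibration from
#'   [unfished_equilibrium()] (reused across sweep cells).
#' @param bau Optional pre-computed BAU \code{scenario_result} (with its
#'   final state), as cached by [run_grid()].
#' @param msy_effort Optional pre-computed MSY aggregate effort for the
#'   strong regime; searched when missing.
#' @return List of class \code{equilibrium_run} with elements \code{farm}
#'   (a \code{scenario_result}, or \code{NULL} for no-farm configs),
#'   \code{bau}, \code{base}, and \code{msy_effort} (strong regime).
#' @export
run_to_equilibrium <- function(config, base = NULL, bau = NULL,
                               msy_effort = NULL) {
  params <- config$params
  fishery <- config$fishery
  n <- config$n_patches
  if (is.null(base))
    base <- unfished_equilibrium(params, n, config$total_biomass_target)
  kernel <- build_kernel(params$sigma_m, n)

  fixed_effort <- NULL
  if (fishery$regime == "strong_msy") {
    if (is.null(msy_effort)) {
      if (fishery$total_effort > 0) {
        msy_effort <- fishery$total_effort
      } else {
        msy_effort <- find_msy_effort(base, params, fishery)$effort
      }
    }
    fixed_effort <- msy_effort
  }

  if (is.null(bau)) {
    bau <- run_until_stable(base$state, base$env, kernel, params, fishery,
                            fixed_effort, farm_m_multiplier = 1,
                            max_years = config$max_years,
                            tol = config$tol, window = config$window,
                            dd_movement = isTRUE(config$dd_movement))
  }

  farm <- NULL
  if (!is.null(config$design) && config$design$total_fraction > 0) {
    design <- config$design
    env_farm <- apply_farm_environment(base$env, design, params$sigma_m)
    farms <- which(env_farm$is_farm)
    zoi <- which(env_farm$in_zoi)
    kernel_farm <- apply_attraction(kernel, farms, zoi, design$attraction,
                                    form = design$attraction_form)
    farm <- run_until_stable(bau$final_state, env_farm, kernel_farm, params,
                             fishery, fixed_effort,
                             farm_m_multiplier = design$m_multiplier,
                             max_years = config$max_years,
                             tol = config$tol, window = config$window,
                             dd_movement = isTRUE(config$dd_movement))
  }

  structure(list(farm = farm, bau = bau, base = base,
                 msy_effort = msy_effort),
            class = "equilibrium_run")
}

#' Equilibrium outcomes of a farm scenario relative to its baseline
#'
#' \code{delta_b} and \code{delta_c} are the ratios of equilibrium total
#' biomass and total catch in the farm scenario to their no-farm
#' business-as-usual values. \code{recovery_year} is the first year since
#' farm introduction (0-based) in which annual catch meets or exceeds the
#' BAU equilibrium catch, or \code{NA} if it never does.
#'
#' @param farm,bau \code{scenario_result} objects.
#' @return List of class \code{relative_outcomes} with \code{delta_b},
#'   \code{delta_c}, \code{recovery_year}.
#' @export
relative_outcomes <- function(farm, bau) {
  if (bau$equilibrium_biomass <= 0)
    stop("baseline equilibrium biomass is zero; ratios undefined")
  delta_b <- farm$equilibrium_biomass / bau$equilibrium_biomass
  delta_c <- if (bau$equilibrium_catch > 0) {
    farm$equilibrium_catch / bau$equilibrium_catch
  } else if (farm$equilibrium_catch == 0) 1 else Inf
  hit <- which(farm$catch_trajectory >=
                 bau$equilibrium_catch * (1 - 1e-9))
  recovery <- if (length(hit)) hit[1] - 1L else NA_integer_
  structure(list(delta_b = delta_b, delta_c = delta_c,
                 recovery_year = recovery),
            class = "relative_outcomes")
}

#' @export
print.relative_outcomes <- function(x, ...) {
  cat(sprintf("<relative_outcomes> dB = %.4f, dC = %.4f, recovery year = %s\n",
              x$delta_b, x$delta_c,
              if (is.na(x$recovery_year)) "never" else x$recovery_year))
  invisible(x)
}
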