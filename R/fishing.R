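#' Fishery management configuration
#'
#' @param regime One of \code{"strong_msy"} (constant aggregate effort at the
#'   level generating maximum sustainable yield) or \code{"weak_open_access"}
#'   (aggregate effort re-optimised every year to maximise current profit).
#' @param total_effort Aggregate effort for the strong regime, in units of
#'   summed per-patch fishing mortality (so \code{total_effort / n} is the
#'   mean F per patch when biomass is uniform). Set by [find_msy_effort()].
#' @param price Ex-vessel price per unit catch biomass (weak regime).
#' @param cost_per_effort Cost per unit aggregate effort (weak regime).
#' @param catchability F generated per unit of per-patch effort; the fixture
#'   uses 1 so effort and F are interchangeable.
#' @param selectivity_steepness Slope of the logistic length selectivity
#'   (per length unit).
#' @param max_effort Upper search bound on aggregate effort for the
#'   open-access optimisation.
#' @return An object of class \code{fishery_config}.
#' @export
fishery_config <- function(regime = c("strong_msy", "weak_open_access"),
                           total_effort = 0,
                           price = 1, cost_per_effort = 0.001,
                           catchability = 1,
                           selectivity_steepness = 0.25,
                           max_effort = 500) {
  regime <- match.arg(regime)
  stopifnot(total_effort >= 0, catchability > 0, selectivity_steepness >= 0,
            max_effort > 0)
  if (regime == "weak_open_access" && (price <= 0 || cost_per_effort <= 0))
    stop("weak regime requires positive price and cost_per_effort")
  structure(list(regime = regime, total_effort = total_effort, price = price,
                 cost_per_effort = cost_per_effort,
                 catchability = catchability,
                 selectivity_steepness = selectivity_steepness,
                 max_effort = max_effort),
            class = "fishery_config")
}

#' Per-patch fishing mortality field
#'
#' @param f_by_patch Numeric vector of per-patch fishing mortalities (1/yr).
#' @return An object of class \code{effort_field} with elements
#'   \code{f_by_patch} and \code{total_effort} (their sum).
#' @export
effort_field <- function(f_by_patch) {
  if (any(f_by_patch < 0)) stop("fishing mortality must be non-negative")
  structure(list(f_by_patch = f_by_patch,
                 total_effort = sum(f_by_patch)),
            class = "effort_field")
}

#' Length-based logistic selectivity at age
#'
#' \deqn{\nu_a = 1 / (1 + e^{-s (L(a) - L_{legal})})}
#' rising through 0.5 at the legal length.
#'
#' @param age Age(s) in years.
#' @param params A [species_params()] object.
#' @param steepness Logistic slope per length unit.
#' @return Selectivity in [0, 1], same shape as \code{age}.
#' @export
selectivity_at_age <- function(age, params, steepness = 0.25) {
  L <- length_at_age(age, params)
  1 / (1 + exp(-steepness * (L - params$legal_length)))
}

#' Fishable (legal-sized, non-farm) biomass by patch
#'
#' Selectivity-weighted biomass per patch, zeroed inside farms, the quantity
#' that attracts fishing effort under the gravity model.
#'
#' @param state A [population_state()].
#' @param env A [patch_environment()].
#' @param params A [species_params()] object.
#' @param steepness Selectivity steepness.
#' @return Numeric vector of fishable biomass per patch.
#' @export
fishable_biomass <- function(state, env, params, steepness = 0.25) {
  ages <- 0:(ncol(state$numbers) - 1)
  nu <- selectivity_at_age(ages, params, steepness)
  b <- (state$numbers * state$weight_at_age) %*% nu
  b <- as.numeric(b)
  b[env$is_farm] <- 0
  b
}

#' Gravity allocation of fishing effort
#'
#' Distributes effort across fishable patches in proportion to fishable
#' biomass: \code{F_i = total_F_scale * n_fishable * B_i / sum(B)}, so that
#' aggregate effort is \code{total_F_scale * n_fishable} and a uniform stock
#' receives \code{F_i = total_F_scale} everywhere.
#'
#' @param total_F_scale Mean per-patch fishing mortality scale.
#' @param fishable Numeric vector of fishable biomass per patch (zeros mark
#'   unfishable patches).
#' @return An [effort_field()].
#' @export
allocate_effort <- function(total_F_scale, fishable) {
  if (total_F_scale < 0) stop("effort scale must be non-negative")
  if (any(fishable < 0)) stop("fishable biomass must be non-negative")
  tot <- sum(fishable)
  if (tot == 0) {
    warning("no fishable biomass anywhere; returning zero effort")
    return(effort_field(rep(0, length(fishable))))
  }
  n_fishable <- sum(fishable > 0)
  effort_field(total_F_scale * n_fishable * fishable / tot)
}

#' Redistribute effort away from farm patches
#'
#' Farms are closed to fishing; the aggregate effort of the pre-farm field is
#' conserved and respread over non-farm patches in proportion to fishable
#' biomass. With a fraction \code{P_farm} of patches farmed and uniform
#' biomass, every non-farm patch's F is inflated by \code{1 / (1 - P_farm)}.
#'
#' @param bau_effort The [effort_field()] before farm closure.
#' @param env A [patch_environment()] with farm flags.
#' @param fishable Fishable biomass per patch (already zero in farms).
#' @return An [effort_field()] with zero F in farms and the same aggregate
#'   effort as \code{bau_effort}.
#' @export
redistribute_for_farm <- function(bau_effort, env, fishable) {
  p_farm <- mean(env$is_farm)
  if (p_farm >= 1) stop("all patches are farmed: nothing left to fish")
  if (p_farm == 0) return(bau_effort)
  b <- fishable
  b[env$is_farm] <- 0
  tot <- sum(b)
  if (tot == 0) {
    warning("no fishable biomass outside farms; returning zero effort")
    return(effort_field(rep(0, length(b))))
  }
  effort_field(bau_effort$total_effort * b / tot)
}

#' Baranov harvest with combined natural and fishing mortality
#'
#' One year of mortality and catch accounting. Per patch \code{i} and age
#' \code{a}, total mortality \code{Z = M_i + F_i nu_a} acts as a single
#' exponential; catch takes the Baranov share:
#' \deqn{C_{i} = \sum_a \frac{F_i \nu_a}{F_i \nu_a + M_i}
#'   N_{i,a} (1 - e^{-M_i - F_i \nu_a}) w_{i,a}}
#' In farm patches \code{M_i = M * farm_m_multiplier}, folding farm fitness
#' impacts into the same exponential.
#'
#' @param state A [population_state()].
#' @param effort An [effort_field()].
#' @param params A [species_params()] object.
#' @param env Optional [patch_environment()]; needed when
#'   \code{farm_m_multiplier != 1}.
#' @param farm_m_multiplier Multiplier on M inside farm patches.
#' @param steepness Selectivity steepness.
#' @return List with \code{catch} (biomass per patch), \code{state} (the
#'   surviving population), and \code{total_catch}.
#' @export
harvest <- function(state, effort, params, env = NULL,
                    farm_m_multiplier = 1, steepness = 0.25) {
  f <- effort$f_by_patch
  if (any(f < 0)) stop("fishing mortality must be non-negative")
  n <- nrow(state$numbers)
  ages <- 0:(ncol(state$numbers) - 1)
  nu <- selectivity_at_age(ages, params, steepness)

  m <- rep(params$m_nat, n)
  if (farm_m_multiplier != 1) {
    if (is.null(env)) stop("env required when farm_m_multiplier != 1")
    m[env$is_farm] <- params$m_nat * farm_m_multiplier
  }

  fa <- outer(f, nu)                  # patch x age fishing mortality
  z <- fa + m                         # recycled by column: m is per patch
  dead_frac <- 1 - exp(-z)
  catch_frac <- ifelse(z > 0, fa / z, 0)
  catch_num <- state$numbers * dead_frac * catch_frac
  catch <- rowSums(catch_num * state$weight_at_age)
  state$numbers <- state$numbers * exp(-z)
  list(catch = catch, state = state, total_catch = sum(catch))
}

#' Aggregate equilibrium catch at a fixed constant effort
#'
#' Runs the no-farm system from its unfished equilibrium under a constant
#' aggregate effort until biomass and catch stabilise; used by the MSY
#' search and the yield-curve diagnostics.
#'
#' @param total_effort Aggregate effort (summed per-patch F).
#' @param base A calibrated baseline from [unfished_equilibrium()].
#' @param kernel A movement kernel.
#' @param params A [species_params()] object.
#' @param fishery A [fishery_config()].
#' @param max_years,tol Equilibrium controls.
#' @return Equilibrium total catch (0 if the run fails to converge).
#' @export
equilibrium_catch_at_effort <- function(total_effort, base, kernel, params,
                                        fishery, max_years = 400,
                                        tol = 1e-8) {
  state <- base$state
  env <- base$env
  n <- nrow(env)
  prev_b <- total_biomass(state)
  prev_c <- -1
  ok <- 0L
  for (yr in seq_len(max_years)) {
    out <- step_population(state, env, kernel,
                           effort = NULL, params = params,
                           fishery = fishery, fixed_effort = total_effort)
    state <- out$state
    cur_b <- total_biomass(state)
    rel <- max(abs(cur_b - prev_b) / max(prev_b, 1e-12),
               abs(out$total_catch - prev_c) / max(abs(prev_c), 1e-12))
    ok <- if (rel < tol) ok + 1L else 0L
    prev_b <- cur_b
    prev_c <- out$total_catch
    if (ok >= 10L) return(prev_c)
  }
  warning(sprintf("no equilibrium at effort %.4g; scoring 0", total_effort))
  0
}

#' Find the constant effort generating maximum sustainable yield
#'
#' Coarse grid search over aggregate effort followed by golden-section
#' refinement of the equilibrium yield curve of the no-farm system. The
#' strong-management regime holds the returned effort constant in every farm
#' scenario.
#'
#' @param base A calibrated baseline from [unfished_equilibrium()].
#' @param params A [species_params()] object.
#' @param fishery A [fishery_config()].
#' @param effort_grid Candidate aggregate efforts for the coarse scan;
#'   default spans mean per-patch F from 0 to 1.
#' @return List with \code{effort} (the MSY aggregate effort), \code{msy}
#'   (equilibrium catch there), and \code{yield_curve} (data.frame of the
#'   coarse scan).
#' @export
find_msy_effort <- function(base, params, fishery,
                            effort_grid = NULL) {
  n <- nrow(base$env)
  if (is.null(effort_grid)) effort_grid <- seq(0, 1, by = 0.05) * n
  kernel <- build_kernel(params$sigma_m, n)
  yields <- vapply(effort_grid, equilibrium_catch_at_effort,
                   numeric(1), base = base, kernel = kernel,
                   params = params, fishery = fishery)
  i <- which.max(yields)
  lo <- effort_grid[max(1, i - 1)]
  hi <- effort_grid[min(length(effort_grid), i + 1)]
  refine <- stats::optimize(
    function(e) equilibrium_catch_at_effort(e, base, kernel, params, fishery),
    interval = c(lo, hi), maximum = TRUE, tol = max(0.002 * n, 1e-4))
  list(effort = refine$maximum, msy = refine$objective,
       yield_curve = data.frame(effort = effort_grid, catch = yields))
}

#' Myopic open-access effort for the current year
#'
#' Chooses the aggregate effort maximising this year's profit
#' \code{price * C_total(E) - cost_per_effort * E}, given the current
#' distribution of fishable biomass and gravity allocation. Catch revenue is
#' concave in effort under Baranov dynamics, so a one-dimensional golden
#' search suffices; zero effort is always admitted.
#'
#' @param state A [population_state()] (post-movement, pre-harvest).
#' @param env A [patch_environment()].
#' @param params A [species_params()] object.
#' @param fishery A [fishery_config()] with \code{regime = "weak_open_access"}.
#' @param farm_m_multiplier Farm mortality multiplier (affects catch).
#' @return The profit-maximising aggregate effort (scalar, >= 0).
#' @export
open_access_effort <- function(state, env, params, fishery,
                               farm_m_multiplier = 1) {
  fb <- fishable_biomass(state, env, params, fishery$selectivity_steepness)
  if (sum(fb) == 0 || fishery$price <= 0) return(0)
  profit <- function(e_total) {
    eff <- effort_field(e_total * fb / sum(fb))
    h <- harvest(state, eff, params, env, farm_m_multiplier,
                 fishery$selectivity_steepness)
    fishery$price * h$total_catch - fishery$cost_per_effort * e_total
  }
  opt <- stats::optimize(profit, interval = c(0, fishery$max_effort),
                         maximum = TRUE, tol = 1e-6 * fishery$max_effort)
  best <- opt$maximum
  # endpoint checks: golden search can miss boundary maxima
  if (profit(fishery$max_effort) > opt$objective) best <- fishery$max_effort
  if (opt$objective <= 0 && profit(fishery$max_effort) <= 0) best <- 0
  best
}
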