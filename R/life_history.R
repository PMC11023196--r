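#' Species life-history parameters
#'
#' Bundles the biological constants of the simulated stock: von Bertalanffy
#' growth, the allometric weight-length relationship, natural mortality, the
#' age structure, adult mobility, and the density-dependent recruitment shape.
#'
#' @param linf Asymptotic length (length units). Must be positive.
#' @param k_growth von Bertalanffy growth rate (1/yr). Must be positive.
#' @param t0 Theoretical age at length zero (yr).
#' @param b1 Weight-length exponent (dimensionless, typically near 3).
#' @param b2 Weight-length coefficient (weight per length^b1).
#' @param m_nat Instantaneous natural mortality M (1/yr). Must be positive.
#' @param max_age Plus-group age (yr); all survivors older than this
#'   accumulate in the terminal class. Must be at least 2.
#' @param age_mature Age at maturity (yr); fish of this age and older spawn.
#' @param sigma_m Movement-kernel scale in patches. Ignored (recomputed) when
#'   \code{range_fraction} is supplied to a simulation configuration.
#' @param range_fraction Adult home range as a fraction of the whole lattice,
#'   in [0, 1]; converted to \code{sigma_m} via [sigma_from_range()].
#' @param recruit_steepness Beverton-Holt settlement-survival shape: the
#'   asymptotic number of recruits a patch can produce equals
#'   \code{recruit_steepness * k_patch}.
#' @param fecundity Larvae produced per unit of mature (spawning) biomass.
#' @param move_threshold Crowding level \code{bm/K} at which the annual
#'   emigrating fraction reaches 1 under density-dependent movement (fish
#'   leave crowded patches and stay where there is room); 1 means full
#'   mixing only at capacity, values near 0 recover crowding-independent
#'   kernel mixing.
#' @param legal_length Minimum fishable length (length units); defaults to the
#'   length at \code{age_mature}.
#'
#' @return An object of class \code{species_params}.
#' @seealso [default_species()] for the calibrated generic-teleost fixture.
#' @export
species_params <- function(linf = 100, k_growth = 0.2, t0 = 0,
                           b1 = 3, b2 = 1e-5,
                           m_nat = 0.2, max_age = 20, age_mature = 3,
                           sigma_m = 7.5, range_fraction = NULL,
                           recruit_steepness = 0.2, fecundity = 1,
                           move_threshold = 1, legal_length = NULL) {
  stopifnot(linf > 0, k_growth > 0, b1 > 0, b2 > 0, m_nat > 0,
            max_age >= 2, age_mature >= 0, recruit_steepness > 0,
            fecundity >= 0, move_threshold > 0, move_threshold <= 1)
  if (!is.null(range_fraction)) {
    if (range_fraction < 0 || range_fraction > 1)
      stop("range_fraction must lie in [0, 1]")
  }
  if (sigma_m < 0) stop("sigma_m must be non-negative")
  p <- list(linf = linf, k_growth = k_growth, t0 = t0, b1 = b1, b2 = b2,
            m_nat = m_nat, max_age = as.integer(max_age),
            age_mature = as.integer(age_mature),
            sigma_m = sigma_m, range_fraction = range_fraction,
            recruit_steepness = recruit_steepness, fecundity = fecundity,
            move_threshold = move_threshold)
  p$legal_length <- if (is.null(legal_length)) {
    length_at_age(p$age_mature, structure(p, class = "species_params"))
  } else legal_length
  structure(p, class = "species_params")
}

#' @export
print.species_params <- function(x, ...) {
  cat("<species_params>\n")
  cat(sprintf("  von Bertalanffy: Linf = %g, k = %g, t0 = %g\n",
              x$linf, x$k_growth, x$t0))
  cat(sprintf("  weight-length:   w = %g * L^%g\n", x$b2, x$b1))
  cat(sprintf("  M = %g /yr, ages 0..%d (plus group), mature at %d\n",
              x$m_nat, x$max_age, x$age_mature))
  cat(sprintf("  sigma_m = %g patches, legal length = %g\n",
              x$sigma_m, x$legal_length))
  invisible(x)
}

#' Length at age from the von Bertalanffy growth curve
#'
#' \deqn{L(a) = L_\infty (1 - e^{-k (a - t_0)})}, floored at zero for ages
#' younger than \code{t0}.
#'
#' @param age Age in years (scalar or vector); must be non-negative.
#' @param params A [species_params()] object.
#' @return Length(s) at age, same shape as \code{age}.
#' @export
length_at_age <- function(age, params) {
  if (any(age < 0)) stop("age must be non-negative")
  pmax(0, params$linf * (1 - exp(-params$k_growth * (age - params$t0))))
}

#' Weight at age, unconstrained by density
#'
#' The allometric weight \code{b2 * L(age)^b1} a fish would reach growing at
#' carrying-capacity-free rates; used to seed initial states.
#'
#' @inheritParams length_at_age
#' @return Weight(s) at age.
#' @keywords internal
weight_at_age_free <- function(age, params) {
  params$b2 * length_at_age(age, params)^params$b1
}

#' Density-dependent annual weight increment
#'
#' One year of somatic growth under local crowding: the allometric increment
#' from length \code{L_age} to \code{L_next} is scaled by
#' \code{(1 - bm_patch / k_patch)}. The increment is floored at zero when
#' local biomass exceeds carrying capacity (fish do not shrink during the
#' transient over-capacity that attraction creates at farms).
#'
#' @param w_age Current weight of the cohort.
#' @param L_age Length at the current age.
#' @param L_next Length at the next age.
#' @param bm_patch Total biomass currently in the patch.
#' @param k_patch Patch carrying capacity (biomass); must be positive.
#' @param params A [species_params()] object (supplies \code{b1}, \code{b2}).
#' @return The weight at the next age.
#' @export
update_weight_at_age <- function(w_age, L_age, L_next, bm_patch, k_patch,
                                 params) {
  if (any(k_patch <= 0)) stop("k_patch must be positive")
  if (any(bm_patch < 0)) stop("bm_patch must be non-negative")
  increment <- params$b2 * (L_next^params$b1 - L_age^params$b1)
  w_age + increment * pmax(0, 1 - bm_patch / k_patch)
}

#' Per-patch habitat description
#'
#' @param k_patch Numeric vector of per-patch carrying capacities (biomass).
#' @param is_farm Logical vector flagging farm patches.
#' @param in_zoi Logical vector flagging the farm zone of influence
#'   (farm patches included).
#' @return A data.frame of class \code{patch_environment} with columns
#'   \code{patch} (1-based index), \code{k_patch}, \code{is_farm},
#'   \code{in_zoi}.
#' @export
patch_environment <- function(k_patch,
                              is_farm = rep(FALSE, length(k_patch)),
                              in_zoi = rep(FALSE, length(k_patch))) {
  stopifnot(all(k_patch > 0),
            length(is_farm) == length(k_patch),
            length(in_zoi) == length(k_patch))
  env <- data.frame(patch = seq_along(k_patch), k_patch = k_patch,
                    is_farm = is_farm, in_zoi = in_zoi)
  class(env) <- c("patch_environment", "data.frame")
  env
}

#' Calibrate patch carrying capacities to an unfished equilibrium target
#'
#' Runs the full no-farm, no-fishing dynamics to equilibrium and scales the
#' (uniform) per-patch carrying capacity so that the equilibrium system
#' biomass equals \code{total_biomass_target}. The model is homogeneous of
#' degree one in (K, abundance), so a single reference run determines the
#' scaling exactly; the returned environment is verified by re-simulation.
#'
#' @param params A [species_params()] object.
#' @param n_patches Number of lattice patches.
#' @param total_biomass_target Desired unfished equilibrium system biomass.
#' @param max_years Iteration cap for the equilibrium search.
#' @param tol Relative-change convergence tolerance.
#' @return A list with elements \code{env} (a [patch_environment()] with the
#'   calibrated uniform \code{k_patch}), \code{state} (the unfished
#'   equilibrium [population_state()]), and \code{equilibrium_biomass}.
#' @export
unfished_equilibrium <- function(params, n_patches = 100,
                                 total_biomass_target = 1e5,
                                 max_years = 3000, tol = 1e-12) {
  stopifnot(n_patches >= 1, total_biomass_target > 0)
  kernel <- build_kernel(params$sigma_m, n_patches)
  env <- patch_environment(rep(1, n_patches))
  state <- seed_state(params, env)
  effort <- effort_field(rep(0, n_patches))

  prev <- total_biomass(state)
  ok <- 0L
  for (yr in seq_len(max_years)) {
    state <- step_population(state, env, kernel, effort, params)$state
    cur <- total_biomass(state)
    rel <- abs(cur - prev) / max(abs(prev), .Machine$double.eps)
    ok <- if (rel < tol) ok + 1L else 0L
    prev <- cur
    if (ok >= 10L) break
  }
  if (ok < 10L)
    stop(sprintf(
      "unfished equilibrium did not converge in %d years (last relative change %.3g)",
      max_years, rel))

  scale <- total_biomass_target / prev
  env$k_patch <- env$k_patch * scale
  state$numbers <- state$numbers * scale
  list(env = env, state = state,
       equilibrium_biomass = total_biomass(state))
}

#' Seed state for equilibrium searches: one unit of recruits per patch decayed
#' by natural mortality, with density-free weights.
#' @keywords internal
seed_state <- function(params, env) {
  n <- nrow(env)
  ages <- 0:params$max_age
  surv <- exp(-params$m_nat * ages)
  surv[length(surv)] <- surv[length(surv)] / (1 - exp(-params$m_nat))
  numbers <- matrix(rep(surv, each = n) * 0.05 * params$recruit_steepness *
                      env$k_patch, nrow = n)
  weights <- matrix(rep(weight_at_age_free(ages, params), each = n), nrow = n)
  population_state(numbers, weights)
}
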