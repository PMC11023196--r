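#' Spatial age-structured population state
#'
#' @param numbers Patches x ages matrix of abundances (columns are ages 0 to
#'   the plus group).
#' @param weight_at_age Patches x ages matrix of mean individual weights.
#' @param year Integer time-step index.
#' @return An object of class \code{population_state}.
#' @export
population_state <- function(numbers, weight_at_age, year = 0L) {
  numbers <- as.matrix(numbers)
  weight_at_age <- as.matrix(weight_at_age)
  if (!all(dim(numbers) == dim(weight_at_age)))
    stop("numbers and weight_at_age must have identical dimensions")
  if (any(numbers < 0)) stop("abundances must be non-negative")
  if (any(weight_at_age < 0)) stop("weights must be non-negative")
  structure(list(numbers = numbers, weight_at_age = weight_at_age,
                 year = as.integer(year)),
            class = "population_state")
}

#' @export
print.population_state <- function(x, ...) {
  cat(sprintf("<population_state> year %d: %d patches x %d age classes\n",
              x$year, nrow(x$numbers), ncol(x$numbers)))
  cat(sprintf("  total abundance %.4g, total biomass %.4g\n",
              sum(x$numbers), total_biomass(x)))
  invisible(x)
}

#' Per-patch and total biomass of a state
#'
#' @param state A [population_state()].
#' @return \code{patch_biomass}: numeric vector of per-patch biomass;
#'   \code{total_biomass}: its sum.
#' @export
patch_biomass <- function(state) {
  rowSums(state$numbers * state$weight_at_age)
}

#' @rdname patch_biomass
#' @export
total_biomass <- function(state) {
  sum(state$numbers * state$weight_at_age)
}

#' Annual larval production
#'
#' Larvae are produced in proportion to system-wide spawning biomass (fish at
#' or above the age of maturity): \code{larvae = fecundity * SSB}.
#'
#' @param state A [population_state()].
#' @param params A [species_params()] object.
#' @return Total larvae entering the common pool (a scalar).
#' @export
spawn <- function(state, params) {
  mature <- (params$age_mature + 1):ncol(state$numbers)
  ssb <- sum(state$numbers[, mature, drop = FALSE] *
               state$weight_at_age[, mature, drop = FALSE])
  params$fecundity * ssb
}

#' Uniform larval settlement with per-patch density-dependent survival
#'
#' The larval pool settles uniformly over all patches; settlers then survive
#' a patch-level Beverton-Holt bottleneck whose asymptote scales with local
#' carrying capacity:
#' \deqn{R_i = \frac{s_i}{1 + s_i / (h K_i)}}
#' where \code{s_i = larvae / n} and \code{h} is the recruit steepness.
#' \code{K_i} is the baseline habitat capacity (\code{env$k_settle} when the
#' environment carries farm modifications, else \code{env$k_patch}): farm
#' structure raises the adult growth/biomass ceiling but not larval
#' settlement survival.
#'
#' @param larvae Total larvae (scalar, non-negative).
#' @param env A [patch_environment()].
#' @param params A [species_params()] object.
#' @return Numeric vector of age-0 recruits per patch.
#' @export
settle_and_survive <- function(larvae, env, params) {
  if (larvae < 0) stop("larvae must be non-negative")
  n <- nrow(env)
  settlers <- rep(larvae / n, n)
  # settlement survival saturates against the patch's baseline habitat
  # capacity: farm structure raises the adult growth ceiling (k_patch) but
  # not the nursery capacity of the seabed beneath it
  k <- if (!is.null(env$k_settle)) env$k_settle else env$k_patch
  settlers / (1 + settlers / (params$recruit_steepness * k))
}

#' Natural survival with a farm fitness modifier
#'
#' Annual survival \code{exp(-M)} outside farms; inside farm patches the
#' mortality rate is scaled by \code{farm_m_multiplier} (0.9 = net benefit
#' such as food supplementation, 1.1 = net harm such as disease or
#' pollutants, 1 = neutral). Used on fishing-free paths; when fishing is
#' active, [harvest()] applies the combined exponential instead.
#'
#' @param state A [population_state()].
#' @param env A [patch_environment()].
#' @param params A [species_params()] object.
#' @param farm_m_multiplier Positive scalar multiplier on M in farm patches.
#' @return The state after natural mortality.
#' @export
natural_survival <- function(state, env, params, farm_m_multiplier = 1) {
  if (farm_m_multiplier <= 0) stop("farm_m_multiplier must be positive")
  m <- ifelse(env$is_farm, params$m_nat * farm_m_multiplier, params$m_nat)
  state$numbers <- state$numbers * exp(-m)
  state
}

#' Advance all cohorts by one year
#'
#' Shifts every age class up by one; the terminal class is a plus group that
#' accumulates its own survivors. When \code{growth_factor} is supplied
#' (per-patch density factor \code{max(0, 1 - bm/K)} from the growth stage),
#' cohort weights are advanced along the density-dependent growth curve as
#' they age; the plus-group weight is the abundance-weighted mean of the
#' incoming cohort's grown weight and the resident plus-group weight. The
#' age-0 slot is cleared for the next season's recruits.
#'
#' @param state A [population_state()].
#' @param params A [species_params()] object.
#' @param growth_factor Optional per-patch growth scaling in [0, 1]; omit to
#'   age numbers only, leaving weights untouched (useful in isolation tests).
#' @return The aged state, with \code{year} incremented.
#' @export
advance_age <- function(state, params, growth_factor = NULL) {
  n_age <- ncol(state$numbers)
  num <- state$numbers
  w <- state$weight_at_age

  new_num <- num
  new_num[, 2:n_age] <- num[, 1:(n_age - 1)]
  new_num[, n_age] <- new_num[, n_age] + num[, n_age]  # plus group
  new_num[, 1] <- 0

  new_w <- w
  if (!is.null(growth_factor)) {
    ages <- 0:(n_age - 1)
    len <- length_at_age(ages, params)
    for (a in 2:n_age) {
      new_w[, a] <- update_weight_at_age(
        w[, a - 1], len[a - 1], len[a],
        bm_patch = 1 - growth_factor, k_patch = 1, params = params)
    }
    # resident plus-group fish keep their weight; merge by abundance
    incoming <- num[, n_age - 1]
    resident <- num[, n_age]
    tot <- incoming + resident
    merged <- ifelse(tot > 0,
                     (incoming * new_w[, n_age] + resident * w[, n_age]) / tot,
                     w[, n_age])
    new_w[, n_age] <- merged
  } else {
    new_w[, 2:n_age] <- w[, 1:(n_age - 1)]
    incoming <- num[, n_age - 1]
    resident <- num[, n_age]
    tot <- incoming + resident
    new_w[, n_age] <- ifelse(tot > 0,
                             (incoming * w[, n_age - 1] +
                                resident * w[, n_age]) / tot,
                             w[, n_age])
  }
  new_w[, 1] <- weight_at_age_free(0, params)

  population_state(new_num, new_w, year = state$year + 1L)
}
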