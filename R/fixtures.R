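#' Default generic-teleost study fixture
#'
#' The calibrated parameterisation of the theoretical fishery stock used
#' throughout the package's examples, tests, and scenario sweeps: a
#' moderately mobile, moderately long-lived demersal teleost on a 100-patch
#' wrapped lattice. See the methods vignette for the calibration rationale.
#'
#' @param range_fraction Adult home range as a fraction of total space;
#'   default 0.28 (moderately mobile).
#' @param ... Overrides for any [species_params()] argument.
#' @return A [species_params()] object.
#' @export
default_species <- function(range_fraction = 0.28, ...) {
  args <- list(linf = 100, k_growth = 0.2, t0 = 0,
               b1 = 3, b2 = 1e-5,
               m_nat = 0.2, max_age = 20, age_mature = 3,
               range_fraction = range_fraction,
               sigma_m = sigma_from_range(range_fraction, 100),
               recruit_steepness = 0.3, fecundity = 2,
               move_threshold = 0.75)
  do.call(species_params, utils::modifyList(args, list(...)))
}

#' Default fishery configurations for the two management regimes
#'
#' \code{strong}: constant aggregate effort at maximum sustainable yield
#' (the effort itself is found by [find_msy_effort()] at run time).
#' \code{weak}: a high-value open-access fishery whose effort is re-optimised
#' myopically each year; the price/cost ratio is set so the no-farm
#' open-access equilibrium is well below the MSY biomass (an overfished
#' baseline).
#'
#' @param regime \code{"strong"} or \code{"weak"}.
#' @param ... Overrides for any [fishery_config()] argument.
#' @return A [fishery_config()] object.
#' @export
default_fishery <- function(regime = c("strong", "weak"), ...) {
  regime <- match.arg(regime)
  args <- if (regime == "strong") {
    list(regime = "strong_msy")
  } else {
    list(regime = "weak_open_access",
         price = 1, cost_per_effort = 83.5, max_effort = 200)
  }
  do.call(fishery_config, utils::modifyList(args, list(...)))
}
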