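#' Farm layout and impact configuration
#'
#' Describes where farms sit on the lattice and how they alter local
#' conditions: attraction of wild fish, elevated carrying capacity, and a
#' natural-mortality modifier.
#'
#' @param total_fraction Fraction of all patches occupied by farms, in
#'   [0, 1); the study range is 0 to 0.4.
#' @param layout \code{"several_small"} (equal clusters spread evenly around
#'   the ring) or \code{"one_large"} (a single contiguous block).
#' @param farm_unit_size Patches per farm under \code{several_small}
#'   (default 5); ignored for \code{one_large}.
#' @param attraction Attraction multiplier A >= 1 (1 = no attraction; the
#'   study sweeps 1 to 15).
#' @param k_multiplier Farm carrying capacity relative to a plain patch
#'   (default 3).
#' @param m_multiplier Natural-mortality multiplier inside farms (0.9 =
#'   fitness benefit, 1.1 = harm, 1 = neutral).
#' @param zoi_halfwidth Zone-of-influence half-width in patches, or
#'   \code{NULL} to tie it to mobility as \code{ceiling(2 * sigma_m)}
#'   (sessile species: farms only).
#' @param anchor 1-based patch index where the first farm block starts; the
#'   wrapped lattice is translation-invariant, so this only shifts profiles.
#' @return An object of class \code{farm_design}.
#' @export
farm_design <- function(total_fraction, layout = c("several_small", "one_large"),
                        farm_unit_size = 5, attraction = 1,
                        k_multiplier = 3, m_multiplier = 1,
                        zoi_halfwidth = NULL, anchor = 1,
                        attraction_form = c("multiplicative", "exponent")) {
  layout <- match.arg(layout)
  attraction_form <- match.arg(attraction_form)
  stopifnot(total_fraction >= 0, total_fraction < 1,
            farm_unit_size >= 1, attraction >= 1,
            k_multiplier > 0, m_multiplier > 0, anchor >= 1)
  structure(list(total_fraction = total_fraction, layout = layout,
                 farm_unit_size = as.integer(farm_unit_size),
                 attraction = attraction, k_multiplier = k_multiplier,
                 m_multiplier = m_multiplier, zoi_halfwidth = zoi_halfwidth,
                 anchor = as.integer(anchor),
                 attraction_form = attraction_form),
            class = "farm_design")
}

#' Number of individual farms in a design
#'
#' @param n_farm_patches Total patches devoted to farms.
#' @param farm_unit_size Patches per farm; must divide \code{n_farm_patches}.
#' @return The integer count of farms.
#' @export
number_of_farms <- function(n_farm_patches, farm_unit_size) {
  if (farm_unit_size < 1) stop("farm_unit_size must be at least 1")
  if (n_farm_patches %% farm_unit_size != 0)
    stop(sprintf("farm_unit_size (%d) does not divide farm patch count (%d)",
                 farm_unit_size, n_farm_patches))
  n_farm_patches %/% farm_unit_size
}

#' Place farm patches on the lattice
#'
#' \code{one_large}: a single contiguous block of
#' \code{round(total_fraction * n)} patches starting at the anchor.
#' \code{several_small}: equal blocks of \code{farm_unit_size} patches whose
#' starts are spread with equal wrapped spacing. Deterministic for a given
#' design.
#'
#' @param design A [farm_design()].
#' @param n Number of lattice patches.
#' @return Sorted integer vector of farm patch indices (1-based); empty when
#'   \code{total_fraction = 0}.
#' @export
layout_farms <- function(design, n) {
  n_farm <- round(design$total_fraction * n)
  if (n_farm == 0) return(integer(0))
  if (design$layout == "one_large") {
    block <- design$anchor + 0:(n_farm - 1)
  } else {
    n_farms <- number_of_farms(n_farm, design$farm_unit_size)
    spacing <- n / n_farms
    starts <- design$anchor + round((0:(n_farms - 1)) * spacing)
    block <- unlist(lapply(starts, function(s) s + 0:(design$farm_unit_size - 1)))
  }
  patches <- sort(((block - 1) %% n) + 1)
  if (anyDuplicated(patches))
    stop("farm blocks overlap; reduce total_fraction or farm count")
  patches
}

#' Zone of influence around farm patches
#'
#' All patches whose wrapped distance to the nearest farm patch is at most
#' \code{halfwidth} (farm patches themselves included).
#'
#' @param farm_patches Integer vector of farm patch indices.
#' @param halfwidth Non-negative integer reach in patches.
#' @param n Number of lattice patches.
#' @return Sorted integer vector of ZOI patch indices.
#' @export
zone_of_influence <- function(farm_patches, halfwidth, n) {
  if (halfwidth < 0) stop("halfwidth must be non-negative")
  if (length(farm_patches) == 0) return(integer(0))
  idx <- seq_len(n)
  d <- vapply(idx, function(i) min(wrapped_distance(i, farm_patches, n)),
              numeric(1))
  idx[d <= halfwidth]
}

#' Apply farm modifications to a patch environment
#'
#' Flags farm and ZOI patches and raises farm carrying capacity by the
#' design's \code{k_multiplier}; non-farm patches are untouched.
#'
#' @param env A [patch_environment()] (typically the calibrated no-farm one).
#' @param design A [farm_design()].
#' @param sigma_m Movement scale used for the default ZOI half-width when the
#'   design leaves it \code{NULL}.
#' @return The modified [patch_environment()].
#' @export
apply_farm_environment <- function(env, design, sigma_m = 0) {
  n <- nrow(env)
  farms <- layout_farms(design, n)
  env$is_farm <- FALSE
  env$in_zoi <- FALSE
  if (length(farms) == 0) return(env)
  hw <- if (is.null(design$zoi_halfwidth)) ceiling(2 * sigma_m)
        else design$zoi_halfwidth
  zoi <- zone_of_influence(farms, hw, n)
  env$is_farm[farms] <- TRUE
  env$in_zoi[zoi] <- TRUE
  # the k multiplier raises the adult biomass/growth ceiling at farms;
  # larval settlement keeps saturating against the baseline habitat capacity
  env$k_settle <- env$k_patch
  env$k_patch[farms] <- env$k_patch[farms] * design$k_multiplier
  env
}
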