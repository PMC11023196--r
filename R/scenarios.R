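#' Scenario sweep grid
#'
#' Cartesian grid of farm and fishery factors, one simulation per cell.
#'
#' @param farm_fractions Total farm area fractions (0 to 0.4).
#' @param attraction_levels Attraction multipliers (1 to 15).
#' @param movement_fractions Species range fractions (0 = sessile to 0.6 =
#'   highly mobile); defaults to the study fixture's range fraction.
#' @param regimes Management regimes, subset of
#'   \code{c("strong", "weak")}.
#' @param layouts Farm layouts, subset of
#'   \code{c("several_small", "one_large")}.
#' @param m_multipliers Farm natural-mortality multipliers.
#' @return An object of class \code{scenario_grid} (a data.frame with one
#'   row per cell).
#' @export
scenario_grid <- function(farm_fractions = seq(0.05, 0.40, by = 0.05),
                          attraction_levels = c(1, 2, 5, 10, 15),
                          movement_fractions = 0.28,
                          regimes = c("strong", "weak"),
                          layouts = c("several_small", "one_large"),
                          m_multipliers = 1) {
  stopifnot(length(farm_fractions) > 0, length(attraction_levels) > 0,
            length(movement_fractions) > 0, length(regimes) > 0,
            length(layouts) > 0, length(m_multipliers) > 0)
  g <- expand.grid(farm_fraction = farm_fractions,
                   attraction = attraction_levels,
                   movement = movement_fractions,
                   regime = regimes, layout = layouts,
                   m_multiplier = m_multipliers,
                   stringsAsFactors = FALSE)
  class(g) <- c("scenario_grid", "data.frame")
  g
}

#' Run a scenario grid
#'
#' Executes one equilibrium simulation per grid cell and returns a tidy
#' table. Expensive shared work is cached and reused: the carrying-capacity
#' calibration and MSY effort per movement rate, and the BAU equilibrium per
#' (regime, movement) pair. A failing cell is flagged in the \code{converged}
#' column and the sweep continues.
#'
#' @param grid A [scenario_grid()].
#' @param n_patches Lattice size.
#' @param total_biomass_target Carrying-capacity calibration target.
#' @param fishery_overrides Named list of [fishery_config()] overrides
#'   applied to both regimes (e.g. \code{list(cost_per_effort = 40)}).
#' @param quiet Suppress per-cell progress messages.
#' @return A data.frame with the grid coordinates plus \code{delta_b},
#'   \code{delta_c}, \code{recovery_year}, \code{converged},
#'   \code{bau_biomass}, \code{bau_catch}, \code{farm_biomass},
#'   \code{farm_catch}.
#' @export
run_grid <- function(grid, n_patches = 100, total_biomass_target = 1e5,
                     fishery_overrides = list(), quiet = TRUE) {
  base_cache <- list()
  msy_cache <- list()
  bau_cache <- list()
  rows <- vector("list", nrow(grid))

  make_fishery <- function(regime) {
    do.call(default_fishery, c(list(regime = regime), fishery_overrides))
  }

  for (r in seq_len(nrow(grid))) {
    cell <- grid[r, ]
    mov_key <- sprintf("m%.6f", cell$movement)
    reg_key <- paste0(cell$regime, "_", mov_key)

    params <- default_species(range_fraction = cell$movement)
    params$sigma_m <- sigma_from_range(cell$movement, n_patches)
    fishery <- make_fishery(cell$regime)

    row <- data.frame(cell, delta_b = NA_real_, delta_c = NA_real_,
                      recovery_year = NA_integer_, converged = FALSE,
                      bau_biomass = NA_real_, bau_catch = NA_real_,
                      farm_biomass = NA_real_, farm_catch = NA_real_)
    ok <- tryCatch({
      if (is.null(base_cache[[mov_key]]))
        base_cache[[mov_key]] <- unfished_equilibrium(
          params, n_patches, total_biomass_target)
      base <- base_cache[[mov_key]]

      msy <- NULL
      if (cell$regime == "strong") {
        if (is.null(msy_cache[[mov_key]]))
          msy_cache[[mov_key]] <- find_msy_effort(base, params, fishery)$effort
        msy <- msy_cache[[mov_key]]
      }

      design <- farm_design(total_fraction = cell$farm_fraction,
                            layout = cell$layout,
                            attraction = cell$attraction,
                            m_multiplier = cell$m_multiplier)
      config <- sim_config(params = params, fishery = fishery,
                           design = design, n_patches = n_patches,
                           total_biomass_target = total_biomass_target)

      if (is.null(bau_cache[[reg_key]])) {
        first <- run_to_equilibrium(config, base = base, msy_effort = msy)
        bau_cache[[reg_key]] <- first$bau
        run <- first
      } else {
        run <- run_to_equilibrium(config, base = base,
                                  bau = bau_cache[[reg_key]],
                                  msy_effort = msy)
      }

      if (cell$farm_fraction == 0) {
        row$delta_b <- 1; row$delta_c <- 1; row$recovery_year <- 0L
        row$converged <- run$bau$converged
        row$farm_biomass <- run$bau$equilibrium_biomass
        row$farm_catch <- run$bau$equilibrium_catch
      } else {
        rel <- relative_outcomes(run$farm, run$bau)
        row$delta_b <- rel$delta_b
        row$delta_c <- rel$delta_c
        row$recovery_year <- rel$recovery_year
        row$converged <- run$farm$converged && run$bau$converged
        row$farm_biomass <- run$farm$equilibrium_biomass
        row$farm_catch <- run$farm$equilibrium_catch
      }
      row$bau_biomass <- run$bau$equilibrium_biomass
      row$bau_catch <- run$bau$equilibrium_catch
      TRUE
    }, error = function(e) {
      warning(sprintf("grid row %d failed: %s", r, conditionMessage(e)))
      FALSE
    })
    if (!quiet)
      message(sprintf("[%d/%d] %s %s frac=%.2f A=%g: dC=%.3f",
                      r, nrow(grid), cell$regime, cell$layout,
                      cell$farm_fraction, cell$attraction, row$delta_c))
    rows[[r]] <- row
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Maximum catch benefit over a sweep slice
#'
#' The headline design metric: the largest percent increase in equilibrium
#' catch over the no-farm baseline, taken across all farm areas and
#' attraction levels of one (regime, layout) slice.
#'
#' @param table A [run_grid()] result.
#' @param regime,layout Slice selectors; \code{NULL} keeps all.
#' @return Percent increase \code{100 * (max(delta_c) - 1)} (negative when
#'   every cell loses catch).
#' @export
summarize_max_benefit <- function(table, regime = NULL, layout = NULL) {
  sel <- rep(TRUE, nrow(table))
  if (!is.null(regime)) sel <- sel & table$regime == regime
  if (!is.null(layout)) sel <- sel & table$layout == layout
  slice <- table[sel & !is.na(table$delta_c), ]
  if (nrow(slice) == 0) stop("empty slice: no matching rows with results")
  100 * (max(slice$delta_c) - 1)
}
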