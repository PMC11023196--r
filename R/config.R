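#' Build a simulation configuration from a config list or YAML/JSON file
#'
#' Reads the blocks \code{species:}, \code{fishery:}, \code{farm:} and
#' \code{simulation:} and assembles a [sim_config()]. Every key is optional;
#' omitted keys fall back to the calibrated defaults of [default_species()],
#' [default_fishery()], [farm_design()] and [sim_config()]. An absent or
#' empty \code{farm:} block gives a no-farm (baseline) configuration.
#'
#' Recognised keys:
#' \describe{
#'   \item{species}{any [species_params()] argument, plus
#'     \code{range_fraction}.}
#'   \item{fishery}{\code{regime} ("strong" or "weak") plus any
#'     [fishery_config()] argument.}
#'   \item{farm}{any [farm_design()] argument (\code{total_fraction},
#'     \code{layout}, \code{attraction}, ...).}
#'   \item{simulation}{\code{n_patches}, \code{total_biomass_target},
#'     \code{max_years}, \code{tol}, \code{window}, \code{dd_movement}.}
#' }
#'
#' @param config A named list with the blocks above, or a path to a YAML or
#'   JSON file containing them (YAML requires the \pkg{yaml} package, JSON
#'   the \pkg{jsonlite} package).
#' @return A [sim_config()].
#' @export
read_sim_config <- function(config) {
  if (is.character(config)) config <- read_config_file(config)
  if (!is.list(config)) stop("config must be a list or a file path")

  sp <- config$species
  species <- do.call(default_species, if (is.null(sp)) list() else sp)

  fi <- if (is.null(config$fishery)) list() else config$fishery
  regime <- if (is.null(fi$regime)) "strong" else fi$regime
  fi$regime <- NULL
  fishery <- do.call(default_fishery, c(list(regime = regime), fi))

  fa <- config$farm
  design <- if (is.null(fa) || is.null(fa$total_fraction) ||
                fa$total_fraction == 0) NULL else do.call(farm_design, fa)

  si <- if (is.null(config$simulation)) list() else config$simulation
  do.call(sim_config,
          c(list(params = species, fishery = fishery, design = design), si))
}

read_config_file <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path))
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs requires the 'yaml' package")
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    if (!requireNamespace("jsonlite", quietly = TRUE))
      stop("reading JSON configs requires the 'jsonlite' package")
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop("config file must end in .yaml, .yml or .json")
  }
}
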