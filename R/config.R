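#' Read and validate a run configuration
#'
#' A single YAML file declares the toy potential, the state definitions,
#' the dynamics, the sampler settings and the analysis settings.  Schema
#' (defaults in parentheses):
#'
#' \preformatted{
#' potential:
#'   centers: [[0, 1], [-0.866, -0.5], [0.866, -0.5]]
#'   depths:  [4, 4, 4]       # kT
#'   widths:  [0.3, 0.3, 0.3]
#' states:
#'   labels:  [A, B, C]
#'   centers: [[0, 1], [-0.866, -0.5], [0.866, -0.5]]
#'   radii:   [0.3, 0.3, 0.3]
#' dynamics:
#'   timestep: 0.005
#'   diffusion: 1.0
#' sampler:
#'   n_trials: 2000
#'   max_length_factor: 50
#'   equilibrate: true
#'   max_equil_trials: 5000
#' analysis:
#'   bin_width: 0.1
#'   xlim: [-2, 2]
#'   ylim: [-2, 2]
#'   decorrelated_only: false
#' seed: 42
#' }
#'
#' The file is schema-validated before any computation; unknown top-level
#' keys are an error.
#'
#' @param file path to the YAML configuration.
#' @return An object of class \code{"mstps_config"}: validated settings
#'   with constructed \code{potential}, \code{states} and \code{dynamics}
#'   objects.
#' @export
read_run_config <- function(file) {
  if (!file.exists(file)) stop("config file not found: ", file)
  raw <- yaml::read_yaml(file)
  known <- c("potential", "states", "dynamics", "sampler", "analysis", "seed")
  extra <- setdiff(names(raw), known)
  if (length(extra) > 0)
    stop("unknown config key(s): ", paste(extra, collapse = ", "))
  need <- c("potential", "states")
  miss <- setdiff(need, names(raw))
  if (length(miss) > 0)
    stop("missing config section(s): ", paste(miss, collapse = ", "))

  as_mat <- function(x) do.call(rbind, lapply(x, as.numeric))
  pot <- toy_potential(as_mat(raw$potential$centers),
                       raw$potential$depths, raw$potential$widths)
  st <- disc_states(raw$states$labels, as_mat(raw$states$centers),
                    raw$states$radii)
  dynr <- raw$dynamics
  dyn <- dynamics_params(timestep = dynr$timestep %||% 0.005,
                         diffusion = dynr$diffusion %||% 1)
  smp <- raw$sampler
  sampler <- list(n_trials = as.integer(smp$n_trials %||% 2000L),
                  max_length_factor = smp$max_length_factor %||% 50,
                  equilibrate = isTRUE(smp$equilibrate %||% TRUE),
                  max_equil_trials = as.integer(smp$max_equil_trials %||% 5000L))
  if (sampler$n_trials < 0) stop("sampler$n_trials must be nonnegative")
  ana <- raw$analysis
  analysis <- list(bin_width = ana$bin_width %||% 0.1,
                   xlim = as.numeric(ana$xlim %||% c(-2, 2)),
                   ylim = as.numeric(ana$ylim %||% c(-2, 2)),
                   decorrelated_only = isTRUE(ana$decorrelated_only %||% FALSE))
  if (analysis$bin_width <= 0) stop("analysis$bin_width must be positive")
  structure(list(potential = pot, states = st, dynamics = dyn,
                 sampler = sampler, analysis = analysis,
                 seed = if (!is.null(raw$seed)) as.integer(raw$seed),
                 file = normalizePath(file)),
            class = "mstps_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.mstps_config <- function(x, ...) {
  cat("MSTPS run configuration (", x$file, ")\n", sep = "")
  print(x$potential); print(x$states); print(x$dynamics)
  cat(sprintf("sampler: %d trials, max length %gx initial, equilibrate = %s\n",
              x$sampler$n_trials, x$sampler$max_length_factor,
              x$sampler$equilibrate))
  invisible(x)
}

#' Write the resolved configuration next to run outputs
#'
#' @param config an \code{"mstps_config"}.
#' @param dir output directory.
#' @param seed the seed actually used (overrides the config's).
#' @return The written path, invisibly.
#' @export
write_resolved_config <- function(config, dir, seed = config$seed) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  out <- file.path(dir, "resolved_config.yaml")
  yaml::write_yaml(list(
    potential = list(centers = apply(config$potential$centers, 1, as.list),
                     depths = config$potential$depths,
                     widths = config$potential$widths),
    states = list(labels = config$states$labels,
                  centers = apply(config$states$centers, 1, as.list),
                  radii = config$states$radii),
    dynamics = list(timestep = config$dynamics$timestep,
                    diffusion = config$dynamics$diffusion),
    sampler = config$sampler,
    analysis = config$analysis,
    seed = seed), out)
  invisible(out)
}

#' Run an MSTPS simulation from a configuration
#'
#' Convenience wrapper used by the command-line interface: builds the
#' system from a validated config and runs the sampler.
#'
#' @param config an \code{"mstps_config"} (or a YAML path).
#' @param seed overrides the config's seed when given.
#' @return An \code{"mstps"} chain.
#' @export
run_from_config <- function(config, seed = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "mstps_config"))
  run_mstps(config$potential, config$states, config$dynamics,
            n_trials = config$sampler$n_trials,
            seed = seed %||% config$seed,
            max_length_factor = config$sampler$max_length_factor,
            equilibrate = config$sampler$equilibrate,
            max_equil_trials = config$sampler$max_equil_trials)
}
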