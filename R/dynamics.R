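#' Overdamped Langevin dynamics parameters
#'
#' Parameters for Euler--Maruyama integration of overdamped (Brownian)
#' dynamics, \eqn{x \leftarrow x - \nabla V \Delta t + \sqrt{2 D \Delta t}\,\xi},
#' with \eqn{\xi} standard normal per axis and unit mobility.  Temperature is
#' folded into the diffusion coefficient via the Einstein relation
#' (\eqn{D = kT} at unit mobility), so the stationary density is
#' \eqn{\propto \exp(-V / D)}: at the default \code{diffusion = 1}, well
#' depths are directly in units of kT.
#'
#' @param timestep integration step \eqn{\Delta t} (dimensionless time); > 0.
#' @param diffusion diffusion coefficient \eqn{D} (length^2 / time); >= 0.
#'   \code{D = 0} gives deterministic steepest-descent dynamics.
#' @param seed optional integer seed used by \code{\link{propagate}} for a
#'   self-contained reproducible trajectory.
#' @return An object of class \code{"dynamics_params"}.
#' @export
dynamics_params <- function(timestep = 0.005, diffusion = 1, seed = NULL) {
  stopifnot(is.numeric(timestep), length(timestep) == 1L, timestep > 0,
            is.numeric(diffusion), length(diffusion) == 1L, diffusion >= 0)
  structure(list(timestep = as.numeric(timestep),
                 diffusion = as.numeric(diffusion),
                 seed = if (!is.null(seed)) as.integer(seed)),
            class = "dynamics_params")
}

#' @export
print.dynamics_params <- function(x, ...) {
  cat(sprintf("Overdamped Langevin: dt = %g, D = %g%s\n", x$timestep,
              x$diffusion,
              if (is.null(x$seed)) "" else sprintf(", seed = %d", x$seed)))
  invisible(x)
}

#' Propagate a trajectory on a toy potential
#'
#' Integrates overdamped Langevin dynamics for a fixed number of steps and
#' returns the frames, including the initial point, with fresh frame
#' identities.  With identical \code{params$seed}, initial condition and
#' parameters the coordinate sequence is bitwise reproducible.
#'
#' @param potential a \code{\link{toy_potential}}.
#' @param params a \code{\link{dynamics_params}}.
#' @param x0 length-2 numeric starting position.
#' @param n_steps number of integration steps (>= 1).
#' @return A list with \code{coords} ((n_steps + 1) x 2 matrix),
#'   \code{frame_ids} (integer vector) and \code{time_index}
#'   (0:n_steps).  Aborts with a diagnostic if a coordinate becomes
#'   non-finite (timestep too large).
#' @export
propagate <- function(potential, params, x0, n_steps) {
  stopifnot(inherits(potential, "toy_potential"),
            inherits(params, "dynamics_params"),
            length(x0) == 2L, is.finite(x0[1]), is.finite(x0[2]),
            n_steps >= 1)
  if (!is.null(params$seed)) set.seed(params$seed)
  coords <- cpp_propagate(pot_centers(potential), potential$depths,
                          potential$widths, as.numeric(x0),
                          params$timestep, params$diffusion,
                          as.integer(n_steps))
  list(coords = coords,
       frame_ids = seq_len(nrow(coords)),
       time_index = 0:(nrow(coords) - 1L))
}

# zero-well potentials still need a 0 x 2 matrix for the kernels
pot_centers <- function(potential) {
  c <- potential$centers
  if (nrow(c) == 0L) matrix(numeric(0), 0, 2) else c
}
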