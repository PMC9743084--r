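#' Multi-well toy potential
#'
#' A two-dimensional potential built as a sum of isotropic negative Gaussian
#' wells, \eqn{V(x) = \sum_k -d_k \exp(-|x - c_k|^2 / (2 w_k^2))}, with energy
#' in units of kT.  Far from all wells the energy tends to zero, so barrier
#' heights between non-overlapping wells are approximately the well depths.
#'
#' @param centers numeric matrix (K x 2) of well centers, or a single length-2
#'   vector for one well.
#' @param depths numeric vector of well depths in kT; all positive.
#' @param widths numeric vector of well widths (Gaussian sigma); all positive.
#' @return An object of class \code{"toy_potential"}.
#' @examples
#' pot <- symmetric_three_well()
#' potential_energy(pot, rbind(c(0, 1)))
#' @export
toy_potential <- function(centers, depths, widths) {
  if (is.null(dim(centers))) centers <- matrix(centers, ncol = 2)
  centers <- as.matrix(centers)
  storage.mode(centers) <- "double"
  if (ncol(centers) != 2L)
    stop("centers must be a K x 2 matrix")
  K <- nrow(centers)
  depths <- rep_len(as.numeric(depths), K)
  widths <- rep_len(as.numeric(widths), K)
  if (K > 0 && (any(depths <= 0) || any(widths <= 0)))
    stop("well depths and widths must be strictly positive")
  structure(list(centers = centers, depths = depths, widths = widths),
            class = "toy_potential")
}

#' @export
print.toy_potential <- function(x, ...) {
  cat(sprintf("Toy potential: %d Gaussian well(s)\n", nrow(x$centers)))
  for (k in seq_len(nrow(x$centers)))
    cat(sprintf("  well %d: center (%.3f, %.3f), depth %.2f kT, width %.3f\n",
                k, x$centers[k, 1], x$centers[k, 2], x$depths[k], x$widths[k]))
  invisible(x)
}

#' Potential energy of configurations
#'
#' @param potential a \code{\link{toy_potential}}.
#' @param xy numeric matrix (n x 2) of positions (a length-2 vector is
#'   treated as one position).
#' @return Numeric vector of energies in kT.
#' @export
potential_energy <- function(potential, xy) {
  xy <- as_coords(xy)
  if (nrow(potential$centers) == 0L) return(numeric(nrow(xy)))
  cpp_energy(potential$centers, potential$depths, potential$widths, xy)
}

#' Force (negative potential gradient) of configurations
#'
#' Analytic companion to \code{\link{potential_energy}}.
#'
#' @inheritParams potential_energy
#' @return Numeric matrix (n x 2) of forces in kT per length unit.
#' @export
potential_force <- function(potential, xy) {
  xy <- as_coords(xy)
  if (nrow(potential$centers) == 0L) return(matrix(0, nrow(xy), 2))
  cpp_force(potential$centers, potential$depths, potential$widths, xy)
}

as_coords <- function(xy) {
  if (is.null(dim(xy))) xy <- matrix(xy, ncol = 2)
  xy <- as.matrix(xy)
  storage.mode(xy) <- "double"
  if (ncol(xy) != 2L) stop("coordinates must be n x 2")
  xy
}

#' Bundled symmetric three-well landscape
#'
#' Three wells of equal depth (default 4 kT) at the vertices of an
#' equilateral triangle of circumradius 1.  Barriers between wells are close
#' to the well depth because the wells barely overlap at the default width.
#'
#' @param depth well depth in kT.
#' @param width well width.
#' @return A \code{\link{toy_potential}}.
#' @export
symmetric_three_well <- function(depth = 4, width = 0.3) {
  toy_potential(triangle_centers(), rep(depth, 3), rep(width, 3))
}

#' Bundled asymmetric three-well landscape
#'
#' Same geometry as \code{\link{symmetric_three_well}} but with one well
#' shallower, for mechanism-difference demonstrations.
#'
#' @param depths length-3 vector of well depths in kT.
#' @param width well width.
#' @return A \code{\link{toy_potential}}.
#' @export
asymmetric_three_well <- function(depths = c(4, 4, 2.5), width = 0.3) {
  toy_potential(triangle_centers(), depths, rep(width, 3))
}

triangle_centers <- function() {
  ang <- c(pi / 2, pi / 2 + 2 * pi / 3, pi / 2 + 4 * pi / 3)
  cbind(cos(ang), sin(ang))
}
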