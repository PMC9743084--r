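#' Monte-Carlo-weighted path density histogram
#'
#' Projects a path ensemble onto two collective variables as a reactive-flux
#' density: for each path, the set of bins visited by any of its frames is
#' computed and the path's MC weight is added once to each visited bin — no
#' matter how often the path revisits a bin, it counts once.  The
#' accumulated grid is divided by the total number of MC trials, so each
#' bin value is the weight fraction of sampling during which the current
#' path visited that bin (in [0, 1]).  Unlike a configurational density,
#' this projection is not overwhelmed by long-lived intermediates.
#'
#' Bins are half-open \code{[lo, hi)} with the last bin closed.  Frames
#' falling outside the binning range are assigned to no bin; their count is
#' recorded in the result (never silently clamped).
#'
#' @param paths list of \code{\link{tps_path}} objects (or an
#'   \code{"mstps"} chain, whose accepted paths and trial count are used).
#' @param cv_x,cv_y collective-variable extractors: functions mapping an
#'   n x 2 coordinate matrix to a numeric vector.  Defaults are the two
#'   coordinates.
#' @param breaks_x,breaks_y strictly increasing bin edge vectors.
#' @param weights per-path MC weights; defaults to the paths' own weights.
#' @param total_trials normalisation denominator; defaults to
#'   \code{sum(weights)} (= n_trials + 1 for a full chain).  When pooling
#'   runs, pass the summed trial count.
#' @return An object of class \code{"path_density"}: \code{values} matrix
#'   (x bins by y bins), bin edges, CV names, \code{total_trials} and
#'   \code{dropped_frames}.
#' @examples
#' \donttest{
#' chain <- run_mstps(symmetric_three_well(), three_well_states(),
#'                    dynamics_params(), n_trials = 100, seed = 2)
#' pd <- path_density(chain, breaks_x = seq(-2, 2, 0.1),
#'                    breaks_y = seq(-2, 2, 0.1))
#' }
#' @export
path_density <- function(paths, cv_x = function(xy) xy[, 1],
                         cv_y = function(xy) xy[, 2],
                         breaks_x, breaks_y, weights = NULL,
                         total_trials = NULL) {
  if (inherits(paths, "mstps")) {
    if (is.null(total_trials)) total_trials <- paths$n_trials + 1L
    paths <- paths$paths
  }
  stopifnot(length(paths) > 0L,
            all(diff(breaks_x) > 0), all(diff(breaks_y) > 0))
  if (is.null(weights))
    weights <- vapply(paths, `[[`, integer(1), "weight")
  weights <- as.numeric(weights)
  stopifnot(length(weights) == length(paths), all(weights >= 0))
  if (is.null(total_trials)) total_trials <- sum(weights)

  nx <- length(breaks_x) - 1L
  ny <- length(breaks_y) - 1L
  values <- matrix(0, nx, ny)
  dropped <- 0L
  for (i in seq_along(paths)) {
    xy <- paths[[i]]$coords
    bx <- findInterval(cv_x(xy), breaks_x, rightmost.closed = TRUE)
    by <- findInterval(cv_y(xy), breaks_y, rightmost.closed = TRUE)
    out <- bx < 1L | bx > nx | by < 1L | by > ny
    dropped <- dropped + sum(out)
    if (all(out)) next
    cells <- unique((by[!out] - 1L) * nx + bx[!out])
    values[cells] <- values[cells] + weights[i]
  }
  values <- values / total_trials
  if (dropped > 0L)
    message(sprintf("path_density: %d frame(s) outside the binning range were dropped", dropped))
  structure(list(values = values, breaks_x = breaks_x, breaks_y = breaks_y,
                 cv_names = c(deparse1(substitute(cv_x)),
                              deparse1(substitute(cv_y))),
                 total_trials = total_trials, dropped_frames = dropped),
            class = "path_density")
}

#' @export
print.path_density <- function(x, ...) {
  cat(sprintf("Path density histogram: %d x %d bins, normalised by %d MC trials\n",
              nrow(x$values), ncol(x$values), as.integer(x$total_trials)))
  cat(sprintf("  max bin value %.4f; %d frame(s) outside range dropped\n",
              max(x$values), x$dropped_frames))
  invisible(x)
}

#' @export
plot.path_density <- function(x, ...) {
  mx <- x$breaks_x[-1] - diff(x$breaks_x) / 2
  my <- x$breaks_y[-1] - diff(x$breaks_y) / 2
  graphics::image(mx, my, x$values,
                  col = grDevices::hcl.colors(50, "viridis"),
                  xlab = "CV x", ylab = "CV y", ...)
  invisible(x)
}

#' Configurational probability histogram of in-state frames
#'
#' Per-frame (not once-per-path) weighted 2D histogram: each frame carries
#' the MC weight of its source path, and the grid is normalised to sum 1.
#' Used to characterise the configurations a state adopts within the path
#' ensemble.
#'
#' @param coords n x 2 matrix of frame coordinates (e.g. the frames of all
#'   visits to one state).
#' @param weights per-frame weights (the source path's MC weight).
#' @param cv_x,cv_y collective-variable extractors as in
#'   \code{\link{path_density}}.
#' @param breaks_x,breaks_y strictly increasing bin edges.
#' @return A \code{"path_density"}-style object whose \code{values} sum
#'   to 1.
#' @export
state_probability_histogram <- function(coords, weights = rep(1, nrow(coords)),
                                        cv_x = function(xy) xy[, 1],
                                        cv_y = function(xy) xy[, 2],
                                        breaks_x, breaks_y) {
  coords <- as_coords(coords)
  if (nrow(coords) == 0L) stop("empty frame set")
  stopifnot(length(weights) == nrow(coords), all(weights >= 0),
            all(diff(breaks_x) > 0), all(diff(breaks_y) > 0))
  nx <- length(breaks_x) - 1L
  ny <- length(breaks_y) - 1L
  bx <- findInterval(cv_x(coords), breaks_x, rightmost.closed = TRUE)
  by <- findInterval(cv_y(coords), breaks_y, rightmost.closed = TRUE)
  out <- bx < 1L | bx > nx | by < 1L | by > ny
  if (all(out)) stop("all frames fall outside the binning range")
  values <- matrix(0, nx, ny)
  cells <- (by[!out] - 1L) * nx + bx[!out]
  w <- as.numeric(weights)[!out]
  for (i in seq_along(cells))
    values[cells[i]] <- values[cells[i]] + w[i]
  values <- values / sum(values)
  if (any(out))
    message(sprintf("state_probability_histogram: %d frame(s) outside the binning range were dropped", sum(out)))
  structure(list(values = values, breaks_x = breaks_x, breaks_y = breaks_y,
                 cv_names = c("cv_x", "cv_y"),
                 total_trials = NA_real_, dropped_frames = sum(out)),
            class = "path_density")
}

#' Collect in-state frames with path weights from a chain
#'
#' Helper feeding \code{\link{state_probability_histogram}}: all frames of
#' accepted paths lying inside one state, each tagged with its path's MC
#' weight.
#'
#' @param chain an \code{"mstps"} object.
#' @param state state label.
#' @return List with \code{coords} and \code{weights}.
#' @export
state_frames <- function(chain, state) {
  stopifnot(inherits(chain, "mstps"), state %in% chain$states$labels)
  cs <- lapply(chain$paths, function(p) {
    lab <- assign_state(p$coords, chain$states)
    keep <- !is.na(lab) & lab == state
    list(coords = p$coords[keep, , drop = FALSE],
         weights = rep(p$weight, sum(keep)))
  })
  list(coords = do.call(rbind, lapply(cs, `[[`, "coords")),
       weights = unlist(lapply(cs, `[[`, "weights")))
}
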