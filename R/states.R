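#' Disc-shaped stable state definitions
#'
#' Stable states for the toy system are discs in the two collective-variable
#' coordinates: a frame belongs to state \code{i} when its distance to
#' \code{centers[i, ]} is at most \code{radii[i]}.  States must be pairwise
#' disjoint (no point may satisfy two membership predicates); for discs this
#' is checked analytically at construction.
#'
#' @param labels character vector of unique state labels.
#' @param centers numeric matrix (S x 2) of disc centers.
#' @param radii numeric vector of disc radii; positive.
#' @return An object of class \code{"state_set"}.
#' @examples
#' st <- disc_states(c("A", "B"), rbind(c(-1, 0), c(1, 0)), 0.3)
#' assign_state(c(-1, 0), st)
#' @export
disc_states <- function(labels, centers, radii) {
  labels <- as.character(labels)
  if (anyDuplicated(labels)) stop("state labels must be unique")
  if (is.null(dim(centers))) centers <- matrix(centers, ncol = 2)
  centers <- as.matrix(centers)
  storage.mode(centers) <- "double"
  S <- nrow(centers)
  if (length(labels) != S) stop("one label per state required")
  radii <- rep_len(as.numeric(radii), S)
  if (any(radii <= 0)) stop("state radii must be positive")
  if (S >= 2L) {
    d <- as.matrix(stats::dist(centers))
    need <- outer(radii, radii, `+`)
    diag(d) <- Inf
    if (any(d <= need))
      stop("overlapping state definitions: state discs must be pairwise disjoint")
  }
  structure(list(labels = labels, centers = centers, radii = radii),
            class = "state_set")
}

#' @export
print.state_set <- function(x, ...) {
  cat(sprintf("%d disjoint disc state(s):\n", length(x$labels)))
  for (s in seq_along(x$labels))
    cat(sprintf("  %s: center (%.3f, %.3f), radius %.3f\n", x$labels[s],
                x$centers[s, 1], x$centers[s, 2], x$radii[s]))
  invisible(x)
}

#' Default states for the bundled three-well landscapes
#'
#' Discs of radius one well-width centred on the wells of
#' \code{\link{symmetric_three_well}}, labelled A, B, C.
#'
#' @param radius disc radius; the default matches the default well width.
#' @return A \code{\link{disc_states}} object.
#' @export
three_well_states <- function(radius = 0.3) {
  disc_states(c("A", "B", "C"), triangle_centers(), radius)
}

#' Assign frames to stable states
#'
#' @param xy frame coordinates: length-2 vector or n x 2 matrix.
#' @param states a \code{\link{disc_states}} object.
#' @return Character vector of state labels, \code{NA} where a frame lies in
#'   no state.  Because states are disjoint the assignment is unique.
#' @export
assign_state <- function(xy, states) {
  xy <- as_coords(xy)
  idx <- state_index(xy, states)
  out <- rep(NA_character_, nrow(xy))
  out[idx > 0L] <- states$labels[idx[idx > 0L]]
  out
}

# integer state index per frame, 0 = none (vectorised)
state_index <- function(xy, states) {
  n <- nrow(xy)
  idx <- integer(n)
  for (s in seq_along(states$labels)) {
    d2 <- (xy[, 1] - states$centers[s, 1])^2 + (xy[, 2] - states$centers[s, 2])^2
    hit <- idx == 0L & d2 <= states$radii[s]^2
    idx[hit] <- s
  }
  idx
}
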