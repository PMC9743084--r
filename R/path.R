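#' Transition path objects
#'
#' A path is an ordered sequence of frames in collective-variable space.  In
#' the flexible-length, all-to-all ensemble a valid path starts inside
#' exactly one state, ends inside exactly one *different* state, and has no
#' interior frame inside any state.  Each frame carries a globally unique
#' integer identity (\code{frame_ids}), the primitive on which decorrelation
#' between accepted paths is defined.
#'
#' @param coords n x 2 numeric matrix of frame coordinates.
#' @param frame_ids integer vector of unique frame identities.
#' @param transition length-2 character vector (from-state, to-state).
#' @param weight nonnegative integer Monte Carlo weight: the number of MC
#'   trials for which the path was the current path (accepting trial plus
#'   subsequent rejections), plus one for the initial path's occupancy.
#' @param accepted_at_trial trial index at which the path was accepted (0 for
#'   the initial path).
#' @return An object of class \code{"tps_path"}.
#' @export
tps_path <- function(coords, frame_ids, transition, weight = 0L,
                     accepted_at_trial = 0L) {
  coords <- as_coords(coords)
  frame_ids <- as.integer(frame_ids)
  if (length(frame_ids) != nrow(coords))
    stop("one frame_id per frame required")
  if (anyDuplicated(frame_ids)) stop("frame_ids must be unique within a path")
  stopifnot(length(transition) == 2L, weight >= 0)
  structure(list(coords = coords, frame_ids = frame_ids,
                 transition = as.character(transition),
                 weight = as.integer(weight),
                 accepted_at_trial = as.integer(accepted_at_trial)),
            class = "tps_path")
}

#' @export
print.tps_path <- function(x, ...) {
  cat(sprintf("Transition path %s -> %s: %d frames, MC weight %d%s\n",
              x$transition[1], x$transition[2], nrow(x$coords), x$weight,
              if (x$accepted_at_trial > 0)
                sprintf(", accepted at trial %d", x$accepted_at_trial) else ""))
  invisible(x)
}

#' @export
length.tps_path <- function(x) nrow(x$coords)

#' Transition label of a path
#'
#' Ordered-pair label \code{"from->to"}; with S states there are S(S-1)
#' labels and the reverse of a label is a distinct label.
#'
#' @param path a \code{\link{tps_path}} (or length-2 character vector).
#' @return Character scalar.
#' @export
transition_label <- function(path) {
  tr <- if (inherits(path, "tps_path")) path$transition else as.character(path)
  paste0(tr[1], "->", tr[2])
}

#' All ordered transition labels for a set of states
#'
#' @param states a \code{\link{disc_states}} object or character vector of
#'   state labels.
#' @return Character vector of the S(S-1) ordered-pair labels.
#' @export
all_transition_labels <- function(states) {
  s <- if (inherits(states, "state_set")) states$labels else as.character(states)
  g <- expand.grid(to = s, from = s, stringsAsFactors = FALSE)
  g <- g[g$from != g$to, ]
  paste0(g$from, "->", g$to)
}

split_label <- function(label) strsplit(label, "->", fixed = TRUE)

#' Validate a path against the ensemble definition
#'
#' Checks the flexible-length all-to-all ensemble invariants: endpoints in
#' two distinct states, no interior frame in any state, transition field
#' matching the endpoint assignments.
#'
#' @param path a \code{\link{tps_path}}.
#' @param states a \code{\link{disc_states}} object.
#' @return \code{TRUE} invisibly, or an error describing the violation.
#' @export
validate_path <- function(path, states) {
  lab <- assign_state(path$coords, states)
  n <- length(lab)
  if (n < 2L) stop("a path needs at least two frames")
  if (is.na(lab[1]) || is.na(lab[n]))
    stop("path endpoints must lie inside states")
  if (lab[1] == lab[n])
    stop("self-transition: path endpoints must lie in two distinct states")
  if (n > 2L && any(!is.na(lab[2:(n - 1L)])))
    stop("interior path frame lies inside a state")
  if (!identical(path$transition, c(lab[1], lab[n])))
    stop("transition field does not match endpoint state assignments")
  invisible(TRUE)
}
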