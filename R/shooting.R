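#' One-way shooting move
#'
#' Regenerates one side of the current path from a shooting frame using the
#' stochastic dynamics.  A forward shot keeps frames \code{1..shooting_index}
#' and integrates forward until a newly generated frame enters any state; a
#' backward shot integrates backward from the shooting frame (time reversal
#' is valid for overdamped dynamics) and keeps
#' \code{shooting_index..length}.  Retained frames keep their frame
#' identities; new frames receive fresh ones.  The assembled trial is trimmed
#' at its first (forward) or last (backward) in-state frame so that no
#' interior frame lies inside a state; shooting from an endpoint frame
#' therefore yields a duplicate of the current path, which the acceptance
#' rule handles as an ordinary trial.
#'
#' @param current the current \code{\link{tps_path}}.
#' @param direction \code{"forward"} or \code{"backward"}.
#' @param shooting_index frame index in \code{1..length(current)}, chosen
#'   uniformly by the sampler.
#' @param potential,states,dynamics system definition
#'   (\code{\link{toy_potential}}, \code{\link{disc_states}},
#'   \code{\link{dynamics_params}}).
#' @param max_length maximum number of frames allowed in the trial path; a
#'   segment still outside all states at the cap is a failed trial
#'   (reason \code{"max_length"}), not an error.
#' @param next_id first unused frame id (monotone counter).
#' @return A list with \code{path} (the trial \code{\link{tps_path}}, or
#'   \code{NULL} on failure), \code{reason} (\code{NULL} or
#'   \code{"max_length"}), \code{n_new_steps} (dynamics steps generated,
#'   including any trimmed away) and \code{next_id} (updated counter).
#' @export
shoot_one_way <- function(current, direction = c("forward", "backward"),
                          shooting_index, potential, states, dynamics,
                          max_length, next_id = max(current$frame_ids) + 1L) {
  direction <- match.arg(direction)
  L <- length(current)
  stopifnot(shooting_index >= 1L, shooting_index <= L)
  k <- as.integer(shooting_index)

  kept_n <- if (direction == "forward") k else L - k + 1L
  budget <- max_length - kept_n
  if (budget < 1L)
    return(list(path = NULL, reason = "max_length", n_new_steps = 0L,
                next_id = next_id))

  seg <- cpp_shoot_segment(pot_centers(potential), potential$depths,
                           potential$widths, states$centers, states$radii,
                           current$coords[k, ], dynamics$timestep,
                           dynamics$diffusion, as.integer(budget))
  n_new <- nrow(seg$coords)
  new_ids <- seq.int(next_id, length.out = n_new)
  next_id <- next_id + n_new
  if (seg$state == 0L)
    return(list(path = NULL, reason = "max_length", n_new_steps = n_new,
                next_id = next_id))

  if (direction == "forward") {
    coords <- rbind(current$coords[seq_len(k), , drop = FALSE], seg$coords)
    ids <- c(current$frame_ids[seq_len(k)], new_ids)
    lab <- assign_state(coords, states)
    end <- 1L + which(!is.na(lab[-1L]))[1L]  # first in-state frame after start
    coords <- coords[seq_len(end), , drop = FALSE]
    ids <- ids[seq_len(end)]
    tr <- c(lab[1L], lab[end])
  } else {
    coords <- rbind(seg$coords[rev(seq_len(n_new)), , drop = FALSE],
                    current$coords[seq.int(k, L), , drop = FALSE])
    ids <- c(rev(new_ids), current$frame_ids[seq.int(k, L)])
    lab <- assign_state(coords, states)
    M <- nrow(coords)
    beg <- max(which(!is.na(lab[-M])))  # last in-state frame before end
    coords <- coords[seq.int(beg, M), , drop = FALSE]
    ids <- ids[seq.int(beg, M)]
    tr <- c(lab[beg], lab[M])
  }
  list(path = tps_path(coords, ids, tr), reason = NULL,
       n_new_steps = n_new, next_id = next_id)
}

#' Acceptance rule for one-way shooting trials
#'
#' A trial whose endpoints do not lie in two distinct states is rejected
#' (reason \code{"self_transition"} for a path returning to its initial
#' state, \code{"max_length"} for a non-terminating segment).  A valid trial
#' is accepted with probability \code{min(1, L_current / L_trial)}, where L
#' is the frame count: the detailed-balance correction for uniform
#' shooting-point selection in a flexible-length ensemble.
#'
#' @param current the current \code{\link{tps_path}}.
#' @param trial the trial path, or \code{NULL} for a failed shot.
#' @param reason failure reason passed through from
#'   \code{\link{shoot_one_way}}.
#' @return A list with \code{accepted} (logical) and \code{reason}
#'   (\code{"accepted"}, \code{"self_transition"}, \code{"max_length"} or
#'   \code{"metropolis"}).  Consumes one uniform deviate only when the
#'   length criterion is actually tested.
#' @export
accept_trial <- function(current, trial, reason = NULL) {
  if (is.null(trial))
    return(list(accepted = FALSE, reason = if (is.null(reason)) "max_length" else reason))
  if (trial$transition[1] == trial$transition[2])
    return(list(accepted = FALSE, reason = "self_transition"))
  ratio <- length(current) / length(trial)
  if (ratio >= 1 || stats::runif(1) < ratio)
    list(accepted = TRUE, reason = "accepted")
  else
    list(accepted = FALSE, reason = "metropolis")
}
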