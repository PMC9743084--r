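#' Generate an initial transition path
#'
#' Builds a starting path for MSTPS by shooting forward and backward from a
#' point between two state discs (by default the midpoint of the first two
#' states, close to the barrier saddle on the bundled landscapes) until both
#' segments terminate in states; retries until the two endpoint states
#' differ.
#'
#' @param potential,states,dynamics system definition.
#' @param x0 length-2 starting point; default midpoint of the first two
#'   state centers.
#' @param max_segment cap on each segment's length.
#' @param max_attempts retries before giving up.
#' @return A valid \code{\link{tps_path}} with frame ids \code{1..n}.
#' @export
initial_path <- function(potential, states, dynamics,
                         x0 = colMeans(states$centers[1:2, , drop = FALSE]),
                         max_segment = 100000L, max_attempts = 100L) {
  if (!is.na(assign_state(x0, states)[1]))
    stop("initial shooting point must lie outside all states")
  for (i in seq_len(max_attempts)) {
    fwd <- cpp_shoot_segment(pot_centers(potential), potential$depths,
                             potential$widths, states$centers, states$radii,
                             as.numeric(x0), dynamics$timestep,
                             dynamics$diffusion, as.integer(max_segment))
    bwd <- cpp_shoot_segment(pot_centers(potential), potential$depths,
                             potential$widths, states$centers, states$radii,
                             as.numeric(x0), dynamics$timestep,
                             dynamics$diffusion, as.integer(max_segment))
    if (fwd$state == 0L || bwd$state == 0L || fwd$state == bwd$state) next
    nb <- nrow(bwd$coords)
    coords <- rbind(bwd$coords[rev(seq_len(nb)), , drop = FALSE],
                    matrix(as.numeric(x0), 1, 2), fwd$coords)
    path <- tps_path(coords, seq_len(nrow(coords)),
                     c(states$labels[bwd$state], states$labels[fwd$state]),
                     weight = 0L, accepted_at_trial = 0L)
    validate_path(path, states)
    return(path)
  }
  stop("failed to generate an initial transition path; check state/potential geometry")
}

#' Run multiple-state transition path sampling
#'
#' Flexible-length, all-to-all MSTPS with one-way shooting.  Each trial
#' picks forward or backward with probability 1/2, a shooting frame
#' uniformly over the current path, regenerates that side with the
#' stochastic dynamics, and applies the acceptance rule of
#' \code{\link{accept_trial}} (self-transitions are excluded from the
#' ensemble).  The accepted path becomes current; every trial attributes one
#' unit of Monte Carlo weight to the path current after the trial, so that
#' the weights of all paths sum to \code{n_trials + 1} (the extra unit is
#' the initial occupancy).
#'
#' @param potential,states,dynamics system definition.
#' @param n_trials number of production shooting trials.
#' @param initial optional starting \code{\link{tps_path}}; generated with
#'   \code{\link{initial_path}} when omitted.  Validated before sampling.
#' @param seed optional integer seed for the whole run.
#' @param max_length_factor trial paths are capped at this multiple of the
#'   initial path length (cap in frames); exceeding it is a rejection.
#' @param equilibrate when \code{TRUE}, a pre-phase of shooting trials runs
#'   until the current path is decorrelated from the initial path (shares no
#'   frame ids); the pre-phase is excluded from all production records and
#'   weights.
#' @param max_equil_trials cap on the equilibration pre-phase.
#' @return An object of class \code{"mstps"}: the sampling record, with
#'   \code{paths} (accepted paths, element 1 the production starting path,
#'   each with its MC weight), \code{records} (one row per trial: direction,
#'   shooting frame id, outcome, rejection reason, current transition label
#'   after the trial, dynamics steps generated) and equilibration metadata.
#' @examples
#' \donttest{
#' chain <- run_mstps(symmetric_three_well(), three_well_states(),
#'                    dynamics_params(), n_trials = 50, seed = 1)
#' summary(chain)
#' }
#' @export
run_mstps <- function(potential, states, dynamics, n_trials, initial = NULL,
                      seed = NULL, max_length_factor = 50,
                      equilibrate = FALSE, max_equil_trials = 5000L) {
  stopifnot(n_trials >= 0)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(initial)) initial <- initial_path(potential, states, dynamics)
  validate_path(initial, states)
  max_length <- as.integer(ceiling(max_length_factor * length(initial)))

  env <- new.env(parent = emptyenv())
  env$next_id <- max(initial$frame_ids) + 1L

  one_trial <- function(current) {
    direction <- if (stats::runif(1) < 0.5) "forward" else "backward"
    k <- sample.int(length(current), 1L)
    shot <- shoot_one_way(current, direction, k, potential, states, dynamics,
                          max_length, env$next_id)
    env$next_id <- shot$next_id
    dec <- accept_trial(current, shot$path, shot$reason)
    list(direction = direction, shoot_id = current$frame_ids[k],
         accepted = dec$accepted, reason = dec$reason,
         path = if (dec$accepted) shot$path else NULL,
         n_new_steps = shot$n_new_steps)
  }

  equil <- list(performed = FALSE, n_trials = 0L, n_accepted = 0L,
                decorrelated = NA, n_steps = 0L)
  current <- initial
  if (equilibrate) {
    equil$performed <- TRUE
    init_ids <- initial$frame_ids
    t <- 0L
    while (t < max_equil_trials &&
           length(intersect(current$frame_ids, init_ids)) > 0L) {
      t <- t + 1L
      res <- one_trial(current)
      equil$n_steps <- equil$n_steps + res$n_new_steps
      if (res$accepted) {
        equil$n_accepted <- equil$n_accepted + 1L
        current <- res$path
      }
    }
    equil$n_trials <- t
    equil$decorrelated <- length(intersect(current$frame_ids, init_ids)) == 0L
    if (!equil$decorrelated)
      warning("equilibration pre-phase ended before full decorrelation")
    current$accepted_at_trial <- 0L
  }

  paths <- list()
  cur_weight <- 1L  # initial occupancy
  records <- vector("list", n_trials)
  for (trial in seq_len(n_trials)) {
    res <- one_trial(current)
    if (res$accepted) {
      current$weight <- cur_weight
      paths[[length(paths) + 1L]] <- current
      current <- res$path
      current$accepted_at_trial <- trial
      cur_weight <- 1L
    } else {
      cur_weight <- cur_weight + 1L
    }
    records[[trial]] <- data.frame(
      trial = trial, direction = res$direction, shoot_frame_id = res$shoot_id,
      accepted = res$accepted, reason = res$reason,
      label = transition_label(current), n_new_steps = res$n_new_steps,
      stringsAsFactors = FALSE)
  }
  current$weight <- cur_weight
  paths[[length(paths) + 1L]] <- current
  records <- if (n_trials > 0) do.call(rbind, records) else
    data.frame(trial = integer(), direction = character(),
               shoot_frame_id = integer(), accepted = logical(),
               reason = character(), label = character(),
               n_new_steps = integer(), stringsAsFactors = FALSE)

  structure(list(paths = paths, records = records,
                 n_trials = as.integer(n_trials), states = states,
                 potential = potential, dynamics = dynamics,
                 max_length = max_length, equilibration = equil),
            class = "mstps")
}

#' @export
print.mstps <- function(x, ...) {
  s <- summary(x)
  cat(sprintf("MSTPS chain: %d MC trials, %d accepted (%.1f%%), %d decorrelated\n",
              s$mc_steps, s$accepted_steps, 100 * s$acceptance,
              s$decorrelated))
  invisible(x)
}

#' Per-trial transition labels of a chain
#'
#' The label of the current (most recently accepted) path after each
#' production trial — the sequence on which residence times and switch
#' counts are defined, so rejected trials extend the residence time of the
#' current transition.
#'
#' @param chain an \code{"mstps"} object.
#' @return Character vector of length \code{n_trials}.
#' @export
trial_labels <- function(chain) {
  stopifnot(inherits(chain, "mstps"))
  chain$records$label
}

#' Count decorrelated paths in a chain
#'
#' Greedy scan of the accepted-path sequence: the initial path is the first
#' decorrelated path, and each subsequent accepted path sharing zero frame
#' ids with the most recent decorrelated path becomes the next reference.
#' Matches the usual "trajectories with no frames in common" bookkeeping of
#' path-sampling convergence reports.
#'
#' @param chain an \code{"mstps"} object (or plain list of
#'   \code{\link{tps_path}}).
#' @return Integer count; see \code{\link{decorrelated_indices}} for the
#'   positions.
#' @export
count_decorrelated <- function(chain) {
  length(decorrelated_indices(chain))
}

#' Indices of decorrelated paths
#'
#' @inheritParams count_decorrelated
#' @return Integer vector of indices into the accepted-path sequence.
#' @export
decorrelated_indices <- function(chain) {
  paths <- if (inherits(chain, "mstps")) chain$paths else chain
  if (length(paths) == 0L) return(integer())
  ref <- paths[[1L]]$frame_ids
  out <- 1L
  for (i in seq_along(paths)[-1L]) {
    if (length(intersect(paths[[i]]$frame_ids, ref)) == 0L) {
      out <- c(out, i)
      ref <- paths[[i]]$frame_ids
    }
  }
  out
}

#' Summarise an MSTPS chain
#'
#' The standard per-simulation statistics table: MC trials, accepted trials,
#' acceptance fraction, decorrelated-path count, average accepted-path
#' length in time units ((frames - 1) x timestep x save interval), and the
#' total dynamics time generated over all shooting segments, accepted and
#' rejected.
#'
#' @param object an \code{"mstps"} object.
#' @param save_interval dynamics steps per saved frame (1 for the toy
#'   engine).
#' @param ... unused.
#' @return A list of class \code{"summary.mstps"}.
#' @export
summary.mstps <- function(object, save_interval = 1, ...) {
  acc <- sum(object$records$accepted)
  nt <- object$n_trials
  dt <- object$dynamics$timestep
  lens <- vapply(object$paths, length, integer(1))
  total_steps <- sum(object$records$n_new_steps)
  out <- list(mc_steps = nt, accepted_steps = acc,
              acceptance = if (nt > 0) acc / nt else NA_real_,
              decorrelated = count_decorrelated(object),
              avg_path_length = mean(lens - 1L) * dt * save_interval,
              total_dynamics_time = total_steps * dt * save_interval,
              sum_weights = sum(vapply(object$paths, `[[`, integer(1), "weight")),
              n_paths = length(object$paths))
  class(out) <- "summary.mstps"
  out
}

#' @export
print.summary.mstps <- function(x, ...) {
  cat("MSTPS simulation statistics\n")
  cat(sprintf("  MC steps                 %d\n", x$mc_steps))
  cat(sprintf("  accepted steps           %d\n", x$accepted_steps))
  cat(sprintf("  acceptance               %.1f%%\n", 100 * x$acceptance))
  cat(sprintf("  decorrelated trajectories %d\n", x$decorrelated))
  cat(sprintf("  average path length      %.4g time units\n", x$avg_path_length))
  cat(sprintf("  total dynamics time      %.4g time units\n", x$total_dynamics_time))
  invisible(x)
}

#' Plot an MSTPS chain
#'
#' Draws the potential-energy surface as filled contours with state discs
#' and a subsample of accepted paths coloured by transition label.
#'
#' @param x an \code{"mstps"} object.
#' @param n_paths maximum number of paths to draw.
#' @param ... passed to \code{\link[graphics]{image}}.
#' @export
plot.mstps <- function(x, n_paths = 30, ...) {
  rng <- range(x$states$centers) + c(-1, 1)
  gx <- seq(rng[1], rng[2], length.out = 120)
  grid <- as.matrix(expand.grid(gx, gx))
  z <- matrix(potential_energy(x$potential, grid), 120, 120)
  graphics::image(gx, gx, z, col = grDevices::hcl.colors(40, "Blues", rev = TRUE),
                  xlab = "CV x", ylab = "CV y", ...)
  th <- seq(0, 2 * pi, length.out = 100)
  for (s in seq_along(x$states$labels)) {
    graphics::lines(x$states$centers[s, 1] + x$states$radii[s] * cos(th),
                    x$states$centers[s, 2] + x$states$radii[s] * sin(th))
    graphics::text(x$states$centers[s, 1], x$states$centers[s, 2],
                   x$states$labels[s])
  }
  labs <- vapply(x$paths, transition_label, character(1))
  cols <- grDevices::hcl.colors(length(unique(labs)), "Dark 3")
  names(cols) <- unique(labs)
  idx <- unique(round(seq(1, length(x$paths), length.out = min(n_paths, length(x$paths)))))
  for (i in idx)
    graphics::lines(x$paths[[i]]$coords, col = cols[labs[i]], lwd = 0.5)
  invisible(x)
}
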