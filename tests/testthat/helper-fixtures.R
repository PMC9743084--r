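# Shared fixtures, built in code at test time.

two_well_system <- function(depth = 4, width = 0.3) {
  list(potential = toy_potential(rbind(c(-1, 0), c(1, 0)),
                                 rep(depth, 2), rep(width, 2)),
       states = disc_states(c("A", "B"), rbind(c(-1, 0), c(1, 0)), width),
       dynamics = dynamics_params(0.005, 1))
}

three_well_system <- function() {
  list(potential = symmetric_three_well(),
       states = three_well_states(),
       dynamics = dynamics_params(0.005, 1))
}

# A straight-line path between two well/state centers whose interior frames
# lie outside all state discs; convenient hand-built valid path.
line_path <- function(states, from = 1L, to = 2L, n_interior = 11L,
                      ids = NULL) {
  a <- states$centers[from, ]
  b <- states$centers[to, ]
  t <- c(0, seq(0.3, 0.7, length.out = n_interior), 1)
  coords <- cbind(a[1] + t * (b[1] - a[1]), a[2] + t * (b[2] - a[2]))
  if (is.null(ids)) ids <- seq_len(nrow(coords))
  tps_path(coords, ids, c(states$labels[from], states$labels[to]))
}

# One moderate sampled chain shared across tests (computed once per run).
.fixture_env <- new.env(parent = emptyenv())
get_demo_chain <- function() {
  if (is.null(.fixture_env$chain)) {
    sys <- three_well_system()
    .fixture_env$chain <- run_mstps(sys$potential, sys$states, sys$dynamics,
                                    n_trials = 1500, seed = 101,
                                    equilibrate = TRUE)
  }
  .fixture_env$chain
}

# Independent brute-force path-density oracle: per-path binary occupancy
# matrices, summed with weights, divided by total trials.
brute_force_path_density <- function(paths, weights, breaks_x, breaks_y,
                                     total_trials) {
  nx <- length(breaks_x) - 1L
  ny <- length(breaks_y) - 1L
  acc <- matrix(0, nx, ny)
  for (i in seq_along(paths)) {
    occ <- matrix(0, nx, ny)
    xy <- paths[[i]]$coords
    for (f in seq_len(nrow(xy))) {
      bx <- findInterval(xy[f, 1], breaks_x, rightmost.closed = TRUE)
      by <- findInterval(xy[f, 2], breaks_y, rightmost.closed = TRUE)
      if (bx >= 1 && bx <= nx && by >= 1 && by <= ny) occ[bx, by] <- 1
    }
    acc <- acc + weights[i] * occ
  }
  acc / total_trials
}

# Total-variation distance between two probability vectors.
tv_dist <- function(p, q) 0.5 * sum(abs(p - q))

# Familywise critical value for m simultaneous two-sided checks at the
# strength of a single 3-sigma comparison (Sidak-style bound).
z_crit <- function(m) qnorm(1 - (1 - pnorm(3)) / m)

# A fixed asymmetric 6-label switch-probability matrix used as kinetics
# ground truth (row sums comfortably below 1).
kinetics_oracle_q <- function() {
  labs <- all_transition_labels(c("A", "B", "C"))
  q <- matrix(0, 6, 6, dimnames = list(labs, labs))
  q[upper.tri(q)] <- c(0.02, 0.01, 0.03, 0.015, 0.005, 0.02,
                       0.01, 0.03, 0.005, 0.02, 0.015, 0.01,
                       0.02, 0.01, 0.005)[1:15]
  q[lower.tri(q)] <- t(q)[lower.tri(q)] * c(1.5)
  diag(q) <- 0
  q
}
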