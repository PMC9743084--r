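test_that("state assignment is unique, disc-based and rejects overlaps", {
  st <- three_well_states()
  expect_identical(assign_state(st$centers, st), c("A", "B", "C"))
  expect_identical(assign_state(c(5, 5), st), NA_character_)
  expect_error(disc_states(c("A", "B"), rbind(c(0, 0), c(0.5, 0)), 0.3),
               "overlapping")
  expect_error(disc_states(c("A", "A"), rbind(c(0, 0), c(5, 0)), 0.3),
               "unique")
})

test_that("path validation enforces the ensemble invariants", {
  st <- three_well_states()
  good <- line_path(st, 1, 2)
  expect_true(validate_path(good, st))
  # same-state endpoints
  bad <- good; bad$coords[nrow(bad$coords), ] <- st$centers[1, ]
  bad$transition <- c("A", "A")
  expect_error(validate_path(bad, st), "self-transition")
  # interior frame inside a state
  bad2 <- good; bad2$coords[5, ] <- st$centers[3, ]
  expect_error(validate_path(bad2, st), "interior")
})

test_that("a forward shot shares exactly frames 1..k with the current path", {
  sys <- three_well_system()
  set.seed(12)
  cur <- initial_path(sys$potential, sys$states, sys$dynamics)
  k <- ceiling(length(cur) / 2)
  shot <- shoot_one_way(cur, "forward", k, sys$potential, sys$states,
                        sys$dynamics, max_length = 50 * length(cur))
  expect_null(shot$reason)
  shared <- intersect(shot$path$frame_ids, cur$frame_ids)
  expect_identical(sort(shared), cur$frame_ids[seq_len(k)])
  expect_identical(shot$path$frame_ids[seq_len(k)], cur$frame_ids[seq_len(k)])
  # fresh identities for the regenerated side
  expect_gt(min(setdiff(shot$path$frame_ids, cur$frame_ids)),
            max(cur$frame_ids))
})

test_that("a backward shot keeps the tail and regenerates the head", {
  sys <- three_well_system()
  set.seed(13)
  cur <- initial_path(sys$potential, sys$states, sys$dynamics)
  k <- ceiling(length(cur) / 2)
  shot <- shoot_one_way(cur, "backward", k, sys$potential, sys$states,
                        sys$dynamics, max_length = 50 * length(cur))
  expect_null(shot$reason)
  L <- length(cur)
  shared <- intersect(shot$path$frame_ids, cur$frame_ids)
  expect_identical(sort(shared), cur$frame_ids[seq.int(k, L)])
  nL <- length(shot$path)
  expect_identical(shot$path$frame_ids[seq.int(nL - (L - k), nL)],
                   cur$frame_ids[seq.int(k, L)])
})

test_that("D = 0 shooting terminates in the state of the shooting point's basin", {
  sys <- three_well_system()
  frozen <- dynamics_params(timestep = 0.005, diffusion = 0)
  cur <- line_path(sys$states, 1, 2, n_interior = 21)
  # interior frame index 18 lies well inside state B's basin
  k <- 18L
  stopifnot(is.na(assign_state(cur$coords[k, ], sys$states)))
  shot <- shoot_one_way(cur, "forward", k, sys$potential, sys$states,
                        frozen, max_length = 5000)
  expect_identical(shot$path$transition[2], "B")
  # and from an index in A's basin, a backward descent ends in A
  shot2 <- shoot_one_way(cur, "backward", 4L, sys$potential, sys$states,
                         frozen, max_length = 5000)
  expect_identical(shot2$path$transition[1], "A")
})

test_that("shooting from the final frame yields a near-duplicate valid trial", {
  sys <- three_well_system()
  set.seed(14)
  cur <- initial_path(sys$potential, sys$states, sys$dynamics)
  shot <- shoot_one_way(cur, "forward", length(cur), sys$potential,
                        sys$states, sys$dynamics, max_length = 50 * length(cur))
  expect_null(shot$reason)
  expect_gte(shot$n_new_steps, 1L)
  expect_true(validate_path(shot$path, sys$states))
  # trial is trimmed at its first in-state frame: identical to current
  expect_identical(shot$path$frame_ids, cur$frame_ids)
  dec <- accept_trial(cur, shot$path)
  expect_true(dec$accepted)
})

test_that("acceptance rule: self-transitions always rejected, length ratio respected", {
  st <- three_well_states()
  cur <- line_path(st, 1, 2, n_interior = 11)           # 13 frames
  selftr <- line_path(st, 1, 2, n_interior = 11, ids = 100:112)
  selftr$transition <- c("A", "A")
  dec <- accept_trial(cur, selftr)
  expect_false(dec$accepted)
  expect_identical(dec$reason, "self_transition")
  expect_identical(accept_trial(cur, NULL)$reason, "max_length")
  # shorter or equal-length valid trial: always accepted
  short <- line_path(st, 1, 3, n_interior = 5, ids = 200:206)
  expect_true(all(replicate(50, accept_trial(cur, short)$accepted)))
  # trial twice as long: accepted about half the time
  long <- line_path(st, 1, 3, n_interior = 24, ids = 300:325)  # 26 frames
  set.seed(77)
  acc <- mean(replicate(4000, accept_trial(cur, long)$accepted))
  expect_lt(abs(acc - 0.5), 3 * sqrt(0.25 / 4000))
})

test_that("weight conservation: path weights sum to n_trials + 1", {
  sys <- three_well_system()
  chain0 <- run_mstps(sys$potential, sys$states, sys$dynamics, n_trials = 0,
                      seed = 3)
  expect_length(chain0$paths, 1L)
  expect_identical(chain0$paths[[1]]$weight, 1L)
  chain <- get_demo_chain()
  w <- vapply(chain$paths, `[[`, integer(1), "weight")
  expect_identical(sum(w), chain$n_trials + 1L)
})

test_that("every accepted path satisfies the ensemble invariants", {
  chain <- get_demo_chain()
  for (p in chain$paths) expect_true(validate_path(p, chain$states))
  # one Monte Carlo record per trial, reasons from the closed enumeration
  expect_identical(nrow(chain$records), chain$n_trials)
  expect_true(all(chain$records$reason %in%
                  c("accepted", "self_transition", "max_length", "metropolis")))
  expect_identical(chain$records$accepted, chain$records$reason == "accepted")
})

test_that("all six ordered transitions appear in a symmetric run", {
  chain <- get_demo_chain()
  labs <- unique(vapply(chain$paths, transition_label, character(1)))
  expect_setequal(labs, all_transition_labels(chain$states))
})

test_that("sampling runs are reproducible under a fixed seed", {
  sys <- three_well_system()
  c1 <- run_mstps(sys$potential, sys$states, sys$dynamics, n_trials = 100,
                  seed = 8)
  c2 <- run_mstps(sys$potential, sys$states, sys$dynamics, n_trials = 100,
                  seed = 8)
  expect_identical(c1$records, c2$records)
  expect_identical(lapply(c1$paths, `[[`, "coords"),
                   lapply(c2$paths, `[[`, "coords"))
})

test_that("decorrelated counting follows the greedy no-shared-frames rule", {
  st <- three_well_states()
  p0 <- line_path(st, 1, 2, ids = 1:13)
  # paths all sharing at least one frame with the initial -> count 1
  p1 <- line_path(st, 1, 3, ids = c(1, 20:31))
  p2 <- line_path(st, 1, 2, ids = c(13, 40:51))
  expect_identical(count_decorrelated(list(p0, p1, p2)), 1L)
  # forward shot replaces the tail, then a backward shot replaces the
  # remaining original head: second accepted path shares nothing with p0
  fwd <- line_path(st, 1, 3, ids = c(1:6, 60:66))    # keeps head 1..6
  bwd <- line_path(st, 2, 3, ids = c(70:75, 60:66))  # replaces that head
  expect_identical(count_decorrelated(list(p0, fwd, bwd)), 2L)
  expect_identical(decorrelated_indices(list(p0, fwd, bwd)), c(1L, 3L))
  # all trials rejected -> only the initial path
  expect_identical(count_decorrelated(list(p0)), 1L)
})

test_that("summary reports the Monte Carlo statistics with correct arithmetic", {
  # hand-built chain: 100 trials, 38 accepted, one 50-frame path, dt 0.01
  st <- three_well_states()
  p <- line_path(st, 1, 2, n_interior = 48)  # 50 frames
  p$weight <- 101L
  records <- data.frame(
    trial = 1:100, direction = "forward", shoot_frame_id = 1L,
    accepted = rep(c(TRUE, FALSE), c(38, 62)),
    reason = rep(c("accepted", "metropolis"), c(38, 62)),
    label = "A->B", n_new_steps = 60L, stringsAsFactors = FALSE)
  chain <- structure(list(paths = list(p), records = records,
                          n_trials = 100L, states = st,
                          potential = symmetric_three_well(),
                          dynamics = dynamics_params(0.01, 1),
                          max_length = 2500L,
                          equilibration = list(performed = FALSE)),
                     class = "mstps")
  s <- summary(chain)
  expect_equal(s$acceptance, 0.38)
  expect_equal(s$avg_path_length, 0.49)          # 49 steps x dt 0.01
  expect_equal(s$total_dynamics_time, 100 * 60 * 0.01)
  expect_gte(s$total_dynamics_time, s$avg_path_length * s$accepted_steps)
})

test_that("sampler path lengths match a brute-force first-passage ensemble", {
  # Exact construction of the two-state flexible-length ensemble: iid
  # Boltzmann-distributed points inside state A (rejection sampling),
  # conditioned to leave A in one step, continued to first passage into any
  # state; A -> B connectors under the same length cap as the sampler.
  sys <- two_well_system()
  pot <- sys$potential; st <- sys$states; dyn <- sys$dynamics
  cap <- 10000L
  set.seed(61)
  sample_in_A <- function(n) {
    out <- matrix(NA_real_, 0, 2)
    while (nrow(out) < n) {
      m <- 4 * (n - nrow(out))
      th <- runif(m, 0, 2 * pi); r <- 0.3 * sqrt(runif(m))
      pts <- cbind(-1 + r * cos(th), r * sin(th))
      V <- potential_energy(pot, pts)
      keep <- runif(m) < exp(-(V - (-4)))  # V_min = -4 at the well center
      out <- rbind(out, pts[keep, , drop = FALSE])
    }
    out[seq_len(n), , drop = FALSE]
  }
  x0 <- sample_in_A(200000)
  x1 <- x0 + potential_force(pot, x0) * dyn$timestep +
    sqrt(2 * dyn$diffusion * dyn$timestep) *
    matrix(rnorm(2 * nrow(x0)), ncol = 2)
  lab1 <- assign_state(x1, st)
  brute <- rep(2L, sum(!is.na(lab1) & lab1 == "B"))
  dummy <- tps_path(rbind(c(0, 0), c(0, 0.1)), 1:2, c("A", "B"))
  for (i in which(is.na(lab1))) {
    dummy$coords[1, ] <- x1[i, ]
    seg <- shoot_one_way(dummy, "forward", 1L, pot, st, dyn, cap - 1L)
    if (!is.null(seg$path) && seg$path$transition[2] == "B")
      brute <- c(brute, 1L + length(seg$path))
  }
  expect_gt(length(brute), 100)

  set.seed(62)
  ip <- initial_path(pot, st, dyn)
  chain <- run_mstps(pot, st, dyn, n_trials = 8000, seed = 63, initial = ip,
                     max_length_factor = cap / length(ip), equilibrate = TRUE)
  # systematic weighted sample spaced beyond the decorrelation time, so the
  # KS comparison uses effectively independent draws
  lens_by_trial <- rep(vapply(chain$paths, length, integer(1)),
                       vapply(chain$paths, `[[`, integer(1), "weight"))
  spacing <- max(1L, 2L * ceiling((chain$n_trials + 1) / count_decorrelated(chain)))
  samp <- lens_by_trial[seq(spacing, length(lens_by_trial), by = spacing)]
  p <- suppressWarnings(ks.test(jitter(samp, amount = 0.4),
                                jitter(brute, amount = 0.4))$p.value)
  expect_gt(p, 0.01)
})
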