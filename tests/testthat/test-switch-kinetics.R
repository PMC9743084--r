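test_that("switch detection reads label changes directly", {
  ev <- detect_switches(c("AB", "AB", "AC", "CB"))
  expect_identical(ev$trial_index, c(2L, 3L))
  expect_identical(ev$from, c("AB", "AC"))
  expect_identical(ev$to, c("AC", "CB"))
  expect_identical(nrow(detect_switches(rep("AB", 10))), 0L)
  expect_identical(nrow(detect_switches(c("AB", "AC", "AB", "AC"))), 3L)
  expect_error(detect_switches(character()), "empty")
  expect_error(detect_switches(c("AB", NA)), "unknown")
})

test_that("tally satisfies the count identities on any sequence", {
  counts <- tally_switches(c("AB", "AB", "AC", "CB"))
  expect_identical(counts$t[["AB"]], 2L)
  expect_identical(counts$t[["AC"]], 1L)
  expect_identical(counts$t[["CB"]], 1L)
  expect_identical(counts$n["AB", "AC"], 1L)
  expect_identical(counts$n["AC", "CB"], 1L)
  expect_identical(sum(counts$n), 2L)
  # identities hold for arbitrary random sequences
  set.seed(2)
  for (i in 1:5) {
    labs <- sample(c("x", "y", "z"), 300, replace = TRUE)
    ct <- tally_switches(labs)
    expect_identical(sum(ct$t), 300L)
    expect_identical(sum(ct$n), nrow(detect_switches(labs)))
    expect_true(all(diag(ct$n) == 0))
  }
})

test_that("population solver: symmetry forces uniformity, sum is exactly one", {
  labs <- all_transition_labels(c("A", "B", "C"))
  n <- matrix(5L, 6, 6, dimnames = list(labs, labs)); diag(n) <- 0L
  counts <- switch_counts(n, stats::setNames(rep(100, 6), labs))
  P <- solve_populations(counts)
  expect_equal(as.numeric(P), rep(1 / 6, 6), tolerance = 1e-12)
  # sum-to-one at solver precision for arbitrary valid count data
  q <- kinetics_oracle_q()
  for (seed in 1:5) {
    spec <- switch_chain_spec(rownames(q), q, 5000, seed = seed)
    P <- solve_populations(tally_switches(generate_switch_chain(spec),
                                          rownames(q)))
    expect_lt(abs(sum(P) - 1), 1e-12)
    expect_true(all(P >= 0))
  }
})

test_that("population solver error and degenerate-input contracts", {
  labs <- c("AB", "BA")
  z <- matrix(0L, 2, 2, dimnames = list(labs, labs))
  expect_error(solve_populations(switch_counts(z, c(10, 0))),
               "no switching")
  # two disconnected switch components -> per-component solve with warning
  labs4 <- c("a", "b", "c", "d")
  n <- matrix(0L, 4, 4, dimnames = list(labs4, labs4))
  n["a", "b"] <- n["b", "a"] <- 10L
  n["c", "d"] <- n["d", "c"] <- 10L
  counts <- switch_counts(n, stats::setNames(c(100, 100, 300, 100), labs4))
  expect_warning(P <- solve_populations(counts), "disconnected")
  expect_equal(sum(P), 1, tolerance = 1e-12)
  expect_identical(max(attr(P, "components")), 2L)
  # unvisited transition flagged, not dropped silently
  labs3 <- c("u", "v", "w")
  n3 <- matrix(0L, 3, 3, dimnames = list(labs3, labs3))
  n3["u", "v"] <- n3["v", "u"] <- 4L
  P3 <- solve_populations(switch_counts(n3, c(10, 10, 0)))
  expect_identical(attr(P3, "unvisited"), "w")
  expect_identical(P3[["w"]], 0)
})

test_that("populations recover the stationary vector of the generating chain", {
  q <- kinetics_oracle_q()
  pi0 <- stationary_distribution(q)
  spec <- switch_chain_spec(rownames(q), q, 100000, seed = 11)
  ch <- generate_switch_chain(spec)
  counts <- tally_switches(ch, rownames(q))
  P <- solve_populations(counts)
  expect_lt(tv_dist(as.numeric(P), as.numeric(pi0)), 0.02)
  # ... and agrees with the empirical residence fractions
  expect_lt(tv_dist(as.numeric(P), as.numeric(counts$t / sum(counts$t))), 0.02)
})

test_that("switching rates recover the generating per-trial probabilities", {
  q <- kinetics_oracle_q()
  spec <- switch_chain_spec(rownames(q), q, 100000, seed = 19)
  counts <- tally_switches(generate_switch_chain(spec), rownames(q))
  P <- solve_populations(counts)
  k <- switching_rates(P, counts)
  se <- sqrt(q * (1 - q) / pmax(1, as.numeric(counts$t)))
  off <- row(q) != col(q)
  expect_true(all(abs(k$per_step[off] - q[off]) <=
                    z_crit(30) * se[off] + 1e-12))
  # units round-trip exactly
  expect_identical(k$per_100_steps, 100 * k$per_step)
})

test_that("rates for a symmetric chain agree across all directions", {
  labs <- all_transition_labels(c("A", "B", "C"))
  q <- matrix(0.02, 6, 6, dimnames = list(labs, labs)); diag(q) <- 0
  spec <- switch_chain_spec(labs, q, 50000, seed = 23)
  counts <- tally_switches(generate_switch_chain(spec), labs)
  k <- switching_rates(solve_populations(counts), counts)
  off <- row(q) != col(q)
  se <- sqrt(0.02 * 0.98 / min(counts$t))
  expect_true(all(abs(k$per_step[off] - 0.02) <= z_crit(30) * se))
})

test_that("never-visited sources give flagged NA rates, inconsistency errors", {
  labs <- c("u", "v", "w")
  n3 <- matrix(0L, 3, 3, dimnames = list(labs, labs))
  n3["u", "v"] <- n3["v", "u"] <- 4L
  counts <- switch_counts(n3, c(10, 10, 0))
  P <- solve_populations(counts)
  k <- switching_rates(P, counts)
  expect_identical(k$undefined_sources, "w")
  expect_true(all(is.na(k$per_step["w", ])))
  # switches out of a transition with zero residence time are inconsistent
  bad <- matrix(0L, 3, 3, dimnames = list(labs, labs))
  bad["w", "u"] <- 2L
  expect_error(switch_counts(bad, c(10, 10, 0)), "inconsistent")
})

test_that("reversing a transition needs exactly three switches (all n >= 3)", {
  expect_identical(min_switches_between("A->B", "B->A", 3), 3L)
  expect_identical(min_switches_between("A->B", "A->B", 3), 0L)
  expect_identical(min_switches_between("A->B", "A->C", 3), 1L)
  expect_identical(min_switches_between("A->B", "B->A", 2), Inf)
  for (n in 3:6)
    expect_identical(min_switches_between("A->B", "B->A", n), 3L)
  # independent exhaustive check: no move sequence of length <= 2 reaches
  # the reversed transition
  states <- LETTERS[1:4]
  moves <- function(p) {
    out <- list()
    for (s in states) {
      if (s != p[1] && s != p[2]) out <- c(out, list(c(p[1], s)), list(c(s, p[2])))
    }
    out
  }
  lvl1 <- moves(c("A", "B"))
  lvl2 <- unlist(lapply(lvl1, moves), recursive = FALSE)
  reach2 <- unique(vapply(c(lvl1, lvl2), paste, character(1), collapse = ">"))
  expect_false("B>A" %in% reach2)
  lvl3 <- unlist(lapply(lvl2, moves), recursive = FALSE)
  expect_true("B>A" %in% vapply(lvl3, paste, character(1), collapse = ">"))
})

test_that("population estimate converges with chain length (median TV decreasing)", {
  q <- kinetics_oracle_q()
  pi0 <- as.numeric(stationary_distribution(q))
  tv <- sapply(1:20, function(seed) {
    vapply(c(1000, 10000, 100000), function(n) {
      spec <- switch_chain_spec(rownames(q), q, n, seed = seed * 1000 + n %% 997)
      ch <- generate_switch_chain(spec)
      P <- try(solve_populations(tally_switches(ch, rownames(q))), silent = TRUE)
      if (inherits(P, "try-error")) return(NA_real_)
      tv_dist(as.numeric(P), pi0)
    }, numeric(1))
  })
  med <- apply(tv, 1, median, na.rm = TRUE)
  expect_true(all(diff(med) < 0))
})

test_that("convergence report flags asymmetry, unvisited labels, decorrelation", {
  # symmetric fast-mixing chain (uniform rows -> iid labels): nothing flagged
  labs <- all_transition_labels(c("A", "B", "C"))
  q <- matrix(1 / 6, 6, 6, dimnames = list(labs, labs)); diag(q) <- 0
  ch <- generate_switch_chain(switch_chain_spec(labs, q, 50000, seed = 37))
  rep1 <- convergence_report(ch, tally_switches(ch, labs))
  expect_length(rep1$unvisited, 0)
  expect_false(any(rep1$symmetry$flagged))
  # chain confined to one label: everything else unvisited
  const <- rep("A->B", 50)
  rep2 <- convergence_report(const, tally_switches(const, labs))
  expect_setequal(rep2$unvisited, setdiff(labs, "A->B"))
  # gross forward/backward asymmetry raises the z flag
  fix <- c(rep("A->B", 900), rep("B->A", 100))
  rep3 <- convergence_report(fix, tally_switches(fix, labs))
  row <- rep3$symmetry[rep3$symmetry$pair == "A->B / B->A", ]
  expect_true(row$flagged)
  expect_gt(abs(row$z), 20)
  # with a sampled chain: per-transition decorrelated counts and KS columns
  chain <- get_demo_chain()
  rep4 <- convergence_report(chain)
  expect_identical(rep4$decorrelated$total, count_decorrelated(chain))
  expect_true(all(rep4$decorrelated$per_transition >= 0))
  expect_true(is.data.frame(rep4$path_length_ks))
})

test_that("absorbing chains are excluded when pooling counts", {
  labs <- c("AB", "BA", "AC")
  n1 <- matrix(0L, 3, 3, dimnames = list(labs, labs))
  n1["AB", "BA"] <- n1["BA", "AB"] <- 5L
  n1["AB", "AC"] <- n1["AC", "AB"] <- 3L
  good <- switch_counts(n1, c(50, 30, 20))
  # absorbing: AC visited but never switches out
  n2 <- matrix(0L, 3, 3, dimnames = list(labs, labs))
  n2["AB", "AC"] <- 2L
  absorbing <- switch_counts(n2, c(10, 0, 90))
  expect_warning(pooled <- pool_switch_counts(list(good, absorbing)),
                 "absorbing")
  expect_identical(attr(pooled, "excluded"), 2L)
  expect_identical(pooled$n, good$n)
  # pooling two healthy chains sums counts and residence
  expect_warning(p2 <- pool_switch_counts(list(good, good)), NA)
  expect_identical(p2$n, good$n + good$n)
  expect_identical(as.numeric(p2$t), as.numeric(good$t * 2))
})

test_that("switch_kinetics fit object has the modelling-idiom surface", {
  q <- kinetics_oracle_q()
  ch <- generate_switch_chain(switch_chain_spec(rownames(q), q, 20000,
                                                seed = 41))
  fit <- switch_kinetics(ch)
  expect_s3_class(fit, "switch_kinetics")
  expect_equal(sum(coef(fit)), 1, tolerance = 1e-12)
  expect_output(print(fit), "transition populations")
  sims <- simulate(fit, nsim = 2, seed = 1, n_trials = 500)
  expect_length(sims, 2)
  expect_length(sims[[1]], 500)
  expect_true(all(sims[[1]] %in% rownames(q)))
  # both analysis modes run on a sampled chain
  chain <- get_demo_chain()
  fit_all <- switch_kinetics(chain)
  expect_equal(sum(coef(fit_all)), 1, tolerance = 1e-12)
  fit_dec <- switch_kinetics(chain, decorrelated_only = TRUE)
  expect_true(fit_dec$decorrelated_only)
  expect_lte(fit_dec$counts$n_trials, fit_all$counts$n_trials)
})
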