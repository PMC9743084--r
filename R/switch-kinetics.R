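#' Detect switches in a transition-label sequence
#'
#' A "switch" is a change in which transition (ordered state pair) is being
#' sampled: one event per position t where label(t + 1) differs from
#' label(t).
#'
#' @param labels character vector: the per-trial transition label sequence.
#' @return A data frame with columns \code{trial_index} (the position t
#'   before the change), \code{from} and \code{to}.
#' @examples
#' detect_switches(c("A->B", "A->B", "A->C", "C->B"))
#' @export
detect_switches <- function(labels) {
  labels <- as.character(labels)
  if (length(labels) == 0L) stop("empty label sequence")
  if (anyNA(labels)) stop("unknown (NA) label in sequence")
  n <- length(labels)
  if (n == 1L)
    return(data.frame(trial_index = integer(), from = character(),
                      to = character(), stringsAsFactors = FALSE))
  idx <- which(labels[-1L] != labels[-n])
  data.frame(trial_index = idx, from = labels[idx], to = labels[idx + 1L],
             stringsAsFactors = FALSE)
}

#' Tally switch counts and residence times
#'
#' Builds the count data of the switching-kinetics analysis: \code{n[i, j]}
#' is the number of switches from transition i to transition j and
#' \code{t[i]} the number of MC trials during which transition i was
#' current (rejected trials extend the residence of the current
#' transition).  Identities asserted on every tally: \code{sum(t)} equals
#' the sequence length, \code{sum(n)} equals the number of label changes and
#' the diagonal of \code{n} is zero.
#'
#' @param labels per-trial transition-label sequence (character), e.g. from
#'   \code{\link{trial_labels}}.
#' @param all_labels optional character vector of the full transition-label
#'   universe (e.g. \code{\link{all_transition_labels}}), so never-visited
#'   transitions appear as zero rows.
#' @return An object of class \code{"switch_counts"} with fields \code{n}
#'   (matrix), \code{t} (named vector) and \code{n_trials}.
#' @export
tally_switches <- function(labels, all_labels = NULL) {
  labels <- as.character(labels)
  if (length(labels) == 0L) stop("empty label sequence")
  labs <- if (is.null(all_labels)) sort(unique(labels)) else as.character(all_labels)
  if (!all(labels %in% labs)) stop("label sequence contains labels outside all_labels")
  m <- length(labs)
  ev <- detect_switches(labels)
  n <- unclass(table(factor(ev$from, levels = labs),
                     factor(ev$to, levels = labs)))
  dimnames(n) <- list(labs, labs)
  t <- stats::setNames(integer(m), labs)
  tab <- table(factor(labels, levels = labs))
  t[names(tab)] <- as.integer(tab)
  stopifnot(sum(t) == length(labels), sum(n) == nrow(ev), all(diag(n) == 0L))
  structure(list(n = n, t = t, n_trials = length(labels)),
            class = "switch_counts")
}

#' Construct switch-count data directly
#'
#' For count data coming from outside the toy sampler (or from hand-built
#' fixtures).
#'
#' @param n square integer matrix of switch counts (zero diagonal).
#' @param t named or unnamed residence-time vector (MC trials per
#'   transition), aligned with the rows of \code{n}.
#' @return A \code{"switch_counts"} object.
#' @export
switch_counts <- function(n, t) {
  n <- as.matrix(n)
  stopifnot(nrow(n) == ncol(n), length(t) == nrow(n), all(n >= 0), all(t >= 0))
  if (any(diag(n) != 0)) stop("diagonal switch counts must be zero")
  labs <- rownames(n)
  if (is.null(labs)) labs <- if (!is.null(names(t))) names(t) else
    paste0("T", seq_len(nrow(n)))
  dimnames(n) <- list(labs, labs)
  inconsistent <- t == 0 & rowSums(n) > 0
  if (any(inconsistent))
    stop("inconsistent counts: switches out of a transition with zero residence time")
  structure(list(n = n, t = stats::setNames(as.numeric(t), labs),
                 n_trials = sum(t)),
            class = "switch_counts")
}

#' @export
print.switch_counts <- function(x, ...) {
  cat(sprintf("Switch counts over %d transition labels, %d MC trials, %d switches\n",
              nrow(x$n), as.integer(x$n_trials), sum(x$n)))
  cat("residence t_i:\n"); print(x$t)
  cat("switch matrix n_ij:\n"); print(x$n)
  invisible(x)
}

#' Pool switch counts from independent chains
#'
#' Counts and residence times are summed before solving, the standard way of
#' combining independent simulations of the same system.  A chain in which
#' some visited transition has no switches out (an absorbing transition) is
#' excluded from the pool with a warning, since it cannot contribute to an
#' equilibrium estimate.
#'
#' @param counts_list list of \code{"switch_counts"} over the same label
#'   universe.
#' @param drop_absorbing exclude chains containing an absorbing visited
#'   transition (default TRUE).
#' @return A pooled \code{"switch_counts"} object; excluded chain indices
#'   are attached as attribute \code{"excluded"}.
#' @export
pool_switch_counts <- function(counts_list, drop_absorbing = TRUE) {
  stopifnot(length(counts_list) >= 1L)
  labs <- rownames(counts_list[[1L]]$n)
  excluded <- integer()
  if (drop_absorbing) {
    for (i in seq_along(counts_list)) {
      ci <- counts_list[[i]]
      if (any(ci$t > 0 & rowSums(ci$n) == 0)) excluded <- c(excluded, i)
    }
    if (length(excluded) > 0L)
      warning(sprintf("excluding %d chain(s) with an absorbing transition from the pool: %s",
                      length(excluded), paste(excluded, collapse = ", ")))
    counts_list <- counts_list[setdiff(seq_along(counts_list), excluded)]
    if (length(counts_list) == 0L) stop("all chains excluded as absorbing")
  }
  n <- Reduce(`+`, lapply(counts_list, function(c) {
    stopifnot(identical(rownames(c$n), labs)); c$n
  }))
  t <- Reduce(`+`, lapply(counts_list, `[[`, "t"))
  out <- switch_counts(n, t)
  attr(out, "excluded") <- excluded
  out
}

#' Solve for transition populations
#'
#' Equilibrium population \eqn{P_i} of each sampled transition, from the
#' switch counts \eqn{n_{ij}} and residence times \eqn{t_i}: assuming the
#' switching samples an equilibrium distribution, the populations satisfy the
#' stationarity (global balance) conditions
#' \deqn{\sum_{j \ne i} P_j \frac{n_{ji}}{t_j} = P_i \sum_{j \ne i} \frac{n_{ij}}{t_i},}
#' which together with the normalisation \eqn{\sum_i P_i = 1} determine all
#' \eqn{P_i}.  For a long equilibrium chain this recovers both the analytic
#' stationary vector of the generating switch-probability matrix and the
#' empirical residence fractions \eqn{t_i / \sum t}.
#'
#' If the switch graph over visited transitions is disconnected the system
#' is solved per connected component; component populations are weighted by
#' the component's share of the total residence time (with a warning), so
#' the overall normalisation still holds.  Never-visited transitions get
#' \eqn{P_i = 0} and are flagged.
#'
#' @param counts a \code{"switch_counts"} object.
#' @return Named numeric vector \code{P} summing to 1, with attributes
#'   \code{"unvisited"} (labels never sampled) and \code{"components"}
#'   (component membership of the visited labels).
#' @export
solve_populations <- function(counts) {
  stopifnot(inherits(counts, "switch_counts"))
  labs <- rownames(counts$n)
  visited <- counts$t > 0
  if (!any(visited) || sum(counts$n) == 0)
    stop("no switching observed")
  vlabs <- labs[visited]
  nv <- counts$n[visited, visited, drop = FALSE]
  tv <- counts$t[visited]

  comp <- graph_components(nv)
  if (max(comp) > 1L)
    warning("switch graph is disconnected; solving populations per component")

  P <- stats::setNames(numeric(length(labs)), labs)
  tvis <- sum(tv)
  for (c in seq_len(max(comp))) {
    sel <- comp == c
    m <- sum(sel)
    w <- sum(tv[sel]) / tvis
    if (m == 1L) { P[vlabs[sel]] <- w; next }
    K <- nv[sel, sel, drop = FALSE] / tv[sel]  # per-trial switch rates n_ij / t_i
    G <- K; diag(G) <- -rowSums(K)
    A <- rbind(t(G), rep(1, m))
    b <- c(rep(0, m), 1)
    p <- qr.solve(A, b)
    if (any(p < -1e-8))
      stop("population solve produced negative probabilities; counts inconsistent with equilibrium")
    p <- pmax(p, 0)
    P[vlabs[sel]] <- w * p / sum(p)
  }
  attr(P, "unvisited") <- labs[!visited]
  attr(P, "components") <- stats::setNames(comp, vlabs)
  P
}

# connected components of the undirected graph with edges where n_ij + n_ji > 0
graph_components <- function(n) {
  m <- nrow(n)
  adj <- (n + t(n)) > 0
  comp <- integer(m)
  cur <- 0L
  for (s in seq_len(m)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue) > 0L) {
      v <- queue[1L]; queue <- queue[-1L]
      nb <- which(adj[v, ] & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

#' Switching rates between transitions
#'
#' From the populations, the switching rate from transition i to j is
#' \deqn{k_{ij} = \frac{n_{ij}}{P_i N},}
#' the switch count divided by the effective residence time \eqn{P_i N}
#' implied by the equilibrium populations (N = total MC trials).  Rates are
#' reported both per MC step and per 100 MC steps (the conventional
#' reporting unit, exactly 100 times the per-step rate).  Rows for
#' transitions never observed as a source are \code{NA} and flagged, never
#' silently zero.
#'
#' @param P population vector from \code{\link{solve_populations}}.
#' @param counts the \code{"switch_counts"} the populations were solved
#'   from.
#' @return A list with matrices \code{per_step} and \code{per_100_steps}
#'   and the character vector \code{undefined_sources}.
#' @export
switching_rates <- function(P, counts) {
  stopifnot(inherits(counts, "switch_counts"))
  labs <- rownames(counts$n)
  stopifnot(identical(names(P), labs))
  bad <- counts$t == 0 & rowSums(counts$n) > 0
  if (any(bad))
    stop("inconsistent counts: switches out of a transition with zero residence time")
  N <- counts$n_trials
  k <- matrix(NA_real_, length(labs), length(labs), dimnames = dimnames(counts$n))
  src <- P > 0
  k[src, ] <- counts$n[src, , drop = FALSE] / (P[src] * N)
  diag(k) <- NA_real_
  list(per_step = k, per_100_steps = 100 * k,
       undefined_sources = labs[!src])
}

#' Fit the switching-kinetics model to a label sequence
#'
#' The one-call analysis of an MSTPS switching record: tallies switch counts
#' and residence times, solves the global-balance system for the transition
#' populations under the normalisation constraint, computes switching rates
#' per (100) MC steps, and attaches convergence diagnostics.  Operates on
#' the per-trial transition-label sequence, either from
#' \code{\link{trial_labels}} on a sampled chain (optionally restricted to
#' decorrelated paths) or from any external label CSV.
#'
#' @param labels per-trial transition-label sequence, or an \code{"mstps"}
#'   chain.
#' @param all_labels optional full transition-label universe (derived from
#'   the chain's states when a chain is given).
#' @param decorrelated_only when \code{labels} is a chain: restrict the
#'   sequence to trials whose current path is one of the decorrelated paths
#'   (both analysis modes are conventional; the default uses all accepted
#'   paths).
#' @return An object of class \code{"switch_kinetics"} with components
#'   \code{counts}, \code{P}, \code{rates} (\code{per_step},
#'   \code{per_100_steps}), \code{unvisited} and \code{convergence}.
#'   Methods: \code{print}, \code{summary}, \code{coef} (returns P),
#'   \code{simulate} (new label chains from the fitted per-step switch
#'   probabilities) and \code{plot}.
#' @examples
#' q <- matrix(0.05, 3, 3); diag(q) <- 0
#' sp <- switch_chain_spec(c("A->B", "B->C", "C->A"), q, 2000, seed = 7)
#' fit <- switch_kinetics(generate_switch_chain(sp))
#' coef(fit)
#' @export
switch_kinetics <- function(labels, all_labels = NULL,
                            decorrelated_only = FALSE) {
  chain <- NULL
  if (inherits(labels, "mstps")) {
    chain <- labels
    if (is.null(all_labels)) all_labels <- all_transition_labels(chain$states)
    labels <- trial_labels(chain)
    if (decorrelated_only) {
      keep_paths <- decorrelated_indices(chain)
      path_of_trial <- findInterval(seq_along(labels),
                                    vapply(chain$paths, `[[`, integer(1),
                                           "accepted_at_trial"))
      labels <- labels[path_of_trial %in% keep_paths]
      if (length(labels) == 0L) stop("no trials left after decorrelated-only filter")
    }
  }
  counts <- tally_switches(labels, all_labels)
  P <- solve_populations(counts)
  rates <- switching_rates(P, counts)
  conv <- convergence_report(labels, counts, chain)
  structure(list(counts = counts, P = P, rates = rates,
                 unvisited = attr(P, "unvisited"),
                 components = attr(P, "components"),
                 decorrelated_only = decorrelated_only,
                 convergence = conv, call = match.call()),
            class = "switch_kinetics")
}

#' @export
print.switch_kinetics <- function(x, ...) {
  cat("Switching-kinetics fit\n")
  cat(sprintf("  %d MC trials, %d switches over %d transition labels%s\n",
              as.integer(x$counts$n_trials), sum(x$counts$n),
              nrow(x$counts$n),
              if (x$decorrelated_only) " (decorrelated paths only)" else ""))
  cat("  transition populations P_i (%):\n")
  print(round(stats::setNames(100 * as.numeric(x$P), names(x$P)), 2))
  if (length(x$unvisited) > 0)
    cat("  never visited:", paste(x$unvisited, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.switch_kinetics <- function(object, ...) {
  cat("Switching-kinetics fit\n\n")
  cat("Populations P_i (sum = 1):\n")
  print(object$P)
  cat("\nSwitching rates per 100 MC steps (rows = from, cols = to):\n")
  print(round(object$rates$per_100_steps, 3))
  if (length(object$rates$undefined_sources) > 0)
    cat("\nUndefined source rows (never visited):",
        paste(object$rates$undefined_sources, collapse = ", "), "\n")
  cat("\n")
  print(object$convergence)
  invisible(object)
}

#' @export
coef.switch_kinetics <- function(object, ...) object$P

#' Simulate label chains from a fitted switching model
#'
#' Draws new Markov switch chains using the fitted per-step switch
#' probabilities \code{n_ij / t_i} (restricted to visited transitions),
#' starting from a label drawn from the fitted populations.
#'
#' @param object a \code{"switch_kinetics"} fit.
#' @param nsim number of chains.
#' @param seed optional seed.
#' @param n_trials length of each simulated chain (default: the fitted
#'   chain's length).
#' @param ... unused.
#' @return A list of character label vectors.
#' @export
simulate.switch_kinetics <- function(object, nsim = 1, seed = NULL,
                                     n_trials = object$counts$n_trials, ...) {
  if (!is.null(seed)) set.seed(seed)
  visited <- object$counts$t > 0
  labs <- rownames(object$counts$n)[visited]
  q <- object$counts$n[visited, visited, drop = FALSE] /
    object$counts$t[visited]
  spec <- switch_chain_spec(labs, q, n_trials)
  Pv <- object$P[visited] / sum(object$P[visited])
  lapply(seq_len(nsim), function(i)
    generate_switch_chain(spec, start = sample(labs, 1, prob = Pv)))
}

#' Plot a switching-kinetics fit
#'
#' Image of the switching-rate matrix (per 100 MC steps) with populations
#' printed on the diagonal.
#'
#' @param x a \code{"switch_kinetics"} fit.
#' @param ... passed to \code{\link[graphics]{image}}.
#' @export
plot.switch_kinetics <- function(x, ...) {
  k <- x$rates$per_100_steps
  m <- nrow(k)
  z <- t(k)[, m:1]
  graphics::image(seq_len(m), seq_len(m), z,
                  col = grDevices::hcl.colors(30, "YlOrRd", rev = TRUE),
                  axes = FALSE, xlab = "to", ylab = "from", ...)
  graphics::axis(1, seq_len(m), colnames(k), las = 2, cex.axis = 0.7)
  graphics::axis(2, seq_len(m), rev(rownames(k)), las = 2, cex.axis = 0.7)
  for (i in seq_len(m))
    graphics::text(i, m - i + 1, sprintf("P=%.2f", x$P[i]), cex = 0.6)
  invisible(x)
}

#' Minimum number of switches between two transitions
#'
#' Breadth-first search over the one-way-shooting move graph: one switch
#' changes exactly one endpoint of the sampled transition (a forward shot
#' changes the final state, a backward shot the initial state), endpoints
#' must remain distinct, and every move must actually change the label.
#' Reversing a transition (A->B to B->A) therefore takes at least three
#' switches in any system with three or more states, and is unreachable
#' with only two states.
#'
#' @param transition_a,transition_b transition labels (\code{"X->Y"}) or
#'   length-2 character vectors.
#' @param n_states number of states (>= 2); states beyond those named in
#'   the two transitions are available as intermediates.
#' @return Integer switch count (0 for identical labels), or \code{Inf}
#'   when unreachable.
#' @examples
#' min_switches_between("A->B", "B->A", 3)  # 3
#' @export
min_switches_between <- function(transition_a, transition_b, n_states) {
  stopifnot(n_states >= 2)
  pa <- parse_transition(transition_a)
  pb <- parse_transition(transition_b)
  sts <- unique(c(pa, pb))
  if (length(sts) > n_states)
    stop("transitions name more states than n_states")
  if (length(sts) < n_states)
    sts <- c(sts, paste0(".s", seq_len(n_states - length(sts))))
  key <- function(p) paste0(p[1], "|", p[2])
  target <- key(pb)
  dist <- stats::setNames(0L, key(pa))
  frontier <- list(pa)
  if (key(pa) == target) return(0L)
  d <- 0L
  while (length(frontier) > 0L) {
    d <- d + 1L
    nxt <- list()
    for (p in frontier) {
      for (s in sts) {
        for (cand in list(c(p[1], s), c(s, p[2]))) {
          if (cand[1] == cand[2]) next          # endpoints must differ
          if (identical(cand, p)) next          # must change the label
          k <- key(cand)
          if (k %in% names(dist)) next
          dist[k] <- d
          if (k == target) return(d)
          nxt[[length(nxt) + 1L]] <- cand
        }
      }
    }
    frontier <- nxt
  }
  Inf
}

parse_transition <- function(x) {
  if (length(x) == 2L) return(as.character(x))
  p <- split_label(as.character(x))[[1L]]
  if (length(p) != 2L || p[1] == p[2]) stop("invalid transition label: ", x)
  p
}
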