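#' Specification of a Markov switch chain
#'
#' Defines a discrete-time Markov chain over transition labels, used as a
#' synthetic stand-in (with known ground truth) for the sequence of sampled
#' transitions in an MSTPS run.  \code{switch_probabilities[i, j]} is the
#' probability that one Monte Carlo trial switches the sampled transition
#' from label \code{i} to label \code{j}; each off-diagonal row sum must be
#' at most 1, and the diagonal is the implied probability of staying.
#'
#' @param labels character vector of transition labels.
#' @param switch_probabilities square numeric matrix q with \code{q[i, j]} in
#'   [0, 1] and off-diagonal row sums <= 1.  The diagonal is ignored and
#'   recomputed as 1 - sum of the off-diagonal row.
#' @param n_trials chain length (number of MC trials).
#' @param seed optional integer seed.
#' @return An object of class \code{"switch_chain_spec"}.
#' @export
switch_chain_spec <- function(labels, switch_probabilities, n_trials,
                              seed = NULL) {
  labels <- as.character(labels)
  q <- as.matrix(switch_probabilities)
  m <- length(labels)
  if (anyDuplicated(labels)) stop("labels must be unique")
  if (nrow(q) != m || ncol(q) != m)
    stop("switch_probabilities must be a square matrix matching labels")
  if (any(q < 0) || any(q > 1))
    stop("switch probabilities must lie in [0, 1]")
  diag(q) <- 0
  off <- rowSums(q)
  if (any(off > 1 + 1e-12))
    stop("off-diagonal row sums of switch_probabilities must be <= 1")
  diag(q) <- pmax(0, 1 - off)
  dimnames(q) <- list(labels, labels)
  stopifnot(n_trials >= 1)
  structure(list(labels = labels, q = q, n_trials = as.integer(n_trials),
                 seed = if (!is.null(seed)) as.integer(seed)),
            class = "switch_chain_spec")
}

#' Generate a synthetic switch-label chain
#'
#' Simulates the Markov chain defined by a \code{\link{switch_chain_spec}}:
#' the label at trial t + 1 is drawn from the row of the transition matrix
#' given the label at trial t.
#'
#' @param spec a \code{\link{switch_chain_spec}}.
#' @param start starting label (default: first label).
#' @return Character vector of length \code{spec$n_trials}, with the
#'   generating probability matrix attached as attribute \code{"q"}.
#' @examples
#' q <- matrix(0.1, 2, 2); diag(q) <- 0
#' sp <- switch_chain_spec(c("AB", "BA"), q, 100, seed = 1)
#' table(generate_switch_chain(sp))
#' @export
generate_switch_chain <- function(spec, start = spec$labels[1]) {
  stopifnot(inherits(spec, "switch_chain_spec"))
  s0 <- match(start, spec$labels)
  if (is.na(s0)) stop("unknown starting label")
  if (!is.null(spec$seed)) set.seed(spec$seed)
  idx <- cpp_markov_chain(spec$q, s0, spec$n_trials)
  structure(spec$labels[idx], q = spec$q)
}

#' Analytic stationary distribution of a switch-chain spec
#'
#' Left Perron eigenvector of the full (diagonal-included) transition matrix,
#' normalised to sum 1.  Ground truth for the kinetics solver.
#'
#' @param spec a \code{\link{switch_chain_spec}} (or a full row-stochastic
#'   matrix).
#' @return Named numeric vector of stationary probabilities.
#' @export
stationary_distribution <- function(spec) {
  q <- if (inherits(spec, "switch_chain_spec")) spec$q else as.matrix(spec)
  # accept a bare switch-probability matrix: complete the diagonal so rows
  # are stochastic (the convention of switch_chain_spec)
  diag(q) <- 0
  diag(q) <- pmax(0, 1 - rowSums(q))
  e <- eigen(t(q))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  v <- v / sum(v)
  if (any(v < -1e-9)) stop("chain has no nonnegative stationary vector")
  stats::setNames(pmax(v, 0) / sum(pmax(v, 0)), rownames(q))
}
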