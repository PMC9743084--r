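#' Convergence diagnostics for a switching record
#'
#' Heuristics for whether an MSTPS run has sampled the transition network
#' adequately: (a) ergodicity — which transitions were never visited;
#' (b) forward/backward symmetry — at equilibrium the fraction of MC trials
#' spent in a transition and in its time-reversed partner should match, so
#' for every state pair a two-proportion z statistic on the residence counts
#' is reported (|z| > 3 flags asymmetry); (c) when a sampled chain is
#' available, a two-sample Kolmogorov-Smirnov comparison of the
#' accepted-path length distributions of each transition and its reverse;
#' (d) the decorrelated-path count, overall and per transition.
#'
#' @param labels per-trial transition-label sequence.
#' @param counts optional \code{"switch_counts"}; tallied from
#'   \code{labels} when omitted.
#' @param chain optional \code{"mstps"} chain providing path data for (c)
#'   and (d).
#' @return An object of class \code{"mstps_convergence"}.
#' @export
convergence_report <- function(labels, counts = NULL, chain = NULL) {
  if (inherits(labels, "mstps") && is.null(chain)) {
    chain <- labels
    labels <- trial_labels(chain)
  }
  if (is.null(counts)) {
    universe <- if (!is.null(chain)) all_transition_labels(chain$states) else NULL
    counts <- tally_switches(labels, universe)
  }
  labs <- rownames(counts$n)
  unvisited <- labs[counts$t == 0]

  pairs <- transition_pairs(labs)
  sym <- NULL
  if (nrow(pairs) > 0L) {
    tf <- counts$t[pairs$fwd]
    tr <- counts$t[pairs$rev]
    z <- ifelse(tf + tr > 0, (tf - tr) / sqrt(tf + tr), 0)
    sym <- data.frame(pair = paste(pairs$fwd, "/", pairs$rev),
                      t_fwd = as.numeric(tf), t_rev = as.numeric(tr),
                      frac_fwd = ifelse(tf + tr > 0, tf / (tf + tr), NA),
                      z = as.numeric(z),
                      flagged = abs(z) > 3,
                      row.names = NULL, stringsAsFactors = FALSE)
  }

  ks <- NULL
  dec <- NULL
  if (!is.null(chain)) {
    plabs <- vapply(chain$paths, transition_label, character(1))
    plens <- vapply(chain$paths, length, integer(1))
    if (nrow(pairs) > 0L) {
      ks <- pairs
      ks$n_fwd <- ks$n_rev <- 0L
      ks$ks_p <- NA_real_
      for (r in seq_len(nrow(pairs))) {
        lf <- plens[plabs == pairs$fwd[r]]
        lr <- plens[plabs == pairs$rev[r]]
        ks$n_fwd[r] <- length(lf)
        ks$n_rev[r] <- length(lr)
        if (length(lf) >= 5 && length(lr) >= 5)
          ks$ks_p[r] <- suppressWarnings(
            stats::ks.test(lf, lr, exact = FALSE)$p.value)
      }
    }
    di <- decorrelated_indices(chain)
    per <- vapply(labs, function(l) {
      sub <- chain$paths[plabs == l]
      length(decorrelated_indices(sub))
    }, integer(1))
    dec <- list(total = length(di), per_transition = per)
  }

  structure(list(unvisited = unvisited, symmetry = sym,
                 path_length_ks = ks, decorrelated = dec,
                 n_trials = counts$n_trials),
            class = "mstps_convergence")
}

transition_pairs <- function(labs) {
  parts <- do.call(rbind, split_label(labs))
  fwd <- labs[parts[, 1] < parts[, 2]]
  rev <- vapply(split_label(fwd), function(p) paste0(p[2], "->", p[1]),
                character(1))
  keep <- rev %in% labs
  data.frame(fwd = fwd[keep], rev = rev[keep], stringsAsFactors = FALSE)
}

#' @export
print.mstps_convergence <- function(x, ...) {
  cat("Convergence diagnostics\n")
  if (length(x$unvisited) == 0)
    cat("  ergodicity: all transitions visited\n")
  else
    cat("  ergodicity: UNVISITED transitions:",
        paste(x$unvisited, collapse = ", "), "\n")
  if (!is.null(x$symmetry)) {
    cat("  forward/backward residence symmetry (|z| > 3 flagged):\n")
    print(x$symmetry, digits = 3)
  }
  if (!is.null(x$path_length_ks)) {
    cat("  path-length distribution comparison (two-sample KS):\n")
    print(x$path_length_ks, digits = 3)
  }
  if (!is.null(x$decorrelated)) {
    cat(sprintf("  decorrelated paths: %d total\n", x$decorrelated$total))
    print(x$decorrelated$per_transition)
  }
  invisible(x)
}

#' Forward/backward accepted-path count symmetry with batch-corrected z
#'
#' At equilibrium a transition and its time-reversed partner are sampled
#' equally often, so the accepted-path counts per state pair should agree
#' within sampling error.  Consecutive accepted paths are strongly
#' autocorrelated, so the standard error of the count difference is
#' estimated by batch means over the chronological accepted-path sequence
#' rather than by the naive binomial formula.
#'
#' @param chain an \code{"mstps"} object.
#' @param n_batches number of contiguous batches for the variance estimate.
#' @return Data frame with one row per state pair: forward and reverse
#'   counts, the batch-means z statistic and an \code{abs(z) > 3} flag.
#' @export
path_count_symmetry <- function(chain, n_batches = 25) {
  stopifnot(inherits(chain, "mstps"))
  labs <- vapply(chain$paths, transition_label, character(1))
  pairs <- transition_pairs(sort(unique(labs)))
  M <- length(labs)
  batch <- pmin(ceiling(seq_len(M) / (M / n_batches)), n_batches)
  out <- pairs
  out$n_fwd <- out$n_rev <- 0L
  out$z <- NA_real_
  for (r in seq_len(nrow(pairs))) {
    d <- (labs == pairs$fwd[r]) - (labs == pairs$rev[r])
    out$n_fwd[r] <- sum(labs == pairs$fwd[r])
    out$n_rev[r] <- sum(labs == pairs$rev[r])
    S <- tapply(d, batch, sum)
    se <- stats::sd(S) * sqrt(length(S))
    out$z[r] <- if (se > 0) sum(d) / se else 0
  }
  out$flagged <- abs(out$z) > 3
  out
}

#' Path-length symmetry on decorrelated paths
#'
#' Two-sample Kolmogorov-Smirnov comparison of the path-length
#' distributions of each transition and its time-reversed partner,
#' restricted to decorrelated paths (paths sharing no frames with the
#' previous decorrelated path), which are effectively independent draws
#' from the ensemble so the KS p-value is meaningful.
#'
#' @param chain an \code{"mstps"} object.
#' @return Data frame with one row per state pair: sample sizes and the KS
#'   p-value (NA when a side has fewer than 5 decorrelated paths).
#' @export
decorrelated_length_ks <- function(chain) {
  stopifnot(inherits(chain, "mstps"))
  di <- decorrelated_indices(chain)
  labs <- vapply(chain$paths[di], transition_label, character(1))
  lens <- vapply(chain$paths[di], length, integer(1))
  pairs <- transition_pairs(sort(unique(labs)))
  pairs$n_fwd <- pairs$n_rev <- 0L
  pairs$ks_p <- NA_real_
  for (r in seq_len(nrow(pairs))) {
    lf <- lens[labs == pairs$fwd[r]]
    lr <- lens[labs == pairs$rev[r]]
    pairs$n_fwd[r] <- length(lf)
    pairs$n_rev[r] <- length(lr)
    if (length(lf) >= 5 && length(lr) >= 5)
      pairs$ks_p[r] <- suppressWarnings(
        stats::ks.test(lf, lr, exact = FALSE)$p.value)
  }
  pairs
}
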