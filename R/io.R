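#' Write / read a trial-label CSV
#'
#' The interchange contract between sampling and analysis: one row per MC
#' trial with columns \code{trial_index}, \code{transition_label} and
#' \code{accepted_flag}.  Switching records exported from other
#' path-sampling tools in this format can be analysed without the toy
#' engine.
#'
#' @param x an \code{"mstps"} chain or a data frame with the three columns.
#' @param file output path.
#' @return \code{file}, invisibly.
#' @export
write_labels_csv <- function(x, file) {
  if (inherits(x, "mstps"))
    x <- data.frame(trial_index = x$records$trial,
                    transition_label = x$records$label,
                    accepted_flag = x$records$accepted,
                    stringsAsFactors = FALSE)
  stopifnot(all(c("trial_index", "transition_label", "accepted_flag") %in% names(x)))
  utils::write.csv(x, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname write_labels_csv
#' @return For \code{read_labels_csv}, a data frame with the three columns,
#'   rows ordered by \code{trial_index}.
#' @export
read_labels_csv <- function(file) {
  d <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("trial_index", "transition_label", "accepted_flag")
  if (!all(need %in% names(d)))
    stop("label CSV must have columns: ", paste(need, collapse = ", "))
  d <- d[order(d$trial_index), need]
  d$accepted_flag <- as.logical(d$accepted_flag)
  if (anyNA(d$transition_label) || any(!grepl("->", d$transition_label, fixed = TRUE)))
    stop("invalid transition label in CSV")
  d
}

#' Write an MSTPS path archive
#'
#' Serialises a sampled chain to a directory of plain-text tables: a JSON
#' manifest, per-path metadata (transition, MC weight, accepting trial),
#' the frame table (path index, sequence position, frame id, coordinates at
#' full precision) and the per-trial Monte Carlo record.  Frame ids,
#' weights and labels round-trip exactly; coordinates are written with 17
#' significant digits so they re-read bitwise.
#'
#' @param chain an \code{"mstps"} object.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_path_archive <- function(chain, dir) {
  stopifnot(inherits(chain, "mstps"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    format = "mstps-archive-1",
    n_trials = chain$n_trials,
    n_paths = length(chain$paths),
    max_length = chain$max_length,
    states = list(labels = chain$states$labels,
                  centers = chain$states$centers,
                  radii = chain$states$radii),
    potential = list(centers = chain$potential$centers,
                     depths = chain$potential$depths,
                     widths = chain$potential$widths),
    dynamics = list(timestep = chain$dynamics$timestep,
                    diffusion = chain$dynamics$diffusion),
    equilibration = chain$equilibration)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  meta <- data.frame(
    path_index = seq_along(chain$paths),
    from = vapply(chain$paths, function(p) p$transition[1], character(1)),
    to = vapply(chain$paths, function(p) p$transition[2], character(1)),
    weight = vapply(chain$paths, `[[`, integer(1), "weight"),
    accepted_at_trial = vapply(chain$paths, `[[`, integer(1), "accepted_at_trial"),
    n_frames = vapply(chain$paths, length, integer(1)))
  utils::write.csv(meta, file.path(dir, "paths_meta.csv"), row.names = FALSE,
                   quote = FALSE)
  frames <- do.call(rbind, lapply(seq_along(chain$paths), function(i) {
    p <- chain$paths[[i]]
    data.frame(path_index = i, seq = seq_len(length(p)),
               frame_id = p$frame_ids,
               x = sprintf("%.17g", p$coords[, 1]),
               y = sprintf("%.17g", p$coords[, 2]),
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(frames, file.path(dir, "frames.csv"), row.names = FALSE,
                   quote = FALSE)
  utils::write.csv(chain$records, file.path(dir, "records.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' Read an MSTPS path archive
#'
#' Reconstructs the chain written by \code{\link{write_path_archive}}.
#'
#' @param dir archive directory.
#' @return An \code{"mstps"} object (potential/states/dynamics rebuilt from
#'   the manifest).
#' @export
read_path_archive <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  if (!identical(manifest$format, "mstps-archive-1"))
    stop("not an mstps path archive: ", dir)
  meta <- utils::read.csv(file.path(dir, "paths_meta.csv"),
                          stringsAsFactors = FALSE)
  frames <- utils::read.csv(file.path(dir, "frames.csv"),
                            stringsAsFactors = FALSE)
  records <- utils::read.csv(file.path(dir, "records.csv"),
                             stringsAsFactors = FALSE)
  states <- disc_states(manifest$states$labels,
                        matrix(unlist(manifest$states$centers), ncol = 2),
                        manifest$states$radii)
  potential <- toy_potential(matrix(unlist(manifest$potential$centers), ncol = 2),
                             manifest$potential$depths,
                             manifest$potential$widths)
  dynamics <- dynamics_params(manifest$dynamics$timestep,
                              manifest$dynamics$diffusion)
  paths <- lapply(seq_len(nrow(meta)), function(i) {
    f <- frames[frames$path_index == i, ]
    f <- f[order(f$seq), ]
    tps_path(cbind(as.numeric(f$x), as.numeric(f$y)), f$frame_id,
             c(meta$from[i], meta$to[i]), meta$weight[i],
             meta$accepted_at_trial[i])
  })
  structure(list(paths = paths, records = records,
                 n_trials = as.integer(manifest$n_trials), states = states,
                 potential = potential, dynamics = dynamics,
                 max_length = as.integer(manifest$max_length),
                 equilibration = manifest$equilibration),
            class = "mstps")
}

#' Write a kinetics report
#'
#' JSON report of a \code{\link{switch_kinetics}} fit (counts, populations,
#' rates per 100 MC steps, convergence flags), plus CSV matrices of the
#' switch counts and rates alongside it.
#'
#' @param fit a \code{"switch_kinetics"} object.
#' @param file output JSON path; sibling CSVs get suffixes
#'   \code{_counts.csv} and \code{_rates_per100.csv}.
#' @return \code{file}, invisibly.
#' @export
write_kinetics_report <- function(fit, file) {
  stopifnot(inherits(fit, "switch_kinetics"))
  report <- list(
    n_trials = fit$counts$n_trials,
    n_switches = sum(fit$counts$n),
    labels = rownames(fit$counts$n),
    residence_t = as.list(fit$counts$t),
    populations = as.list(fit$P),
    rates_per_100_steps = apply(fit$rates$per_100_steps, 1, as.list,
                                simplify = FALSE),
    unvisited = fit$unvisited,
    decorrelated_only = fit$decorrelated_only,
    convergence = list(
      unvisited = fit$convergence$unvisited,
      symmetry = fit$convergence$symmetry,
      decorrelated = fit$convergence$decorrelated))
  jsonlite::write_json(report, file, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  base <- sub("\\.json$", "", file)
  utils::write.csv(fit$counts$n, paste0(base, "_counts.csv"), quote = FALSE)
  utils::write.csv(fit$rates$per_100_steps, paste0(base, "_rates_per100.csv"),
                   quote = FALSE)
  invisible(file)
}

#' Write a path-density histogram
#'
#' CSV matrix of bin values plus a JSON sidecar carrying the bin edges, CV
#' names and the trial-count denominator.
#'
#' @param pd a \code{"path_density"} object.
#' @param file output CSV path; the sidecar gets suffix \code{.json}.
#' @return \code{file}, invisibly.
#' @export
write_path_density <- function(pd, file) {
  stopifnot(inherits(pd, "path_density"))
  utils::write.csv(pd$values, file, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(breaks_x = pd$breaks_x, breaks_y = pd$breaks_y,
                            cv_names = pd$cv_names,
                            total_trials = pd$total_trials,
                            dropped_frames = pd$dropped_frames),
                       paste0(file, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(file)
}
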