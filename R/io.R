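## Text export of trajectories and summaries.

#' Write a trajectory as a delimited table
#'
#' One row per recorded host generation, tab-separated, with a header row.
#'
#' @param traj a \linkS4class{SimulationTrajectory}.
#' @param file output path.
#' @return the file path, invisibly.
#' @export
writeTrajectory <- function(traj, file) {
  utils::write.table(trajectory(traj), file, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(file)
}

#' Write density snapshots as delimited matrices
#'
#' Writes each kept per-generation density (see the keepDensities argument
#' of \code{\link{runSimulation}}) as one tab-separated matrix file per
#' generation and population under \code{dir}.
#'
#' @param traj a \linkS4class{SimulationTrajectory} run with
#'   \code{keepDensities = TRUE}.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
writeDensities <- function(traj, dir) {
  if (!length(traj@densities)) stop("trajectory holds no density snapshots")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(traj@densities)) {
    d <- traj@densities[[i]]
    utils::write.table(d$H, file.path(dir, sprintf("host-%04d.tsv", i - 1L)),
                       sep = "\t", row.names = FALSE, col.names = FALSE)
    utils::write.table(as.matrix(d$S),
                       file.path(dir, sprintf("symbiont-%04d.tsv", i - 1L)),
                       sep = "\t", row.names = FALSE, col.names = FALSE)
  }
  invisible(dir)
}

## Plain-list view of a parameter object, for config echo and JSON.
.paramsAsList <- function(p) {
  nm <- methods::slotNames(class(p))
  stats::setNames(lapply(nm, function(s) {
    v <- methods::slot(p, s)
    if (is.na(v) && is.integer(v)) NULL else v
  }), nm)
}

#' Write a structured JSON summary of a run
#'
#' Records the resolved parameters, run length, convergence flag and the
#' final trait means.
#'
#' @param traj a \linkS4class{SimulationTrajectory}.
#' @param file output path.
#' @return the file path, invisibly.
#' @export
writeSummary <- function(traj, file) {
  r <- trajectory(traj)
  last <- r[nrow(r), ]
  s <- list(variant = traj@variant,
            params = .paramsAsList(runParams(traj)),
            generationsRun = last$generation,
            converged = traj@converged,
            final = as.list(last))
  jsonlite::write_json(s, file, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(file)
}
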