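## Parameter-sweep driver and outcome classification: the layer that maps
## out where cooperation, collapse and loss of control occur across
## relatedness and benefit-to-cost gradients.

#' Classify the evolutionary outcome of a run
#'
#' A trajectory counts as "cooperation" when the final mean symbiont
#' cooperation exceeds the environmental-pool mean by at least
#' \code{margin} AND the final mean host cooperation exceeds its initial
#' mean by at least \code{margin} - i.e. both partners ended up
#' substantially more cooperative than the uncooperative baseline. A run
#' that is not cooperative is labelled "control_lost" when control was
#' enabled but the final mean control fell below 10% of its initial mean,
#' and "collapse" otherwise. The rule is a numeric convention: the
#' underlying model output is a continuous equilibrium, and the default
#' margin of 0.2 separates the pool baseline from near-full cooperation.
#' Enlarging the margin can only demote "cooperation", never create it.
#'
#' @param traj a \linkS4class{SimulationTrajectory}.
#' @param pool the environmental pool the run used (defaults to the
#'   standard pool for the run's parameters).
#' @param margin classification margin (> 0), default 0.2.
#' @return one of "cooperation", "collapse", "control_lost".
#' @export
classifyOutcome <- function(traj, pool = environmentalPool(runParams(traj)),
                            margin = 0.2) {
  r <- trajectory(traj)
  if (nrow(r) < 1L) stop("empty trajectory")
  if (margin <= 0) stop("margin must be > 0")
  poolMeanB <- meanTrait(pool)["b"]
  first <- r[1L, ]; last <- r[nrow(r), ]
  coop <- (last$meanB - poolMeanB >= margin) &&
          (last$meanA - first$meanA >= margin)
  if (coop) return("cooperation")
  p <- runParams(traj)
  if (p@controlEnabled && first$meanC > 0 &&
      last$meanC < 0.1 * first$meanC) return("control_lost")
  "collapse"
}

#' Construct a sweep specification
#'
#' @param axes named list of parameter values to cross (cartesian
#'   product). Names must be ModelParams slots, or "benefit" to sweep
#'   x = y jointly (the benefit-to-cost axis, since trait costs are 1).
#' @param fixed baseline parameter set for everything not on an axis.
#' @param variant model run per cell: "base" (control disabled), "control"
#'   (control enabled) or "escape" (default schedule).
#' @param margin classification margin.
#' @return a validated \linkS4class{SweepSpec}.
#' @examples
#' sweepSpec(list(R = c(0.2, 0.5, 0.8), benefit = c(1, 2, 4)),
#'           fixed = modelParams(generationRatio = 100))
#' @export
sweepSpec <- function(axes, fixed = modelParams(),
                      variant = c("base", "control", "escape"),
                      margin = 0.2) {
  variant <- match.arg(variant)
  methods::new("SweepSpec", axes = axes, fixed = fixed, variant = variant,
               margin = as.numeric(margin))
}

#' Run a parameter sweep
#'
#' Runs the selected model variant for every combination of axis values
#' and classifies each outcome. Cells are independent (results do not
#' depend on execution order); a cell that errors is recorded as
#' "extinct" (for population-extinction errors) or with an NA label and
#' the error message, without aborting the sweep.
#'
#' @param spec a \linkS4class{SweepSpec}.
#' @param cellHook optional function(index, result) called after each
#'   cell, e.g. for progress logging or checkpointing.
#' @return a \linkS4class{SweepResult} whose grid has one row per
#'   combination with the outcome label and equilibrium trait means.
#' @export
runSweep <- function(spec, cellHook = NULL) {
  methods::validObject(spec)
  grid <- expand.grid(spec@axes, KEEP.OUT.ATTRS = FALSE)
  out <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    out[[i]] <- runSweepCell(spec, grid[i, , drop = FALSE])
    if (!is.null(cellHook)) cellHook(i, out[[i]])
  }
  methods::new("SweepResult",
               grid = cbind(grid, do.call(rbind, out)),
               spec = spec)
}

#' Run a single sweep cell
#'
#' @param spec a \linkS4class{SweepSpec}.
#' @param row one-row data.frame of axis values (as produced by the
#'   cartesian product over \code{spec@axes}).
#' @return one-row data.frame with label, meanA, meanB, meanC, error.
#' @export
runSweepCell <- function(spec, row) {
  p <- spec@fixed
  for (nm in names(row)) {
    v <- row[[nm]]
    if (nm == "benefit") {
      p <- updateParams(p, x = v, y = v)
    } else {
      args <- list(p); args[[nm]] <- v
      p <- do.call(updateParams, args)
    }
  }
  p <- updateParams(p, controlEnabled = spec@variant %in% c("control", "escape"))
  res <- tryCatch({
    traj <- if (spec@variant == "escape") runEscapeSimulation(p)
            else runSimulation(p)
    last <- trajectory(traj)[nrow(trajectory(traj)), ]
    data.frame(label = classifyOutcome(traj, margin = spec@margin),
               meanA = last$meanA, meanB = last$meanB, meanC = last$meanC,
               error = NA_character_, stringsAsFactors = FALSE)
  }, ecoleashExtinction = function(e) {
    data.frame(label = "extinct", meanA = NA_real_, meanB = NA_real_,
               meanC = NA_real_, error = conditionMessage(e),
               stringsAsFactors = FALSE)
  }, error = function(e) {
    data.frame(label = NA_character_, meanA = NA_real_, meanB = NA_real_,
               meanC = NA_real_, error = conditionMessage(e),
               stringsAsFactors = FALSE)
  })
  res
}

setMethod("show", "SweepResult", function(object) {
  tab <- table(object@grid$label, useNA = "ifany")
  cat(sprintf("SweepResult (%s variant): %d cells\n", object@spec@variant,
              nrow(object@grid)))
  print(tab)
})

#' @rdname runParams
#' @export
setMethod("runParams", "SweepResult", function(x) x@spec@fixed)
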