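## S4 class definitions. Validity methods enforce the model's structural
## invariants: trait grids are strictly increasing and endpoint-inclusive,
## and population densities are non-negative and sum to 1 within 1e-12.

.NORM_TOL <- 1e-12

#' Discrete support grid for a trait
#'
#' An ordered vector of evenly spaced support points for one trait axis.
#' Cooperation traits live on [0, 1]; the host control trait lives on
#' [0, cMax]. Populations are probability masses on these points.
#'
#' @slot .Data numeric vector of strictly increasing support points.
#' @export
setClass("TraitGrid", contains = "numeric", validity = function(object) {
  v <- object@.Data
  if (length(v) < 2L) return("a trait grid needs at least 2 points")
  if (any(diff(v) <= 0)) return("grid values must be strictly increasing")
  TRUE
})

#' Model parameters for the host-microbiome cooperation model
#'
#' Holds every parameter of the trait-distribution model. Benefits of
#' received cooperation are \code{x} (to hosts) and \code{y} (to symbionts);
#' \code{R} is symbiont relatedness in the social-evolution sense (the
#' probability, above the population average, that two symbiont cells share
#' the cooperation allele; 1 for a clonal population). Host control carries
#' a symbiont-side suppression cost \code{f} and a direct host cost
#' \code{g}; \code{M} and \code{m} are immigration fractions from the
#' environmental pool per host generation and per symbiont generation
#' respectively; \code{generationRatio} is the number of symbiont
#' generations per host generation.
#'
#' @slot x,y benefit coefficients (dimensionless, >= 0).
#' @slot R relatedness in [0, 1].
#' @slot f symbiont-side cost of control, >= 0.
#' @slot g host-side cost of control, >= 0 (maximal direct cost is g at
#'   c = cMax regardless of cMax).
#' @slot M,m immigration fractions in [0, 1].
#' @slot generationRatio integer >= 1.
#' @slot cMax upper bound of the control trait, > 0.
#' @slot nGrid points per trait axis (default 11).
#' @slot benefitForm one of "linear", "diminishing", "accelerating",
#'   "sigmoidal"; shape of the curve translating mean symbiont cooperation
#'   into host benefit.
#' @slot nHostGenerations run length in host generations.
#' @slot controlEnabled when FALSE the control trait is pinned at 0.
#' @slot mutationRate optional nearest-neighbour mutation rate applied to
#'   the symbiont distribution after each selection step (0 disables; the
#'   model's default source of fresh variation is immigration, not
#'   mutation).
#' @export
setClass("ModelParams", slots = c(
  x = "numeric", y = "numeric", R = "numeric",
  f = "numeric", g = "numeric",
  M = "numeric", m = "numeric",
  generationRatio = "integer",
  cMax = "numeric", nGrid = "integer",
  benefitForm = "character",
  nHostGenerations = "integer",
  controlEnabled = "logical",
  mutationRate = "numeric"
), validity = function(object) {
  msg <- character()
  chk1 <- function(v, nm) if (length(slot(object, v)) != 1L || !is.finite(slot(object, v)))
    sprintf("%s must be a single finite value", nm) else NULL
  for (s in c("x", "y", "R", "f", "g", "M", "m", "cMax", "mutationRate")) {
    e <- chk1(s, s); if (!is.null(e)) msg <- c(msg, e)
  }
  if (length(msg)) return(msg)
  if (object@R < 0 || object@R > 1) msg <- c(msg, "R must lie in [0, 1]")
  if (object@M < 0 || object@M > 1) msg <- c(msg, "M must lie in [0, 1]")
  if (object@m < 0 || object@m > 1) msg <- c(msg, "m must lie in [0, 1]")
  if (object@f < 0) msg <- c(msg, "f must be >= 0")
  if (object@g < 0) msg <- c(msg, "g must be >= 0")
  if (object@x < 0 || object@y < 0) msg <- c(msg, "x and y must be >= 0")
  if (object@generationRatio < 1L) msg <- c(msg, "generationRatio must be >= 1")
  if (object@cMax <= 0) msg <- c(msg, "cMax must be > 0")
  if (object@nGrid < 2L) msg <- c(msg, "nGrid must be >= 2")
  if (object@nHostGenerations < 1L) msg <- c(msg, "nHostGenerations must be >= 1")
  if (!object@benefitForm %in% c("linear", "diminishing", "accelerating", "sigmoidal"))
    msg <- c(msg, sprintf("unknown benefitForm '%s'", object@benefitForm))
  if (object@mutationRate < 0 || object@mutationRate > 0.5)
    msg <- c(msg, "mutationRate must lie in [0, 0.5]")
  if (length(msg)) msg else TRUE
})

#' Host population as a probability density over (cooperation, control)
#'
#' @slot density matrix of probability masses, rows indexed by the host
#'   cooperation grid (a), columns by the control grid (c).
#' @slot aGrid,cGrid the trait grids.
#' @export
setClass("HostPopulation", slots = c(
  density = "matrix", aGrid = "TraitGrid", cGrid = "TraitGrid"
), validity = function(object) {
  d <- object@density
  if (nrow(d) != length(object@aGrid) || ncol(d) != length(object@cGrid))
    return("density dimensions must match the trait grids")
  if (any(d < 0)) return("density entries must be >= 0")
  if (abs(sum(d) - 1) > .NORM_TOL) return("density must sum to 1 (tolerance 1e-12)")
  TRUE
})

#' Symbiont population as a probability density over cooperation
#'
#' @slot density numeric vector of probability masses over the b grid.
#' @slot bGrid the cooperation grid.
#' @export
setClass("SymbiontPopulation", slots = c(
  density = "numeric", bGrid = "TraitGrid"
), validity = function(object) {
  d <- object@density
  if (length(d) != length(object@bGrid))
    return("density length must match the trait grid")
  if (any(d < 0)) return("density entries must be >= 0")
  if (abs(sum(d) - 1) > .NORM_TOL) return("density must sum to 1 (tolerance 1e-12)")
  TRUE
})

#' Symbiont population over (trait expression, linkage)
#'
#' Extended symbiont representation for the escape-from-control model:
#' symbionts carry an expression level B of the trait the host monitors and
#' a linkage gamma tying expression to realized cooperation, b = gamma * B.
#'
#' @slot density matrix of probability masses, rows indexed by the
#'   expression grid (B), columns by the linkage grid (gamma).
#' @slot BGrid,gammaGrid the trait grids (both on [0, 1]).
#' @export
setClass("LinkedSymbiontPopulation", slots = c(
  density = "matrix", BGrid = "TraitGrid", gammaGrid = "TraitGrid"
), validity = function(object) {
  d <- object@density
  if (nrow(d) != length(object@BGrid) || ncol(d) != length(object@gammaGrid))
    return("density dimensions must match the trait grids")
  if (any(d < 0)) return("density entries must be >= 0")
  if (abs(sum(d) - 1) > .NORM_TOL) return("density must sum to 1 (tolerance 1e-12)")
  TRUE
})

#' Record of a simulation run
#'
#' @slot records data.frame of per-host-generation trait means (generation
#'   0 is the initial state).
#' @slot densities list of per-generation density snapshots (empty unless
#'   the run was asked to keep them).
#' @slot params the parameter set of the run.
#' @slot finalHost,finalSymbiont populations at the last recorded
#'   generation.
#' @slot converged TRUE if the run stopped early because the L1 change of
#'   both densities fell below the convergence tolerance.
#' @slot variant which model produced the run ("base", "escape" or "ibm").
#' @export
setClass("SimulationTrajectory", slots = c(
  records = "data.frame",
  densities = "list",
  params = "ModelParams",
  finalHost = "HostPopulation",
  finalSymbiont = "ANY",
  converged = "logical",
  variant = "character"
))

#' Configuration of the individual-based (pathogen) model
#'
#' Extends \linkS4class{ModelParams} with finite population sizes, pathogen
#' parameters and an RNG seed. Pathogens are microbes that never cooperate
#' (b = 0), are subject to host control like any non-cooperative symbiont,
#' and additionally harm their host through the pathogenicity factor
#' \code{exp(v * p * c/cMax) * exp(-v * p)} multiplying host fitness, where
#' p is the within-host pathogen proportion and v the virulence.
#'
#' @slot nHosts number of hosts (reference scale 1e4).
#' @slot microbesPerHost microbes carried per host (reference scale 1e3).
#' @slot virulence pathogen virulence v >= 0.
#' @slot pathogenInflux fraction of the global microbe pool replaced by
#'   pathogens each host generation, in [0, 1].
#' @slot seed RNG seed (NA leaves the RNG state untouched).
#' @export
setClass("IBMConfig", contains = "ModelParams", slots = c(
  nHosts = "integer", microbesPerHost = "integer",
  virulence = "numeric", pathogenInflux = "numeric",
  seed = "integer"
), validity = function(object) {
  msg <- character()
  if (object@nHosts < 1L) msg <- c(msg, "nHosts must be >= 1")
  if (object@microbesPerHost < 1L) msg <- c(msg, "microbesPerHost must be >= 1")
  if (object@virulence < 0) msg <- c(msg, "virulence must be >= 0")
  if (object@pathogenInflux < 0 || object@pathogenInflux > 1)
    msg <- c(msg, "pathogenInflux must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' State of the individual-based model
#'
#' Microbes take genotype values on the same cooperation grid as the
#' deterministic model; each host's community is stored as counts per
#' genotype category, with one extra category for pathogens (b = 0,
#' pathogen flag set). Microbes within a host are exchangeable, so the
#' count representation is equivalent to per-individual arrays with a
#' microbe-to-host assignment.
#'
#' @slot hostA,hostC per-host trait values (on the grids).
#' @slot counts integer matrix nHosts x (nGrid + 1): microbe counts per
#'   genotype category; the last column is the pathogen category.
#' @slot bValues cooperation value of each category (pathogens: 0).
#' @slot generation host-generation counter (0 at initialization).
#' @export
setClass("IBMState", slots = c(
  hostA = "numeric", hostC = "numeric",
  counts = "matrix", bValues = "numeric",
  generation = "integer"
), validity = function(object) {
  if (length(object@hostA) != length(object@hostC))
    return("hostA and hostC must have equal length")
  if (nrow(object@counts) != length(object@hostA))
    return("counts must have one row per host")
  if (ncol(object@counts) != length(object@bValues))
    return("counts must have one column per genotype category")
  if (any(object@counts < 0)) return("counts must be >= 0")
  if (length(unique(rowSums(object@counts))) != 1L)
    return("every host must carry the same number of microbes")
  TRUE
})

#' Specification of a parameter sweep
#'
#' @slot axes named list mapping parameter names to value vectors; the
#'   sweep runs the cartesian product. The pseudo-axis "benefit" sets x and
#'   y jointly.
#' @slot fixed parameter set used for everything not on an axis.
#' @slot variant which model to run per cell: "base" (control disabled),
#'   "control" (control enabled), or "escape".
#' @slot margin classification margin passed to \code{classifyOutcome}.
#' @export
setClass("SweepSpec", slots = c(
  axes = "list", fixed = "ModelParams", variant = "character",
  margin = "numeric"
), validity = function(object) {
  if (length(object@axes) < 1L) return("at least one sweep axis is required")
  nm <- names(object@axes)
  if (is.null(nm) || any(!nzchar(nm))) return("axes must be a named list")
  ok <- c(slotNames("ModelParams"), "benefit")
  bad <- setdiff(nm, ok)
  if (length(bad)) return(sprintf("unknown axis name(s): %s", paste(bad, collapse = ", ")))
  if (!object@variant %in% c("base", "control", "escape"))
    return(sprintf("unknown sweep variant '%s'", object@variant))
  if (object@margin <= 0) return("margin must be > 0")
  TRUE
})

#' Result of a parameter sweep
#'
#' @slot grid data.frame with one row per parameter combination: the axis
#'   values, the outcome label ("cooperation", "collapse", "control_lost"
#'   or "extinct") and equilibrium trait means.
#' @slot spec the sweep specification.
#' @export
setClass("SweepResult", slots = c(grid = "data.frame", spec = "SweepSpec"))
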