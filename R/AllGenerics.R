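#' @include AllClasses.R
NULL

#' Probability density of a population object
#'
#' Returns the probability masses a population places on its trait grid:
#' a vector over the cooperation grid for a \linkS4class{SymbiontPopulation},
#' a matrix over (cooperation x control) for a \linkS4class{HostPopulation},
#' and a matrix over (expression x linkage) for a
#' \linkS4class{LinkedSymbiontPopulation}.
#'
#' @param x a population object.
#' @return numeric vector or matrix of probability masses (sums to 1).
#' @export
setGeneric("popDensity", function(x) standardGeneric("popDensity"))

#' Mean trait values of a population
#'
#' @param x a population object.
#' @return named numeric vector of trait means: \code{b} for symbionts,
#'   \code{a} and \code{c} for hosts, \code{b}, \code{B} and \code{gamma}
#'   for the linked symbiont representation.
#' @export
setGeneric("meanTrait", function(x) standardGeneric("meanTrait"))

#' Per-generation records of a simulation
#'
#' @param x a \linkS4class{SimulationTrajectory}.
#' @return a data.frame with one row per host generation (generation 0 is
#'   the initial state) holding trait means and, depending on the model
#'   variant, additional columns such as pathogen prevalence.
#' @export
setGeneric("trajectory", function(x) standardGeneric("trajectory"))

#' Parameters used by a simulation or sweep object
#'
#' @param x an object carrying a parameter set.
#' @return the \linkS4class{ModelParams} (or subclass) stored in \code{x}.
#' @export
setGeneric("runParams", function(x) standardGeneric("runParams"))
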