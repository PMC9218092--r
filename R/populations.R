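#' Construct a trait grid
#'
#' @param n number of support points (>= 2).
#' @param lower,upper grid endpoints (inclusive).
#' @return a \linkS4class{TraitGrid} of n evenly spaced points.
#' @examples
#' traitGrid(11, 0, 1)
#' @export
traitGrid <- function(n, lower = 0, upper = 1) {
  methods::new("TraitGrid", seq(lower, upper, length.out = n))
}

## Probability masses of a normal density truncated to a grid: evaluate the
## density at each support point and renormalize. Densities in this model
## are proportions of the population at each grid value, not quadrature
## approximations, so no cell weights are applied.
.discretizedTruncNorm <- function(grid, mean, sd) {
  w <- stats::dnorm(as.numeric(grid), mean = mean, sd = sd)
  w / sum(w)
}

#' Construct a host population
#'
#' @param density matrix of probability masses over (aGrid x cGrid).
#' @param aGrid,cGrid trait grids for cooperation and control.
#' @return a validated \linkS4class{HostPopulation}.
#' @export
hostPopulation <- function(density, aGrid, cGrid) {
  if (!methods::is(aGrid, "TraitGrid")) aGrid <- methods::new("TraitGrid", aGrid)
  if (!methods::is(cGrid, "TraitGrid")) cGrid <- methods::new("TraitGrid", cGrid)
  methods::new("HostPopulation", density = density, aGrid = aGrid, cGrid = cGrid)
}

#' Construct a symbiont population
#'
#' @param density vector of probability masses over bGrid.
#' @param bGrid trait grid for symbiont cooperation.
#' @return a validated \linkS4class{SymbiontPopulation}.
#' @export
symbiontPopulation <- function(density, bGrid) {
  if (!methods::is(bGrid, "TraitGrid")) bGrid <- methods::new("TraitGrid", bGrid)
  methods::new("SymbiontPopulation", density = as.numeric(density), bGrid = bGrid)
}

#' Initial host population
#'
#' The starting distribution is the outer product of two discretized
#' truncated normals: cooperation with mean 0 and SD 0.5 on [0, 1], control
#' with mean 0 and SD 1 on [0, cMax]. These give a small but finite amount
#' of cooperation and pre-existing variation in control, without which
#' neither trait can get off the ground. When control is disabled all
#' control mass sits at c = 0.
#'
#' @param params a \linkS4class{ModelParams}.
#' @return a \linkS4class{HostPopulation}.
#' @export
initHostPopulation <- function(params) {
  ag <- traitGrid(params@nGrid, 0, 1)
  cg <- traitGrid(params@nGrid, 0, params@cMax)
  ha <- .discretizedTruncNorm(ag, 0, 0.5)
  hc <- if (params@controlEnabled) {
    .discretizedTruncNorm(cg, 0, 1)
  } else {
    c(1, rep(0, params@nGrid - 1L))
  }
  hostPopulation(outer(ha, hc), ag, cg)
}

#' Initial symbiont population
#'
#' Discretized truncated normal on the cooperation grid, mean 0, SD 0.5.
#'
#' @param params a \linkS4class{ModelParams}.
#' @return a \linkS4class{SymbiontPopulation}.
#' @export
initSymbiontPopulation <- function(params) {
  bg <- traitGrid(params@nGrid, 0, 1)
  symbiontPopulation(.discretizedTruncNorm(bg, 0, 0.5), bg)
}

#' Environmental pool of immigrant symbionts
#'
#' The fixed source population supplying immigrants at rate M per host
#' generation and m per symbiont generation. Immigrants are largely
#' uncooperative but carry a small baseline of cooperation; by default the
#' pool equals the initial symbiont distribution (truncated normal, mean 0,
#' SD 0.5), which provides that baseline without introducing a new
#' parameter.
#'
#' @param params a \linkS4class{ModelParams}.
#' @return a \linkS4class{SymbiontPopulation}.
#' @export
environmentalPool <- function(params) initSymbiontPopulation(params)

## ---- accessors -----------------------------------------------------------

#' @rdname popDensity
#' @export
setMethod("popDensity", "HostPopulation", function(x) x@density)

#' @rdname popDensity
#' @export
setMethod("popDensity", "SymbiontPopulation", function(x) x@density)

#' @rdname popDensity
#' @export
setMethod("popDensity", "LinkedSymbiontPopulation", function(x) x@density)

#' @rdname meanTrait
#' @export
setMethod("meanTrait", "HostPopulation", function(x) {
  c(a = sum(rowSums(x@density) * as.numeric(x@aGrid)),
    c = sum(colSums(x@density) * as.numeric(x@cGrid)))
})

#' @rdname meanTrait
#' @export
setMethod("meanTrait", "SymbiontPopulation", function(x) {
  c(b = sum(x@density * as.numeric(x@bGrid)))
})

#' @rdname meanTrait
#' @export
setMethod("meanTrait", "LinkedSymbiontPopulation", function(x) {
  b <- outer(as.numeric(x@BGrid), as.numeric(x@gammaGrid))
  c(b = sum(x@density * b),
    B = sum(rowSums(x@density) * as.numeric(x@BGrid)),
    gamma = sum(colSums(x@density) * as.numeric(x@gammaGrid)))
})

setMethod("show", "HostPopulation", function(object) {
  mt <- meanTrait(object)
  cat(sprintf("HostPopulation on a %d x %d (a x c) grid; mean a = %.4f, mean c = %.4f\n",
              nrow(object@density), ncol(object@density), mt["a"], mt["c"]))
})

setMethod("show", "SymbiontPopulation", function(object) {
  cat(sprintf("SymbiontPopulation on a %d-point grid; mean b = %.4f\n",
              length(object@density), meanTrait(object)["b"]))
})

setMethod("show", "LinkedSymbiontPopulation", function(object) {
  mt <- meanTrait(object)
  cat(sprintf(
    "LinkedSymbiontPopulation on a %d x %d (B x gamma) grid; mean b = %.4f, mean B = %.4f, mean gamma = %.4f\n",
    nrow(object@density), ncol(object@density), mt["b"], mt["B"], mt["gamma"]))
})
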