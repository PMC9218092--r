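#' Construct a model parameter set
#'
#' Defaults follow the reference configuration used throughout the package's
#' examples: benefits x = y = 2, relatedness R = 0.5, control costs f = 0.02
#' (on symbionts) and g = 0.1 (on hosts), immigration M = 0.05 per host
#' generation and m = 1e-6 per symbiont generation, an 11-point grid per
#' trait axis, and a control trait bounded by cMax = 10 (the host cost term
#' uses c/cMax, so the maximal direct cost of control is g regardless of
#' cMax).
#'
#' @param x,y benefit to hosts (x) and to symbionts (y) of receiving the
#'   partner's cooperation.
#' @param R symbiont relatedness in [0, 1].
#' @param f,g symbiont-side and host-side costs of control.
#' @param M,m immigration fractions per host and per symbiont generation.
#' @param generationRatio symbiont generations per host generation (>= 1).
#' @param cMax upper bound of the control trait.
#' @param nGrid points per trait axis.
#' @param benefitForm shape of the cooperation-to-benefit curve; see
#'   \code{\link{benefitTransform}}.
#' @param nHostGenerations run length in host generations.
#' @param controlEnabled if FALSE the control trait is pinned at 0.
#' @param mutationRate optional nearest-neighbour mutation rate for the
#'   symbiont distribution (0 disables).
#' @return a validated \linkS4class{ModelParams} object.
#' @examples
#' p <- modelParams(generationRatio = 100, controlEnabled = TRUE)
#' p
#' @export
modelParams <- function(x = 2, y = 2, R = 0.5, f = 0.02, g = 0.1,
                        M = 0.05, m = 1e-6, generationRatio = 1,
                        cMax = 10, nGrid = 11,
                        benefitForm = c("linear", "diminishing",
                                        "accelerating", "sigmoidal"),
                        nHostGenerations = 200, controlEnabled = FALSE,
                        mutationRate = 0) {
  benefitForm <- match.arg(benefitForm)
  methods::new("ModelParams",
    x = as.numeric(x), y = as.numeric(y), R = as.numeric(R),
    f = as.numeric(f), g = as.numeric(g),
    M = as.numeric(M), m = as.numeric(m),
    generationRatio = as.integer(generationRatio),
    cMax = as.numeric(cMax), nGrid = as.integer(nGrid),
    benefitForm = benefitForm,
    nHostGenerations = as.integer(nHostGenerations),
    controlEnabled = isTRUE(controlEnabled),
    mutationRate = as.numeric(mutationRate))
}

#' Derive a modified copy of a parameter set
#'
#' @param params a \linkS4class{ModelParams} (or subclass).
#' @param ... named slot values to replace.
#' @return an object of the same class with the given slots replaced.
#' @export
updateParams <- function(params, ...) {
  repl <- list(...)
  if (!length(repl)) return(params)
  nm <- names(repl)
  bad <- setdiff(nm, methods::slotNames(class(params)))
  if (length(bad))
    stop("unknown parameter(s): ", paste(bad, collapse = ", "))
  for (s in nm) {
    proto <- slot(params, s)
    slot(params, s) <- if (is.integer(proto)) as.integer(repl[[s]])
      else if (is.logical(proto)) isTRUE(repl[[s]])
      else if (is.character(proto)) as.character(repl[[s]])
      else as.numeric(repl[[s]])
  }
  methods::validObject(params)
  params
}

setMethod("show", "ModelParams", function(object) {
  cat("ModelParams:",
      sprintf("x=%g y=%g R=%g f=%g g=%g", object@x, object@y, object@R,
              object@f, object@g), "\n")
  cat(sprintf("  M=%g m=%g generationRatio=%d cMax=%g nGrid=%d\n",
              object@M, object@m, object@generationRatio, object@cMax,
              object@nGrid))
  cat(sprintf("  benefitForm=%s nHostGenerations=%d control=%s mutationRate=%g\n",
              object@benefitForm, object@nHostGenerations,
              if (object@controlEnabled) "enabled" else "disabled",
              object@mutationRate))
})
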