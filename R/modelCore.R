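## Core fitness and control computations on discretized trait
## distributions. All integrals over trait densities are
## probability-weighted sums over grid points.

.checkSymbiont <- function(S) {
  if (!methods::is(S, "SymbiontPopulation"))
    stop("S must be a SymbiontPopulation")
  methods::validObject(S)
  invisible(S)
}

.checkHost <- function(H) {
  if (!methods::is(H, "HostPopulation"))
    stop("H must be a HostPopulation")
  methods::validObject(H)
  invisible(H)
}

.checkControlLevel <- function(cc, params) {
  if (any(cc < 0 | cc > params@cMax))
    stop(sprintf("control level must lie in [0, %g]", params@cMax))
  invisible(cc)
}

#' Effect of host control on a focal symbiont
#'
#' Host control preferentially benefits symbionts expressing more of the
#' monitored trait: a focal symbiont with cooperation b inside a host with
#' control investment c receives relative weight
#' \deqn{q(b, c) = \frac{e^{bc}}{\sum_{b'} e^{(1-R) b' c} S(b')} e^{-fc}.}
#' The denominator makes control relative to the competitors the focal
#' symbiont is compared against, scaled by the genetic diversity (1 - R):
#' a clonal population (R = 1) offers nothing to discriminate between, so
#' the denominator is exactly 1. The factor exp(-f c) is the indiscriminate
#' harm of the control mechanism (e.g. antimicrobial peptides) to all
#' symbionts. q(b, 0) = 1 for every b.
#'
#' @param b focal cooperation level(s) in [0, 1].
#' @param c control level in [0, cMax].
#' @param S the competing \linkS4class{SymbiontPopulation}.
#' @param params a \linkS4class{ModelParams}.
#' @return relative weight(s) q >= 0, vectorized over b.
#' @examples
#' p <- modelParams()
#' S <- initSymbiontPopulation(p)
#' controlEffect(0.5, 0, S, p)  # no control: q = 1
#' @export
controlEffect <- function(b, c, S, params) {
  .checkSymbiont(S)
  stopifnot(length(c) == 1L)
  .checkControlLevel(c, params)
  if (any(b < 0 | b > 1)) stop("cooperation level b must lie in [0, 1]")
  bg <- as.numeric(S@bGrid)
  Z <- sum(exp((1 - params@R) * bg * c) * S@density)
  exp(b * c) / Z * exp(-params@f * c)
}

#' Mean symbiont cooperation after host control
#'
#' The control-weighted mean of the symbiont distribution,
#' \deqn{\bar b(c) = \frac{\sum_b q(b,c) S(b) b}{\sum_b q(b,c) S(b)},}
#' i.e. the average cooperation a host with control c actually experiences.
#' The indiscriminate factor exp(-f c) cancels between numerator and
#' denominator; \eqn{\bar b(c)} is non-decreasing in c because exponential
#' tilting enriches high-cooperation mass.
#'
#' @param c control level(s) in [0, cMax] (vectorized).
#' @inheritParams controlEffect
#' @return mean cooperation value(s) in [0, 1].
#' @export
meanTraitAfterControl <- function(c, S, params) {
  .checkSymbiont(S)
  .checkControlLevel(c, params)
  bg <- as.numeric(S@bGrid)
  vapply(c, function(ci) {
    w <- exp(bg * ci) * S@density   # Z and exp(-f c) cancel in the ratio
    den <- sum(w)
    if (den <= 0) stop("degenerate symbiont distribution: zero total weight")
    sum(w * bg) / den
  }, numeric(1))
}

#' Partner fidelity feedback to the host
#'
#' A host that invests a in its symbionts increases their capacity to help
#' back; the feedback is proportional to the benefit y the symbionts
#' received: \eqn{p_a = a y}.
#'
#' @param a host cooperation in [0, 1] (vectorized).
#' @param params a \linkS4class{ModelParams}.
#' @return feedback effect(s) a * y.
#' @export
hostFeedback <- function(a, params) {
  if (any(a < 0 | a > 1)) stop("host cooperation a must lie in [0, 1]")
  a * params@y
}

#' Partner fidelity feedback to a symbiont
#'
#' \eqn{p_b(c) = R b x + (1 - R) \bar b(c) x}: the return benefit a
#' cooperative symbiont receives, split between the share attributable to
#' its own genotype (weighted by relatedness R) and the share set by the
#' post-control population average.
#'
#' @param b focal symbiont cooperation in [0, 1].
#' @inheritParams meanTraitAfterControl
#' @return feedback effect(s), vectorized over b.
#' @export
symbiontFeedback <- function(b, c, S, params) {
  if (any(b < 0 | b > 1)) stop("cooperation level b must lie in [0, 1]")
  bbar <- meanTraitAfterControl(c, S, params)
  params@R * b * params@x + (1 - params@R) * bbar * params@x
}

#' Host fitness
#'
#' \deqn{W_a = (1 - a) + x\, p_a\, \phi(\bar b(c)) - g\, c / c_{max}}
#' with \eqn{p_a = a y}: the baseline minus the cost of cooperating, plus
#' the benefit of the (control-filtered) symbiont cooperation fed back
#' through partner fidelity, minus the direct cost of running the control
#' mechanism. \eqn{\phi} is the configured benefit curve
#' (\code{\link{benefitTransform}}; identity for the linear form).
#'
#' @param a host cooperation in [0, 1] (vectorized; recycled against c).
#' @param c host control in [0, cMax].
#' @inheritParams controlEffect
#' @return host fitness value(s).
#' @export
hostFitness <- function(a, c, S, params) {
  if (any(a < 0 | a > 1)) stop("host cooperation a must lie in [0, 1]")
  .checkControlLevel(c, params)
  bbar <- meanTraitAfterControl(c, S, params)
  benefit <- benefitTransform(bbar, params@benefitForm)
  (1 - a) + params@x * (a * params@y) * benefit - params@g * c / params@cMax
}

#' Symbiont fitness between host generations
#'
#' Dispersal-stage fitness: every symbiont genotype samples every host
#' genotype, so
#' \deqn{W_b = (1 - b) + y \sum_a \sum_c H(a,c)\, q(b,c)\, p_b(c)\, a.}
#'
#' @param b focal symbiont cooperation in [0, 1] (vectorized).
#' @param H the \linkS4class{HostPopulation}.
#' @inheritParams controlEffect
#' @return symbiont fitness value(s).
#' @export
symbiontFitnessBetween <- function(b, H, S, params) {
  .checkHost(H)
  .checkSymbiont(S)
  if (any(b < 0 | b > 1)) stop("cooperation level b must lie in [0, 1]")
  cg <- as.numeric(H@cGrid)
  ag <- as.numeric(H@aGrid)
  bbar <- meanTraitAfterControl(cg, S, params)
  wAC <- as.vector(ag %*% H@density)          # sum_a H(a, c) a, per c
  vapply(b, function(bi) {
    q <- controlEffectPerC(bi, cg, S, params)
    pb <- params@R * bi * params@x + (1 - params@R) * bbar * params@x
    (1 - bi) + params@y * sum(wAC * q * pb)
  }, numeric(1))
}

## q(b, c) for a scalar b across a vector of control levels.
controlEffectPerC <- function(b, cg, S, params) {
  bg <- as.numeric(S@bGrid)
  Z <- as.vector(crossprod(exp(outer(bg, cg) * (1 - params@R)), S@density))
  exp(b * cg) / Z * exp(-params@f * cg)
}

#' Symbiont fitness within a host generation
#'
#' Growth-stage fitness under pure local competition:
#' \deqn{W_b = (1 - b) + \sum_c q(b,c)\, h(c),}
#' where h(c) is the marginal density of control in the host population, so
#' that within-host selection reflects the hosts symbionts actually occupy.
#' With all control mass at c = 0 this reduces to (1 - b) + 1 and
#' cooperation is pure cost.
#'
#' @inheritParams symbiontFitnessBetween
#' @return symbiont fitness value(s).
#' @export
symbiontFitnessWithin <- function(b, H, S, params) {
  .checkHost(H)
  .checkSymbiont(S)
  if (any(b < 0 | b > 1)) stop("cooperation level b must lie in [0, 1]")
  cg <- as.numeric(H@cGrid)
  hC <- colSums(H@density)
  vapply(b, function(bi) {
    q <- controlEffectPerC(bi, cg, S, params)
    (1 - bi) + sum(q * hC)
  }, numeric(1))
}

#' Benefit curves translating symbiont cooperation into host benefit
#'
#' The linear form is the identity. The three non-linear forms are smooth
#' curves anchored at (0, 0) and (1, 1): diminishing returns (concave,
#' saturating), accelerating returns (convex) and sigmoidal returns
#' (benefits only felt above a threshold of symbiont investment). The
#' concave/convex forms are scaled exponentials with shape constant 3; the
#' sigmoidal form is a rescaled logistic with steepness 10 centred at 0.5.
#'
#' With \code{asPrinted = TRUE} the function instead evaluates, verbatim,
#' an alternative set of published formulas for inspection:
#' \code{1 - (1-b)/(1-6b)} (diminishing; note this expression diverges at
#' b = 1/6), \code{b/(b + 0.3(1-b))} (accelerating; note this expression is
#' concave) and \code{(1 + b/(1+b))^6} (sigmoidal; note this expression
#' exceeds 1). Because these expressions are not anchored on [0, 1] they
#' are never used by the simulator.
#'
#' @param b mean cooperation value(s) in [0, 1].
#' @param form one of "linear", "diminishing", "accelerating", "sigmoidal".
#' @param asPrinted evaluate the alternative published expressions
#'   literally instead of the anchored curves.
#' @return transformed benefit value(s).
#' @examples
#' benefitTransform(0.5, "diminishing")
#' curve(benefitTransform(x, "sigmoidal"), 0, 1)
#' @export
benefitTransform <- function(b, form = c("linear", "diminishing",
                                         "accelerating", "sigmoidal"),
                             asPrinted = FALSE) {
  form <- match.arg(form)
  if (any(b < 0 | b > 1)) stop("benefit input must lie in [0, 1]")
  if (asPrinted) {
    return(switch(form,
      linear = b,
      diminishing = 1 - (1 - b) / (1 - 6 * b),
      accelerating = b / (b + 0.3 * (1 - b)),
      sigmoidal = (1 + b / (1 + b))^6))
  }
  switch(form,
    linear = b,
    diminishing = (1 - exp(-3 * b)) / (1 - exp(-3)),
    accelerating = (exp(3 * b) - 1) / (exp(3) - 1),
    sigmoidal = {
      lg <- function(z) 1 / (1 + exp(-10 * (z - 0.5)))
      (lg(b) - lg(0)) / (lg(1) - lg(0))
    })
}

## Fast internal benefit evaluation used by the engines.
.benefit <- function(bbar, params) {
  if (params@benefitForm == "linear") bbar
  else benefitTransform(bbar, params@benefitForm)
}
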