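# Independent naive-scalar-loop oracles for the fitness and control
# equations, plus random normalized population generators. The oracles
# deliberately use explicit element-by-element loops and no shared code
# with the package internals.

randomSymbiont <- function(params, seed) {
  set.seed(seed)
  d <- stats::runif(params@nGrid)
  symbiontPopulation(d / sum(d), traitGrid(params@nGrid, 0, 1))
}

randomHost <- function(params, seed) {
  set.seed(seed)
  d <- matrix(stats::runif(params@nGrid^2), params@nGrid)
  hostPopulation(d / sum(d), traitGrid(params@nGrid, 0, 1),
                 traitGrid(params@nGrid, 0, params@cMax))
}

# q(b, c): Eq.-by-eq scalar evaluation.
oracleQ <- function(b, cc, S, params) {
  bg <- as.numeric(S@bGrid)
  Z <- 0
  for (i in seq_along(bg))
    Z <- Z + exp((1 - params@R) * bg[i] * cc) * S@density[i]
  exp(b * cc) / Z * exp(-params@f * cc)
}

oracleBbar <- function(cc, S, params) {
  bg <- as.numeric(S@bGrid)
  num <- 0; den <- 0
  for (i in seq_along(bg)) {
    qi <- oracleQ(bg[i], cc, S, params)
    num <- num + qi * S@density[i] * bg[i]
    den <- den + qi * S@density[i]
  }
  num / den
}

oracleHostFitness <- function(a, cc, S, params) {
  bb <- benefitTransform(oracleBbar(cc, S, params), params@benefitForm)
  (1 - a) + params@x * (a * params@y) * bb - params@g * cc / params@cMax
}

oracleWbBetween <- function(b, H, S, params) {
  ag <- as.numeric(H@aGrid); cg <- as.numeric(H@cGrid)
  acc <- 0
  for (i in seq_along(ag)) for (j in seq_along(cg)) {
    pb <- params@R * b * params@x +
      (1 - params@R) * oracleBbar(cg[j], S, params) * params@x
    acc <- acc + H@density[i, j] * oracleQ(b, cg[j], S, params) * pb * ag[i]
  }
  (1 - b) + params@y * acc
}

oracleWbWithin <- function(b, H, S, params) {
  cg <- as.numeric(H@cGrid)
  hC <- colSums(H@density)
  acc <- 0
  for (j in seq_along(cg)) acc <- acc + oracleQ(b, cg[j], S, params) * hC[j]
  (1 - b) + acc
}

# One simultaneous generational update composed from the exported step
# operations (within-host phase, then host and symbiont fitness both
# evaluated on the same state, then both updated + migration).
oracleGeneration <- function(H, S, pool, params) {
  S1 <- withinHostPhase(S, H, params, pool)
  Snext <- selectionStepSymbionts(S1, H, params, phase = "between")
  Snext <- applyMigration(Snext, pool, params@M)
  Hnext <- selectionStepHosts(H, S1, params)
  list(H = Hnext, S = Snext)
}
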