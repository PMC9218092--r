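## Individual-based variant of the model with an influx of rare, costly
## pathogens. Microbe genotypes live on the same cooperation grid as the
## deterministic model (so the deterministic model is the exact
## infinite-population limit); each host's community is a vector of counts
## per genotype category plus one pathogen category. Pathogens never
## cooperate (b = 0), are subject to host control exactly like
## non-cooperative symbionts, and multiply host fitness by the
## pathogenicity factor.

#' Construct an individual-based model configuration
#'
#' Extends \code{\link{modelParams}} with population sizes, pathogen
#' parameters and a seed. The reference scale is 1e4 hosts carrying 1e3
#' microbes each (1e7 microbes total); runs at that scale are slow, and
#' scaled-down sizes preserve the qualitative behaviour.
#'
#' @param nHosts number of hosts.
#' @param microbesPerHost microbes carried per host.
#' @param virulence pathogen virulence v.
#' @param pathogenInflux fraction of the global microbe pool replaced by
#'   pathogens each host generation (0 disables pathogens).
#' @param seed RNG seed for \code{\link{runIBM}} (NA: do not seed).
#' @param ... parameters forwarded to \code{\link{modelParams}}.
#' @return an \linkS4class{IBMConfig}.
#' @examples
#' cfg <- ibmConfig(nHosts = 100, microbesPerHost = 100, seed = 1)
#' @export
ibmConfig <- function(nHosts = 10000, microbesPerHost = 1000,
                      virulence = 100, pathogenInflux = 1e-3,
                      seed = NA_integer_, ...) {
  p <- modelParams(...)
  methods::new("IBMConfig", p,
    nHosts = as.integer(nHosts),
    microbesPerHost = as.integer(microbesPerHost),
    virulence = as.numeric(virulence),
    pathogenInflux = as.numeric(pathogenInflux),
    seed = as.integer(seed))
}

#' Pathogenicity factor
#'
#' Multiplicative host-fitness penalty from carrying pathogens:
#' \deqn{p_f = e^{v p (c / c_{max})} e^{-v p},}
#' where p is the within-host pathogen proportion, v the virulence and c
#' the host's control investment. p_f is 1 when there are no pathogens or
#' when control is maximal (full control nullifies the harm), and e^{-vp}
#' at c = 0; the exponent makes even a small pathogen load costly.
#'
#' @param p pathogen proportion(s) in [0, 1].
#' @param c host control level(s) in [0, cMax].
#' @param config an \linkS4class{IBMConfig} (supplies v and cMax).
#' @return factor(s) in (0, 1].
#' @export
pathogenicityFactor <- function(p, c, config) {
  if (any(p < 0 | p > 1)) stop("pathogen proportion must lie in [0, 1]")
  .checkControlLevel(c, config)
  v <- config@virulence
  exp(v * p * (c / config@cMax)) * exp(-v * p)
}

#' Construct an individual-based model state
#'
#' @param hostA,hostC per-host trait values.
#' @param counts matrix of microbe counts, hosts x categories; the last
#'   column is the pathogen category.
#' @param bValues cooperation value of each category (the pathogen
#'   category must be 0).
#' @param generation generation counter.
#' @return a validated \linkS4class{IBMState}.
#' @export
ibmState <- function(hostA, hostC, counts, bValues, generation = 0L) {
  storage.mode(counts) <- "integer"
  methods::new("IBMState", hostA = as.numeric(hostA),
               hostC = as.numeric(hostC), counts = counts,
               bValues = as.numeric(bValues),
               generation = as.integer(generation))
}

#' Initialize the individual-based model
#'
#' Host and microbe traits are sampled from the same discretized truncated
#' normals as the deterministic model (cooperation: mean 0, SD 0.5 on
#' [0, 1]; control: mean 0, SD 1 on [0, cMax], or pinned at 0 when control
#' is disabled); microbes are assigned microbesPerHost to each host. No
#' pathogens are present at initialization - they arrive only through the
#' influx.
#'
#' @param config an \linkS4class{IBMConfig}.
#' @param seed RNG seed (defaults to the config's; NA leaves the RNG
#'   untouched).
#' @return an \linkS4class{IBMState}.
#' @export
ibmInit <- function(config, seed = config@seed) {
  if (!is.na(seed)) set.seed(seed)
  n <- config@nGrid
  ag <- seq(0, 1, length.out = n)
  cg <- seq(0, config@cMax, length.out = n)
  nh <- config@nHosts
  hostA <- sample(ag, nh, replace = TRUE,
                  prob = .discretizedTruncNorm(ag, 0, 0.5))
  hostC <- if (config@controlEnabled) {
    sample(cg, nh, replace = TRUE, prob = .discretizedTruncNorm(cg, 0, 1))
  } else rep(0, nh)
  sProb <- c(.discretizedTruncNorm(ag, 0, 0.5), 0)   # no pathogens initially
  counts <- t(stats::rmultinom(nh, config@microbesPerHost, sProb))
  ibmState(hostA, hostC, counts, c(ag, 0), 0L)
}

## ---- internal pieces, shared by the generation step and the tests -------

## Per-host control weights q for every genotype category, given each
## host's own community as the competitor pool (local competition).
## Returns an nHosts x nCat matrix.
.ibmControlWeights <- function(state, config) {
  mph <- sum(state@counts[1L, ])
  bV <- state@bValues
  cH <- state@hostC
  ER <- exp(outer(bV, cH) * (1 - config@R))          # cat x host
  Z <- colSums(t(state@counts) * ER) / mph           # per host
  t(exp(outer(bV, cH))) / Z * exp(-config@f * cH)    # host x cat
}

## Within-host resampling probabilities per host (rows sum to 1).
.ibmWithinProbs <- function(state, config) {
  q <- .ibmControlWeights(state, config)
  W <- pmax(sweep(q, 2, 1 - state@bValues, "+"), 0)  # (1 - b) + q
  w <- state@counts * W
  tot <- rowSums(w)
  if (any(tot <= 0)) .extinctError("within-host symbiont")
  w / tot
}

## Host reproduction weights: max(W_a, 0) * p_f.
.ibmHostWeights <- function(state, config) {
  q <- .ibmControlWeights(state, config)
  num <- rowSums(q * state@counts * rep(state@bValues, each = nrow(q)))
  den <- rowSums(q * state@counts)
  bbar <- num / den
  a <- state@hostA; cH <- state@hostC
  Wa <- (1 - a) + config@x * (a * config@y) * .benefit(bbar, config) -
    config@g * cH / config@cMax
  pProp <- state@counts[, ncol(state@counts)] / rowSums(state@counts)
  pmax(Wa, 0) * pathogenicityFactor(pProp, cH, config)
}

## Colonization probabilities over categories: pooled parental microbes
## reweighted by between-host fitness, mixed with environmental
## immigration at rate M.
.ibmColonizationProbs <- function(state, config, poolCat) {
  bV <- state@bValues
  nCat <- length(bV)
  tot <- colSums(state@counts)
  Scat <- tot / sum(tot)
  cg <- seq(0, config@cMax, length.out = config@nGrid)
  cIdx <- match(state@hostC, cg)
  wAC <- vapply(seq_along(cg), function(j)
    sum(state@hostA[cIdx == j]), numeric(1)) / length(state@hostA)
  E <- exp(outer(bV, cg))
  ER <- exp(outer(bV, cg) * (1 - config@R))
  Z <- as.vector(crossprod(ER, Scat))
  q <- E * rep(exp(-config@f * cg) / Z, each = nCat)  # cat x c
  den <- as.vector(crossprod(q, Scat))
  num <- as.vector(crossprod(q, Scat * bV))
  bbar <- num / den
  pb <- config@R * config@x * matrix(bV, nCat, length(cg)) +
    (1 - config@R) * config@x * rep(bbar, each = nCat)
  Wb <- pmax((1 - bV) + config@y * as.vector((q * pb) %*% wAC), 0)
  w <- Scat * Wb
  totW <- sum(w)
  if (totW <= 0) .extinctError("symbiont")
  (1 - config@M) * w / totW + config@M * poolCat
}

## Replace, in expectation, pathogenInflux of the global microbe pool by
## pathogens: per host a binomial number of resident microbes (drawn
## without replacement across categories) is converted.
.ibmPathogenInflux <- function(state, config) {
  if (config@pathogenInflux <= 0) return(state)
  counts <- state@counts
  nCat <- ncol(counts)
  mph <- sum(counts[1L, ])
  k <- stats::rbinom(nrow(counts), mph, config@pathogenInflux)
  for (i in which(k > 0L)) {
    take <- tabulate(sample(rep.int(seq_len(nCat), counts[i, ]), k[i]), nCat)
    counts[i, ] <- counts[i, ] - take
    counts[i, nCat] <- counts[i, nCat] + k[i]
  }
  state@counts <- counts
  state
}

#' Advance the individual-based model by one host generation
#'
#' Steps: (1) pathogen influx converts a random fraction of microbes to
#' pathogens; (2) generationRatio - 1 rounds of within-host competition, in
#' which each host's community is multinomially resampled with
#' probabilities proportional to counts times max(within-host fitness, 0),
#' computed against that host's control level and local competitors; (3)
#' hosts reproduce, sampled with probabilities proportional to
#' max(host fitness, 0) times the pathogenicity factor; (4) each offspring
#' host draws its microbes from the pooled parental microbe population
#' reweighted by between-host symbiont fitness and mixed with environmental
#' immigrants at rate M.
#'
#' @param state an \linkS4class{IBMState}.
#' @param config an \linkS4class{IBMConfig}.
#' @param poolCat optional environmental pool over categories (defaults to
#'   the standard pool with zero pathogen mass).
#' @return the next \linkS4class{IBMState}.
#' @export
ibmHostGeneration <- function(state, config, poolCat = NULL) {
  nCat <- ncol(state@counts)
  mph <- config@microbesPerHost
  if (is.null(poolCat))
    poolCat <- c(.discretizedTruncNorm(seq(0, 1, length.out = config@nGrid),
                                       0, 0.5), 0)
  state <- .ibmPathogenInflux(state, config)
  for (r in seq_len(config@generationRatio - 1L)) {
    pr <- .ibmWithinProbs(state, config)
    state@counts <- t(vapply(seq_len(nrow(pr)), function(i)
      stats::rmultinom(1L, mph, pr[i, ])[, 1L], integer(nCat)))
  }
  wHost <- .ibmHostWeights(state, config)
  if (sum(wHost) <= 0) .extinctError("host")
  parents <- sample.int(length(wHost), length(wHost), replace = TRUE,
                        prob = wHost)
  colProbs <- .ibmColonizationProbs(state, config, poolCat)
  counts <- t(stats::rmultinom(length(parents), mph, colProbs))
  ibmState(state@hostA[parents], state@hostC[parents], counts,
           state@bValues, state@generation + 1L)
}

.ibmRecord <- function(state) {
  tot <- colSums(state@counts)
  N <- sum(tot)
  data.frame(generation = state@generation,
             meanA = mean(state@hostA),
             meanC = mean(state@hostC),
             meanB = sum(tot * state@bValues) / N,
             pathogenPrevalence = tot[length(tot)] / N)
}

#' Run the individual-based model
#'
#' Seeds the RNG from the config, initializes the state and advances it for
#' the configured number of host generations, recording trait means and
#' pathogen prevalence each generation.
#'
#' @param config an \linkS4class{IBMConfig}.
#' @param nGenerations run length (defaults to the config's
#'   nHostGenerations).
#' @return a \linkS4class{SimulationTrajectory} (variant "ibm") whose
#'   finalSymbiont slot holds the final \linkS4class{IBMState}; the final
#'   empirical populations are also available as finalHost and through the
#'   records.
#' @examples
#' cfg <- ibmConfig(nHosts = 50, microbesPerHost = 50, seed = 1,
#'                  nHostGenerations = 5, pathogenInflux = 0)
#' traj <- runIBM(cfg)
#' @export
runIBM <- function(config, nGenerations = config@nHostGenerations) {
  methods::validObject(config)
  if (!is.na(config@seed)) set.seed(config@seed)
  state <- ibmInit(config, seed = NA_integer_)
  recs <- vector("list", nGenerations + 1L)
  recs[[1L]] <- .ibmRecord(state)
  for (t in seq_len(nGenerations)) {
    state <- ibmHostGeneration(state, config)
    recs[[t + 1L]] <- .ibmRecord(state)
  }
  n <- config@nGrid
  ag <- seq(0, 1, length.out = n)
  cg <- seq(0, config@cMax, length.out = n)
  Hemp <- matrix(0, n, n)
  ai <- match(state@hostA, ag); ci <- match(state@hostC, cg)
  for (i in seq_along(ai)) Hemp[ai[i], ci[i]] <- Hemp[ai[i], ci[i]] + 1
  methods::new("SimulationTrajectory",
    records = do.call(rbind, recs),
    densities = list(),
    params = config,
    finalHost = hostPopulation(Hemp / sum(Hemp), traitGrid(n, 0, 1),
                               traitGrid(n, 0, config@cMax)),
    finalSymbiont = state,
    converged = FALSE,
    variant = "ibm")
}
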