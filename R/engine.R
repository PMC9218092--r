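## Evolution engine: replicator-style selection on the discretized trait
## distributions, within-host phases at the configured generation ratio,
## and immigration from the environmental pool.
##
## Update convention: within a host generation, host and symbiont fitnesses
## are evaluated simultaneously on the same current state (the host
## distribution and the symbiont distribution the hosts carried this
## generation) and both distributions are then updated. This is the usual
## convention for coupled discrete-time replicator dynamics; sequential
## updates (one species updating against the other's already-updated
## distribution) distort the coevolutionary race at the basin boundary.

.extinctError <- function(who) {
  stop(errorCondition(
    sprintf("population extinct: all %s selection weights are zero", who),
    class = c("ecoleashExtinction", "error", "condition")))
}

## Precomputed exponentials shared by every step of a run.
.engineContext <- function(params) {
  n <- params@nGrid
  bg <- seq(0, 1, length.out = n)
  cg <- seq(0, params@cMax, length.out = n)
  list(n = n, ag = bg, bg = bg, cg = cg,
       E = exp(outer(bg, cg)),                     # e^{b c}
       ER = exp((1 - params@R) * outer(bg, cg)),   # e^{(1-R) b c}
       efc = exp(-params@f * cg))
}

## q(b, c) matrix (b rows, c columns) for symbiont density S.
.qMat <- function(S, ctx) {
  Z <- as.vector(crossprod(ctx$ER, S))
  ctx$E * rep(ctx$efc / Z, each = ctx$n)
}

## Control-weighted mean cooperation per control level (f and Z cancel).
.bbarPerC <- function(S, ctx) {
  num <- as.vector(crossprod(ctx$E, S * ctx$bg))
  den <- as.vector(crossprod(ctx$E, S))
  num / den
}

## Nearest-neighbour mutation kernel (mass-conserving; end cells have one
## neighbour). Off unless params@mutationRate > 0.
.mutateVec <- function(S, mu) {
  if (mu <= 0) return(S)
  n <- length(S)
  deg <- c(1, rep(2, n - 2L), 1)
  inflow <- c(S[-1], 0) + c(0, S[-n])
  S * (1 - mu * deg) + mu * inflow
}

#' One host-generation selection step for hosts
#'
#' Reweights the host density by (clamped) host fitness:
#' H'(a, c) proportional to H(a, c) * max(W_a(a, c), 0), renormalized.
#' Fitness is clamped at zero before use because replicator weights must be
#' non-negative; host fitness can go slightly negative at extreme
#' parameters.
#'
#' @param H a \linkS4class{HostPopulation}.
#' @param S the \linkS4class{SymbiontPopulation} the hosts carry.
#' @param params a \linkS4class{ModelParams}.
#' @return the selected \linkS4class{HostPopulation}.
#' @export
selectionStepHosts <- function(H, S, params) {
  .checkHost(H); .checkSymbiont(S)
  cg <- as.numeric(H@cGrid); ag <- as.numeric(H@aGrid)
  bbar <- meanTraitAfterControl(cg, S, params)
  benefit <- .benefit(bbar, params)
  Wa <- outer(ag, seq_along(cg), function(a, j)
    (1 - a) + params@x * (a * params@y) * benefit[j] - params@g * cg[j] / params@cMax)
  Wa <- pmax(Wa, 0)
  d <- H@density * Wa
  tot <- sum(d)
  if (tot <= 0) .extinctError("host")
  hostPopulation(d / tot, H@aGrid, H@cGrid)
}

#' One selection step for symbionts
#'
#' Reweights the symbiont density by (clamped) symbiont fitness,
#' S'(b) proportional to S(b) * max(W_b(b), 0), where W_b is the
#' between-host (dispersal, \code{\link{symbiontFitnessBetween}}) or
#' within-host (growth, \code{\link{symbiontFitnessWithin}}) form.
#'
#' @param S a \linkS4class{SymbiontPopulation}.
#' @param H the \linkS4class{HostPopulation}.
#' @param params a \linkS4class{ModelParams}.
#' @param phase "between" or "within".
#' @return the selected \linkS4class{SymbiontPopulation}.
#' @export
selectionStepSymbionts <- function(S, H, params,
                                   phase = c("between", "within")) {
  phase <- match.arg(phase)
  .checkHost(H); .checkSymbiont(S)
  bg <- as.numeric(S@bGrid)
  W <- if (phase == "between") symbiontFitnessBetween(bg, H, S, params)
       else symbiontFitnessWithin(bg, H, S, params)
  W <- pmax(W, 0)
  d <- S@density * W
  tot <- sum(d)
  if (tot <= 0) .extinctError("symbiont")
  symbiontPopulation(.mutateVec(d / tot, params@mutationRate), S@bGrid)
}

#' Immigration from the environmental pool
#'
#' Convex mixture S' = (1 - rate) * S + rate * pool; normalization is
#' preserved by construction. Works for both the plain and the linked
#' symbiont representations.
#'
#' @param S a \linkS4class{SymbiontPopulation} or
#'   \linkS4class{LinkedSymbiontPopulation}.
#' @param pool the environmental pool, same class and grids as S.
#' @param rate immigration fraction in [0, 1].
#' @return the mixed population, same class as S.
#' @export
applyMigration <- function(S, pool, rate) {
  if (rate < 0 || rate > 1) stop("migration rate must lie in [0, 1]")
  if (!identical(class(S), class(pool)))
    stop("S and pool must be the same population class")
  S@density <- (1 - rate) * S@density + rate * pool@density
  S
}

#' Within-host competition phase
#'
#' Applies generationRatio - 1 cycles of within-host selection followed by
#' immigration at rate m. With generationRatio = 1 (one symbiont generation
#' per host generation) the phase is a no-op and the model reduces to the
#' pure between-host model.
#'
#' @param S a \linkS4class{SymbiontPopulation}.
#' @param H the \linkS4class{HostPopulation} (its control marginal weights
#'   the competition).
#' @param params a \linkS4class{ModelParams}.
#' @param pool environmental pool (defaults to
#'   \code{environmentalPool(params)}).
#' @return the \linkS4class{SymbiontPopulation} after the phase.
#' @export
withinHostPhase <- function(S, H, params, pool = environmentalPool(params)) {
  for (k in seq_len(params@generationRatio - 1L)) {
    S <- selectionStepSymbionts(S, H, params, phase = "within")
    S <- applyMigration(S, pool, params@m)
  }
  S
}

## ---- fast internal loop --------------------------------------------------

## One host generation on raw densities. Returns updated H (matrix), S
## (vector). Simultaneous update: Wa and Wb are both computed from (H, S
## after the within-host phase) before either density is updated.
.baseGeneration <- function(H, S, pool, params, ctx) {
  hC <- colSums(H)
  mu <- params@mutationRate
  for (k in seq_len(params@generationRatio - 1L)) {
    q <- .qMat(S, ctx)
    W <- pmax((1 - ctx$bg) + as.vector(q %*% hC), 0)
    S <- S * W
    tot <- sum(S)
    if (tot <= 0) .extinctError("symbiont")
    S <- .mutateVec(S / tot, mu)
    S <- (1 - params@m) * S + params@m * pool
  }
  q <- .qMat(S, ctx)
  bbar <- .bbarPerC(S, ctx)
  benefit <- .benefit(bbar, params)
  wAC <- as.vector(ctx$ag %*% H)                    # sum_a H(a,c) a, per c
  pb <- params@R * params@x * outer(ctx$bg, rep(1, ctx$n)) +
        (1 - params@R) * params@x * rep(bbar, each = ctx$n)
  Wb <- pmax((1 - ctx$bg) + params@y * as.vector((q * pb) %*% wAC), 0)
  Wa <- pmax(
    (1 - ctx$ag) +
      params@x * params@y * outer(ctx$ag, benefit) -
      rep(params@g * ctx$cg / params@cMax, each = ctx$n), 0)
  S <- S * Wb
  totS <- sum(S)
  if (totS <= 0) .extinctError("symbiont")
  S <- .mutateVec(S / totS, mu)
  S <- (1 - params@M) * S + params@M * pool
  H <- H * Wa
  totH <- sum(H)
  if (totH <= 0) .extinctError("host")
  H <- H / totH
  list(H = H, S = S)
}

.baseRecord <- function(gen, H, S, ctx) {
  bbar <- .bbarPerC(S, ctx)
  hC <- colSums(H)
  data.frame(generation = gen,
             meanA = sum(rowSums(H) * ctx$ag),
             meanC = sum(hC * ctx$cg),
             meanB = sum(S * ctx$bg),
             meanBControlled = sum(hC * bbar))
}

#' Run the deterministic host-microbiome simulation
#'
#' Iterates host generations. Each generation: (1) the within-host
#' competition phase (generationRatio - 1 cycles of growth-stage selection
#' plus immigration at rate m); (2) a simultaneous generational update in
#' which host fitness and between-host (dispersal) symbiont fitness are
#' evaluated on the current state, both densities are reweighted, and
#' symbionts receive immigration at rate M. The run stops after
#' \code{nHostGenerations} or as soon as the L1 change of both densities
#' falls below \code{convergenceTol}.
#'
#' @param params a \linkS4class{ModelParams}.
#' @param pool environmental pool (defaults to
#'   \code{environmentalPool(params)}).
#' @param H0,S0 optional initial populations (default
#'   \code{\link{initHostPopulation}} / \code{\link{initSymbiontPopulation}}).
#' @param keepDensities keep per-generation density snapshots in the
#'   trajectory (off by default; means are always recorded).
#' @param convergenceTol early-stopping tolerance on the L1 change of both
#'   densities per host generation; set to 0 to always run the full length.
#' @param progress optional function(generation) called after each host
#'   generation (used e.g. for logging).
#' @return a \linkS4class{SimulationTrajectory}. The record column
#'   \code{meanBControlled} is the control-weighted mean cooperation
#'   averaged over the host control marginal (the cooperation hosts
#'   actually experience).
#' @examples
#' p <- modelParams(nHostGenerations = 50)
#' traj <- runSimulation(p)
#' tail(trajectory(traj))
#' @export
runSimulation <- function(params, pool = environmentalPool(params),
                          H0 = initHostPopulation(params),
                          S0 = initSymbiontPopulation(params),
                          keepDensities = FALSE,
                          convergenceTol = 1e-10, progress = NULL) {
  methods::validObject(params)
  .checkHost(H0); .checkSymbiont(S0); .checkSymbiont(pool)
  ctx <- .engineContext(params)
  H <- H0@density; S <- S0@density; poolD <- pool@density
  recs <- vector("list", params@nHostGenerations + 1L)
  dens <- if (keepDensities) vector("list", params@nHostGenerations + 1L) else list()
  recs[[1L]] <- .baseRecord(0L, H, S, ctx)
  if (keepDensities) dens[[1L]] <- list(H = H, S = S)
  converged <- FALSE
  ngen <- params@nHostGenerations
  for (t in seq_len(ngen)) {
    st <- .baseGeneration(H, S, poolD, params, ctx)
    d1 <- sum(abs(st$H - H)); d2 <- sum(abs(st$S - S))
    H <- st$H; S <- st$S
    recs[[t + 1L]] <- .baseRecord(t, H, S, ctx)
    if (keepDensities) dens[[t + 1L]] <- list(H = H, S = S)
    if (!is.null(progress)) progress(t)
    if (convergenceTol > 0 && d1 < convergenceTol && d2 < convergenceTol) {
      converged <- TRUE
      recs <- recs[seq_len(t + 1L)]
      if (keepDensities) dens <- dens[seq_len(t + 1L)]
      break
    }
  }
  methods::new("SimulationTrajectory",
    records = do.call(rbind, recs),
    densities = dens,
    params = params,
    finalHost = hostPopulation(H, traitGrid(ctx$n, 0, 1),
                               traitGrid(ctx$n, 0, params@cMax)),
    finalSymbiont = symbiontPopulation(S, traitGrid(ctx$n, 0, 1)),
    converged = converged,
    variant = "base")
}

#' @rdname trajectory
#' @export
setMethod("trajectory", "SimulationTrajectory", function(x) x@records)

#' @rdname runParams
#' @export
setMethod("runParams", "SimulationTrajectory", function(x) x@params)

setMethod("show", "SimulationTrajectory", function(object) {
  r <- object@records
  last <- r[nrow(r), ]
  cat(sprintf("SimulationTrajectory (%s model): %d host generations%s\n",
              object@variant, last$generation,
              if (object@converged) " (converged)" else ""))
  cat(sprintf("  final means: a = %.4f, c = %.4f, b = %.4f\n",
              last$meanA, last$meanC, last$meanB))
})
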