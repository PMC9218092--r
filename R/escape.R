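## Escape-from-control extension: symbionts carry an expression level B of
## the trait the host monitors and a linkage gamma between expression and
## realized cooperation, b = gamma * B. Host control targets expression
## (q is evaluated with B, and its denominator aggregates the joint
## (B, gamma) density through B), while cooperation costs and feedback use
## the realized b. Selection can therefore favour genotypes that keep the
## monitored trait while dropping cooperation - escape from control -
## whenever the linkage is free to evolve.

#' Realized cooperation under the trait-cooperation linkage
#'
#' b = gamma * B. With gamma = 1 the monitored trait and cooperation are
#' strictly linked and the base model is recovered; with gamma = 0 the link
#' is broken: the trait is expressed but confers no cooperation.
#'
#' @param B trait expression level(s) in [0, 1].
#' @param gamma linkage value(s) in [0, 1] (recycled against B).
#' @return realized cooperation b = gamma * B.
#' @examples
#' effectiveCooperation(0.8, 0.5)
#' @export
effectiveCooperation <- function(B, gamma) {
  if (any(B < 0 | B > 1)) stop("trait expression B must lie in [0, 1]")
  if (any(gamma < 0 | gamma > 1)) stop("linkage gamma must lie in [0, 1]")
  gamma * B
}

#' Construct a linked symbiont population
#'
#' @param density matrix of probability masses over (BGrid x gammaGrid).
#' @param BGrid,gammaGrid trait grids on [0, 1].
#' @return a validated \linkS4class{LinkedSymbiontPopulation}.
#' @export
linkedSymbiontPopulation <- function(density, BGrid, gammaGrid) {
  if (!methods::is(BGrid, "TraitGrid")) BGrid <- methods::new("TraitGrid", BGrid)
  if (!methods::is(gammaGrid, "TraitGrid"))
    gammaGrid <- methods::new("TraitGrid", gammaGrid)
  methods::new("LinkedSymbiontPopulation", density = density,
               BGrid = BGrid, gammaGrid = gammaGrid)
}

#' Phase schedule for the escape experiment
#'
#' Ordered contiguous spans of host generations in which the
#' trait-cooperation linkage is either hardwired ("fixed": all gamma mass
#' projected onto gamma = 1, immigrants enter at gamma = 1) or free to
#' evolve ("free": the full (B, gamma) grid evolves under selection and
#' immigration, and immigrants carry uniform gamma, since environmental
#' strains have not coevolved the linkage).
#'
#' The default schedule reproduces the collapse-and-restore experiment:
#' 100 generations fixed (cooperation and control establish), 40 free
#' (escape genotypes sweep; cooperation and control decline), 160 fixed
#' (control becomes effective again and cooperation is restored).
#'
#' @param span generations per phase (positive integers).
#' @param mode "fixed" or "free", one per span.
#' @return a data.frame with columns span and mode.
#' @export
escapeSchedule <- function(span = c(100, 40, 160),
                           mode = c("fixed", "free", "fixed")) {
  span <- as.integer(span)
  mode <- as.character(mode)
  if (length(span) != length(mode)) stop("span and mode must have equal length")
  if (any(span < 1L)) stop("phase spans must be positive")
  if (!all(mode %in% c("fixed", "free"))) stop("mode must be 'fixed' or 'free'")
  data.frame(span = span, mode = mode)
}

## Project all linkage mass onto gamma = 1, preserving the B marginal.
.projectGammaFixed <- function(Smat) {
  n <- ncol(Smat)
  out <- matrix(0, nrow(Smat), n)
  out[, n] <- rowSums(Smat)
  out
}

.escapeRecord <- function(gen, mode, H, Smat, ctx, bmat) {
  SB <- rowSums(Smat)
  num <- as.vector(crossprod(ctx$E, rowSums(Smat * bmat)))
  den <- as.vector(crossprod(ctx$E, SB))
  bbar <- num / den
  hC <- colSums(H)
  mB <- sum(SB * ctx$bg)
  mg <- sum(colSums(Smat) * ctx$bg)          # gamma grid == b grid on [0,1]
  mb <- sum(Smat * bmat)
  data.frame(generation = gen, mode = mode,
             meanA = sum(rowSums(H) * ctx$ag),
             meanC = sum(hC * ctx$cg),
             meanB = mb, meanBExpr = mB, meanGamma = mg,
             meanBControlled = sum(hC * bbar),
             covBGamma = sum(Smat * outer(ctx$bg - mB, ctx$bg - mg)))
}

## One host generation of the linked model. q and its denominator use the
## expression level B; costs and feedback use b = gamma * B.
.escapeGeneration <- function(H, Smat, poolMat, params, ctx, bmat) {
  n <- ctx$n
  hC <- colSums(H)
  for (k in seq_len(params@generationRatio - 1L)) {
    SB <- rowSums(Smat)
    q <- .qMat(SB, ctx)                       # B x c
    qh <- as.vector(q %*% hC)                 # per B
    W <- pmax((1 - bmat) + qh, 0)             # B x gamma
    Smat <- Smat * W
    tot <- sum(Smat)
    if (tot <= 0) .extinctError("symbiont")
    Smat <- Smat / tot
    Smat <- (1 - params@m) * Smat + params@m * poolMat
  }
  SB <- rowSums(Smat)
  q <- .qMat(SB, ctx)
  den <- as.vector(crossprod(q, SB))
  num <- as.vector(crossprod(q, rowSums(Smat * bmat)))
  bbar <- num / den
  benefit <- .benefit(bbar, params)
  wAC <- as.vector(ctx$ag %*% H)
  t1 <- as.vector(q %*% wAC)                  # sum_c wAC q, per B
  t2 <- as.vector(q %*% (wAC * bbar))         # sum_c wAC q bbar, per B
  Wb <- pmax((1 - bmat) + params@y *
               (params@R * params@x * bmat * t1 +
                (1 - params@R) * params@x * matrix(t2, n, n)), 0)
  Wa <- pmax(
    (1 - ctx$ag) +
      params@x * params@y * outer(ctx$ag, benefit) -
      rep(params@g * ctx$cg / params@cMax, each = n), 0)
  Smat <- Smat * Wb
  totS <- sum(Smat)
  if (totS <= 0) .extinctError("symbiont")
  Smat <- Smat / totS
  Smat <- (1 - params@M) * Smat + params@M * poolMat
  H <- H * Wa
  totH <- sum(H)
  if (totH <= 0) .extinctError("host")
  list(H = H / totH, S = Smat)
}

#' Run the escape-from-control experiment
#'
#' Runs the evolution engine on the linked (B, gamma) symbiont
#' representation under a phase schedule. In "fixed" phases the linkage is
#' hardwired at gamma = 1 (mass is projected onto the gamma = 1 column on
#' phase entry, preserving B marginals, and immigrants enter at gamma = 1),
#' so the dynamics coincide exactly with the base model. In "free" phases
#' the full (B, gamma) grid evolves and immigrants carry uniform linkage.
#'
#' @param params a \linkS4class{ModelParams}; control should normally be
#'   enabled, since escape is escape from control.
#' @param schedule a data.frame from \code{\link{escapeSchedule}}.
#' @param pool environmental pool over B (defaults to
#'   \code{environmentalPool(params)}).
#' @param keepDensities keep per-generation density snapshots.
#' @param progress optional function(generation) called after each host
#'   generation.
#' @return a \linkS4class{SimulationTrajectory} (variant "escape") whose
#'   records include mean realized cooperation (meanB), mean expression
#'   (meanBExpr), mean linkage (meanGamma) and their covariance.
#' @examples
#' p <- modelParams(generationRatio = 10, controlEnabled = TRUE)
#' traj <- runEscapeSimulation(p, escapeSchedule(c(20, 10, 20),
#'                                               c("fixed", "free", "fixed")))
#' @export
runEscapeSimulation <- function(params, schedule = escapeSchedule(),
                                pool = environmentalPool(params),
                                keepDensities = FALSE, progress = NULL) {
  methods::validObject(params)
  .checkSymbiont(pool)
  if (!is.data.frame(schedule) || !all(c("span", "mode") %in% names(schedule)))
    stop("schedule must be a data.frame with columns span and mode")
  ctx <- .engineContext(params)
  n <- ctx$n
  bmat <- outer(ctx$bg, ctx$bg)               # b = gamma * B; gamma grid = [0,1]
  poolB <- pool@density
  poolFixed <- cbind(matrix(0, n, n - 1L), poolB)
  poolFree <- matrix(poolB / n, n, n)         # uniform gamma among immigrants
  H0 <- initHostPopulation(params)
  H <- H0@density
  Smat <- if (schedule$mode[1L] == "fixed") {
    cbind(matrix(0, n, n - 1L), initSymbiontPopulation(params)@density)
  } else {
    matrix(initSymbiontPopulation(params)@density / n, n, n)
  }
  recs <- list(.escapeRecord(0L, schedule$mode[1L], H, Smat, ctx, bmat))
  dens <- if (keepDensities) list(list(H = H, S = Smat)) else list()
  gen <- 0L
  for (ph in seq_len(nrow(schedule))) {
    mode <- schedule$mode[ph]
    if (mode == "fixed") {
      Smat <- .projectGammaFixed(Smat)
      poolMat <- poolFixed
    } else {
      poolMat <- poolFree
    }
    for (t in seq_len(schedule$span[ph])) {
      gen <- gen + 1L
      st <- .escapeGeneration(H, Smat, poolMat, params, ctx, bmat)
      H <- st$H; Smat <- st$S
      recs[[length(recs) + 1L]] <- .escapeRecord(gen, mode, H, Smat, ctx, bmat)
      if (keepDensities) dens[[length(dens) + 1L]] <- list(H = H, S = Smat)
      if (!is.null(progress)) progress(gen)
    }
  }
  methods::new("SimulationTrajectory",
    records = do.call(rbind, recs),
    densities = dens,
    params = params,
    finalHost = hostPopulation(H, traitGrid(n, 0, 1),
                               traitGrid(n, 0, params@cMax)),
    finalSymbiont = linkedSymbiontPopulation(Smat, traitGrid(n, 0, 1),
                                             traitGrid(n, 0, 1)),
    converged = FALSE,
    variant = "escape")
}
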