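test_that("control effect obeys its analytic identities", {
  p <- modelParams()
  S <- initSymbiontPopulation(p)
  bg <- as.numeric(S@bGrid)

  # no control: q = 1 for every b and every normalized S
  expect_equal(controlEffect(bg, 0, S, p), rep(1, length(bg)))
  for (seed in 1:5)
    expect_equal(controlEffect(bg, 0, randomSymbiont(p, seed), p),
                 rep(1, length(bg)))

  # clonal population (R = 1): denominator is exactly 1
  p1 <- modelParams(R = 1, f = 0)
  Spoint <- symbiontPopulation(c(rep(0, 5), 1, rep(0, 5)), traitGrid(11, 0, 1))
  b0 <- 0.5
  expect_equal(controlEffect(b0, 3, Spoint, p1), exp(b0 * 3))

  # three-point uniform support, hand-evaluated sum
  Stri <- symbiontPopulation(c(1, 0, 0, 0, 0, 1, 0, 0, 0, 0, 1) / 3,
                             traitGrid(11, 0, 1))
  pTri <- modelParams(R = 0.5, f = 0)
  expected <- exp(1) / mean(exp(0.5 * c(0, 0.5, 1) * 1))
  expect_equal(controlEffect(1, 1, Stri, pTri), expected)
})

test_that("control effect rejects invalid inputs", {
  p <- modelParams()
  S <- initSymbiontPopulation(p)
  expect_error(controlEffect(0.5, p@cMax + 1, S, p), "control level")
  badS <- S; badS@density <- badS@density * 2
  expect_error(controlEffect(0.5, 1, badS, p), "sum to 1")
})

test_that("mean trait after control reduces to the plain mean at c = 0 and is invariant for point masses", {
  p <- modelParams()
  for (seed in 1:5) {
    S <- randomSymbiont(p, seed)
    expect_equal(meanTraitAfterControl(0, S, p), meanTrait(S)[["b"]])
  }
  Spoint <- symbiontPopulation(c(0, 0, 0, 1, rep(0, 7)), traitGrid(11, 0, 1))
  b0 <- as.numeric(Spoint@bGrid)[4]
  expect_equal(meanTraitAfterControl(c(0, 1, 5, 10), Spoint, p),
               rep(b0, 4))
})

test_that("mean trait after control is non-decreasing in control and independent of f", {
  p <- modelParams()
  cs <- seq(0, p@cMax, length.out = 60)
  for (seed in 1:10) {
    S <- randomSymbiont(p, seed)
    bb <- meanTraitAfterControl(cs, S, p)
    expect_true(all(diff(bb) >= -1e-12))
    pf <- updateParams(p, f = 0.7)
    expect_equal(meanTraitAfterControl(cs, S, pf), bb)
  }
})

test_that("feedback terms are the stated linear forms", {
  p <- modelParams()  # y = 2, x = 2, R = 0.5
  expect_identical(hostFeedback(0, p), 0)
  expect_equal(hostFeedback(1, p), 2)
  expect_equal(hostFeedback(0.5, p), 1)

  # R = 1: feedback is own-genotype only; R = 0: population mean only
  S <- randomSymbiont(p, 3)
  p1 <- updateParams(p, R = 1)
  expect_equal(symbiontFeedback(c(0.2, 0.9), 2, S, p1),
               c(0.2, 0.9) * p1@x)
  p0 <- updateParams(p, R = 0)
  fb0 <- symbiontFeedback(c(0.2, 0.9), 2, S, p0)
  expect_equal(fb0[1], fb0[2])
  # half-half split, hand evaluation: R=0.5, x=2, b=1, bbar=0.5 -> 1.5
  Smid <- symbiontPopulation(c(rep(0, 5), 1, rep(0, 5)), traitGrid(11, 0, 1))
  expect_equal(symbiontFeedback(1, 0, Smid, p), 0.5 * 1 * 2 + 0.5 * 0.5 * 2)
})

test_that("host fitness matches its closed form at reference points", {
  p <- modelParams()
  S <- initSymbiontPopulation(p)
  expect_equal(hostFitness(0, 0, S, p), 1)                 # baseline
  expect_equal(hostFitness(0, p@cMax, S, p), 1 - p@g)      # control cost only
  Smid <- symbiontPopulation(c(rep(0, 5), 1, rep(0, 5)), traitGrid(11, 0, 1))
  expect_equal(hostFitness(1, 0, Smid, p), 0 + 2 * 2 * 0.5)
})

test_that("symbiont fitness reduces correctly for degenerate host populations", {
  p <- modelParams()
  S <- randomSymbiont(p, 11)
  n <- p@nGrid
  # all hosts at (a = 0, c = 0): no investment, no control
  d <- matrix(0, n, n); d[1, 1] <- 1
  H00 <- hostPopulation(d, traitGrid(n, 0, 1), traitGrid(n, 0, p@cMax))
  bg <- as.numeric(S@bGrid)
  expect_equal(symbiontFitnessBetween(bg, H00, S, p), 1 - bg)
  # point mass at (a, c = 0), focal b = 0: q = 1 and only the mean-field
  # feedback term remains
  d2 <- matrix(0, n, n); d2[7, 1] <- 1
  Ha <- hostPopulation(d2, traitGrid(n, 0, 1), traitGrid(n, 0, p@cMax))
  a <- as.numeric(Ha@aGrid)[7]
  bbar0 <- meanTrait(S)[["b"]]
  expect_equal(symbiontFitnessBetween(0, Ha, S, p),
               1 + p@y * a * (1 - p@R) * bbar0 * p@x)
  # control mass at 0: within-host fitness is (1 - b) + 1
  expect_equal(symbiontFitnessWithin(bg, H00, S, p), (1 - bg) + 1)
})

test_that("within-host fitness is suppressed to baseline under very costly control", {
  p <- modelParams(f = 60)
  n <- p@nGrid
  d <- matrix(0, n, n); d[1, n] <- 1   # all hosts at c = cMax
  H <- hostPopulation(d, traitGrid(n, 0, 1), traitGrid(n, 0, p@cMax))
  S <- initSymbiontPopulation(p)
  bg <- as.numeric(S@bGrid)
  W <- symbiontFitnessWithin(bg, H, S, p)
  expect_equal(W, 1 - bg, tolerance = 1e-6)
})

test_that("vectorized fitness computations match naive scalar-loop oracles", {
  p <- modelParams(f = 0.02, R = 0.37)
  bg <- seq(0, 1, length.out = p@nGrid)
  cg <- seq(0, p@cMax, length.out = p@nGrid)
  for (seed in 1:25) {
    S <- randomSymbiont(p, seed)
    H <- randomHost(p, seed + 1000)
    # q over the full grid
    ctx <- ecoleash:::.engineContext(p)
    qv <- ecoleash:::.qMat(S@density, ctx)
    for (j in seq_along(cg))
      expect_equal(qv[, j],
                   vapply(bg, oracleQ, numeric(1), cc = cg[j], S = S,
                          params = p),
                   tolerance = 1e-12)
    # control-weighted means, host fitness, both symbiont fitness forms
    expect_equal(meanTraitAfterControl(cg, S, p),
                 vapply(cg, oracleBbar, numeric(1), S = S, params = p),
                 tolerance = 1e-12)
    expect_equal(hostFitness(bg, cg[4], S, p),
                 vapply(bg, oracleHostFitness, numeric(1), cc = cg[4],
                        S = S, params = p),
                 tolerance = 1e-12)
    expect_equal(symbiontFitnessBetween(bg, H, S, p),
                 vapply(bg, oracleWbBetween, numeric(1), H = H, S = S,
                        params = p),
                 tolerance = 1e-12)
    expect_equal(symbiontFitnessWithin(bg, H, S, p),
                 vapply(bg, oracleWbWithin, numeric(1), H = H, S = S,
                        params = p),
                 tolerance = 1e-12)
  }
})

test_that("benefit curves are anchored and have the named shapes", {
  forms <- c("linear", "diminishing", "accelerating", "sigmoidal")
  for (fo in forms) {
    expect_equal(benefitTransform(0, fo), 0)
    expect_equal(benefitTransform(1, fo), 1)
  }
  expect_equal(benefitTransform(0.5, "linear"), 0.5)
  b <- seq(0, 1, length.out = 101)
  # concavity / convexity via second differences on a fine scan
  expect_true(all(diff(diff(benefitTransform(b, "diminishing"))) <= 1e-12))
  expect_true(all(diff(diff(benefitTransform(b, "accelerating"))) >= -1e-12))
  sg <- benefitTransform(b, "sigmoidal")
  d2 <- diff(diff(sg))
  expect_true(all(d2[1:40] > 0) && all(d2[60:99] < 0))  # inflection point
  expect_error(benefitTransform(0.5, "quadratic"))
})

test_that("as-printed benefit formulas evaluate verbatim (and are unanchored)", {
  b <- 0.5
  expect_equal(benefitTransform(b, "diminishing", asPrinted = TRUE),
               1 - (1 - b) / (1 - 6 * b))
  expect_equal(benefitTransform(b, "accelerating", asPrinted = TRUE),
               b / (b + 0.3 * (1 - b)))
  expect_gt(benefitTransform(1, "sigmoidal", asPrinted = TRUE), 1)
})
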