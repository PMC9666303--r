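test_that("transfer functions obey their saturation limits", {
  lin <- transferSpec("linear")
  expect_equal(transferFunction(1.3, lin), 1.3)
  rect <- transferSpec("rectified")
  expect_equal(transferFunction(c(-2, 0.7), rect), c(0, 0.7))

  bs <- transferSpec("bi_sigmoid")
  expect_equal(transferFunction(0, bs), 0)
  expect_equal(transferFunction(1e6, bs), 50)
  expect_equal(transferFunction(-1e6, bs), -0.01)
  # continuous and ~linear near zero
  expect_equal(transferFunction(1e-4, bs), 1e-4, tolerance = 1e-6)
  expect_equal(transferFunction(-1e-4, bs), -1e-4, tolerance = 1e-4)
})

test_that("modification drive changes sign at zero and at threshold", {
  expect_equal(bcmModification(0, 5), 0)
  expect_equal(bcmModification(2, 2), 0)
  expect_equal(bcmModification(1, 2), -1)
  expect_lt(bcmModification(0.5, 1), 0)  # depression window 0 < y < theta
  expect_gt(bcmModification(2, 1), 0)    # potentiation above threshold
})

test_that("threshold step is an Euler low-pass of the squared activity", {
  cfg <- plasticityConfig(tauTheta = 100, dt = 1)
  st <- neuronState(c(0, 0), theta = 4)
  expect_equal(stepThreshold(st, 2, cfg)@theta, 4)  # fixed point theta = y^2
  st0 <- neuronState(c(0, 0), theta = 0)
  expect_equal(stepThreshold(st0, 2, cfg)@theta, 0.04)
  # geometric approach to y^2 under a constant activity
  th <- 0
  for (i in 1:2000) th <- th + (1 / 100) * (4 - th)
  expect_equal(th, 4, tolerance = 1e-6)
})

test_that("weight step branches distinguish the rules only under depression", {
  x <- c(0.9, 0.4)
  stdCfg <- plasticityConfig(rule = "standard", tauW = 10, dt = 1)
  wdCfg <- plasticityConfig(rule = "weight_dependent", u = 1.3, tauW = 10,
                            dt = 1)

  # zero drive: state unchanged under both rules
  st <- neuronState(c(0.5, 0.2), theta = 1)
  expect_equal(stepWeights(st, x, stdCfg, yTilde = 1)@w, st@w)
  expect_equal(stepWeights(st, x, wdCfg, yTilde = 1)@w, st@w)

  # potentiation steps are bit-identical between rules
  expect_identical(stepWeights(st, x, stdCfg, yTilde = 3)@w,
                   stepWeights(st, x, wdCfg, yTilde = 3)@w)

  # depression vanishes at the excitatory bound w = -u
  stB <- neuronState(c(-1.3, 0.2), theta = 2)
  out <- stepWeights(stB, x, wdCfg, yTilde = 1)
  expect_equal(out@w[1], -1.3)
  expect_lt(out@w[2], 0.2)

  # the multiplicative decay is clamped so v cannot cross zero
  stC <- neuronState(c(0.5, 0.5), theta = 1e4)
  big <- stepWeights(stC, x, wdCfg, yTilde = 50)
  expect_true(all(big@w + wdCfg@u >= 0))
  expect_gt(attr(big, "guardTrips"), 0)
})

test_that("mean-field threshold averages squared responses plus noise", {
  expect_equal(meanFieldTheta(c(2, 0)), 2)
  expect_equal(meanFieldTheta(c(0, 0)), 0)
  expect_equal(meanFieldTheta(c(1, 1), sigmaY = 1), 2)
  st <- neuronState(c(1, 1))
  expect_equal(meanFieldTheta(st, makePair2d(0.4)),
               mean((rowSums(patterns(makePair2d(0.4))))^2))
})

test_that("compiled loop reproduces the R single-step loop exactly", {
  ens <- makePair2d(0.4)
  for (cfg in list(pairCfg("standard", dt = 1, seed = 21L),
                   pairCfg("weight_dependent", u = 1.3, sigmaY = 0.4,
                           dt = 1, seed = 22L))) {
    ref <- rReferenceLoop(ens, cfg, 400)
    tr <- simulateBCM(ens, cfg, nPresentations = 400, recordEvery = 1000,
                      convTol = 0)
    expect_identical(finalState(tr)@w, ref@w)
    expect_identical(finalState(tr)@theta, ref@theta)
  }
})

test_that("an all-zero stimulus matrix leaves the neuron untouched", {
  cfg <- pairCfg(dt = 1)
  tr <- simulateBCM(matrix(0, 2, 3), cfg, nPresentations = 50,
                    convTol = 0, recordEvery = 100)
  expect_equal(finalState(tr)@w, numeric(3), tolerance = 0.11)  # init only
  expect_equal(finalState(tr)@theta, 0)
  w0 <- withr::with_seed(cfg@rngSeed, runif(3, 0, 0.1))
  expect_equal(finalState(tr)@w, w0)
})

test_that("noiseless standard learning reaches the analytic fixed point", {
  ens <- makePair2d(0.4)
  cfg <- pairCfg("standard", dt = 0.01, seed = 42L)
  tr <- simulateBCM(ens, cfg, nPresentations = 1e5)
  expect_true(isConverged(tr))
  w <- finalState(tr)@w
  fps <- standardFixedPoints(ens)[1:2]
  d <- vapply(fps, function(f) max(abs(f@wStar - w) / (abs(f@wStar))), 0)
  expect_lt(min(d), 1e-3)  # relative match to 2 X^{-1} e_m

  # threshold consistency: epoch-averaged online theta vs mean-field value
  y <- as.numeric(patterns(ens) %*% w)
  expect_equal(thetaEpochMean(tr), meanFieldTheta(y), tolerance = 5e-3)

  # and the mean-field threshold mode lands on the exact fixed point
  cfgMf <- pairCfg("standard", dt = 0.05, seed = 42L,
                   thresholdMode = "mean_field")
  trMf <- simulateBCM(ens, cfgMf, nPresentations = 1e5)
  yMf <- as.numeric(patterns(ens) %*% finalState(trMf)@w)
  expect_equal(max(yMf), 2, tolerance = 1e-5)
  expect_equal(finalState(trMf)@theta, 2, tolerance = 1e-5)
})

test_that("weight-dependent equilibrium balances the two patterns", {
  ens <- makePair2d(0.4)
  X <- patterns(ens)
  cfg <- pairCfg("weight_dependent", u = 1.3, seed = 7L)
  tr <- simulateBCM(ens, cfg, nPresentations = 4e5)
  w <- finalState(tr)@w
  y <- as.numeric(X %*% w)
  expect_true(all(y > 0))          # both patterns keep driving the neuron
  expect_gt(max(y) / min(y), 2)    # but one is clearly preferred

  # per-pattern updates cancel: Delta w^(1) ~ -Delta w^(2), componentwise
  theta <- meanFieldTheta(y)
  drv <- y * (y - theta)
  g <- function(k) if (drv[k] < 0) w + cfg@u else 1
  d1 <- g(1) * X[1, ] * drv[1]
  d2 <- g(2) * X[2, ] * drv[2]
  expect_true(all(abs(d1 + d2) < 0.05 * pmax(abs(d1), abs(d2))))
  expect_gt(max(abs(d1)), 0.01)    # the individual updates are not zero
})

test_that("divergent parameter regimes abort with a diagnostic", {
  ens <- makePair2d(0.4)
  # tauTheta slower than tauW destabilises the threshold feedback
  cfg <- plasticityConfig(rule = "standard", tauTheta = 2000, tauW = 2,
                          dt = 1, rngSeed = 1L)
  expect_error(suppressWarnings(
    simulateBCM(ens, cfg, nPresentations = 5e4, convTol = 0)),
    "diverged|unstable")
})

test_that("equilibrium statistics summarise the sampled window", {
  ens <- makePair2d(0.4)
  cfg <- pairCfg("standard", dt = 0.05, sigmaY = 0.5, seed = 11L)
  tr <- simulateBCM(ens, cfg, nPresentations = 2e5, recordEvery = 101)
  es <- equilibriumStats(tr, fraction = 0.5)
  expect_length(es$responses, 2)
  expect_true(all(is.finite(es$responsesSE)))
  expect_gt(es$nSamples, 100)
  # noise-free recorded responses stay within the transfer's linear range
  expect_true(all(abs(responseSamples(tr)) < 10))
})
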