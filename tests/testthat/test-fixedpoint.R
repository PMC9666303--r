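test_that("standard fixed points are K times the inverse-matrix columns", {
  fps <- standardFixedPoints(makePair2d(0))
  expect_equal(fps[[1]]@wStar, c(2, 0))
  expect_equal(fps[[2]]@wStar, c(0, 2))

  ens <- makePair2d(0.4)
  X <- patterns(ens)
  fps <- standardFixedPoints(ens)
  expect_equal(fps[[1]]@wStar, as.numeric(2 * solve(X)[, 1]))
  expect_equal(fps[[1]]@wStar, c(2.644, -1.118), tolerance = 1e-3)
  expect_equal(as.numeric(X %*% fps[[1]]@wStar), c(2, 0))
  expect_equal(fps[[1]]@thetaStar, 2)

  # symmetric points: origin and the equal-response point y = theta = 1
  cls <- vapply(fps, fpClassification, "")
  expect_identical(cls, c("standard_bcm", "standard_bcm",
                          "symmetric_unstable", "symmetric_unstable"))
  expect_equal(fps[[3]]@wStar, c(0, 0))
  expect_equal(as.numeric(X %*% fps[[4]]@wStar), c(1, 1))

  # higher-dimensional generalisation: responses are K e_m.  (The width
  # must keep the circulant spectrum away from zero: at omega = 0.5 with
  # even N the triangular profile's DFT has exact zeros and the pattern
  # matrix is singular, which standardFixedPoints correctly rejects.)
  expect_error(standardFixedPoints(makeTriangular(20, 20, 0.5)), "singular")
  ens20 <- makeTriangular(20, 20, 0.7)
  fp20 <- standardFixedPoints(ens20)
  for (m in c(1L, 7L, 20L)) {
    y <- as.numeric(patterns(ens20) %*% fp20[[m]]@wStar)
    expect_equal(y, replace(numeric(20), m, 20))
  }

  expect_error(standardFixedPoints(makePair2d(pi / 4)), "singular")
})

test_that("mean update vanishes exactly at fixed points", {
  ens <- makePair2d(0.4)
  stdCfg <- plasticityConfig(rule = "standard")
  wdCfg <- plasticityConfig(rule = "weight_dependent", u = 2.3)
  fp <- standardFixedPoints(ens)[[1]]

  expect_equal(meanUpdate(fp@wStar, ens, stdCfg), c(0, 0))
  # above u*, also a fixed point of the weight-dependent rule
  expect_equal(meanUpdate(fp@wStar, ens, wdCfg), c(0, 0))

  wdCfg13 <- plasticityConfig(rule = "weight_dependent", u = 1.3)
  fps <- wdFixedPoints2d(ens, wdCfg13, assessStability = FALSE)
  expect_length(fps, 2)
  for (f in fps)
    expect_lt(max(abs(meanUpdate(f@wStar, ens, wdCfg13))), 1e-10)
})

test_that("weight-dependent fixed points appear only below u*", {
  ens <- makePair2d(0.4)
  cfg13 <- plasticityConfig(rule = "weight_dependent", u = 1.3)
  fps <- wdFixedPoints2d(ens, cfg13)
  expect_length(fps, 2)
  expect_true(all(vapply(fps, isStable, TRUE)))
  expect_true(all(vapply(fps, isAccessible, TRUE)))
  # mirror images of each other
  expect_equal(fps[[1]]@wStar, rev(fps[[2]]@wStar))
  # both patterns drive the neuron, one preferred
  for (f in fps) expect_true(all(f@responses > 0))

  cfg23 <- plasticityConfig(rule = "weight_dependent", u = 2.3)
  expect_length(wdFixedPoints2d(ens, cfg23), 0)
})

test_that("piecewise stability verdicts match the phase portraits", {
  ens <- makePair2d(0.4)
  for (u in c(1.3, 2.3)) {
    cfg <- plasticityConfig(rule = "weight_dependent", u = u)
    fps <- standardFixedPoints(ens, u = u)
    fps <- lapply(fps, fpStability, ensemble = ens, cfg = cfg)
    # origin and symmetric equal-response point are always unstable
    expect_false(fps[[3]]@stable)
    expect_false(fps[[4]]@stable)
    # winner-take-all points: unstable below u*, stable above
    expect_identical(fps[[1]]@stable, u > 1.94)
    expect_identical(fps[[2]]@stable, u > 1.94)
  }
  # under the standard rule the winner-take-all points are stable
  stdCfg <- plasticityConfig(rule = "standard")
  f <- fpStability(standardFixedPoints(ens)[[1]], ens, stdCfg)
  expect_true(f@stable)
})

test_that("critical inhibition levels match closed forms and limits", {
  ens <- makePair2d(0.4)
  us <- criticalInhibitionUpper(ens)
  expect_equal(unname(us[1]), unname(us[2]))  # mirrored pair: both coincide
  expect_equal(unname(us[1]), 1.9367, tolerance = 1e-4)
  expect_equal(unname(us[1]), uStarPair2d(0.4), tolerance = 1e-10)

  uss <- criticalInhibitionLower(ens)
  expect_equal(uss, -0.7631, tolerance = 1e-4)
  expect_equal(uss, uStarStarPair2d(0.4), tolerance = 1e-10)
  expect_equal(uStarStarPair2d(pi / 4), -1 / sqrt(2))

  # closed-form agreement across the angle range
  for (phi in c(0.1, 0.25, 0.55, 0.7)) {
    e <- makePair2d(phi)
    expect_equal(unname(criticalInhibitionUpper(e)[1]), uStarPair2d(phi),
                 tolerance = 1e-10)
    expect_equal(criticalInhibitionLower(e), uStarStarPair2d(phi),
                 tolerance = 1e-10)
  }

  # orthogonal stimuli need no inhibition: u* -> 0 as phi -> 0
  expect_lt(uStarPair2d(1e-4), 1e-3)
  expect_error(criticalInhibitionUpper(makePair2d(pi / 4)), "singular")
})

test_that("weight-dependent points merge into the standard points at u*", {
  ens <- makePair2d(0.4)
  std <- standardFixedPoints(ens)[[1]]@wStar
  us <- seq(1.3, 1.93, length.out = 8)
  d <- vapply(us, function(u) {
    fps <- wdFixedPoints2d(ens,
                           plasticityConfig(rule = "weight_dependent", u = u),
                           assessStability = FALSE)
    nearestFpDistance(std, fps)
  }, 0)
  expect_true(all(diff(d) < 0))   # monotone approach
  expect_lt(d[length(d)], 0.05)   # essentially merged just below u*
  expect_length(wdFixedPoints2d(ens,
    plasticityConfig(rule = "weight_dependent", u = 1.95),
    assessStability = FALSE), 0)
})

test_that("null-cline intersections count the fixed points", {
  ens <- makePair2d(0.4)
  nc13 <- nullclines2d(ens, plasticityConfig(rule = "weight_dependent",
                                             u = 1.3))
  expect_identical(nc13$nCrossings, 5L)
  nc23 <- nullclines2d(ens, plasticityConfig(rule = "weight_dependent",
                                             u = 2.3))
  expect_identical(nc23$nCrossings, 3L)
  expect_true(length(nc13$curves1) > 0 && length(nc13$curves2) > 0)

  # under the standard rule the crossings coincide with the analytic points
  stdCfg <- plasticityConfig(rule = "standard")
  ncS <- nullclines2d(ens, stdCfg)
  an <- standardFixedPoints(ens)
  for (i in seq_len(nrow(ncS$fixedPoints)))
    expect_lt(nearestFpDistance(ncS$fixedPoints[i, ], an), 1e-6)
})

test_that("grid search finds exactly the analytic fixed points", {
  ens <- makePair2d(0.4)
  for (u in c(1.3, 2.3)) {
    cfg <- plasticityConfig(rule = "weight_dependent", u = u)
    rep <- analyzeFixedPoints(ens, cfg)
    analytic <- Filter(function(f) max(abs(f@wStar)) > 1e-9, rep$fixedPoints)
    grid <- locateFixedPointsGrid(ens, cfg,
                                  w1 = seq(-u + 0.01, 3.5, length.out = 161),
                                  w2 = seq(-u + 0.01, 3.5, length.out = 161))
    expect_identical(nrow(grid), length(analytic))
    for (i in seq_len(nrow(grid)))
      expect_lt(nearestFpDistance(grid[i, ], analytic), 1e-6)
  }
})

test_that("analytic noisy fixed points follow the quadratic solution", {
  expect_equal(noiseFixedPoints(0)$responses, c(2, 0))
  expect_equal(noiseFixedPoints(0)$theta, 2)
  expect_equal(noiseFixedPoints(0.6)$responses, c(1.8, 0.2))
  expect_equal(noiseFixedPoints(1)$responses, c(1, 1))
  expect_equal(noiseFixedPoints(1)$theta, 2)
  expect_equal(noiseFixedPoints(1.5)$theta, 1 + 1.5^2)
  # sum rule below the collapse
  for (s in seq(0, 0.99, by = 0.11))
    expect_equal(sum(noiseFixedPoints(s)$responses), 2)
  expect_error(noiseFixedPoints(-0.1), "sigmaY")
})

test_that("simulated noisy equilibria match the analytic responses", {
  ens <- makePair2d(0.4)
  conds <- list(list(sigma = 0.3, tt = 500, tw = 5000, n = 4e6),
                list(sigma = 0.6, tt = 500, tw = 5000, n = 4e6),
                list(sigma = 0.9, tt = 500, tw = 5000, n = 8e6))
  for (cn in conds) {
    cfg <- plasticityConfig(rule = "standard", tauTheta = cn$tt,
                            tauW = cn$tw, sigmaY = cn$sigma, dt = 0.1,
                            rngSeed = 11L)
    tr <- simulateBCM(ens, cfg, nPresentations = cn$n, recordEvery = 101)
    es <- equilibriumStats(tr, fraction = 0.5, nBatches = 5)
    an <- sort(noiseFixedPoints(cn$sigma)$responses, decreasing = TRUE)
    sim <- sort(es$responses, decreasing = TRUE)
    se <- es$responsesSE[order(es$responses, decreasing = TRUE)]
    for (i in 1:2)
      expect_lt(abs(sim[i] - an[i]), 3 * se[i])
  }
})

test_that("pinned fixed point is classified and stable below u**", {
  ens <- makePair2d(0.4)
  uss <- criticalInhibitionLower(ens)
  cfg <- plasticityConfig(rule = "weight_dependent", u = uss - 0.1)
  rep <- analyzeFixedPoints(ens, cfg)
  cls <- vapply(rep$fixedPoints, fpClassification, "")
  pin <- rep$fixedPoints[[which(cls == "pinned_at_bound")]]
  expect_equal(pin@wStar, rep(-cfg@u, 2))
  expect_true(pin@stable)
})
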