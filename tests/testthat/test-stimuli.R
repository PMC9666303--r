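test_that("mirrored pair ensemble matches its parametrization", {
  expect_equal(patterns(makePair2d(0)), diag(2))

  Xp <- patterns(makePair2d(pi / 4))
  expect_equal(Xp[1, ], Xp[2, ])
  expect_equal(det(Xp), 0)

  X <- patterns(makePair2d(0.4))
  expect_equal(X, rbind(c(cos(0.4), sin(0.4)), c(sin(0.4), cos(0.4))))
  expect_equal(X[1, ], c(0.92106, 0.38942), tolerance = 1e-5)
  expect_equal(sqrt(rowSums(X^2)), c(1, 1))
  expect_equal(X, t(X))
  # mirrored pair: crossprod has equal diagonal entries
  G <- crossprod(X)
  expect_equal(G[1, 1], G[2, 2])

  expect_error(makePair2d(-0.1), "phi")
  expect_error(makePair2d(pi / 2), "phi")
})

test_that("triangular ensemble has the clipped circular profile", {
  expect_equal(patterns(makeTriangular(4, 4, 0.5))[1, ], c(1, 0, 0, 0))

  X <- patterns(makeTriangular(20, 20, 0.5))
  expect_equal(X[1, 2], 0.8)   # slope 2/(N omega) = 0.2, distance 1
  expect_equal(X[1, 6], 0)     # clipped at distance 5
  expect_equal(diag(X), rep(1, 20))  # peak at i = k
  expect_true(all(X >= 0))

  expect_error(makeTriangular(20, omega = 0), "omega")
  expect_error(makeTriangular(1, 1, 0.5), "N >= 2")
})

test_that("von Mises ensemble matches the closed form", {
  X <- patterns(makeVonMises(20))
  expect_equal(diag(X), rep(exp(-2), 20))
  expect_equal(X[1, 11], 1)          # i - k = N/2
  expect_equal(X[1, 6], exp(-1))     # i - k = 5 = N/4
})

test_that("circulant ensembles are circular shifts of the first pattern", {
  for (ens in list(makeTriangular(12, 12, 0.5), makeVonMises(9, 9))) {
    X <- patterns(ens)
    for (k in seq_len(nrow(X) - 1L))
      expect_equal(X[k + 1L, ], X[1L, ((seq_len(ncol(X)) - 1L - k) %%
                                         ncol(X)) + 1L])
  }
})

test_that("synthetic images are deterministic, bounded and 1/f", {
  a <- generateSyntheticImages(3, 64, seed = 7L)
  b <- generateSyntheticImages(3, 64, seed = 7L)
  expect_identical(a, b)
  expect_identical(dim(a), c(64L, 64L, 3L))
  expect_true(min(a) >= 0 && max(a) <= 1)

  slopes <- vapply(1:3, function(j) amplitudeSpectrumSlope(a[, , j]), 0)
  expect_true(all(abs(slopes + 1) < 0.25))

  expect_error(generateSyntheticImages(0, 64), "positive")
  expect_error(generateSyntheticImages(2, 16), "at least 32")
})

test_that("balanced DoG kernel annihilates constants", {
  k <- dogKernel()
  expect_lt(abs(sum(k)), 1e-10)
  expect_gt(k[(nrow(k) + 1) / 2, (ncol(k) + 1) / 2], 0)  # centre-on
  expect_error(dogKernel(3, 1), "surround")
})

test_that("image patches have the configured geometry and scaling", {
  imgs <- generateSyntheticImages(2, 72, seed = 4L)
  cfg <- imagePipelineConfig(nPatches = 40, rngSeed = 9L)
  ens <- makeImagePatches(imgs, cfg, zeroMean = FALSE)
  expect_identical(dim(patterns(ens)), c(40L, 400L))  # 400-pixel patches
  expect_true(min(patterns(ens)) >= 0 && max(patterns(ens)) <= 1)
  expect_equal(min(patterns(ens)), 0)
  expect_equal(max(patterns(ens)), 1)

  # pure function of (images, cfg)
  ens2 <- makeImagePatches(imgs, cfg, zeroMean = FALSE)
  expect_identical(patterns(ens), patterns(ens2))

  ensz <- makeImagePatches(imgs, cfg, zeroMean = TRUE)
  expect_lt(abs(mean(patterns(ensz))), 1e-12)
  expect_true(isZeroMean(ensz) && min(patterns(ensz)) < 0)

  # a constant image gives (near-)zero DoG response before rescaling
  ensc <- makeImagePatches(matrix(0.3, 72, 72),
                           imagePipelineConfig(nPatches = 3, rngSeed = 1L))
  expect_lt(diff(ensembleParams(ensc)$rawRange), 1e-12)

  expect_error(makeImagePatches(matrix(0.5, 30, 30),
                                imagePipelineConfig(nPatches = 2)),
               "too small")
})

test_that("ensembles round-trip through the text serialisation", {
  dir <- withr::local_tempdir()
  ens <- makeTriangular(8, 8, 0.5)
  f <- file.path(dir, "ens.tsv")
  writeEnsemble(ens, f)
  back <- readEnsemble(f)
  expect_equal(patterns(back), patterns(ens))
  expect_identical(ensembleKind(back), "triangular")
  expect_equal(ensembleParams(back)$omega, 0.5)
})

test_that("ensemble validity rejects malformed pattern matrices", {
  expect_error(new("StimulusEnsemble",
                   patterns = matrix(-1, 2, 2), kind = "triangular",
                   params = list(), zeroMean = FALSE), "non-negative")
  expect_error(new("StimulusEnsemble",
                   patterns = rbind(c(1, 0), c(0, 0)), kind = "triangular",
                   params = list(), zeroMean = FALSE), "nonzero")
})
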