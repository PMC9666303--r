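# Reference implementations and small builders shared across tests.

# Pure-R presentation loop built from the exported single-step functions;
# mirrors the compiled loop (same RNG draw order) for dt = 1.
rReferenceLoop <- function(ensemble, cfg, nPresentations) {
  stopifnot(cfg@dt == 1)
  X <- patterns(ensemble)
  K <- nrow(X)
  set.seed(cfg@rngSeed)
  w0 <- runif(ncol(X), 0, 0.1)
  perm <- sample.int(K)
  st <- neuronState(w0, 0)
  for (p in seq_len(nPresentations)) {
    k <- perm[(p - 1) %% K + 1]
    y <- transferFunction(sum(st@w * X[k, ]), cfg@transfer)
    yt <- y + if (cfg@sigmaY > 0) rnorm(1, 0, cfg@sigmaY) else 0
    st <- stepThreshold(st, yt, cfg)
    st <- stepWeights(st, X[k, ], cfg, yTilde = yt)
  }
  st
}

pairCfg <- function(rule = "standard", u = 0, sigmaY = 0, dt = 0.05,
                    seed = 1L, ...) {
  plasticityConfig(rule = rule, u = u, tauTheta = 20, tauW = 200,
                   sigmaY = sigmaY, dt = dt, rngSeed = seed, ...)
}

# Euclidean distance from a weight vector to the nearest fixed point of a
# report list.
nearestFpDistance <- function(w, fps) {
  if (!length(fps)) return(Inf)
  min(vapply(fps, function(f) sqrt(sum((f@wStar - w)^2)), 0))
}
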