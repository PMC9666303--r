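#' Evaluate a transfer function
#'
#' @param h net input (any numeric vector).
#' @param spec a [TransferSpec-class]; default linear.
#' @return the activity `y`.  For `"bi_sigmoid"`,
#'   `y = sigmaMinus * tanh(h / sigmaMinus)` for negative drive and
#'   `y = sigmaPlus * tanh(h / sigmaPlus)` otherwise, continuous at 0.
#' @export
transferFunction <- function(h, spec = transferSpec("linear")) {
  switch(spec@kind,
         linear = h,
         rectified = pmax(0, h),
         bi_sigmoid = ifelse(h < 0,
                             spec@sigmaMinus * tanh(h / spec@sigmaMinus),
                             spec@sigmaPlus * tanh(h / spec@sigmaPlus)))
}

#' BCM modification drive
#'
#' The activity-dependent factor `F(y) = y (y - theta)` of the BCM rule:
#' negative (depression) for `0 < y < theta`, positive (potentiation) for
#' `y > theta`.
#'
#' @param y post-synaptic activity.
#' @param theta modification threshold.
#' @return `y * (y - theta)`, vectorised.
#' @export
bcmModification <- function(y, theta) y * (y - theta)

#' One Euler threshold update
#'
#' `theta <- theta + (dt / tauTheta) (ytilde^2 - theta)`: the threshold is a
#' low-pass filter of the squared (noisy) activity.
#'
#' @param state a [NeuronState-class].
#' @param yTilde the (noisy) activity driving the update.
#' @param cfg a [PlasticityConfig-class] supplying `dt` and `tauTheta`.
#' @return the updated [NeuronState-class].
#' @export
stepThreshold <- function(state, yTilde, cfg) {
  state@theta <- state@theta +
    (cfg@dt / cfg@tauTheta) * (yTilde^2 - state@theta)
  state
}

#' One Euler weight update
#'
#' Standard rule: `w_i <- w_i + (dt / tauW) x_i F(ytilde, theta)`.  Weight
#' dependent rule: when `F < 0` (depression) the update is additionally
#' proportional to the excitatory weight, `w_i + u`, so the excitatory
#' weight `v = w + u` decays multiplicatively and cannot cross zero; the
#' multiplicative factor is clamped at zero should a single step overshoot
#' (guard trips are counted in the `"guardTrips"` attribute).  Potentiation
#' is identical under both rules.  If an effective weight sits below `-u`
#' the depression branch (applied with the negative factor `w_i + u`)
#' produces potentiation, so the synapse returns towards the excitatory
#' range by itself.
#'
#' @param state a [NeuronState-class] whose threshold has already been
#'   updated for this presentation.
#' @param x the input pattern (length `N`).
#' @param cfg a [PlasticityConfig-class].
#' @param yTilde optional noisy activity; if `NULL` it is computed from the
#'   state and `x` (drawing fresh Gaussian noise when `cfg@sigmaY > 0`).
#' @return the updated [NeuronState-class].
#' @export
stepWeights <- function(state, x, cfg, yTilde = NULL) {
  if (any(!is.finite(state@w)) || !is.finite(state@theta))
    stop("non-finite neuron state: weight dynamics diverged")
  if (is.null(yTilde)) {
    y <- transferFunction(sum(state@w * x), cfg@transfer)
    yTilde <- y + if (cfg@sigmaY > 0) rnorm(1L, 0, cfg@sigmaY) else 0
  }
  F <- bcmModification(yTilde, state@theta)
  trips <- 0L
  if (cfg@rule == "weight_dependent" && F < 0) {
    fac <- 1 + (cfg@dt / cfg@tauW) * x * F
    trips <- sum(fac < 0)
    fac <- pmax(fac, 0)
    state@w <- (state@w + cfg@u) * fac - cfg@u
  } else {
    state@w <- state@w + (cfg@dt / cfg@tauW) * x * F
  }
  attr(state, "guardTrips") <- trips
  state
}

#' Mean-field modification threshold
#'
#' The sliding threshold replaced by its stimulus average,
#' `theta = (1/K) sum_k (y^(k))^2`, plus `sigmaY^2` when analysing noisy
#' dynamics (the noise contributes its variance to the average squared
#' activity).
#'
#' @param responses per-pattern noise-free responses, or a
#'   [NeuronState-class] together with `ensemble`.
#' @param ensemble optional [StimulusEnsemble-class] used to compute the
#'   responses from a state.
#' @param cfg optional [PlasticityConfig-class] supplying the transfer
#'   function when responses are computed from a state.
#' @param sigmaY noise s.d. entering as `+ sigmaY^2`; default 0.
#' @return the mean-field threshold (numeric scalar).
#' @examples
#' meanFieldTheta(c(2, 0))            # 2
#' meanFieldTheta(c(1, 1), sigmaY = 1)  # 2
#' @export
meanFieldTheta <- function(responses, ensemble = NULL, cfg = NULL,
                           sigmaY = 0) {
  if (is(responses, "NeuronState")) {
    if (is.null(ensemble)) stop("need an ensemble to compute responses")
    spec <- if (is.null(cfg)) transferSpec("linear") else cfg@transfer
    responses <- as.numeric(
      transferFunction(ensembleMatrix(ensemble) %*% responses@w, spec))
  }
  if (!length(responses)) stop("ensemble must be nonempty")
  mean(responses^2) + sigmaY^2
}

#' Simulate BCM learning on a stimulus ensemble
#'
#' Presents the patterns in a randomly permuted, fixed sequence (the
#' permutation is drawn once and reused every epoch), integrating the
#' coupled threshold and weight updates with explicit Euler substeps of
#' `cfg@dt` presentations.  Within each presentation a single Gaussian
#' noise value is drawn (if `cfg@sigmaY > 0`) and added to the activity;
#' per substep the threshold is updated first and the weight update uses
#' the same activity with the updated threshold.  The run stops early once
#' the net weight change over one epoch falls below
#' `convTol * (1 + max |w|)` (noise-free runs only).
#'
#' @param ensemble a [StimulusEnsemble-class].
#' @param cfg a [PlasticityConfig-class]; `cfg@rngSeed` fixes the weight
#'   initialisation, presentation order and noise stream.
#' @param init optional initial [NeuronState-class]; by default effective
#'   weights are drawn uniformly from `(0, 0.1)` and the threshold starts
#'   at zero (it is pulled towards the running average of the squared
#'   activity within a few `tauTheta`).
#' @param nPresentations maximum number of pattern presentations (`>= K`).
#' @param recordEvery sampling interval in presentations (default:
#'   `max(1, nPresentations / 1000)`).
#' @param convTol epoch-level convergence tolerance (set to 0 to disable).
#' @return a [Trajectory-class]; recorded responses are noise-free.
#' @examples
#' ens <- makePair2d(0.4)
#' cfg <- plasticityConfig(tauTheta = 20, tauW = 200, rngSeed = 1L)
#' traj <- simulateBCM(ens, cfg, nPresentations = 20000)
#' fpResponses <- responseSamples(traj)[length(sampleTimes(traj)), ]
#' @export
simulateBCM <- function(ensemble, cfg, init = NULL, nPresentations = 1e5,
                        recordEvery = NULL, convTol = 1e-9) {
  X <- ensembleMatrix(ensemble)
  K <- nrow(X); N <- ncol(X)
  if (nPresentations < K) stop("need at least K presentations")
  if (cfg@tauTheta < K)
    warning(sprintf("tauTheta (%g) below the number of patterns (%d); threshold may not average the ensemble", cfg@tauTheta, K))
  if (cfg@tauW < cfg@tauTheta)
    warning("tauW below tauTheta; weight dynamics may be unstable")
  if (is.null(recordEvery))
    recordEvery <- max(1L, floor(nPresentations / 1000))
  recordEvery <- as.integer(recordEvery)
  # avoid phase-locking the samples to the presentation cycle
  if (K > 1L && recordEvery > 1L && recordEvery %% K == 0L)
    recordEvery <- recordEvery + 1L

  res <- withSeed(cfg@rngSeed, {
    if (is.null(init)) {
      w0 <- runif(N, 0, 0.1)
    } else {
      stopifnot(is(init, "NeuronState"), length(init@w) == N)
      w0 <- init@w
    }
    perm <- sample.int(K) - 1L
    theta0 <- if (is.null(init)) 0 else init@theta
    cpp_bcm_run(X, perm, w0, theta0,
                rule = if (cfg@rule == "weight_dependent") 1L else 0L,
                u = cfg@u, tau_w = cfg@tauW, tau_theta = cfg@tauTheta,
                sigma_y = cfg@sigmaY, dt = cfg@dt,
                transfer = match(cfg@transfer@kind,
                                 c("linear", "rectified", "bi_sigmoid")) - 1L,
                sigma_minus = cfg@transfer@sigmaMinus,
                sigma_plus = cfg@transfer@sigmaPlus,
                theta_mode = if (cfg@thresholdMode == "mean_field") 1L else 0L,
                n_pres = as.integer(nPresentations),
                record_every = recordEvery, conv_tol = convTol,
                w_cap = 1e6)
  })

  final <- neuronState(res$w, res$theta)
  # always include the final state as the last sample
  times <- res$rec_t; ws <- res$rec_w; ths <- res$rec_theta; ys <- res$rec_y
  if (!length(times) || times[length(times)] != res$n_done) {
    times <- c(times, res$n_done)
    ws <- rbind(ws, res$w)
    ths <- c(ths, res$theta)
    ys <- rbind(ys, as.numeric(transferFunction(X %*% res$w, cfg@transfer)))
  }
  new("Trajectory", times = times, wSamples = ws, thetaSamples = ths,
      responses = ys, converged = res$converged, finalState = final,
      nPresentations = res$n_done, guardTrips = res$guard_trips,
      thetaEpochMean = res$theta_epoch_mean)
}

#' Equilibrium statistics of a trajectory
#'
#' Means and batch-means standard errors of the noise-free responses, the
#' threshold and the weights over the final portion of the recorded samples.
#' For noise-free converged runs the window statistics coincide with the
#' final state; for noisy runs they estimate the stochastic equilibrium.
#'
#' @param traj a [Trajectory-class].
#' @param fraction fraction of recorded samples (from the end) to average
#'   over.
#' @param nBatches number of batches for the batch-means standard error.
#' @return a list with `responses`, `responsesSE`, `theta`, `thetaSE`,
#'   `w`, and the window size `nSamples`.
#' @export
equilibriumStats <- function(traj, fraction = 0.25, nBatches = 10) {
  ns <- length(traj@times)
  take <- max(2L, ceiling(ns * fraction))
  idx <- seq.int(ns - take + 1L, ns)
  Y <- traj@responses[idx, , drop = FALSE]
  th <- traj@thetaSamples[idx]
  W <- traj@wSamples[idx, , drop = FALSE]
  nb <- min(nBatches, length(idx) %/% 2)
  batchSE <- function(v) {
    if (nb < 2) return(NA_real_)
    bm <- tapply(v, cut(seq_along(v), nb, labels = FALSE), mean)
    sd(bm) / sqrt(nb)
  }
  list(responses = colMeans(Y),
       responsesSE = apply(Y, 2L, batchSE),
       theta = mean(th), thetaSE = batchSE(th),
       w = colMeans(W), nSamples = length(idx))
}
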