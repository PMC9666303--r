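#' StimulusEnsemble: a set of input patterns
#'
#' A `K x N` matrix of input firing rates, one pattern per row, together with
#' metadata on how it was generated.  Entries are non-negative rates except
#' for the zero-mean image-patch variant used for Gabor-like receptive field
#' development, where the ensemble mean has been subtracted.
#'
#' @slot patterns numeric matrix, `K` patterns by `N` inputs.
#' @slot kind character, one of `"pair2d"`, `"triangular"`, `"von_mises"`,
#'   `"image_patches"`.
#' @slot params list of generator parameters (e.g. `phi`, `omega`, `N`, `K`).
#' @slot zeroMean logical, `TRUE` only for the zero-mean image pipeline.
#'
#' @seealso [makePair2d()], [makeTriangular()], [makeVonMises()],
#'   [makeImagePatches()]
#' @export
setClass("StimulusEnsemble",
  representation(patterns = "matrix", kind = "character", params = "list",
                 zeroMean = "logical"),
  prototype(kind = "pair2d", params = list(), zeroMean = FALSE))

setValidity("StimulusEnsemble", function(object) {
  msg <- character()
  X <- object@patterns
  if (!is.numeric(X)) msg <- c(msg, "patterns must be numeric")
  if (!object@kind %in% c("pair2d", "triangular", "von_mises", "image_patches"))
    msg <- c(msg, "unknown ensemble kind")
  if (length(object@zeroMean) != 1L) msg <- c(msg, "zeroMean must be a flag")
  if (nrow(X) < 1L || ncol(X) < 2L)
    msg <- c(msg, "need at least one pattern and two inputs")
  if (any(!is.finite(X))) msg <- c(msg, "patterns must be finite")
  else {
    if (!object@zeroMean && any(X < 0))
      msg <- c(msg, "patterns must be non-negative unless zeroMean")
    if (any(apply(abs(X), 1L, max) == 0))
      msg <- c(msg, "every pattern needs at least one nonzero entry")
    if (object@kind == "pair2d" &&
        any(abs(sqrt(rowSums(X^2)) - 1) > 1e-12))
      msg <- c(msg, "pair2d patterns must have unit Euclidean norm")
  }
  if (length(msg)) msg else TRUE
})

#' TransferSpec: the neuron's input-output function
#'
#' Linear (`y = h`), rectified (`y = max(0, h)`), or the bi-sigmoid used for
#' receptive-field development: `y = sigma_- tanh(h/sigma_-)` for `h < 0` and
#' `y = sigma_+ tanh(h/sigma_+)` for `h >= 0`, so that the output saturates
#' within `(-sigma_-, sigma_+)` while remaining approximately linear for
#' small drive.
#'
#' @slot kind character, `"linear"`, `"rectified"` or `"bi_sigmoid"`.
#' @slot sigmaMinus positive saturation level for negative drive (default 0.01).
#' @slot sigmaPlus positive saturation level for positive drive (default 50).
#' @export
setClass("TransferSpec",
  representation(kind = "character", sigmaMinus = "numeric",
                 sigmaPlus = "numeric"),
  prototype(kind = "linear", sigmaMinus = 0.01, sigmaPlus = 50))

setValidity("TransferSpec", function(object) {
  msg <- character()
  if (!object@kind %in% c("linear", "rectified", "bi_sigmoid"))
    msg <- c(msg, "unknown transfer kind")
  if (object@sigmaMinus <= 0 || object@sigmaPlus <= 0)
    msg <- c(msg, "saturation levels must be positive")
  if (length(msg)) msg else TRUE
})

#' PlasticityConfig: learning-rule parameters
#'
#' Bundles the plasticity rule variant, the feed-forward inhibition strength
#' `u` (negative values mean feed-forward excitation), the weight and
#' threshold time constants (in units of stimulus presentations), the
#' post-synaptic noise standard deviation, the transfer function, the Euler
#' substep `dt`, the threshold mode and the RNG seed.
#'
#' @slot rule character, `"standard"` or `"weight_dependent"`.
#' @slot u numeric feed-forward inhibition strength.
#' @slot tauW weight time constant (presentations), `> 0`.
#' @slot tauTheta threshold time constant (presentations), `> 0`.
#' @slot sigmaY post-synaptic Gaussian noise s.d., `>= 0`.
#' @slot transfer a [TransferSpec-class] object.
#' @slot dt Euler substep in units of one presentation; `1/dt` must be a
#'   whole number of substeps.
#' @slot thresholdMode character, `"online"` (Eq.-style low-pass filter of
#'   the squared activity) or `"mean_field"` (threshold recomputed as the
#'   stimulus average of the squared responses each substep).
#' @slot rngSeed integer seed, or `NA` to use the current RNG state.
#' @export
setClass("PlasticityConfig",
  representation(rule = "character", u = "numeric", tauW = "numeric",
                 tauTheta = "numeric", sigmaY = "numeric",
                 transfer = "TransferSpec", dt = "numeric",
                 thresholdMode = "character", rngSeed = "integer"),
  prototype(rule = "standard", u = 0, tauW = 200, tauTheta = 20, sigmaY = 0,
            dt = 0.1, thresholdMode = "online", rngSeed = NA_integer_))

setValidity("PlasticityConfig", function(object) {
  msg <- character()
  if (!object@rule %in% c("standard", "weight_dependent"))
    msg <- c(msg, "rule must be 'standard' or 'weight_dependent'")
  if (object@tauW <= 0 || object@tauTheta <= 0)
    msg <- c(msg, "time constants must be positive")
  if (object@sigmaY < 0) msg <- c(msg, "sigmaY must be >= 0")
  if (object@dt <= 0 || object@dt > 1 ||
      abs(1 / object@dt - round(1 / object@dt)) > 1e-8)
    msg <- c(msg, "dt must be in (0, 1] with 1/dt a whole number")
  if (!object@thresholdMode %in% c("online", "mean_field"))
    msg <- c(msg, "thresholdMode must be 'online' or 'mean_field'")
  if (length(msg)) msg else TRUE
})

#' NeuronState: effective weights and threshold
#'
#' The effective weight vector `w` combines the plastic excitatory weights
#' `v` and the fixed inhibition `u` as `w = v - u`; the excitatory weights
#' are recovered with [excitatoryWeights()].
#'
#' @slot w numeric vector of effective weights.
#' @slot theta numeric scalar, the sliding modification threshold.
#' @export
setClass("NeuronState",
  representation(w = "numeric", theta = "numeric"),
  prototype(w = numeric(), theta = 0))

setValidity("NeuronState", function(object) {
  if (length(object@theta) != 1L || !is.finite(object@theta))
    "theta must be a finite scalar"
  else if (any(!is.finite(object@w))) "weights must be finite"
  else TRUE
})

#' Trajectory: sampled time course of a simulation
#'
#' Regularly sampled weights, threshold and noise-free per-pattern responses,
#' plus the final state and convergence information.
#'
#' @slot times numeric vector of presentation indices at the sample points.
#' @slot wSamples numeric matrix, samples by inputs.
#' @slot thetaSamples numeric vector.
#' @slot responses numeric matrix, samples by patterns; computed with the
#'   noise-free transfer function.
#' @slot converged logical; `TRUE` if the per-epoch net weight change fell
#'   below tolerance (never set for noisy runs).
#' @slot finalState a [NeuronState-class].
#' @slot nPresentations number of presentations actually simulated.
#' @slot guardTrips number of clamped depression substeps (see
#'   [simulateBCM()]).
#' @slot thetaEpochMean time average of the threshold over the last
#'   completed epoch; with the online threshold mode the instantaneous
#'   threshold oscillates within the presentation cycle, so this is the
#'   phase-free equilibrium value.
#' @export
setClass("Trajectory",
  representation(times = "numeric", wSamples = "matrix",
                 thetaSamples = "numeric", responses = "matrix",
                 converged = "logical", finalState = "NeuronState",
                 nPresentations = "numeric", guardTrips = "numeric",
                 thetaEpochMean = "numeric"))

setValidity("Trajectory", function(object) {
  n <- length(object@times)
  if (nrow(object@wSamples) != n || length(object@thetaSamples) != n ||
      nrow(object@responses) != n)
    "sample arrays must share their length"
  else TRUE
})

#' FixedPointReport: a located fixed point of the learning dynamics
#'
#' @slot wStar numeric weight vector at the fixed point.
#' @slot thetaStar threshold at the fixed point (mean-field value).
#' @slot responses per-pattern responses `X w*`.
#' @slot stable logical stability verdict (`NA` if not assessed).
#' @slot classification character: `"standard_bcm"`, `"weight_dependent"`,
#'   `"pinned_at_bound"` or `"symmetric_unstable"`.
#' @slot accessible logical: all excitatory weights `w* + u >= 0`.
#' @slot eigenvalues list of per-branch Jacobian spectra (complex vectors);
#'   several entries for piecewise points.
#' @export
setClass("FixedPointReport",
  representation(wStar = "numeric", thetaStar = "numeric",
                 responses = "numeric", stable = "logical",
                 classification = "character", accessible = "logical",
                 eigenvalues = "list"),
  prototype(stable = NA, accessible = NA, eigenvalues = list()))

setValidity("FixedPointReport", function(object) {
  if (!object@classification %in%
      c("standard_bcm", "weight_dependent", "pinned_at_bound",
        "symmetric_unstable"))
    "unknown fixed-point classification"
  else TRUE
})

#' ImagePipelineConfig: retina-like preprocessing parameters
#'
#' Geometry and filtering parameters for extracting circular
#' difference-of-Gaussians (DoG) filtered patches from greyscale images.
#'
#' @slot patchPixels number of pixels per circular patch (default 400).
#' @slot dogCenterWidth centre Gaussian standard deviation in pixels.
#' @slot dogSurroundWidth surround Gaussian standard deviation in pixels;
#'   must exceed the centre width.
#' @slot nPatches number of patches to sample.
#' @slot rngSeed integer seed for patch placement.
#' @export
setClass("ImagePipelineConfig",
  representation(patchPixels = "numeric", dogCenterWidth = "numeric",
                 dogSurroundWidth = "numeric", nPatches = "numeric",
                 rngSeed = "integer"),
  prototype(patchPixels = 400, dogCenterWidth = 1, dogSurroundWidth = 3,
            nPatches = 1000, rngSeed = 1L))

setValidity("ImagePipelineConfig", function(object) {
  msg <- character()
  if (object@patchPixels <= 0) msg <- c(msg, "patchPixels must be positive")
  if (object@dogSurroundWidth <= object@dogCenterWidth)
    msg <- c(msg, "surround width must exceed centre width")
  if (object@nPatches < 1) msg <- c(msg, "need at least one patch")
  if (length(msg)) msg else TRUE
})

#' PhaseDiagram: selectivity of the stable fixed points over (phi, u)
#'
#' @slot phiValues stimulus-angle grid.
#' @slot uValues inhibition grid.
#' @slot selectivity matrix of selectivity values, `phi` by `u` (NA where
#'   the stimulus matrix is singular).
#' @slot regime character matrix: `"standard_wta"`,
#'   `"weight_dependent_partial"` or `"pinned_unselective"`.
#' @slot boundaries list with the critical-inhibition curves `uStar(phi)`
#'   and `uStarStar(phi)`.
#' @export
setClass("PhaseDiagram",
  representation(phiValues = "numeric", uValues = "numeric",
                 selectivity = "matrix", regime = "matrix",
                 boundaries = "list"))
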