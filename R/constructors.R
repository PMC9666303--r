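#' Create a transfer-function specification
#'
#' @param kind `"linear"`, `"rectified"` or `"bi_sigmoid"`.
#' @param sigmaMinus saturation level for negative drive (bi-sigmoid only).
#' @param sigmaPlus saturation level for positive drive (bi-sigmoid only).
#' @return a [TransferSpec-class] object.
#' @examples
#' transferSpec("bi_sigmoid")
#' @export
transferSpec <- function(kind = c("linear", "rectified", "bi_sigmoid"),
                         sigmaMinus = 0.01, sigmaPlus = 50) {
  kind <- match.arg(kind)
  new("TransferSpec", kind = kind, sigmaMinus = sigmaMinus,
      sigmaPlus = sigmaPlus)
}

#' Create a plasticity configuration
#'
#' Defaults follow the convention that the threshold must average over all
#' `K` patterns while remaining slow relative to single presentations and
#' fast relative to the weights: `tauTheta ~ 10 K` and `tauW = 10 tauTheta`
#' are typical (see [simulateBCM()], which warns outside the stable guidance
#' region `tauTheta >= K`, `tauW >= tauTheta`).
#'
#' @param rule `"standard"` or `"weight_dependent"`.
#' @param u feed-forward inhibition strength (negative = feed-forward
#'   excitation).
#' @param tauW weight time constant in presentations.
#' @param tauTheta threshold time constant in presentations.
#' @param sigmaY post-synaptic Gaussian noise s.d. (`>= 0`).
#' @param transfer a [TransferSpec-class] (default linear).
#' @param dt Euler substep; one presentation is integrated with `1/dt`
#'   substeps.
#' @param thresholdMode `"online"` or `"mean_field"`.
#' @param rngSeed integer seed for weight initialisation, the presentation
#'   permutation and the noise stream, or `NA` to use the current RNG state.
#' @return a [PlasticityConfig-class] object.
#' @examples
#' plasticityConfig(rule = "weight_dependent", u = 1.3, tauTheta = 20,
#'                  tauW = 200, rngSeed = 1L)
#' @export
plasticityConfig <- function(rule = c("standard", "weight_dependent"), u = 0,
                             tauW = 200, tauTheta = 20, sigmaY = 0,
                             transfer = transferSpec("linear"), dt = 0.1,
                             thresholdMode = c("online", "mean_field"),
                             rngSeed = NA) {
  rule <- match.arg(rule)
  thresholdMode <- match.arg(thresholdMode)
  new("PlasticityConfig", rule = rule, u = u, tauW = tauW,
      tauTheta = tauTheta, sigmaY = sigmaY, transfer = transfer, dt = dt,
      thresholdMode = thresholdMode, rngSeed = as.integer(rngSeed))
}

#' Create a neuron state
#'
#' @param w effective weight vector.
#' @param theta threshold.
#' @return a [NeuronState-class] object.
#' @export
neuronState <- function(w, theta = 0) new("NeuronState", w = as.numeric(w),
                                          theta = as.numeric(theta))

#' Create an image-pipeline configuration
#'
#' @param patchPixels pixels per circular patch.
#' @param dogCenterWidth,dogSurroundWidth centre/surround Gaussian widths
#'   (standard deviations, pixels) of the balanced difference-of-Gaussians
#'   retina filter.
#' @param nPatches number of patches to extract.
#' @param rngSeed integer seed for patch placement.
#' @return an [ImagePipelineConfig-class] object.
#' @export
imagePipelineConfig <- function(patchPixels = 400, dogCenterWidth = 1,
                                dogSurroundWidth = 3, nPatches = 1000,
                                rngSeed = 1L) {
  new("ImagePipelineConfig", patchPixels = patchPixels,
      dogCenterWidth = dogCenterWidth, dogSurroundWidth = dogSurroundWidth,
      nPatches = nPatches, rngSeed = as.integer(rngSeed))
}

# Build a StimulusEnsemble, validating invariants.
newEnsemble <- function(patterns, kind, params, zeroMean = FALSE) {
  new("StimulusEnsemble", patterns = patterns, kind = kind, params = params,
      zeroMean = zeroMean)
}

# Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG
# state afterwards; with seed = NA the current stream is used (and consumed).
withSeed <- function(seed, expr) {
  if (is.na(seed)) return(expr)
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}
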