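#' Pattern matrix of a stimulus ensemble
#'
#' @param x a [StimulusEnsemble-class].
#' @return the `K x N` numeric pattern matrix (patterns in rows).
#' @export
setGeneric("patterns", function(x) standardGeneric("patterns"))

#' @rdname patterns
#' @export
setMethod("patterns", "StimulusEnsemble", function(x) x@patterns)

#' Number of patterns / inputs of an ensemble
#'
#' @param x a [StimulusEnsemble-class].
#' @return integer count.
#' @export
setGeneric("nPatterns", function(x) standardGeneric("nPatterns"))

#' @rdname nPatterns
#' @export
setMethod("nPatterns", "StimulusEnsemble", function(x) nrow(x@patterns))

#' @rdname nPatterns
#' @export
setGeneric("nInputs", function(x) standardGeneric("nInputs"))

#' @rdname nPatterns
#' @export
setMethod("nInputs", "StimulusEnsemble", function(x) ncol(x@patterns))

#' Generator kind and parameters of an ensemble
#'
#' @param x a [StimulusEnsemble-class].
#' @return `ensembleKind()` returns the kind string, `ensembleParams()` the
#'   generator parameter list, `isZeroMean()` the zero-mean flag.
#' @export
setGeneric("ensembleKind", function(x) standardGeneric("ensembleKind"))

#' @rdname ensembleKind
#' @export
setMethod("ensembleKind", "StimulusEnsemble", function(x) x@kind)

#' @rdname ensembleKind
#' @export
setGeneric("ensembleParams", function(x) standardGeneric("ensembleParams"))

#' @rdname ensembleKind
#' @export
setMethod("ensembleParams", "StimulusEnsemble", function(x) x@params)

#' @rdname ensembleKind
#' @export
setGeneric("isZeroMean", function(x) standardGeneric("isZeroMean"))

#' @rdname ensembleKind
#' @export
setMethod("isZeroMean", "StimulusEnsemble", function(x) x@zeroMean)

#' Effective and excitatory weights of a neuron state
#'
#' The effective weights are `w = v - u`; `excitatoryWeights()` recovers
#' `v = w + u` for a given feed-forward inhibition strength `u`.
#'
#' @param x a [NeuronState-class] (or [Trajectory-class] for `finalState`).
#' @param u feed-forward inhibition strength.
#' @return numeric weight vector, or scalar threshold for `threshold()`.
#' @export
setGeneric("effectiveWeights", function(x) standardGeneric("effectiveWeights"))

#' @rdname effectiveWeights
#' @export
setMethod("effectiveWeights", "NeuronState", function(x) x@w)

#' @rdname effectiveWeights
#' @export
setGeneric("excitatoryWeights", function(x, u) standardGeneric("excitatoryWeights"))

#' @rdname effectiveWeights
#' @export
setMethod("excitatoryWeights", "NeuronState", function(x, u) x@w + u)

#' @rdname effectiveWeights
#' @export
setGeneric("threshold", function(x) standardGeneric("threshold"))

#' @rdname effectiveWeights
#' @export
setMethod("threshold", "NeuronState", function(x) x@theta)

#' Trajectory accessors
#'
#' @param x a [Trajectory-class].
#' @return the corresponding slot: sample times, weight samples (samples by
#'   inputs), threshold samples, noise-free response samples (samples by
#'   patterns), the final [NeuronState-class], or the convergence flag.
#' @export
setGeneric("sampleTimes", function(x) standardGeneric("sampleTimes"))

#' @rdname sampleTimes
#' @export
setMethod("sampleTimes", "Trajectory", function(x) x@times)

#' @rdname sampleTimes
#' @export
setGeneric("weightSamples", function(x) standardGeneric("weightSamples"))

#' @rdname sampleTimes
#' @export
setMethod("weightSamples", "Trajectory", function(x) x@wSamples)

#' @rdname sampleTimes
#' @export
setGeneric("thetaSamples", function(x) standardGeneric("thetaSamples"))

#' @rdname sampleTimes
#' @export
setMethod("thetaSamples", "Trajectory", function(x) x@thetaSamples)

#' @rdname sampleTimes
#' @export
setGeneric("responseSamples", function(x) standardGeneric("responseSamples"))

#' @rdname sampleTimes
#' @export
setMethod("responseSamples", "Trajectory", function(x) x@responses)

#' @rdname sampleTimes
#' @export
setGeneric("finalState", function(x) standardGeneric("finalState"))

#' @rdname sampleTimes
#' @export
setMethod("finalState", "Trajectory", function(x) x@finalState)

#' @rdname sampleTimes
#' @export
setGeneric("isConverged", function(x) standardGeneric("isConverged"))

#' @rdname sampleTimes
#' @export
setMethod("isConverged", "Trajectory", function(x) x@converged)

#' @rdname sampleTimes
#' @export
setGeneric("thetaEpochMean", function(x) standardGeneric("thetaEpochMean"))

#' @rdname sampleTimes
#' @export
setMethod("thetaEpochMean", "Trajectory", function(x) x@thetaEpochMean)

#' Fixed-point report accessors
#'
#' @param x a [FixedPointReport-class].
#' @return the corresponding slot.
#' @export
setGeneric("fpWeights", function(x) standardGeneric("fpWeights"))

#' @rdname fpWeights
#' @export
setMethod("fpWeights", "FixedPointReport", function(x) x@wStar)

#' @rdname fpWeights
#' @export
setGeneric("fpResponses", function(x) standardGeneric("fpResponses"))

#' @rdname fpWeights
#' @export
setMethod("fpResponses", "FixedPointReport", function(x) x@responses)

#' @rdname fpWeights
#' @export
setGeneric("fpClassification", function(x) standardGeneric("fpClassification"))

#' @rdname fpWeights
#' @export
setMethod("fpClassification", "FixedPointReport", function(x) x@classification)

#' @rdname fpWeights
#' @export
setGeneric("isStable", function(x) standardGeneric("isStable"))

#' @rdname fpWeights
#' @export
setMethod("isStable", "FixedPointReport", function(x) x@stable)

#' @rdname fpWeights
#' @export
setGeneric("isAccessible", function(x) standardGeneric("isAccessible"))

#' @rdname fpWeights
#' @export
setMethod("isAccessible", "FixedPointReport", function(x) x@accessible)

setMethod("show", "StimulusEnsemble", function(object) {
  cat(sprintf("StimulusEnsemble '%s': %d patterns x %d inputs%s\n",
              object@kind, nrow(object@patterns), ncol(object@patterns),
              if (object@zeroMean) " (zero mean)" else ""))
  p <- object@params
  if (length(p))
    cat("  params:", paste(names(p), vapply(p, function(v)
      paste(format(unlist(v), digits = 4), collapse = ","), ""),
      sep = "=", collapse = ", "), "\n")
  invisible(object)
})

setMethod("show", "PlasticityConfig", function(object) {
  cat(sprintf(paste0("PlasticityConfig: rule=%s, u=%g, tauW=%g, tauTheta=%g,",
                     " sigmaY=%g\n  transfer=%s, dt=%g, thresholdMode=%s,",
                     " seed=%s\n"),
              object@rule, object@u, object@tauW, object@tauTheta,
              object@sigmaY, object@transfer@kind, object@dt,
              object@thresholdMode, as.character(object@rngSeed)))
  invisible(object)
})

setMethod("show", "Trajectory", function(object) {
  cat(sprintf(paste0("Trajectory: %d samples over %g presentations",
                     " (%sconverged)\n  final theta = %.6g, final responses:",
                     " %s\n"),
              length(object@times), object@nPresentations,
              if (object@converged) "" else "not ",
              object@finalState@theta,
              paste(format(head(
                as.numeric(tail(object@responses, 1L)), 8L),
                digits = 4), collapse = " ")))
  invisible(object)
})

setMethod("show", "FixedPointReport", function(object) {
  cat(sprintf("FixedPointReport [%s]: %s, %s\n  w* = (%s), theta* = %.6g, y = (%s)\n",
              object@classification,
              if (isTRUE(object@stable)) "stable"
              else if (isFALSE(object@stable)) "unstable" else "stability n/a",
              if (isTRUE(object@accessible)) "accessible"
              else if (isFALSE(object@accessible)) "inaccessible"
              else "accessibility n/a",
              paste(format(head(object@wStar, 6L), digits = 5), collapse = ", "),
              object@thetaStar,
              paste(format(head(object@responses, 6L), digits = 5),
                    collapse = ", ")))
  invisible(object)
})

setMethod("show", "PhaseDiagram", function(object) {
  cat(sprintf("PhaseDiagram: %d phi values x %d u values\n",
              length(object@phiValues), length(object@uValues)))
  cat("  regimes:", paste(names(table(object@regime)),
                          table(object@regime), sep = ":", collapse = ", "),
      "\n")
  invisible(object)
})
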