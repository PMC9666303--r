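#' Selectivity of a response profile
#'
#' `s = max_k y_k / sum_l y_l`, ranging from `1/K` (all patterns drive the
#' neuron equally) to 1 (winner-take-all).  Negative responses, possible
#' transiently with a linear transfer, are clipped to zero first since the
#' index presumes non-negative rates.  Ties are broken deterministically by
#' the lowest pattern index (relevant only for reporting the winner).
#'
#' @param responses per-pattern responses.
#' @return the selectivity in `[1/K, 1]`, with attribute `"winner"` (index
#'   of the preferred pattern); `NA` with a warning if all responses are
#'   zero after clipping.
#' @examples
#' selectivity(c(2, 0))    # 1
#' selectivity(c(1, 1))    # 0.5
#' @export
selectivity <- function(responses) {
  y <- pmax(0, as.numeric(responses))
  tot <- sum(y)
  if (tot == 0) {
    warning("all responses are zero; selectivity undefined")
    return(structure(NA_real_, winner = NA_integer_))
  }
  structure(max(y) / tot, winner = which.max(y))
}

#' Excitation/inhibition imbalance
#'
#' The fraction of peak excitatory drive not cancelled by the feed-forward
#' inhibition: `m = (max_k E_k - I) / max_k E_k`, with excitatory current
#' `E_k = sum_i (w_i + u) x_i^(k)` and inhibitory current
#' `I = u sum_i x_i^(k)` evaluated at the same (preferred) pattern.  `m = 1`
#' iff `u = 0` (purely excitation-driven); small positive `m` means
#' excitation and inhibition largely cancel for the preferred stimulus.
#'
#' @param w effective weight vector.
#' @param u feed-forward inhibition strength.
#' @param ensemble a [StimulusEnsemble-class].
#' @return the imbalance `m` (`<= 1`), or `NA` with a warning if the peak
#'   excitatory current is not positive.
#' @export
imbalance <- function(w, u, ensemble) {
  X <- ensembleMatrix(ensemble)
  E <- as.numeric(X %*% (w + u))
  k <- which.max(E)
  if (E[k] <= 0) {
    warning("peak excitatory current is not positive; imbalance undefined")
    return(NA_real_)
  }
  I <- u * sum(X[k, ])
  (E[k] - I) / E[k]
}

#' Selectivity phase diagram over stimulus angle and inhibition
#'
#' Classifies the stable equilibrium of the weight-dependent rule on the
#' mirrored two-pattern ensemble for every `(phi, u)` pair: winner-take-all
#' (`u > u*(phi)`, selectivity 1), pinned and unselective (`u <= u**(phi)`,
#' selectivity 1/2), or the partially selective weight-dependent fixed
#' point in between (selectivity from its responses).  Angles whose
#' stimulus matrix is singular are masked with `NA`.
#'
#' @param phiValues stimulus angles in `(0, pi/4]`.
#' @param uValues inhibition levels.
#' @param cfg optional [PlasticityConfig-class] template (rule forced to
#'   weight-dependent; `u` is swept).
#' @return a [PhaseDiagram-class].
#' @export
phaseDiagram <- function(phiValues, uValues, cfg = NULL) {
  if (is.null(cfg)) cfg <- plasticityConfig(rule = "weight_dependent")
  sel <- matrix(NA_real_, length(phiValues), length(uValues),
                dimnames = list(format(phiValues, digits = 4),
                                format(uValues, digits = 4)))
  reg <- matrix(NA_character_, length(phiValues), length(uValues),
                dimnames = dimnames(sel))
  uStar <- uStarStar <- rep(NA_real_, length(phiValues))
  for (a in seq_along(phiValues)) {
    phi <- phiValues[a]
    if (abs(phi - pi / 4) < 1e-6) next  # singular stimulus matrix: masked
    ens <- makePair2d(phi)
    uStar[a] <- max(criticalInhibitionUpper(ens))
    uStarStar[a] <- criticalInhibitionLower(ens)
    for (b in seq_along(uValues)) {
      u <- uValues[b]
      if (u > uStar[a]) {
        sel[a, b] <- 1; reg[a, b] <- "standard_wta"
      } else if (u <= uStarStar[a]) {
        sel[a, b] <- 0.5; reg[a, b] <- "pinned_unselective"
      } else {
        cfgU <- cfg; cfgU@u <- u
        cfgU@rule <- "weight_dependent"
        fps <- wdFixedPoints2d(ens, cfgU, assessStability = FALSE)
        if (length(fps)) {
          sel[a, b] <- as.numeric(selectivity(fps[[1]]@responses))
          reg[a, b] <- "weight_dependent_partial"
        } else {
          # numerically merged with the winner-take-all point near u*
          sel[a, b] <- 1; reg[a, b] <- "standard_wta"
        }
      }
    }
  }
  new("PhaseDiagram", phiValues = phiValues, uValues = uValues,
      selectivity = sel, regime = reg,
      boundaries = list(uStar = uStar, uStarStar = uStarStar))
}

#' Weight histogram with skewness summary
#'
#' Pools weight samples, bins them with the Freedman-Diaconis rule and
#' reports the adjusted Fisher-Pearson sample skewness and the spread.
#' Used for qualitative comparison of weight distributions (e.g. the
#' positively skewed distribution produced by soft-bound depression on
#' zero-mean inputs).
#'
#' @param wSamples numeric vector or matrix of pooled weight samples.
#' @return a list with the `hist` object, `skewness`, `sd` and `n`.
#' @export
weightHistogram <- function(wSamples) {
  v <- as.numeric(wSamples)
  if (!length(v)) stop("no weight samples")
  h <- graphics::hist(v, breaks = "FD", plot = FALSE)
  list(histogram = h, skewness = e1071::skewness(v, type = 2),
       sd = sd(v), n = length(v))
}
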