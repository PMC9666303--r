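# Circular (periodic) distance between 0-based indices i and k on a ring of
# size N: min(|i-k|, N-|i-k|).
circularDistance <- function(i, k, N) {
  d <- abs(i - k)
  pmin(d, N - d)
}

#' Mirrored two-pattern stimulus ensemble
#'
#' Two unit-norm input vectors mirrored in the diagonal:
#' `x1 = (cos(phi), sin(phi))` and `x2 = (sin(phi), cos(phi))`, with angle
#' `pi/2 - 2 phi` between them.  `phi = 0` gives orthogonal patterns (the
#' identity matrix), `phi = pi/4` parallel ones (singular stimulus matrix --
#' allowed here, but downstream matrix inversion must guard it).
#'
#' @param phi stimulus angle in radians, `0 <= phi < pi/2`.
#' @return a [StimulusEnsemble-class] with a symmetric `2 x 2` pattern
#'   matrix.
#' @examples
#' patterns(makePair2d(0.4))
#' @export
makePair2d <- function(phi) {
  if (!is.numeric(phi) || length(phi) != 1L || !is.finite(phi) ||
      phi < 0 || phi >= pi / 2)
    stop("phi must be a single value in [0, pi/2)")
  X <- rbind(c(cos(phi), sin(phi)),
             c(sin(phi), cos(phi)))
  newEnsemble(X, "pair2d", list(phi = phi))
}

#' Circulant triangular stimulus ensemble
#'
#' `K` patterns over `N` inputs with a triangular profile of half-width
#' `N * omega / 2` around the pattern centre, periodic boundaries:
#' entry `(k, i) = max(0, 1 - (2 / (N omega)) d(i, k))` where `d` is the
#' circular distance.  Every pattern is a circular shift of pattern 1.
#'
#' @param N number of inputs (`>= 2`).
#' @param K number of patterns (default `N`).
#' @param omega width parameter as a fraction of the ring (`> 0`).
#' @return a [StimulusEnsemble-class].
#' @examples
#' patterns(makeTriangular(20, omega = 0.5))[1, 1:6]
#' @export
makeTriangular <- function(N, K = N, omega = 0.5) {
  if (N < 2 || K < 1) stop("need N >= 2 and K >= 1")
  if (!is.numeric(omega) || omega <= 0) stop("omega must be positive")
  i <- 0:(N - 1)
  X <- t(vapply(0:(K - 1), function(k)
    pmax(0, 1 - 2 / (N * omega) * circularDistance(i, k, N)),
    numeric(N)))
  newEnsemble(X, "triangular", list(N = N, K = K, omega = omega))
}

#' Circulant von Mises stimulus ensemble
#'
#' Smooth periodic tuning profiles
#' `x_i^(k) = exp(-(1 + cos(2 pi (i - k) / N)))`, peaking (at value 1) half
#' a period away from the pattern centre and dipping to `exp(-2)` at it.
#'
#' @param N number of inputs (`>= 2`).
#' @param K number of patterns (default `N`).
#' @return a [StimulusEnsemble-class].
#' @export
makeVonMises <- function(N, K = N) {
  if (N < 2 || K < 1) stop("need N >= 2 and K >= 1")
  i <- 0:(N - 1)
  X <- t(vapply(0:(K - 1), function(k)
    exp(-(1 + cos(2 * pi * (i - k) / N))), numeric(N)))
  newEnsemble(X, "von_mises", list(N = N, K = K))
}

#' Stimulus matrix of an ensemble (with singularity guard)
#'
#' @param ensemble a [StimulusEnsemble-class] or numeric matrix.
#' @param requireSquare require `K == N`.
#' @return the pattern matrix.
#' @keywords internal
ensembleMatrix <- function(ensemble, requireSquare = FALSE) {
  X <- if (is(ensemble, "StimulusEnsemble")) ensemble@patterns
       else as.matrix(ensemble)
  if (requireSquare && nrow(X) != ncol(X))
    stop("need a square stimulus matrix (K == N)")
  X
}

# Stop if the square stimulus matrix is singular or near-singular.
checkInvertible <- function(X, tol = 1e8) {
  kap <- kappa(X, exact = TRUE)
  if (!is.finite(kap) || kap > tol)
    stop(sprintf("stimulus matrix is singular or near-singular (condition number %.3g); fixed-point formulas require linearly independent patterns",
                 kap))
  invisible(kap)
}
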