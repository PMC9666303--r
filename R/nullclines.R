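# Vectorised evaluation of both components of the stimulus-averaged update
# over a set of weight points (rows of W), linear transfer, no noise.
meanUpdateGrid <- function(W, X, rule, u) {
  K <- nrow(X)
  Y <- W %*% t(X)                     # points x patterns
  theta <- rowMeans(Y^2)
  out <- matrix(0, nrow(W), ncol(W))
  for (k in seq_len(K)) {
    drive <- Y[, k] * (Y[, k] - theta)
    for (i in seq_len(ncol(W))) {
      g <- if (rule == "weight_dependent") ifelse(drive < 0, W[, i] + u, 1)
           else 1
      out[, i] <- out[, i] + g * X[k, i] * drive
    }
  }
  out / K
}

#' Null-clines of the two-input learning dynamics
#'
#' Evaluates both components of the stimulus-averaged weight update on a
#' rectangular `(w1, w2)` grid and extracts their zero contours.  The
#' region `w_i < -u`, where an excitatory weight would be negative, is
#' excluded from the curves and reported as a mask.  Fixed points sit at
#' intersections of the two curve families; they are located and polished
#' by [locateFixedPointsGrid()] on the same grid.
#'
#' @param ensemble a two-pattern, two-input [StimulusEnsemble-class].
#' @param cfg a [PlasticityConfig-class] (rule and `u`).
#' @param w1Range,w2Range numeric ranges; default `[-u + 0.01, wMax]` with
#'   `wMax` three times the largest standard fixed-point coordinate.
#' @param n grid points per axis.
#' @return a list with the grid vectors, the two component matrices
#'   (`comp1`, `comp2`), contour curves (`curves1`, `curves2`, as returned
#'   by [grDevices::contourLines()]), the restricted-region mask, the
#'   polished fixed points (`fixedPoints`, rows are points) and their count
#'   `nCrossings` (the origin, a degenerate double zero, is not counted).
#' @export
nullclines2d <- function(ensemble, cfg, w1Range = NULL, w2Range = NULL,
                         n = 161L) {
  X <- ensembleMatrix(ensemble, requireSquare = TRUE)
  if (nrow(X) != 2L) stop("null-cline analysis is two-dimensional")
  if (is.null(w1Range) || is.null(w2Range)) {
    wMax <- 3 * max(abs(vapply(standardFixedPoints(ensemble)[1:2],
                               function(f) max(abs(f@wStar)), 0)))
    lo <- -cfg@u + 0.01
    if (is.null(w1Range)) w1Range <- c(min(lo, -0.5), wMax)
    if (is.null(w2Range)) w2Range <- c(min(lo, -0.5), wMax)
  }
  w1 <- seq(w1Range[1], w1Range[2], length.out = n)
  w2 <- seq(w2Range[1], w2Range[2], length.out = n)
  W <- as.matrix(expand.grid(w1 = w1, w2 = w2))
  U <- meanUpdateGrid(W, X, cfg@rule, cfg@u)
  comp1 <- matrix(U[, 1], n, n)  # w1 varies along rows
  comp2 <- matrix(U[, 2], n, n)
  mask <- matrix(W[, 1] < -cfg@u | W[, 2] < -cfg@u, n, n)
  blank <- function(m) { m[mask] <- NA; m }
  fps <- locateFixedPointsGrid(ensemble, cfg, w1, w2,
                               comp1 = comp1, comp2 = comp2)
  list(w1 = w1, w2 = w2, comp1 = comp1, comp2 = comp2,
       curves1 = grDevices::contourLines(w1, w2, blank(comp1), levels = 0),
       curves2 = grDevices::contourLines(w1, w2, blank(comp2), levels = 0),
       mask = mask, fixedPoints = fps, nCrossings = nrow(fps))
}

# Damped Newton polish of a fixed-point candidate.
newtonPolish <- function(w, ensemble, cfg, maxIter = 60L, tol = 1e-11) {
  f <- meanUpdate(w, ensemble, cfg, sigmaY = 0)
  for (it in seq_len(maxIter)) {
    if (max(abs(f)) < tol) break
    h <- 1e-7 * (1 + max(abs(w)))
    J <- matrix(0, length(w), length(w))
    for (j in seq_along(w)) {
      e <- numeric(length(w)); e[j] <- h
      J[, j] <- (meanUpdate(w + e, ensemble, cfg, sigmaY = 0) -
                 meanUpdate(w - e, ensemble, cfg, sigmaY = 0)) / (2 * h)
    }
    step <- tryCatch(solve(J, f), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) return(NULL)
    lam <- 1
    repeat {
      wNew <- w - lam * step
      fNew <- meanUpdate(wNew, ensemble, cfg, sigmaY = 0)
      if (max(abs(fNew)) < max(abs(f)) || lam < 1e-4) break
      lam <- lam / 2
    }
    w <- wNew; f <- fNew
  }
  if (max(abs(f)) < 1e-9) w else NULL
}

#' Brute-force fixed-point search on a weight grid
#'
#' Scans every grid cell in which both components of the stimulus-averaged
#' update change sign, polishes each candidate with a damped Newton
#' iteration, and deduplicates the results.  Serves as an independent check
#' that the analytic fixed-point lists are complete: on a sufficiently fine
#' grid every transversal zero is found (the origin, where the update
#' vanishes to second order, produces no sign change and is not reported).
#'
#' @param ensemble a two-pattern, two-input [StimulusEnsemble-class].
#' @param cfg a [PlasticityConfig-class].
#' @param w1,w2 grid vectors.
#' @param comp1,comp2 optional precomputed component matrices on the grid.
#' @return a matrix with one polished fixed point per row (0 rows if none).
#' @export
locateFixedPointsGrid <- function(ensemble, cfg, w1, w2, comp1 = NULL,
                                  comp2 = NULL) {
  X <- ensembleMatrix(ensemble, requireSquare = TRUE)
  n1 <- length(w1); n2 <- length(w2)
  if (is.null(comp1) || is.null(comp2)) {
    W <- as.matrix(expand.grid(w1 = w1, w2 = w2))
    U <- meanUpdateGrid(W, X, cfg@rule, cfg@u)
    comp1 <- matrix(U[, 1], n1, n2)
    comp2 <- matrix(U[, 2], n1, n2)
  }
  signChange <- function(m, i, j) {
    v <- c(m[i, j], m[i + 1L, j], m[i, j + 1L], m[i + 1L, j + 1L])
    min(v) < 0 && max(v) > 0
  }
  pts <- NULL
  for (i in seq_len(n1 - 1L)) for (j in seq_len(n2 - 1L)) {
    if (!signChange(comp1, i, j) || !signChange(comp2, i, j)) next
    w0 <- c(mean(w1[i:(i + 1L)]), mean(w2[j:(j + 1L)]))
    w <- newtonPolish(w0, ensemble, cfg)
    if (is.null(w)) next
    if (w[1] < min(w1) - 0.1 || w[1] > max(w1) + 0.1 ||
        w[2] < min(w2) - 0.1 || w[2] > max(w2) + 0.1) next
    if (is.null(pts) || !any(apply(pts, 1L, function(p)
      max(abs(p - w)) < 1e-5)))
      pts <- rbind(pts, w)
  }
  if (is.null(pts)) matrix(numeric(), 0L, 2L,
                           dimnames = list(NULL, c("w1", "w2")))
  else { dimnames(pts) <- list(NULL, c("w1", "w2")); pts }
}

#' Full fixed-point analysis of the two-input system
#'
#' Assembles the standard winner-take-all points, the symmetric unstable
#' points, the weight-dependent points (for the weight-dependent rule) and,
#' in the feed-forward-excitation regime `u <= u**`, the pinned point
#' `w = (-u, -u)`, assessing stability and accessibility of each, together
#' with the critical inhibition levels.
#'
#' @param ensemble a two-pattern, two-input [StimulusEnsemble-class].
#' @param cfg a [PlasticityConfig-class].
#' @return a list with `fixedPoints` (list of [FixedPointReport-class]),
#'   `uStar` (named vector from [criticalInhibitionUpper()]) and
#'   `uStarStar` (from [criticalInhibitionLower()]).
#' @export
analyzeFixedPoints <- function(ensemble, cfg) {
  X <- ensembleMatrix(ensemble, requireSquare = TRUE)
  fps <- standardFixedPoints(ensemble, u = cfg@u)
  if (cfg@rule == "weight_dependent" && nrow(X) == 2L)
    fps <- c(fps, wdFixedPoints2d(ensemble, cfg, assessStability = FALSE))
  uss <- if (nrow(X) == 2L) criticalInhibitionLower(ensemble) else NULL
  if (!is.null(uss) && cfg@u <= uss) {
    w <- rep(-cfg@u, 2L)
    y <- as.numeric(X %*% w)
    fps <- c(fps, list(new("FixedPointReport", wStar = w,
                           thetaStar = mean(y^2), responses = y,
                           classification = "pinned_at_bound",
                           accessible = TRUE)))
  }
  fps <- lapply(fps, fpStability, ensemble = ensemble, cfg = cfg)
  list(fixedPoints = fps,
       uStar = if (nrow(X) == 2L) criticalInhibitionUpper(ensemble) else NULL,
       uStarStar = uss)
}
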