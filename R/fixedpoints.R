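#' Stimulus-averaged weight update
#'
#' The average of the (rule-dependent) weight update over the ensemble at a
#' given weight vector, with the threshold at its mean-field value
#' `theta = (1/K) sum_k y_k^2 + sigmaY^2`:
#' `(1/K) sum_k g_k x^(k) [y_k (y_k - theta) + sigmaY^2]`, in units of
#' `1/tauW` per unit time.  For the weight-dependent rule the depression
#' branch uses `g_k = w + u` (elementwise), the potentiation branch
#' `g_k = 1`.  Fixed points of the learning dynamics are the zeros of this
#' map.
#'
#' @param w effective weight vector.
#' @param ensemble a [StimulusEnsemble-class] (linear transfer assumed).
#' @param cfg a [PlasticityConfig-class] (supplies rule and `u`).
#' @param branch `"auto"` (branch from the sign of the drive) or a character
#'   vector over patterns with entries `"dep"`/`"pot"`/`"auto"` forcing the
#'   branch, used for the piecewise Jacobians in [fpStability()].
#' @param sigmaY noise s.d. for the noise-averaged analysis (Gaussian output
#'   noise adds `sigmaY^2` to both drive and threshold); defaults to
#'   `cfg@sigmaY`.
#' @return numeric vector of length `N`.
#' @export
meanUpdate <- function(w, ensemble, cfg, branch = "auto", sigmaY = NULL) {
  X <- ensembleMatrix(ensemble)
  if (cfg@transfer@kind != "linear")
    stop("mean-update analysis assumes a linear transfer function")
  K <- nrow(X)
  s <- if (is.null(sigmaY)) cfg@sigmaY else sigmaY
  y <- as.numeric(X %*% w)
  theta <- mean(y^2) + s^2
  drive <- y * (y - theta) + s^2
  if (length(branch) == 1L) branch <- rep(branch, K)
  wd <- cfg@rule == "weight_dependent"
  out <- numeric(length(w))
  for (k in seq_len(K)) {
    dep <- switch(branch[k], dep = TRUE, pot = FALSE, drive[k] < 0)
    g <- if (wd && dep) w + cfg@u else 1
    out <- out + g * X[k, ] * drive[k]
  }
  out / K
}

#' Analytic fixed points of standard BCM
#'
#' For `K = N` linearly independent patterns the stable fixed points make
#' the neuron respond with `y = K` to exactly one pattern and `y = 0` to
#' all others: `w = K (X^-1) e_m`, `theta = K` (for two patterns,
#' `w = 2 (X^-1) e_m`).  The unstable symmetric points -- the origin and
#' the equal-response point `y_k = theta = 1` for all `k` -- are appended
#' with classification `"symmetric_unstable"`.
#'
#' @param ensemble a [StimulusEnsemble-class] (or matrix) with `K = N` and
#'   invertible pattern matrix.
#' @param u optional inhibition strength used to fill the accessibility
#'   flag (`all(w + u >= 0)`).
#' @return a list of [FixedPointReport-class] objects (stability not yet
#'   assessed; see [fpStability()]).
#' @examples
#' standardFixedPoints(makePair2d(0.4))[[1]]
#' @export
standardFixedPoints <- function(ensemble, u = NULL) {
  X <- ensembleMatrix(ensemble, requireSquare = TRUE)
  checkInvertible(X)
  K <- nrow(X)
  Xi <- solve(X)
  acc <- function(w) if (is.null(u)) NA else all(w + u >= -1e-12)
  fps <- lapply(seq_len(K), function(m) {
    w <- as.numeric(K * Xi[, m])
    y <- numeric(K); y[m] <- K
    new("FixedPointReport", wStar = w, thetaStar = as.numeric(K),
        responses = y, classification = "standard_bcm",
        accessible = acc(w))
  })
  wSym <- as.numeric(Xi %*% rep(1, K))
  c(fps,
    list(new("FixedPointReport", wStar = numeric(K), thetaStar = 0,
             responses = numeric(K), classification = "symmetric_unstable",
             accessible = acc(numeric(K))),
        new("FixedPointReport", wStar = wSym, thetaStar = 1,
            responses = rep(1, K), classification = "symmetric_unstable",
            accessible = acc(wSym))))
}

# Solve the weight-dependent fixed point for one depression/potentiation
# case assignment (d depresses, p potentiates) along the determinant line.
solveWdCase <- function(X, u, d, p, wMax, eps = 1e-6) {
  num <- X[d, 1] * X[p, 2]
  den <- X[p, 1] * X[d, 2]
  if (abs(den) < 1e-14) return(list())
  slope <- num / den
  lineW <- function(w1) cbind(w1, -u + slope * (w1 + u))
  psi <- function(w1) {
    w <- lineW(w1)
    y <- as.numeric(X %*% as.numeric(w))
    theta <- mean(y^2)
    Fv <- y * (y - theta)
    (w[1] + u) * X[d, 1] * Fv[d] + X[p, 1] * Fv[p]
  }
  grid <- seq(-u + eps, wMax, length.out = 400L)
  vals <- vapply(grid, psi, 0)
  roots <- list()
  for (j in seq_len(length(grid) - 1L)) {
    if (!is.finite(vals[j]) || !is.finite(vals[j + 1L])) next
    if (vals[j] == 0) vals[j] <- .Machine$double.eps
    if (vals[j] * vals[j + 1L] < 0) {
      r <- uniroot(psi, c(grid[j], grid[j + 1L]), tol = 1e-14)$root
      w <- as.numeric(lineW(r))
      y <- as.numeric(X %*% w)
      theta <- mean(y^2)
      Fv <- y * (y - theta)
      # keep only roots consistent with the assumed case
      if (Fv[d] < -1e-8 && y[d] > 0 && y[p] > theta)
        roots <- c(roots, list(list(w = w, y = y, theta = theta)))
    }
  }
  roots
}

#' Weight-dependent fixed points of the two-input system
#'
#' Fixed points unique to the weight-dependent rule require one pattern to
#' depress and the other to potentiate; the singular-matrix condition of the
#' stationarity equations confines them to a line through `(-u, -u)` in the
#' weight plane, reducing the search to a bracketed one-dimensional root
#' problem for each of the two case assignments.  Roots inconsistent with
#' the assumed case are discarded; an empty result means the weight-dependent
#' points have merged with the standard ones (strong-inhibition regime).
#'
#' @param ensemble a two-pattern, two-input [StimulusEnsemble-class].
#' @param cfg a [PlasticityConfig-class] with `rule = "weight_dependent"`
#'   and linear transfer.
#' @param assessStability also run [fpStability()] on each point.
#' @return list of [FixedPointReport-class] objects (possibly empty).
#' @export
wdFixedPoints2d <- function(ensemble, cfg, assessStability = TRUE) {
  X <- ensembleMatrix(ensemble, requireSquare = TRUE)
  if (nrow(X) != 2L) stop("the determinant-line reduction is two-dimensional")
  if (cfg@rule != "weight_dependent")
    stop("weight-dependent fixed points require rule = 'weight_dependent'")
  checkInvertible(X)
  wMax <- 3 * max(abs(vapply(standardFixedPoints(ensemble)[1:2],
                             function(f) max(abs(f@wStar)), 0)))
  u <- cfg@u
  found <- c(solveWdCase(X, u, d = 1L, p = 2L, wMax),
             solveWdCase(X, u, d = 2L, p = 1L, wMax))
  reports <- list()
  for (r in found) {
    if (max(abs(meanUpdate(r$w, ensemble, cfg))) > 1e-9) next
    dup <- any(vapply(reports, function(f)
      max(abs(f@wStar - r$w)) < 1e-8, TRUE))
    if (dup) next
    fp <- new("FixedPointReport", wStar = r$w, thetaStar = r$theta,
              responses = r$y, classification = "weight_dependent",
              accessible = all(r$w + u >= -1e-12))
    if (assessStability) fp <- fpStability(fp, ensemble, cfg)
    reports <- c(reports, list(fp))
  }
  reports
}

# Finite-difference Jacobian of meanUpdate with forced branches.
branchJacobian <- function(w, ensemble, cfg, branch, h) {
  N <- length(w)
  J <- matrix(0, N, N)
  for (j in seq_len(N)) {
    e <- numeric(N); e[j] <- h
    J[, j] <- (meanUpdate(w + e, ensemble, cfg, branch = branch, sigmaY = 0) -
               meanUpdate(w - e, ensemble, cfg, branch = branch, sigmaY = 0)) /
      (2 * h)
  }
  J
}

#' Linear stability of a fixed point
#'
#' Computes finite-difference Jacobians of the stimulus-averaged update.
#' Where the update is not differentiable -- at standard-BCM points the
#' drive of some pattern is exactly zero, so the weight-dependent rule's
#' depression/potentiation branch is undecided -- the Jacobian of every
#' branch combination is evaluated, and the point is stable only if all
#' eigenvalue real parts of all branch Jacobians are negative.  A point
#' whose spectrum sits entirely inside the tolerance band (e.g. the origin,
#' where the linearisation vanishes) is resolved by probing the update
#' field on a small circle around the point; points pinned at the
#' excitatory bound (`classification "pinned_at_bound"`) are governed by
#' the multiplicative decay of the excitatory weights and are classified by
#' the critical level of [criticalInhibitionLower()] instead.
#'
#' @param fp a [FixedPointReport-class] (or bare weight vector).
#' @param ensemble the [StimulusEnsemble-class].
#' @param cfg the [PlasticityConfig-class].
#' @param fdStep relative finite-difference step.
#' @param tol eigenvalue real-part tolerance; spectra within `(-tol, tol)`
#'   in every branch trigger the nonlinear probe, and if that is also
#'   inconclusive the verdict is `NA`.
#' @return the report with `stable` and `eigenvalues` filled in (or, for a
#'   bare vector, a list with `stable` and `eigenvalues`).
#' @export
fpStability <- function(fp, ensemble, cfg, fdStep = 1e-6, tol = 1e-8) {
  bare <- !is(fp, "FixedPointReport")
  w <- if (bare) as.numeric(fp) else fp@wStar
  X <- ensembleMatrix(ensemble)
  K <- nrow(X)

  if (!bare && fp@classification == "pinned_at_bound") {
    fp@stable <- cfg@u <= criticalInhibitionLower(ensemble) + 1e-12
    return(fp)
  }

  y <- as.numeric(X %*% w)
  theta <- mean(y^2)
  drive <- y * (y - theta)
  ambTol <- 1e-7 * (1 + abs(theta))
  wd <- cfg@rule == "weight_dependent"
  ambiguous <- if (wd) which(abs(drive) < ambTol) else integer()
  base <- ifelse(drive < 0, "dep", "pot")

  combos <- if (length(ambiguous)) {
    g <- expand.grid(rep(list(c("dep", "pot")), length(ambiguous)),
                     stringsAsFactors = FALSE)
    lapply(seq_len(nrow(g)), function(r) {
      b <- base; b[ambiguous] <- unlist(g[r, ]); b
    })
  } else list(base)

  h <- fdStep * (1 + max(abs(w)))
  eigs <- lapply(combos, function(b)
    eigen(branchJacobian(w, ensemble, cfg, b, h), only.values = TRUE)$values)
  re <- unlist(lapply(eigs, Re))

  stable <- if (all(re < -tol)) TRUE
            else if (any(re > tol)) FALSE
            else {  # degenerate linearisation: probe the nonlinear field
              N <- length(w)
              dirs <- if (N == 2L) {
                a <- seq(0, 2 * pi, length.out = 17L)[-17L]
                cbind(cos(a), sin(a))
              } else {
                M <- matrix(rnorm(16L * N), 16L, N)
                M / sqrt(rowSums(M^2))
              }
              eps <- 1e-3 * (1 + max(abs(w)))
              proj <- apply(dirs, 1L, function(d)
                sum(d * meanUpdate(w + eps * d, ensemble, cfg, sigmaY = 0)))
              if (any(proj > 1e-12)) FALSE
              else if (all(proj < -1e-12)) TRUE else NA
            }

  if (bare) list(stable = stable, eigenvalues = eigs)
  else { fp@stable <- stable; fp@eigenvalues <- eigs; fp }
}

#' Critical inhibition above which standard BCM fixed points are stable
#'
#' Closed-form level at which the weight-dependent fixed point merges with
#' the standard winner-take-all point, one value per fixed point (they
#' coincide for the mirrored pair parametrization):
#' `u* = 2 x1^(1) x2^(1) (x1^(2) + x2^(2)) / det(X)^2` for the point at
#' which pattern 1 depresses, and the superscript-swapped expression for
#' the other.  For `u > u*` the winner-take-all points are stable under the
#' weight-dependent rule and no separate weight-dependent points exist.
#'
#' @param ensemble a two-pattern, two-input [StimulusEnsemble-class] with a
#'   non-singular pattern matrix.
#' @return named numeric vector of length 2 (one entry per standard fixed
#'   point: first the point where pattern 1 depresses / pattern 2 wins).
#' @examples
#' criticalInhibitionUpper(makePair2d(0.4))  # ~ 1.937 each
#' @export
criticalInhibitionUpper <- function(ensemble) {
  X <- ensembleMatrix(ensemble, requireSquare = TRUE)
  if (nrow(X) != 2L) stop("critical inhibition formulas are two-dimensional")
  checkInvertible(X)
  d2 <- det(X)^2
  c(pattern2wins = 2 * X[1, 1] * X[1, 2] * (X[2, 1] + X[2, 2]) / d2,
    pattern1wins = 2 * X[2, 1] * X[2, 2] * (X[1, 1] + X[1, 2]) / d2)
}

#' Critical feed-forward excitation below which weights pin at the bound
#'
#' For negative `u` (feed-forward excitation) the equilibrium pins at the
#' excitatory bound `w = (-u, -u)` (all excitatory weights zero) once
#' `u <= u**`, with
#' `u** = -2 (x1^(2) + x2^(2)) / ((x1^(1) + x2^(1))^2 + (x1^(2) + x2^(2))^2)`;
#' the neuron is then completely unselective.
#'
#' @param ensemble a two-pattern, two-input [StimulusEnsemble-class].
#' @return the (negative) critical level `u**`.
#' @examples
#' criticalInhibitionLower(makePair2d(0.4))  # ~ -0.763
#' @export
criticalInhibitionLower <- function(ensemble) {
  X <- ensembleMatrix(ensemble, requireSquare = TRUE)
  if (nrow(X) != 2L) stop("critical inhibition formulas are two-dimensional")
  s1 <- X[1, 1] + X[1, 2]
  s2 <- X[2, 1] + X[2, 2]
  -2 * s2 / (s1^2 + s2^2)
}

#' Closed-form critical inhibition for the mirrored pair parametrization
#'
#' `uStarPair2d(phi) = 2 sin(2 phi) / (cos(phi) + cos(3 phi) + sin(phi) -
#' sin(3 phi))` and `uStarStarPair2d(phi) = -1 / (sqrt(2) sin(phi + pi/4))`.
#'
#' @param phi stimulus angle in radians.
#' @return numeric critical level.
#' @export
uStarPair2d <- function(phi)
  2 * sin(2 * phi) / (cos(phi) + cos(3 * phi) + sin(phi) - sin(3 * phi))

#' @rdname uStarPair2d
#' @export
uStarStarPair2d <- function(phi) -1 / (sqrt(2) * sin(phi + pi / 4))

#' Analytic noisy fixed points of standard BCM (mirrored unit-norm pair)
#'
#' With zero-mean Gaussian output noise of s.d. `sigmaY`, the equilibrium
#' responses of the two-pattern standard BCM system satisfy
#' `y1 + y2 = 2`; below the critical noise level the selective solution
#' `y = 1 +/- sqrt(1 - sigmaY^2)` with `theta = 2` holds, while for
#' `sigmaY >= 1` the fixed points collapse onto the symmetric solution
#' `y1 = y2 = 1` with `theta = 1 + sigmaY^2`.
#'
#' @param sigmaY noise standard deviation (`>= 0`).
#' @return a list with `responses` (larger first) and `theta`.
#' @examples
#' noiseFixedPoints(0.6)  # responses 1.8, 0.2; theta 2
#' @export
noiseFixedPoints <- function(sigmaY) {
  if (sigmaY < 0) stop("sigmaY must be >= 0")
  if (sigmaY < 1) {
    r <- sqrt(1 - sigmaY^2)
    list(responses = c(1 + r, 1 - r), theta = 2)
  } else {
    list(responses = c(1, 1), theta = 1 + sigmaY^2)
  }
}
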