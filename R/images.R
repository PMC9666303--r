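#' Synthetic greyscale images with a 1/f amplitude spectrum
#'
#' Generates random images whose amplitude spectrum falls off as the inverse
#' of spatial frequency, the hallmark second-order statistic of natural
#' scenes, by shaping white Gaussian noise in the Fourier domain.  Each image
#' is rescaled to the range `[0, 1]`.  Serves as a built-in stand-in image
#' source for the receptive-field experiments; real greyscale images can be
#' supplied to [makeImagePatches()] instead.
#'
#' @param n number of images (`> 0`).
#' @param size image side length in pixels (`>= 32`).
#' @param seed integer RNG seed; the stack is a pure function of
#'   `(n, size, seed)`.
#' @return a numeric array of dimension `c(size, size, n)` with values in
#'   `[0, 1]`.
#' @examples
#' img <- generateSyntheticImages(1, 64, seed = 7L)[, , 1]
#' range(img)
#' @export
generateSyntheticImages <- function(n, size, seed = 1L) {
  if (!is.numeric(n) || n <= 0) stop("n must be positive")
  if (size < 32) stop("size must be at least 32 pixels")
  n <- as.integer(n); size <- as.integer(size)
  # radial frequency grid in cycles/image (FFT layout)
  f1 <- c(0:(size %/% 2), -((size - size %/% 2 - 1):1)) / size
  fr <- sqrt(outer(f1^2, f1^2, "+"))
  H <- 1 / fr
  H[1, 1] <- 0  # no DC power; mean is set by the rescaling
  withSeed(as.integer(seed), {
    imgs <- array(0, dim = c(size, size, n))
    for (j in seq_len(n)) {
      noise <- matrix(rnorm(size * size), size, size)
      img <- Re(stats::fft(stats::fft(noise) * H, inverse = TRUE)) / size^2
      rng <- range(img)
      imgs[, , j] <- (img - rng[1]) / (rng[2] - rng[1])
    }
    imgs
  })
}

#' Balanced difference-of-Gaussians retina filter kernel
#'
#' Isotropic centre and surround Gaussians (standard deviations in pixels)
#' truncated at four surround widths, each normalised to unit sum before
#' subtraction, so the kernel sums to zero and annihilates constant
#' illumination ("balanced").
#'
#' @param centerWidth centre standard deviation in pixels.
#' @param surroundWidth surround standard deviation in pixels (`> center`).
#' @return a square numeric kernel matrix summing to zero.
#' @examples
#' sum(dogKernel())  # ~ 0
#' @export
dogKernel <- function(centerWidth = 1, surroundWidth = 3) {
  if (surroundWidth <= centerWidth)
    stop("surround width must exceed centre width")
  r <- ceiling(4 * surroundWidth)
  d2 <- outer((-r:r)^2, (-r:r)^2, "+")
  g <- function(s) { m <- exp(-d2 / (2 * s^2)); m / sum(m) }
  g(centerWidth) - g(surroundWidth)
}

# Pixel offsets (dy, dx) of the circular patch mask: the `nPixels` offsets
# with the smallest distance from the centre, ties broken by raster order,
# returned in raster order (row-major over the bounding square).
circularMaskOffsets <- function(nPixels) {
  r <- ceiling(sqrt(nPixels / pi)) + 2
  grid <- expand.grid(dx = -r:r, dy = -r:r)  # row-major: dy slow, dx fast
  grid <- grid[order(grid$dy, grid$dx), ]
  d2 <- grid$dx^2 + grid$dy^2
  keep <- order(d2, seq_along(d2))[seq_len(nPixels)]
  sel <- grid[sort(keep), ]
  cbind(dy = sel$dy, dx = sel$dx)
}

#' Extract DoG-filtered circular image patches as a stimulus ensemble
#'
#' Each image is filtered with the balanced difference-of-Gaussians kernel,
#' then circular patches of exactly `patchPixels` pixels are sampled at
#' random positions (away from the borders, so the filter and mask are fully
#' supported) and flattened in a fixed raster order.  With
#' `zeroMean = FALSE` all entries are mapped to `[0, 1]` with a single
#' affine map over the whole ensemble, preserving relative contrast between
#' patches; with `zeroMean = TRUE` the ensemble grand mean is additionally
#' subtracted after that map and entries may be negative.
#'
#' @param images a `size x size x n` array (e.g. from
#'   [generateSyntheticImages()]), a single matrix, or a list of matrices.
#' @param cfg an [ImagePipelineConfig-class].
#' @param zeroMean logical; see above.
#' @return a [StimulusEnsemble-class] of kind `"image_patches"` with
#'   `cfg@nPatches` patterns of `cfg@patchPixels` inputs.
#' @export
makeImagePatches <- function(images, cfg = imagePipelineConfig(),
                             zeroMean = FALSE) {
  if (is.matrix(images)) images <- list(images)
  if (is.array(images) && length(dim(images)) == 3L)
    images <- lapply(seq_len(dim(images)[3]), function(j) images[, , j])
  if (!is.list(images) || !length(images))
    stop("images must be a matrix, a 3-d array or a list of matrices")

  kern <- dogKernel(cfg@dogCenterWidth, cfg@dogSurroundWidth)
  kr <- (nrow(kern) - 1L) %/% 2L
  mask <- circularMaskOffsets(cfg@patchPixels)
  mr <- max(abs(mask))
  margin <- kr + mr

  filtered <- lapply(images, function(img) {
    img <- as.matrix(img)
    if (nrow(img) < 2 * margin + 1 || ncol(img) < 2 * margin + 1)
      stop(sprintf("image (%d x %d) too small for the circular mask and filter (needs > %d pixels on each side)",
                   nrow(img), ncol(img), 2 * margin))
    EBImage::filter2(img, kern, boundary = "replicate")
  })

  P <- withSeed(cfg@rngSeed, {
    out <- matrix(0, cfg@nPatches, cfg@patchPixels)
    for (p in seq_len(cfg@nPatches)) {
      j <- if (length(filtered) > 1L) sample.int(length(filtered), 1L) else 1L
      img <- filtered[[j]]
      cy <- sample(seq.int(1L + margin, nrow(img) - margin), 1L)
      cx <- sample(seq.int(1L + margin, ncol(img) - margin), 1L)
      out[p, ] <- img[cbind(cy + mask[, "dy"], cx + mask[, "dx"])]
    }
    out
  })

  rawRange <- range(P)
  P <- if (rawRange[2] > rawRange[1])
    (P - rawRange[1]) / (rawRange[2] - rawRange[1])
  else matrix(0.5, nrow(P), ncol(P))
  if (zeroMean) P <- P - mean(P)
  newEnsemble(P, "image_patches",
              list(rawRange = rawRange,
                   patchPixels = cfg@patchPixels,
                   dogCenterWidth = cfg@dogCenterWidth,
                   dogSurroundWidth = cfg@dogSurroundWidth,
                   nPatches = cfg@nPatches, rngSeed = cfg@rngSeed),
              zeroMean = zeroMean)
}

#' Radial amplitude-spectrum slope of an image
#'
#' Fits a straight line to log amplitude versus log radial frequency of the
#' image's discrete Fourier transform (frequencies averaged in radial bins,
#' DC excluded).  A 1/f image has slope close to -1.
#'
#' @param img a square numeric matrix.
#' @param nBins number of radial bins.
#' @return the fitted slope (numeric scalar).
#' @export
amplitudeSpectrumSlope <- function(img, nBins = 20) {
  img <- as.matrix(img)
  size <- nrow(img)
  A <- Mod(stats::fft(img - mean(img)))
  f1 <- c(0:(size %/% 2), -((size - size %/% 2 - 1):1)) / size
  fr <- sqrt(outer(f1^2, f1^2, "+"))
  ok <- fr > 0 & fr <= 0.5
  bins <- cut(log(fr[ok]), breaks = nBins)
  mf <- tapply(log(fr[ok]), bins, mean)
  ma <- tapply(log(A[ok]), bins, function(v) log(mean(exp(v))))
  keep <- is.finite(mf) & is.finite(ma)
  unname(stats::coef(stats::lm(ma[keep] ~ mf[keep]))[2])
}
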