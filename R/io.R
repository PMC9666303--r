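#' Write / read a stimulus ensemble as delimited text
#'
#' The pattern matrix is stored as a tab-separated table (one row per
#' pattern) next to a small JSON sidecar (`<file>.json`) holding the
#' generator metadata, so an ensemble round-trips exactly.
#'
#' @param ensemble a [StimulusEnsemble-class].
#' @param file path of the matrix file (sidecar written to `<file>.json`).
#' @return `writeEnsemble()` returns `file` invisibly; `readEnsemble()`
#'   returns the reconstructed [StimulusEnsemble-class].
#' @export
writeEnsemble <- function(ensemble, file) {
  write.table(ensemble@patterns, file, sep = "\t", row.names = FALSE,
              col.names = FALSE)
  jsonlite::write_json(list(kind = ensemble@kind, params = ensemble@params,
                            zeroMean = ensemble@zeroMean),
                       paste0(file, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' @rdname writeEnsemble
#' @export
readEnsemble <- function(file) {
  X <- as.matrix(read.table(file, sep = "\t"))
  dimnames(X) <- NULL
  meta <- jsonlite::read_json(paste0(file, ".json"), simplifyVector = TRUE)
  newEnsemble(X, meta$kind, as.list(meta$params),
              zeroMean = isTRUE(meta$zeroMean))
}

#' Export a trajectory as delimited text
#'
#' One row per sample: presentation index, threshold, the weights and the
#' noise-free per-pattern responses.
#'
#' @param traj a [Trajectory-class].
#' @param file output path.
#' @return `file`, invisibly.
#' @export
writeTrajectory <- function(traj, file) {
  N <- ncol(traj@wSamples); K <- ncol(traj@responses)
  tab <- cbind(time = traj@times, theta = traj@thetaSamples,
               traj@wSamples, traj@responses)
  colnames(tab) <- c("time", "theta", paste0("w", seq_len(N)),
                     paste0("y", seq_len(K)))
  write.table(tab, file, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(file)
}

# Default run configuration; user files override these keys.
defaultRunConfig <- function() {
  list(
    experiment = "pair2d",
    seed = 1L,
    plasticity = list(rule = "standard", u = 0, tau_w = 200, tau_theta = 20,
                      sigma_y = 0, dt = 0.1, transfer = "linear",
                      sigma_minus = 0.01, sigma_plus = 50,
                      threshold_mode = "online"),
    stimulus = list(phi = 0.4, N = 20, K = 20, omega = 0.5,
                    images = list(n = 4, size = 96, seed = 1),
                    patch_pixels = 400, n_patches = 1000, zero_mean = FALSE),
    training = list(n_presentations = 1e5, record_every = NULL),
    phase_grid = list(phi_from = 0.05, phi_to = 0.75, phi_n = 8,
                      u_from = -1, u_to = 2.5, u_n = 8),
    output_dir = "wdbcm-out")
}

# Recursive list merge: entries of y override x.
mergeConfig <- function(x, y) {
  for (nm in names(y)) {
    x[[nm]] <- if (is.list(x[[nm]]) && is.list(y[[nm]]))
      mergeConfig(x[[nm]], y[[nm]]) else y[[nm]]
  }
  x
}

#' Read a run configuration file
#'
#' Structured key-value configuration in YAML (default) or JSON (by file
#' extension), merged over the documented defaults.  The configuration
#' drives [cmdSimulate()] and the other command entry points.
#'
#' @param path configuration file path.
#' @return a nested named list.
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file '%s' not found", path))
  user <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  cfg <- mergeConfig(defaultRunConfig(), as.list(user))
  if (!cfg$experiment %in% c("pair2d", "triangular", "von_mises", "images"))
    stop(sprintf("unknown experiment '%s'", cfg$experiment))
  cfg
}

# Build the PlasticityConfig object from a run-config list.
configPlasticity <- function(cfg, seed = NULL) {
  p <- cfg$plasticity
  plasticityConfig(rule = p$rule, u = p$u, tauW = p$tau_w,
                   tauTheta = p$tau_theta, sigmaY = p$sigma_y,
                   transfer = transferSpec(p$transfer,
                                           sigmaMinus = p$sigma_minus,
                                           sigmaPlus = p$sigma_plus),
                   dt = p$dt, thresholdMode = p$threshold_mode,
                   rngSeed = if (is.null(seed)) cfg$seed else seed)
}

# Build the stimulus ensemble named by the run-config list.
configEnsemble <- function(cfg) {
  s <- cfg$stimulus
  switch(cfg$experiment,
         pair2d = makePair2d(s$phi),
         triangular = makeTriangular(s$N, s$K, s$omega),
         von_mises = makeVonMises(s$N, s$K),
         images = {
           imgs <- if (!is.null(s$files)) {
             if (!requireNamespace("png", quietly = TRUE))
               stop("reading PNG images requires the 'png' package")
             lapply(s$files, function(f) {
               a <- png::readPNG(f)
               if (length(dim(a)) == 3L) rowMeans(a, dims = 2L) else a
             })
           } else {
             generateSyntheticImages(s$images$n, s$images$size,
                                     seed = s$images$seed)
           }
           makeImagePatches(imgs,
                            imagePipelineConfig(patchPixels = s$patch_pixels,
                                                nPatches = s$n_patches,
                                                rngSeed = cfg$seed),
                            zeroMean = isTRUE(s$zero_mean))
         })
}

# Write the reproducibility manifest (config + seed + code version).
writeManifest <- function(cfg, outDir, extra = list()) {
  man <- c(list(package = "wdbcm",
                version = as.character(utils::packageVersion("wdbcm")),
                seed = cfg$seed, config = cfg), extra)
  jsonlite::write_json(man, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(man)
}
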