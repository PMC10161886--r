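#' Beamline configuration
#'
#' Central configuration for the virtual beamline and the centering/decision
#' algorithms. All defaults describe a realistic MX endstation at desk scale:
#' a narrow-field sample microscope viewing along the beam and a ~4.8x
#' wider-field top camera viewing vertically down for prelocation.
#'
#' Key entries:
#' \describe{
#'   \item{cameras}{named list of [CameraGeometry-class] (`microscope`, `top`)}
#'   \item{limits}{soft motor limits (mm / deg); moves beyond them raise
#'     `motorLimit`}
#'   \item{beamSizeMm}{beam size, also the grid-scan step (mm)}
#'   \item{thresholds}{per-mode grid-scan spot thresholds
#'     (`strong >= default >= weak`, `always_collect` fixed at 0)}
#'   \item{captureRangeMm}{half-range of the uniform random mount error per
#'     axis (mm)}
#'   \item{mountFailureProb, acquisitionFailureProb}{simulated fault rates}
#'   \item{roiDepthMm}{loop region-of-interest depth behind the tip
#'     (1.2x the expected loop diameter)}
#'   \item{tipTolerancePx}{residual tolerance for tip-at-beam (px)}
#'   \item{maxRefineRounds}{centering refinement rounds}
#'   \item{sweepStepDeg}{flat-face sweep spacing (deg; 5 samples over 180)}
#'   \item{minComponentPx}{minimum connected-component area kept by
#'     segmentation}
#'   \item{degenerateFitFrac}{amplitude/mean ratio below which the sinusoid
#'     fit is declared degenerate}
#' }
#'
#' @param ... named overrides, merged recursively into the defaults
#' @return a config list
#' @examples
#' cfg <- beamlineConfig(beamSizeMm = 0.1)
#' @export
beamlineConfig <- function(...) {
  cfg <- list(
    cameras = list(
      microscope = cameraGeometry("microscope", 320, 240, 200,
                                  viewAxis = "horizontal", openingKernel = 3),
      top = cameraGeometry("top", 384, 288, 50,
                           viewAxis = "vertical", openingKernel = 1)
    ),
    limits = list(x = c(-5, 5), y = c(-5, 5), z = c(-5, 5),
                  omega = c(-360, 360), chi = c(0, 40), phi = c(-360, 360)),
    beamSizeMm = 0.05,
    thresholds = list(default = 10, strong = 40, weak = 3),
    captureRangeMm = 0.5,
    mountFailureProb = 0,
    acquisitionFailureProb = 0,
    roiDepthMm = 0.85,
    tipTolerancePx = 2,
    maxRefineRounds = 3,
    sweepStepDeg = 40,
    minComponentPx = 20,
    degenerateFitFrac = 0.02,
    background = 230L,
    foreground = 25L,
    defaults = list(exposure_time = 0.01, oscillation = 0.1,
                    total_range = 360, transmission = 1, resolution = 2.0)
  )
  overrides <- list(...)
  if (length(overrides)) cfg <- utils::modifyList(cfg, overrides)
  cfg
}

#' Read / write a beamline configuration file
#'
#' Plain JSON; camera geometries are flattened to lists on disk.
#'
#' @param path file path
#' @param config a config list (for writing)
#' @return `readBeamlineConfig` returns a config list
#' @export
readBeamlineConfig <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  cams <- lapply(raw$cameras, function(cm) {
    cameraGeometry(cm$name, cm$width, cm$height, cm$pxPerMm,
                   beamMarker = unlist(cm$beamMarker),
                   viewAxis = cm$viewAxis,
                   drift = if (is.null(cm$drift)) c(0, 0) else unlist(cm$drift),
                   openingKernel = if (is.null(cm$openingKernel)) 3
                                   else cm$openingKernel)
  })
  raw$cameras <- NULL
  cfg <- beamlineConfig()
  cfg <- utils::modifyList(cfg, raw)
  if (length(cams)) cfg$cameras[names(cams)] <- cams
  cfg
}

#' @rdname readBeamlineConfig
#' @export
writeBeamlineConfig <- function(config, path) {
  cams <- lapply(config$cameras, function(cm) {
    list(name = cm@name, width = cm@width, height = cm@height,
         pxPerMm = cm@pxPerMm, beamMarker = cm@beamMarker,
         viewAxis = cm@viewAxis, drift = cm@drift,
         openingKernel = cm@openingKernel)
  })
  out <- config
  out$cameras <- cams
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Serialize / restore a loop scene as JSON
#'
#' Used for plain-text fixtures: every scene parameter round-trips exactly.
#'
#' @param scene a [LoopScene-class]
#' @param path file path
#' @return `readLoopScene` returns a `LoopScene`
#' @export
writeLoopScene <- function(scene, path) {
  sl <- slotNames(scene)
  out <- stats::setNames(lapply(sl, function(s) slot(scene, s)), sl)
  jsonlite::write_json(out, path, digits = NA)
  invisible(path)
}

#' @rdname writeLoopScene
#' @export
readLoopScene <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(loopScene, raw)
}
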