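#' @import methods
NULL

# ---------------------------------------------------------------------------
# LoopScene: ground-truth parametric sample (pin + planar elliptical loop +
# optional embedded crystal). All lengths in mm, angles in degrees.
# ---------------------------------------------------------------------------

#' Parametric loop scene
#'
#' Ground truth for the virtual beamline: a pin entering the field from the
#' left carrying a planar elliptical loop (semi-axes `a >= b`) whose plane is
#' parallel to the microscope image plane at goniometer angle
#' `flatFaceOmega`. The loop slab has a small extent (`thickness`) normal to
#' its plane. An optional Gaussian "crystal" embedded in the loop plane drives
#' the simulated diffraction spot counts.
#'
#' Crystal coordinates `(u, v)` are loop-plane coordinates relative to the
#' loop tip: `u` along the pin axis (negative into the loop, `u` in
#' `[-2a, 0]`), `v` across it.
#'
#' @slot pinLength numeric, pin length (mm)
#' @slot a,b numeric, loop ellipse semi-axes (mm), `a >= b > 0`
#' @slot flatFaceOmega numeric, flat-face angle in `[0, 180)` (deg)
#' @slot tipOffset numeric(3), loop-tip offset (dx, dy, dz) from the rotation
#'   axis at omega = 0 (mm)
#' @slot thickness numeric, loop extent normal to its plane (mm), `< 2 b`
#' @slot pinRadius numeric, pin cylinder radius (mm)
#' @slot crystalCenter numeric(2) `(u, v)` or `NA` for a crystal-free loop
#' @slot crystalSigma numeric, Gaussian crystal size (mm)
#' @slot crystalPeakSpots numeric, expected spot count with the beam on the
#'   crystal center
#' @slot backgroundSpots numeric, expected spot count far from the crystal
#' @slot iceJitterSigma numeric, sigma (mm) of the one-off isotropic tip
#'   displacement applied between optical and diffraction centering
#' @export
setClass("LoopScene", representation(
  pinLength = "numeric", a = "numeric", b = "numeric",
  flatFaceOmega = "numeric", tipOffset = "numeric", thickness = "numeric",
  pinRadius = "numeric", crystalCenter = "numeric", crystalSigma = "numeric",
  crystalPeakSpots = "numeric", backgroundSpots = "numeric",
  iceJitterSigma = "numeric"))

setValidity("LoopScene", function(object) {
  msg <- character()
  if (!(object@a >= object@b && object@b > 0))
    msg <- c(msg, "loop semi-axes must satisfy a >= b > 0")
  if (object@thickness <= 0 || object@thickness >= 2 * object@b)
    msg <- c(msg, "loop thickness must lie in (0, 2b)")
  if (object@pinLength <= 0 || object@pinRadius <= 0)
    msg <- c(msg, "pin dimensions must be positive")
  if (object@flatFaceOmega < 0 || object@flatFaceOmega >= 180)
    msg <- c(msg, "flatFaceOmega must lie in [0, 180)")
  if (length(object@tipOffset) != 3)
    msg <- c(msg, "tipOffset must have length 3")
  if (!anyNA(object@crystalCenter)) {
    u <- object@crystalCenter[1]; v <- object@crystalCenter[2]
    if (((u + object@a) / object@a)^2 + (v / object@b)^2 > 1 + 1e-9)
      msg <- c(msg, "crystal must lie inside the loop ellipse")
    if (object@crystalSigma <= 0)
      msg <- c(msg, "crystalSigma must be positive when a crystal is present")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a loop scene
#'
#' @param pinLength,a,b,flatFaceOmega,tipOffset,thickness,pinRadius,crystalCenter,crystalSigma,crystalPeakSpots,backgroundSpots,iceJitterSigma see [LoopScene-class]
#' @return a `LoopScene`
#' @examples
#' sc <- loopScene(flatFaceOmega = 62, crystalCenter = c(-0.35, 0.05))
#' @export
loopScene <- function(pinLength = 2.5, a = 0.35, b = 0.25, flatFaceOmega = 0,
                      tipOffset = c(0, 0, 0), thickness = 0.05,
                      pinRadius = 0.025, crystalCenter = c(NA_real_, NA_real_),
                      crystalSigma = 0.05, crystalPeakSpots = 100,
                      backgroundSpots = 0, iceJitterSigma = 0) {
  new("LoopScene", pinLength = pinLength, a = a, b = b,
      flatFaceOmega = flatFaceOmega, tipOffset = as.numeric(tipOffset),
      thickness = thickness, pinRadius = pinRadius,
      crystalCenter = as.numeric(crystalCenter), crystalSigma = crystalSigma,
      crystalPeakSpots = crystalPeakSpots, backgroundSpots = backgroundSpots,
      iceJitterSigma = iceJitterSigma)
}

setMethod("show", "LoopScene", function(object) {
  cat("LoopScene: ellipse", object@a, "x", object@b, "mm, thickness",
      object@thickness, "mm, flat face at", object@flatFaceOmega, "deg\n")
  if (!anyNA(object@crystalCenter))
    cat("  crystal at (u,v) = (", object@crystalCenter[1], ",",
        object@crystalCenter[2], ") mm, peak", object@crystalPeakSpots,
        "spots\n")
})

#' @describeIn loopScene flat-face angle accessor (degrees)
#' @param scene a `LoopScene`
#' @export
sceneFlatFace <- function(scene) scene@flatFaceOmega

#' @describeIn loopScene TRUE when the scene carries a crystal
#' @export
hasCrystal <- function(scene) !anyNA(scene@crystalCenter)

# ---------------------------------------------------------------------------
# CameraGeometry
# ---------------------------------------------------------------------------

#' Camera geometry
#'
#' Pixel geometry of one of the two beamline cameras. The `microscope`
#' camera views along the beam (horizontal view axis); the wide-field `top`
#' camera views vertically down, perpendicular to the omega rotation axis,
#' and is used for prelocation. Image convention: origin top-left, x right,
#' y down, 0-based pixel indices.
#'
#' @slot name `"microscope"` or `"top"`
#' @slot width,height image size in pixels
#' @slot pxPerMm isotropic pixel pitch (pixels per mm)
#' @slot beamMarker numeric(2), configured beam-marker pixel (bx, by)
#' @slot viewAxis `"horizontal"` (along beam) or `"vertical"` (top-down)
#' @slot drift numeric(2), simulated camera-mount shift in pixels (what
#'   calibration must recover)
#' @slot openingKernel odd integer; size of the morphological opening
#'   structuring element applied after thresholding (1 disables)
#' @export
setClass("CameraGeometry", representation(
  name = "character", width = "numeric", height = "numeric",
  pxPerMm = "numeric", beamMarker = "numeric", viewAxis = "character",
  drift = "numeric", openingKernel = "numeric"))

setValidity("CameraGeometry", function(object) {
  msg <- character()
  if (object@pxPerMm <= 0) msg <- c(msg, "pxPerMm must be positive")
  bm <- object@beamMarker
  if (bm[1] < 0 || bm[1] >= object@width || bm[2] < 0 || bm[2] >= object@height)
    msg <- c(msg, "beam marker must lie inside the image")
  if (!object@viewAxis %in% c("horizontal", "vertical"))
    msg <- c(msg, "viewAxis must be 'horizontal' or 'vertical'")
  if (length(msg)) msg else TRUE
})

#' Construct a camera geometry
#' @param name,width,height,pxPerMm,beamMarker,viewAxis,drift,openingKernel see [CameraGeometry-class]
#' @return a `CameraGeometry`
#' @export
cameraGeometry <- function(name, width, height, pxPerMm,
                           beamMarker = c(width / 2, height / 2),
                           viewAxis = c("horizontal", "vertical"),
                           drift = c(0, 0), openingKernel = 3) {
  new("CameraGeometry", name = name, width = width, height = height,
      pxPerMm = pxPerMm, beamMarker = as.numeric(beamMarker),
      viewAxis = match.arg(viewAxis), drift = as.numeric(drift),
      openingKernel = openingKernel)
}

setMethod("show", "CameraGeometry", function(object) {
  cat("CameraGeometry '", object@name, "': ", object@width, "x",
      object@height, " px @ ", object@pxPerMm, " px/mm (field ",
      round(object@width / object@pxPerMm, 2), " x ",
      round(object@height / object@pxPerMm, 2), " mm)\n", sep = "")
})

#' @describeIn cameraGeometry beam-marker pixel accessor
#' @param cam a `CameraGeometry`
#' @export
beamMarker <- function(cam) cam@beamMarker

#' @describeIn cameraGeometry pixel pitch accessor
#' @export
pxPerMm <- function(cam) cam@pxPerMm

# ---------------------------------------------------------------------------
# Frame
# ---------------------------------------------------------------------------

#' Camera frame
#'
#' An 8-bit grayscale image from one of the simulated cameras: uniform light
#' background with the sample rendered as a dark silhouette.
#'
#' @slot camera camera name
#' @slot pixels integer matrix (rows = image y, cols = image x), values 0-255
#' @slot omegaAtCapture goniometer omega when the frame was taken (deg)
#' @export
setClass("Frame", representation(
  camera = "character", pixels = "matrix", omegaAtCapture = "numeric"))

setMethod("show", "Frame", function(object) {
  cat("Frame from '", object@camera, "': ", ncol(object@pixels), "x",
      nrow(object@pixels), " px at omega = ", object@omegaAtCapture,
      " deg\n", sep = "")
})

#' @describeIn segmentFrame pixel matrix accessor
#' @export
framePixels <- function(frame) frame@pixels

# ---------------------------------------------------------------------------
# Silhouette
# ---------------------------------------------------------------------------

#' Binary silhouette
#'
#' Foreground mask produced by [segmentFrame()] (TRUE = sample).
#'
#' @slot mask logical matrix, same dimensions as the source frame
#' @slot camera source camera name
#' @slot omegaAtCapture omega at capture (deg)
#' @export
setClass("Silhouette", representation(
  mask = "matrix", camera = "character", omegaAtCapture = "numeric"))

setMethod("show", "Silhouette", function(object) {
  cat("Silhouette (", object@camera, "): ", sum(object@mask),
      " foreground px of ", length(object@mask), "\n", sep = "")
})

#' @describeIn segmentFrame mask accessor
#' @param sil a `Silhouette`
#' @export
silhouetteMask <- function(sil) sil@mask

# ---------------------------------------------------------------------------
# Centering results
# ---------------------------------------------------------------------------

#' Sinusoid fit of projected area over omega
#'
#' Least-squares fit of `area(omega) ~ c0 + c1 cos(2 omega) + c2 sin(2 omega)`
#' (the projected area of a planar loop is 180-degree periodic).
#' `omegaStar = atan2(c2, c1) / 2`, normalized to `[0, 180)`, maximizes the
#' fitted area.
#'
#' @slot c0,c1,c2 fitted coefficients
#' @slot omegaStar flat-face angle estimate (deg, in `[0, 180)`)
#' @slot residualNorm residual L2 norm of the fit
#' @export
setClass("SinusoidFit", representation(
  c0 = "numeric", c1 = "numeric", c2 = "numeric",
  omegaStar = "numeric", residualNorm = "numeric"))

setMethod("show", "SinusoidFit", function(object) {
  cat("SinusoidFit: omegaStar =", round(object@omegaStar, 3),
      "deg, amplitude =", round(sqrt(object@c1^2 + object@c2^2), 2),
      "on mean", round(object@c0, 2), "\n")
})

#' @describeIn fitFlatFace fitted flat-face angle accessor (deg)
#' @param fit a `SinusoidFit`
#' @export
omegaStar <- function(fit) fit@omegaStar

#' Optical centering result
#'
#' Output of [centerToFlat()]: the loop-tip motor coordinates, the flat-face
#' omega, the measured loop thickness and the bounding box of the loop region
#' of interest at the flat-face orientation.
#'
#' @slot tipMotor numeric(3), motor (x, y, z) with the tip at the beam (mm)
#' @slot flatFaceOmega flat-face omega (deg, `[0, 180)`); `NA` unless centered
#' @slot thicknessPx measured loop thickness at the edge-on orientation (px)
#' @slot bbox numeric(4) `(x1, y1, x2, y2)` pixel corners (0-based, inclusive)
#'   of the loop ROI at the flat face
#' @slot status `"centered"`, `"not_found"` or `"disabled"`
#' @export
setClass("CenteringResult", representation(
  tipMotor = "numeric", flatFaceOmega = "numeric", thicknessPx = "numeric",
  bbox = "numeric", status = "character"))

setValidity("CenteringResult", function(object) {
  if (!object@status %in% c("centered", "not_found", "disabled"))
    return("status must be centered/not_found/disabled")
  if (object@status != "centered" && !is.na(object@flatFaceOmega))
    return("flatFaceOmega is defined only when status is 'centered'")
  TRUE
})

setMethod("show", "CenteringResult", function(object) {
  cat("CenteringResult:", object@status, "\n")
  if (object@status == "centered") {
    cat("  tip motor (x,y,z) =", paste(round(object@tipMotor, 4), collapse = ", "),
        "mm\n  flat face =", round(object@flatFaceOmega, 2),
        "deg, thickness =", object@thicknessPx, "px\n  bbox =",
        paste(round(object@bbox), collapse = ", "), "\n")
  }
})

#' @describeIn centerToFlat status accessor
#' @param res a `CenteringResult`
#' @export
centeringStatus <- function(res) res@status

#' @describeIn centerToFlat tip motor coordinates accessor (mm)
#' @export
tipMotor <- function(res) res@tipMotor

#' @describeIn centerToFlat flat-face omega accessor (deg)
#' @export
flatFaceOmega <- function(res) res@flatFaceOmega

#' @describeIn centerToFlat ROI bounding box accessor (x1, y1, x2, y2 px)
#' @export
bboxCorners <- function(res) res@bbox

#' Top-camera calibration map
#'
#' Beam-marker pixel on the top camera as measured by [calibrateTopCam()]
#' (the microscope beam position mapped onto the top-camera image).
#'
#' @slot topMarker numeric(2), measured (bx, by) pixel on the top camera
#' @slot timestamp numeric, seconds since epoch
#' @export
setClass("CalibrationMap", representation(
  topMarker = "numeric", timestamp = "numeric"))

setMethod("show", "CalibrationMap", function(object) {
  cat("CalibrationMap: top-camera beam marker at (",
      round(object@topMarker[1], 2), ",", round(object@topMarker[2], 2),
      ") px\n")
})

#' @describeIn calibrateTopCam measured top-camera marker accessor
#' @param map a `CalibrationMap`
#' @export
topMarker <- function(map) map@topMarker

# ---------------------------------------------------------------------------
# Grid scan
# ---------------------------------------------------------------------------

#' Grid-scan result
#'
#' Spot counts aggregated over the boxes of a raster grid scan (rows x cols)
#' or a vertical line scan (n x 1), together with the motor-space geometry.
#' `positions` is a data.frame with one row per box in serpentine acquisition
#' order: `ix`, `iy` (0-based column/row in the grid), `x`, `y`, `z` (motor
#' targets, mm), `px`, `py` (box center projected into the microscope frame
#' at the centered motor position).
#'
#' @slot positions data.frame of box geometry (see above)
#' @slot nrowGrid,ncolGrid grid shape
#' @slot counts integer spot counts, parallel to `positions`
#' @slot omega omega (deg) at which the scan was performed
#' @slot stepMm grid step (= beam size, mm)
#' @export
setClass("GridScanResult", representation(
  positions = "data.frame", nrowGrid = "numeric", ncolGrid = "numeric",
  counts = "numeric", omega = "numeric", stepMm = "numeric"))

setValidity("GridScanResult", function(object) {
  if (length(object@counts) &&
      length(object@counts) != nrow(object@positions))
    return("counts length must equal the number of grid positions")
  if (length(object@counts) && any(object@counts < 0))
    return("counts must be non-negative")
  TRUE
})

setMethod("show", "GridScanResult", function(object) {
  cat("GridScanResult: ", object@nrowGrid, "x", object@ncolGrid,
      " boxes at omega = ", round(object@omega, 2), " deg",
      if (length(object@counts)) paste0(", max count ", max(object@counts)),
      "\n", sep = "")
})

#' @describeIn gridFromResult grid positions accessor
#' @param res a `GridScanResult`
#' @export
gridPositions <- function(res) res@positions

#' @describeIn gridFromResult spot counts accessor
#' @export
spotCounts <- function(res) res@counts

#' Thresholding policy for grid-scan analysis
#'
#' Four modes mirror the production options: `default` for typical samples,
#' `strong` for well-diffracting crystals, `weak` for weak diffractors such
#' as membrane proteins, and `always_collect` when every sample must be
#' collected regardless of spot counts (threshold 0).
#'
#' @slot mode one of `default`, `strong`, `weak`, `always_collect`
#' @slot minSpots per-box spot-count threshold for this mode
#' @export
setClass("ThresholdPolicy", representation(
  mode = "character", minSpots = "numeric"))

setValidity("ThresholdPolicy", function(object) {
  if (!object@mode %in% c("default", "strong", "weak", "always_collect"))
    return("unknown threshold mode")
  if (object@mode == "always_collect" && object@minSpots != 0)
    return("always_collect implies minSpots = 0")
  if (object@minSpots < 0) return("minSpots must be >= 0")
  TRUE
})

#' Build a threshold policy
#'
#' @param mode threshold mode
#' @param config beamline config (supplies per-mode thresholds, which must
#'   satisfy `strong >= default >= weak`)
#' @return a `ThresholdPolicy`
#' @export
thresholdPolicy <- function(mode = c("default", "strong", "weak",
                                     "always_collect"),
                            config = beamlineConfig()) {
  mode <- match.arg(mode)
  th <- config$thresholds
  stopifnot(th$strong >= th$default, th$default >= th$weak)
  new("ThresholdPolicy", mode = mode,
      minSpots = switch(mode, default = th$default, strong = th$strong,
                        weak = th$weak, always_collect = 0))
}

#' Diffraction-centering decision
#'
#' @slot outcome `"collect"` or `"skip"`
#' @slot position numeric(3) motor target for collection (mm); `NA` on skip
#' @slot omega collection omega (deg); `NA` on skip
#' @slot best2dIndex,bestLineIndex 1-based indices of the winning boxes
#' @slot peak2d,peakLine winning spot counts
#' @export
setClass("CenterDecision", representation(
  outcome = "character", position = "numeric", omega = "numeric",
  best2dIndex = "numeric", bestLineIndex = "numeric",
  peak2d = "numeric", peakLine = "numeric"))

setMethod("show", "CenterDecision", function(object) {
  if (object@outcome == "skip") {
    cat("CenterDecision: skip (no box above threshold)\n")
  } else {
    cat("CenterDecision: collect at (",
        paste(round(object@position, 4), collapse = ", "), ") mm, omega =",
        round(object@omega, 2), "deg; peaks", object@peak2d, "/",
        object@peakLine, "\n")
  }
})

#' @describeIn decideCollection outcome accessor (`"collect"`/`"skip"`)
#' @param decision a `CenterDecision`
#' @export
decisionOutcome <- function(decision) decision@outcome
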