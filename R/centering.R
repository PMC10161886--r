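# Optical loop centering. Two-camera path: wide-field top-camera prelocation
# brings the tip to the rotation axis / beam position so it enters the narrow
# microscope field and focus band; microscope centering then aligns the tip
# to the beam marker at two orthogonal omega values (centerOnTip) and the
# full flat-face procedure (centerToFlat) sweeps omega, fits the 180-degree
# periodic projected-area sinusoid, measures thickness edge-on and reports
# the flat-face bounding box for grid scanning.
#
# Pixel -> motor conversion: delta_motor = delta_pixel / pxPerMm. The
# centering motors ride on omega, so an image-vertical (lab y) displacement
# at angle omega maps to the motor pair (dy cos omega, -dy sin omega), and a
# top-camera (lab z) displacement to (dz sin omega, dz cos omega).

moveVerticalLab <- function(bl, dyLab) {
  w <- degToRad(bl$omega)
  bl$moveTo(y = dyLab * cos(w), z = -dyLab * sin(w), relative = TRUE)
}

moveDepthLab <- function(bl, dzLab) {
  w <- degToRad(bl$omega)
  bl$moveTo(y = dzLab * sin(w), z = dzLab * cos(w), relative = TRUE)
}

traceEvent <- function(trace, what, ...) {
  if (is.null(trace)) return(invisible(NULL))
  trace$events[[length(trace$events) + 1]] <- c(list(event = what), list(...))
  invisible(NULL)
}

#' Start a centering trace
#'
#' A trace collects per-step decisions (and optionally intermediate frames
#' as PNG files) from the centering procedures, for offline debugging.
#' Pass the returned environment as `trace =` to [centerOnTip()] /
#' [centerToFlat()]; write it out with [writeTrace()].
#'
#' @param frameDir optional directory for intermediate frame PNGs
#' @return a trace environment
#' @export
newTrace <- function(frameDir = NULL) {
  tr <- new.env(parent = emptyenv())
  tr$events <- list()
  tr$frameDir <- frameDir
  tr$nframes <- 0L
  tr
}

traceFrame <- function(trace, frame, tag) {
  if (is.null(trace) || is.null(trace$frameDir)) return(invisible(NULL))
  trace$nframes <- trace$nframes + 1L
  path <- file.path(trace$frameDir,
                    sprintf("%03d_%s.png", trace$nframes, tag))
  writeFramePNG(frame, path)
  traceEvent(trace, "frame", tag = tag, path = path)
}

#' @rdname newTrace
#' @param trace a trace environment
#' @param path JSON output path
#' @export
writeTrace <- function(trace, path) {
  jsonlite::write_json(trace$events, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Calibrate the beam-marker position on the top camera
#'
#' Mounts a small reference marker at the beam position (in simulation: a
#' marker scene whose tip sits exactly on the rotation axis) and measures
#' where it appears on the top camera. This maps the microscope beam
#' position onto the top-camera image, absorbing any camera-mount shift;
#' routine recalibration keeps the two cameras consistent to about a pixel.
#'
#' @param bl a `VirtualBeamline` (only its config/cameras are used; the
#'   procedure runs on a private beamline so the mounted sample, if any, is
#'   untouched)
#' @param markerScene optional [LoopScene-class] used as the reference marker
#' @return a [CalibrationMap-class]; raises `calibrationFailure` when the
#'   marker cannot be segmented
#' @export
calibrateTopCam <- function(bl, markerScene = NULL) {
  if (is.null(markerScene))
    markerScene <- loopScene(a = 0.12, b = 0.1, thickness = 0.06,
                             pinLength = 1.5, pinRadius = 0.05)
  cal <- virtualBeamline(bl$config)
  cal$scene <- markerScene
  cal$mode <- "alignment"
  sil <- segmentFrame(cal$render("top"), bl$config)
  tip <- tryCatch(findTip(sil),
                  beamloop_loopNotFound = function(e)
                    blStop("calibrationFailure",
                           "calibration marker could not be segmented"))
  new("CalibrationMap", topMarker = as.numeric(tip),
      timestamp = as.numeric(Sys.time()))
}

#' Prelocate the loop with the top camera
#'
#' Wide-field coarse alignment: identifies the loop tip on the top camera,
#' moves it to the calibrated beam position, rotates 90 degrees and repeats.
#' This aligns the tip to the rotation axis and beam so the sample is inside
#' the microscope field of view and its shallow focus band before microscope
#' centering starts.
#'
#' @param bl a `VirtualBeamline` with a sample mounted
#' @param map a [CalibrationMap-class] from [calibrateTopCam()]
#' @param rounds alignment rounds over the two orthogonal omega values
#' @param trace optional trace environment from [newTrace()]
#' @return the beamline, invisibly; raises `loopNotFound` when the tip is
#'   never segmented
#' @export
prelocate <- function(bl, map = calibrateTopCam(bl), rounds = 2,
                      trace = NULL) {
  cam <- bl$config$cameras$top
  entry <- bl$omega
  for (round in seq_len(rounds)) {
    for (off in c(0, 90)) {
      bl$moveTo(omega = normAngle360(entry + off))
      fr <- bl$render("top")
      traceFrame(trace, fr, sprintf("prelocate_w%g", off))
      tip <- findTip(segmentFrame(fr, bl$config))
      dxy <- map@topMarker - tip
      bl$moveTo(x = dxy[1] / cam@pxPerMm, relative = TRUE)
      moveDepthLab(bl, dxy[2] / cam@pxPerMm)
      traceEvent(trace, "prelocate_move", omega = bl$omega,
                 dpx = dxy[1], dpy = dxy[2])
    }
  }
  bl$moveTo(omega = normAngle360(entry))
  invisible(bl)
}

# Tip residual (px) w.r.t. the microscope beam marker at the current state.
tipResidual <- function(bl, config) {
  cam <- config$cameras$microscope
  tip <- findTip(segmentFrame(bl$render("microscope"), config))
  cam@beamMarker - tip
}

#' Center the loop tip on the microscope beam marker
#'
#' Locates the tip and aligns it to the beam marker, rotates 90 degrees and
#' aligns again, refining up to `maxRounds` times until the residual at both
#' orientations is within `tolerancePx`. The entry omega is restored on
#' success.
#'
#' @param bl a `VirtualBeamline` with the tip inside the microscope field
#'   (guaranteed by [prelocate()])
#' @param config beamline config
#' @param tolerancePx acceptance residual (px)
#' @param maxRounds refinement rounds
#' @param trace optional trace environment
#' @return final motor positions (x, y, z), invisibly; raises `loopNotFound`
#'   or `convergenceFailure`
#' @export
centerOnTip <- function(bl, config = bl$config,
                        tolerancePx = config$tipTolerancePx,
                        maxRounds = config$maxRefineRounds, trace = NULL) {
  cam <- config$cameras$microscope
  entry <- bl$omega
  done <- FALSE
  for (round in seq_len(maxRounds)) {
    worst <- 0
    xres <- numeric(0)
    for (off in c(0, 90)) {
      bl$moveTo(omega = normAngle360(entry + off))
      res <- tipResidual(bl, config)
      worst <- max(worst, abs(res[2]))
      xres <- c(xres, res[1])
      moveVerticalLab(bl, -res[2] / cam@pxPerMm)
      traceEvent(trace, "center_on_tip", round = round, omega = bl$omega,
                 residual = as.numeric(res))
    }
    # The along-axis (x) coordinate is orientation independent, and
    # silhouette tip detection can only under-reach (a near-edge-on loop's
    # shallow apex erodes inward), so the orientation whose detected tip
    # extends furthest is authoritative for x: use its residual for the
    # correction and the convergence check.
    xpick <- xres[which.min(xres)]
    worst <- max(worst, abs(xpick))
    bl$moveTo(x = xpick / cam@pxPerMm, relative = TRUE)
    # converged when the pre-move residual was already within tolerance at
    # both orientations
    if (worst <= tolerancePx) { done <- TRUE; break }
  }
  if (!done) {
    # final check after the last correction, same bias-aware measure
    bl$moveTo(omega = normAngle360(entry))
    r0 <- tipResidual(bl, config)
    bl$moveTo(omega = normAngle360(entry + 90))
    r90 <- tipResidual(bl, config)
    resid <- max(abs(r0[2]), abs(r90[2]), abs(min(r0[1], r90[1])))
    if (resid > tolerancePx)
      blStop("convergenceFailure",
             sprintf("tip residual %.1f px above tolerance %g px after %d rounds",
                     resid, tolerancePx, maxRounds))
  }
  bl$moveTo(omega = normAngle360(entry))
  invisible(bl$motor)
}

#' Fit the projected-area sinusoid and find the flat face
#'
#' Least-squares fit of `area ~ c0 + c1 cos(2 omega) + c2 sin(2 omega)` to
#' (omega, area) samples. A planar loop's projected area is 180-degree
#' periodic, so the 2-omega harmonic is the physically forced model; its
#' phase `omegaStar = atan2(c2, c1) / 2` (normalized to `[0, 180)`) is the
#' flat-face angle maximizing the fitted area.
#'
#' @param samples data.frame with columns `omega` (deg) and `area`
#' @param config beamline config (`degenerateFitFrac`: amplitude/mean ratio
#'   below which the fit is declared degenerate, e.g. a spherical sample)
#' @return a [SinusoidFit-class]; raises `degenerateFit` when the modulation
#'   amplitude is below the configured fraction of the mean area
#' @examples
#' w <- c(0, 40, 80, 120, 160)
#' fitFlatFace(data.frame(omega = w, area = 100 + 50 * cos(2 * degToRad(w - 30))))
#' @export
fitFlatFace <- function(samples, config = beamlineConfig()) {
  stopifnot(all(c("omega", "area") %in% names(samples)))
  wdist <- normAngle180(samples$omega)
  if (length(unique(round(wdist, 6))) < 3)
    stop("need >= 3 samples at distinct omega (mod 180)")
  w2 <- 2 * degToRad(samples$omega)
  X <- cbind(1, cos(w2), sin(w2))
  cf <- stats::lm.fit(X, samples$area)
  c0 <- cf$coefficients[1]; c1 <- cf$coefficients[2]; c2 <- cf$coefficients[3]
  amp <- sqrt(c1^2 + c2^2)
  if (amp < config$degenerateFitFrac * abs(c0))
    blStop("degenerateFit",
           sprintf("area modulation %.3g below %.3g of mean %.3g: no unique flat face",
                   amp, config$degenerateFitFrac, abs(c0)))
  new("SinusoidFit", c0 = unname(c0), c1 = unname(c1), c2 = unname(c2),
      omegaStar = unname(normAngle180(atan2(c2, c1) / 2 * 180 / pi)),
      residualNorm = sqrt(sum(cf$residuals^2)))
}

#' Full flat-face optical centering
#'
#' Executes the complete microscope centering procedure: center on the tip;
#' sweep omega over 180 degrees in `sweepStepDeg` steps (default 40, i.e.
#' five images; 180 is redundant with 0 under the 180-degree period)
#' measuring the projected loop-ROI area; fit the flat-face sinusoid; rotate
#' 90 degrees past the flat face and measure the loop thickness; re-center on
#' the tip; rotate to the flat face and compute the ROI bounding box. The
#' beamline is left at the flat-face omega.
#'
#' A degenerate sinusoid fit (near-constant area) downgrades to the entry
#' omega with a warning; a loop that is never found yields status
#' `"not_found"`; `noCentering = TRUE` returns status `"disabled"` without
#' any motor motion.
#'
#' @param bl a `VirtualBeamline`, prelocated
#' @param config beamline config
#' @param noCentering skip all centering (manual/special applications)
#' @param areaNoiseSd multiplicative noise sigma applied to the sweep areas
#'   (0 = measurement as-is; used to study fit robustness)
#' @param noiseSeed seed for `areaNoiseSd` draws
#' @param trace optional trace environment from [newTrace()]
#' @return a [CenteringResult-class]; the omega/area sweep samples are
#'   attached as `attr(result, "sweep")`
#' @export
centerToFlat <- function(bl, config = bl$config, noCentering = FALSE,
                         areaNoiseSd = 0, noiseSeed = NULL, trace = NULL) {
  if (noCentering)
    return(new("CenteringResult", tipMotor = bl$motor,
               flatFaceOmega = NA_real_, thicknessPx = NA_real_,
               bbox = rep(NA_real_, 4), status = "disabled"))
  cam <- config$cameras$microscope
  roiPx <- config$roiDepthMm * cam@pxPerMm
  notFound <- function(e) {
    new("CenteringResult", tipMotor = bl$motor, flatFaceOmega = NA_real_,
        thicknessPx = NA_real_, bbox = rep(NA_real_, 4),
        status = "not_found")
  }
  tryCatch({
    centerOnTip(bl, config, trace = trace)
    entry <- bl$omega
    sweep <- seq(0, 179, by = config$sweepStepDeg)
    areas <- vapply(sweep, function(off) {
      bl$moveTo(omega = normAngle360(entry + off))
      fr <- bl$render("microscope")
      traceFrame(trace, fr, sprintf("sweep_w%g", off))
      projectedArea(segmentFrame(fr, config), roiPx)
    }, numeric(1))
    if (areaNoiseSd > 0)
      areas <- areas * withSeed(noiseSeed,
                                stats::rnorm(length(areas), 1, areaNoiseSd))
    samples <- data.frame(omega = normAngle360(entry + sweep), area = areas)
    traceEvent(trace, "sweep", omega = samples$omega, area = samples$area)
    wstar <- tryCatch(omegaStar(fitFlatFace(samples, config)),
                      beamloop_degenerateFit = function(e) {
                        warning("degenerate flat-face fit; keeping entry omega",
                                call. = FALSE)
                        normAngle180(entry)
                      })
    bl$moveTo(omega = normAngle360(wstar + 90))
    thick <- verticalExtent(segmentFrame(bl$render("microscope"), config),
                            roiPx)
    centerOnTip(bl, config, trace = trace)
    bl$moveTo(omega = normAngle360(wstar))
    fr <- bl$render("microscope")
    traceFrame(trace, fr, "flat_face")
    bbox <- loopBoundingBox(segmentFrame(fr, config), roiPx)
    res <- new("CenteringResult", tipMotor = bl$motor,
               flatFaceOmega = normAngle180(wstar), thicknessPx = thick,
               bbox = as.numeric(bbox), status = "centered")
    traceEvent(trace, "center_to_flat", omegaStar = wstar,
               thicknessPx = thick, bbox = as.numeric(bbox))
    attr(res, "sweep") <- samples
    res
  }, beamloop_loopNotFound = notFound)
}

#' Generate grid-scan motor positions from a centering result
#'
#' Builds the 2D raster covering the flat-face bounding box: step equals the
#' beam size in both axes, the box count per axis follows the ceil rule
#' `n = ceil(extent / step)`, and the grid is centered on the bbox center.
#' The vertical extent spans the full bbox height, not the measured loop
#' thickness: samples commonly settle slightly between optical and
#' diffraction centering, so restricting the scan to the thickness risks
#' missing the crystal. Acquisition order is serpentine (boustrophedon),
#' row-major starting at the top-left box.
#'
#' @param res a [CenteringResult-class] with status `"centered"`
#' @param beamSize beam size = grid step (mm)
#' @param cam microscope [CameraGeometry-class]
#' @return a [GridScanResult-class] with empty counts (geometry only)
#' @export
gridFromResult <- function(res, beamSize, cam) {
  if (res@status != "centered")
    blStop("notCentered", "grid generation requires a centered result")
  ppm <- cam@pxPerMm
  bx <- cam@beamMarker[1]; by <- cam@beamMarker[2]
  bbox <- res@bbox
  widthMm <- (bbox[3] - bbox[1] + 1) / ppm
  heightMm <- (bbox[4] - bbox[2] + 1) / ppm
  ncol <- ceiling(widthMm / beamSize)
  nrow <- ceiling(heightMm / beamSize)
  xc <- ((bbox[1] + bbox[3]) / 2 - bx) / ppm       # lab-x offset of center
  yc <- (by - (bbox[2] + bbox[4]) / 2) / ppm       # lab-y offset of center
  xoff <- xc + (seq_len(ncol) - (ncol + 1) / 2) * beamSize
  yoff <- yc + ((nrow + 1) / 2 - seq_len(nrow)) * beamSize  # top row first
  wstar <- degToRad(res@flatFaceOmega)
  rows <- lapply(seq_len(nrow), function(iy) {
    cols <- if (iy %% 2 == 1) seq_len(ncol) else rev(seq_len(ncol))
    do.call(rbind, lapply(cols, function(ix) {
      ox <- xoff[ix]; oy <- yoff[iy]
      data.frame(ix = ix - 1, iy = iy - 1,
                 x = res@tipMotor[1] - ox,
                 y = res@tipMotor[2] - oy * cos(wstar),
                 z = res@tipMotor[3] + oy * sin(wstar),
                 px = bx + ox * ppm, py = by - oy * ppm)
    }))
  })
  new("GridScanResult", positions = do.call(rbind, rows),
      nrowGrid = nrow, ncolGrid = ncol, counts = numeric(0),
      omega = res@flatFaceOmega, stepMm = beamSize)
}
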