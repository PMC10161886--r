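# Diffraction-based centering decisions: thresholded best-box selection on
# the 2D raster, construction of the 90-degree-away vertical line scan, the
# final collect/skip decision and the heat-map overlay for reports.

#' Select the best grid box
#'
#' Returns the index (1-based, acquisition order) of the box with the
#' maximum spot count, or `NA` (skip) when every count is below the policy
#' threshold. Ties on the count are broken by the smallest Euclidean
#' distance of the box center to the grid centroid (motor space), then by
#' row-major order (`iy`, then `ix`).
#'
#' @param res a [GridScanResult-class] with counts
#' @param policy a [ThresholdPolicy-class]
#' @return integer index or `NA` for skip; raises `emptyGrid` on an empty
#'   grid
#' @export
selectBestBox <- function(res, policy) {
  counts <- res@counts
  if (length(counts) == 0) blStop("emptyGrid", "grid scan has no boxes")
  if (max(counts) < policy@minSpots) return(NA_integer_)
  cand <- which(counts == max(counts))
  if (length(cand) == 1) return(cand)
  pos <- res@positions
  centroid <- c(mean(pos$x), mean(pos$y), mean(pos$z))
  d <- sqrt((pos$x[cand] - centroid[1])^2 + (pos$y[cand] - centroid[2])^2 +
            (pos$z[cand] - centroid[3])^2)
  best <- cand[abs(d - min(d)) < 1e-9]
  best[order(pos$iy[best], pos$ix[best])][1]
}

#' Build the vertical line scan 90 degrees away
#'
#' After the 2D raster at the flat face, a one-dimensional vertical scan at
#' `omega + 90` resolves the crystal position along the former viewing axis.
#' The line sits at the best 2D box's motor position and spans the full ROI
#' height (bounding-box height, same ceil rule as the 2D grid) -- not the
#' measured loop thickness, for the same sample-settling reason as the 2D
#' grid.
#'
#' @param res the [CenteringResult-class] that produced the 2D grid
#' @param bestPos one row of the 2D grid positions (the best box)
#' @param beamSize beam size = step (mm)
#' @param cam microscope [CameraGeometry-class]
#' @param spanMm optional override of the scanned extent (mm); default full
#'   bbox height
#' @return an `n x 1` [GridScanResult-class] (geometry only)
#' @export
lineScanFor <- function(res, bestPos, beamSize, cam, spanMm = NULL) {
  if (res@status != "centered")
    blStop("notCentered", "line scan requires a centered result")
  ppm <- cam@pxPerMm
  if (is.null(spanMm)) spanMm <- (res@bbox[4] - res@bbox[2] + 1) / ppm
  n <- ceiling(spanMm / beamSize)
  omegaLine <- normAngle360(res@flatFaceOmega + 90)
  wl <- degToRad(omegaLine)
  d <- ((n + 1) / 2 - seq_len(n)) * beamSize        # top-of-image first
  pos <- data.frame(
    ix = 0, iy = seq_len(n) - 1,
    x = bestPos$x,
    y = bestPos$y - d * cos(wl),
    z = bestPos$z + d * sin(wl),
    px = bestPos$px, py = cam@beamMarker[2] - d * ppm)
  new("GridScanResult", positions = pos, nrowGrid = n, ncolGrid = 1,
      counts = numeric(0), omega = omegaLine, stepMm = beamSize)
}

#' Attach spot counts to a grid geometry
#'
#' @param grid a [GridScanResult-class] (geometry)
#' @param counts integer spot counts in acquisition order
#' @return the grid with counts
#' @export
withCounts <- function(grid, counts) {
  initialize(grid, counts = as.numeric(counts))
}

#' Decide where (whether) to collect
#'
#' Applies the threshold policy to the 2D raster; if any box passes, runs
#' the 90-degree-away vertical line scan on the beamline, selects the best
#' line box under the same policy, and returns a collect decision at the
#' final (x, y, z) with omega restored to the flat-face value for
#' collection. The sample is skipped if and only if every count in both
#' scans is below the threshold (the line scan only runs when the 2D scan
#' passes).
#'
#' @param res2d 2D [GridScanResult-class] with counts
#' @param policy a [ThresholdPolicy-class]
#' @param bl a `VirtualBeamline` (executes the line scan)
#' @param centering the [CenteringResult-class] behind the grid
#' @param seed seed for the simulated line-scan counts
#' @return a [CenterDecision-class]
#' @export
decideCollection <- function(res2d, policy, bl, centering, seed = 1L) {
  cam <- bl$config$cameras$microscope
  skip <- function(i2 = NA_integer_, p2 = NA_real_)
    new("CenterDecision", outcome = "skip", position = rep(NA_real_, 3),
        omega = NA_real_, best2dIndex = i2, bestLineIndex = NA_integer_,
        peak2d = p2, peakLine = NA_real_)
  i2 <- selectBestBox(res2d, policy)
  if (is.na(i2)) return(skip())
  best <- res2d@positions[i2, ]
  line <- lineScanFor(centering, best, res2d@stepMm, cam)
  lineCounts <- bl$simulateGridScan(line@positions, seed)
  line <- withCounts(line, lineCounts)
  i1 <- selectBestBox(line, policy)
  if (is.na(i1)) {
    out <- skip(i2, res2d@counts[i2])
    attr(out, "line") <- line
    return(out)
  }
  final <- line@positions[i1, ]
  out <- new("CenterDecision", outcome = "collect",
             position = c(final$x, final$y, final$z),
             omega = centering@flatFaceOmega,
             best2dIndex = i2, bestLineIndex = i1,
             peak2d = res2d@counts[i2], peakLine = lineCounts[i1])
  attr(out, "line") <- line
  out
}

#' @rdname decideCollection
#' @param decision a `CenterDecision`
#' @export
decisionPosition <- function(decision) decision@position

#' Heat-map overlay of grid-scan results
#'
#' Colors each grid box by its spot count over `[0, max]` (blue = 0, red =
#' max; uniform minimum color when all counts are zero) and alpha-blends the
#' cells onto a microscope frame at the box's projected pixel rectangle.
#'
#' @param res a [GridScanResult-class] with counts
#' @param frame the current microscope [Frame-class]
#' @param cam microscope [CameraGeometry-class]
#' @param alpha blend weight of the color layer
#' @return an `h x w x 3` integer array (RGB, 0-255)
#' @export
heatMap <- function(res, frame, cam, alpha = 0.45) {
  px <- frame@pixels
  h <- nrow(px); w <- ncol(px)
  out <- array(rep(as.numeric(px), 3), dim = c(h, w, 3))
  counts <- res@counts
  ramp <- grDevices::colorRamp(c("#2166AC", "#F7F7F7", "#B2182B"))
  mx <- if (length(counts) && max(counts) > 0) max(counts) else 1
  half <- res@stepMm * cam@pxPerMm / 2
  for (i in seq_len(nrow(res@positions))) {
    p <- res@positions[i, ]
    rgb <- ramp(if (length(counts)) counts[i] / mx else 0)
    r0 <- max(1, round(p$py - half) + 1); r1 <- min(h, round(p$py + half) + 1)
    c0 <- max(1, round(p$px - half) + 1); c1 <- min(w, round(p$px + half) + 1)
    if (r0 > r1 || c0 > c1) next
    for (k in 1:3)
      out[r0:r1, c0:c1, k] <- (1 - alpha) * out[r0:r1, c0:c1, k] +
        alpha * rgb[k]
  }
  storage.mode(out) <- "integer"
  out
}
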