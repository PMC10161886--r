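# Silhouette image analysis: global automatic (Otsu) thresholding of the
# dark-sample-on-light-background frames, small-object cleanup, loop-tip
# localization and loop ROI measurements. These primitives are camera
# agnostic: they consume any 8-bit grayscale Frame (simulated or loaded from
# PNG).

# Otsu's between-class-variance threshold on a 0-255 image. Returns NA for a
# constant image (nothing to separate).
otsuThreshold <- function(px) {
  counts <- tabulate(as.integer(px) + 1L, nbins = 256L)
  if (sum(counts > 0) < 2) return(NA_real_)
  p <- counts / sum(counts)
  levels <- 0:255
  w0 <- cumsum(p)
  mu <- cumsum(p * levels)
  muT <- mu[256]
  w1 <- 1 - w0
  valid <- w0 > 0 & w1 > 0
  sigmaB <- rep(-Inf, 256)
  sigmaB[valid] <- (muT * w0[valid] - mu[valid])^2 / (w0[valid] * w1[valid])
  levels[which.max(sigmaB)]
}

shiftMask <- function(m, dr, dc, fill = FALSE) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- seq_len(nr) - dr; cs <- seq_len(nc) - dc
  rok <- rs >= 1 & rs <= nr; cok <- cs >= 1 & cs <= nc
  out[rok, cok] <- m[rs[rok], cs[cok]]
  out
}

# Morphological opening with a cross (4-neighbourhood) structuring element
# of size k (k odd; k = 1 disables). The cross is preferred over the full
# square because the square erodes the shallow tip of a near-edge-on loop by
# several pixels, biasing tip detection in an orientation-dependent way.
morphOpen <- function(mask, k = 3) {
  if (k <= 1) return(mask)
  r <- (k - 1) / 2
  offs <- expand.grid(dr = -r:r, dc = -r:r)
  offs <- offs[offs$dr == 0 | offs$dc == 0, ]
  er <- mask
  for (i in seq_len(nrow(offs)))
    er <- er & shiftMask(mask, offs$dr[i], offs$dc[i], fill = FALSE)
  di <- er
  for (i in seq_len(nrow(offs)))
    di <- di | shiftMask(er, offs$dr[i], offs$dc[i], fill = FALSE)
  di
}

# Drop 4-connected components smaller than minPx (noise specks).
removeSmallComponents <- function(mask, minPx) {
  nfg <- sum(mask)
  if (nfg == 0 || minPx <= 1) return(mask)
  lab <- matrix(0L, nrow(mask), ncol(mask))
  lab[mask] <- seq_len(nfg)
  nr <- nrow(mask); nc <- ncol(mask)
  rpair <- mask[, -nc, drop = FALSE] & mask[, -1, drop = FALSE]
  dpair <- mask[-nr, , drop = FALSE] & mask[-1, , drop = FALSE]
  e1 <- cbind(lab[, -nc, drop = FALSE][rpair], lab[, -1, drop = FALSE][rpair])
  e2 <- cbind(lab[-nr, , drop = FALSE][dpair], lab[-1, , drop = FALSE][dpair])
  edges <- rbind(e1, e2)
  g <- igraph::make_empty_graph(n = nfg, directed = FALSE)
  if (nrow(edges)) g <- igraph::add_edges(g, t(edges))
  comp <- igraph::components(g)
  keep <- comp$csize[comp$membership] >= minPx
  out <- matrix(FALSE, nr, nc)
  out[mask] <- keep
  out
}

#' Segment a frame into a binary silhouette
#'
#' Global Otsu thresholding (dark foreground on light background), followed
#' by a morphological opening (square kernel, size from the camera geometry;
#' disabled on the wide-field top camera where thin loop rims are only a
#' couple of pixels) and removal of connected components smaller than
#' `minComponentPx`. A uniform frame yields an empty mask, never an error.
#'
#' @param frame a [Frame-class]
#' @param config a [beamlineConfig()] list (camera lookup + minimum
#'   component size)
#' @return a [Silhouette-class]
#' @export
segmentFrame <- function(frame, config = beamlineConfig()) {
  px <- frame@pixels
  thr <- otsuThreshold(px)
  if (is.na(thr)) {
    mask <- matrix(FALSE, nrow(px), ncol(px))
  } else {
    mask <- px <= thr
    cam <- config$cameras[[frame@camera]]
    kernel <- if (is.null(cam)) 3 else cam@openingKernel
    mask <- morphOpen(mask, kernel)
    mask <- removeSmallComponents(mask, config$minComponentPx)
  }
  new("Silhouette", mask = mask, camera = frame@camera,
      omegaAtCapture = frame@omegaAtCapture)
}

#' Locate the loop tip in a silhouette
#'
#' The tip is the extremal foreground pixel along the tip direction (the pin
#' enters the frame from the left, so the default is +x). Among tied extremal
#' pixels the one at the (lower) median perpendicular coordinate is chosen --
#' a stable, symmetric tie-break.
#'
#' @param sil a [Silhouette-class]
#' @param direction `"+x"` (tip at maximum x, default) or `"-x"`
#' @return numeric(2) 0-based pixel `(px, py)`
#' @export
findTip <- function(sil, direction = c("+x", "-x")) {
  direction <- match.arg(direction)
  mask <- sil@mask
  if (!any(mask)) blStop("loopNotFound", "empty silhouette: no loop tip")
  colsWithFg <- which(colSums(mask) > 0)
  tipCol <- if (direction == "+x") max(colsWithFg) else min(colsWithFg)
  rows <- which(mask[, tipCol])
  tipRow <- sort(rows)[floor((length(rows) + 1) / 2)]
  c(tipCol - 1, tipRow - 1)
}

# Restrict a mask to the loop region of interest: foreground within
# roiDepthPx of the tip along the tip direction (keeps pin and gripper out
# of area/bbox measurements).
roiMask <- function(sil, roiDepthPx = Inf, direction = "+x") {
  mask <- sil@mask
  if (!any(mask) || !is.finite(roiDepthPx)) return(mask)
  tip <- findTip(sil, direction)
  cols <- matrix(rep(seq_len(ncol(mask)) - 1, each = nrow(mask)),
                 nrow(mask), ncol(mask))
  if (direction == "+x") mask & (cols >= tip[1] - roiDepthPx)
  else mask & (cols <= tip[1] + roiDepthPx)
}

#' Loop ROI measurements
#'
#' `projectedArea` counts foreground pixels in the loop region of interest
#' (foreground within `roiDepthPx` of the tip; `Inf` = whole mask).
#' `verticalExtent` is the ROI height in pixels (max row - min row + 1);
#' `loopBoundingBox` the axis-aligned ROI corners `(x1, y1, x2, y2)`
#' (0-based, inclusive). The latter two raise `loopNotFound` on an empty
#' mask; `projectedArea` returns 0.
#'
#' @param sil a [Silhouette-class]
#' @param roiDepthPx ROI depth behind the tip in pixels (default `Inf`)
#' @param direction tip direction, see [findTip()]
#' @return see details
#' @export
projectedArea <- function(sil, roiDepthPx = Inf, direction = "+x") {
  if (!any(sil@mask)) return(0L)
  sum(roiMask(sil, roiDepthPx, direction))
}

#' @rdname projectedArea
#' @export
verticalExtent <- function(sil, roiDepthPx = Inf, direction = "+x") {
  if (!any(sil@mask)) blStop("loopNotFound", "empty silhouette")
  m <- roiMask(sil, roiDepthPx, direction)
  rows <- which(rowSums(m) > 0)
  max(rows) - min(rows) + 1
}

#' @rdname projectedArea
#' @export
loopBoundingBox <- function(sil, roiDepthPx = Inf, direction = "+x") {
  if (!any(sil@mask)) blStop("loopNotFound", "empty silhouette")
  m <- roiMask(sil, roiDepthPx, direction)
  rows <- which(rowSums(m) > 0)
  cols <- which(colSums(m) > 0)
  c(min(cols) - 1, min(rows) - 1, max(cols) - 1, max(rows) - 1)
}
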