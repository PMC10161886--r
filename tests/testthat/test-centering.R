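# Dense grid-search oracle for the flat-face angle of an arbitrary
# 2-omega sinusoid (independent of the closed-form fit).
oracleFlatFace <- function(c0, c1, c2, gridStep = 0.1) {
  grid <- seq(0, 180 - gridStep, by = gridStep)
  vals <- c0 + c1 * cos(2 * grid * pi / 180) + c2 * sin(2 * grid * pi / 180)
  grid[which.max(vals)]
}

test_that("top-camera calibration recovers the beam marker, also after a mount shift", {
  bl <- virtualBeamline()
  map <- calibrateTopCam(bl)
  expect_lte(max(abs(topMarker(map) - beamMarker(bl$config$cameras$top))), 1)

  # simulated camera-mount shift of (7, 2) px: recalibration tracks it
  cfg <- beamlineConfig()
  cfg$cameras$top@drift <- c(7, 2)
  bl2 <- virtualBeamline(cfg)
  map2 <- calibrateTopCam(bl2)
  expect_lte(max(abs(topMarker(map2) -
                       (beamMarker(cfg$cameras$top) + c(7, 2)))), 1)

  # marker placed outside the field of view cannot be segmented
  farScene <- loopScene(tipOffset = c(0, 0, 4))
  expect_error(calibrateTopCam(bl, markerScene = farScene),
               class = "beamloop_calibrationFailure")
})

test_that("prelocation aligns the tip to the beam at two orthogonal omegas", {
  cfg <- beamlineConfig(captureRangeMm = 0)
  topCam <- cfg$cameras$top

  # already centered: essentially no net motion
  bl <- virtualBeamline(cfg)
  bl$mountSample(loopScene(tipOffset = c(0, 0, 0)), seed = 1)
  prelocate(bl)
  expect_lte(max(abs(bl$motor)), 1 / pxPerMm(topCam))

  # a large offset within the top-camera field: tip lands on the beam marker
  bl2 <- virtualBeamline(cfg)
  bl2$mountSample(loopScene(tipOffset = c(0.8, 0.4, -0.3)), seed = 1)
  map <- calibrateTopCam(bl2)
  prelocate(bl2, map)
  for (w in c(bl2$omega, bl2$omega + 90)) {
    bl2$moveTo(omega = w)
    tipPx <- findTip(segmentFrame(bl2$render("top"), cfg))
    expect_lte(max(abs(tipPx - topMarker(map))), 3)
  }
  # and the sample is now inside the microscope field of view
  expect_gt(sum(silhouetteMask(segmentFrame(bl2$render("microscope"), cfg))), 0)

  # no visible loop at all
  bl3 <- virtualBeamline(cfg)
  bl3$mountSample(loopScene(tipOffset = c(0, 3, 3)), seed = 1)
  expect_error(prelocate(bl3), class = "beamloop_loopNotFound")
})

test_that("centerOnTip converges to the beam marker and is idempotent", {
  cfg <- beamlineConfig(captureRangeMm = 0)
  bl <- virtualBeamline(cfg)
  bl$mountSample(loopScene(flatFaceOmega = 25, tipOffset = c(0.3, 0.2, -0.1)),
                 seed = 1)
  centerOnTip(bl)
  cam <- cfg$cameras$microscope
  for (w in c(0, 90)) {
    bl$moveTo(omega = w)
    tipPx <- findTip(segmentFrame(bl$render("microscope"), cfg))
    expect_lte(max(abs(tipPx - beamMarker(cam))), 2)
  }
  bl$moveTo(omega = 0)

  # idempotence: a second run moves the motors by less than the tolerance
  m1 <- bl$motor
  centerOnTip(bl)
  expect_lte(max(abs(bl$motor - m1)), 2 / pxPerMm(cam))
  # entry omega restored
  expect_equal(bl$omega, 0)

  # tip far outside the microscope field without prelocation
  bl2 <- virtualBeamline(cfg)
  bl2$mountSample(loopScene(tipOffset = c(0, 1, 0)), seed = 1)
  expect_error(centerOnTip(bl2), class = "beamloop_loopNotFound")
})

test_that("fitFlatFace recovers the exact phase and matches the dense oracle", {
  w <- c(0, 40, 80, 120, 160)
  area <- 100 + 50 * cos(2 * (w - 30) * pi / 180)
  fit <- fitFlatFace(data.frame(omega = w, area = area))
  expect_equal(omegaStar(fit), 30, tolerance = 1e-6)
  # against the dense 0.1-degree grid search on the generating function
  expect_lte(angDiff180(omegaStar(fit),
                        oracleFlatFace(100, 50 * cos(60 * pi / 180),
                                       50 * sin(60 * pi / 180))), 0.2)

  # random non-degenerate triples
  for (s in 1:50) {
    p <- withr::with_seed(s, {
      c0 <- runif(1, 50, 200)
      amp <- c0 * runif(1, 0.05, 0.8)
      th <- runif(1, 0, 180)
      c(c0, amp * cos(2 * th * pi / 180), amp * sin(2 * th * pi / 180))
    })
    area <- p[1] + p[2] * cos(2 * w * pi / 180) + p[3] * sin(2 * w * pi / 180)
    fit <- fitFlatFace(data.frame(omega = w, area = area))
    expect_lte(angDiff180(omegaStar(fit), oracleFlatFace(p[1], p[2], p[3])),
               0.2)
  }

  # constant area: no unique maximum by symmetry
  expect_error(fitFlatFace(data.frame(omega = w, area = rep(100, 5))),
               class = "beamloop_degenerateFit")
  # too few distinct angles
  expect_error(fitFlatFace(data.frame(omega = c(0, 180), area = c(1, 1))))
})

test_that("centerToFlat recovers the scene's flat face, thickness and bounding box", {
  cfg <- beamlineConfig()
  sc <- loopScene(flatFaceOmega = 62, tipOffset = c(0.02, -0.03, 0.04))
  bl <- virtualBeamline(cfg)
  bl$mountSample(sc, seed = 7)
  prelocate(bl)
  res <- centerToFlat(bl)
  expect_equal(centeringStatus(res), "centered")
  expect_lte(angDiff180(flatFaceOmega(res), 62), 2)

  # thickness measured edge-on, in pixels
  expect_lte(abs(res@thicknessPx - sc@thickness * 200), 3)

  # bounding box against the analytic silhouette at the flat face,
  # restricted to the same ROI depth
  bl$moveTo(omega = flatFaceOmega(res))
  truth <- bl$groundTruthMask("microscope")
  tipPx <- projectPoint(cfg$cameras$microscope, bl$labTip())
  cols <- matrix(rep(seq_len(ncol(truth)) - 1, each = nrow(truth)),
                 nrow(truth), ncol(truth))
  truth <- truth & (cols >= tipPx[1] - cfg$roiDepthMm * 200)
  rows <- which(rowSums(truth) > 0); colsFg <- which(colSums(truth) > 0)
  tb <- c(min(colsFg) - 1, min(rows) - 1, max(colsFg) - 1, max(rows) - 1)
  bb <- bboxCorners(res)
  inter <- max(0, min(bb[3], tb[3]) - max(bb[1], tb[1]) + 1) *
           max(0, min(bb[4], tb[4]) - max(bb[2], tb[2]) + 1)
  areaB <- (bb[3] - bb[1] + 1) * (bb[4] - bb[2] + 1)
  areaT <- (tb[3] - tb[1] + 1) * (tb[4] - tb[2] + 1)
  iou <- inter / (areaB + areaT - inter)
  expect_gte(iou, 0.8)

  # tip's projected pixel lies on the bbox tip-direction edge
  expect_lte(abs(bb[3] - tipPx[1]), 2)
  # beamline left at the flat-face omega, within [0, 360)
  expect_equal(bl$omega, flatFaceOmega(res))
  expect_true(bl$omega >= 0 && bl$omega < 360)
})

test_that("noCentering and loop-free scenes short-circuit with the right status", {
  cfg <- beamlineConfig(captureRangeMm = 0)
  bl <- virtualBeamline(cfg)
  bl$mountSample(loopScene(tipOffset = c(0.1, 0.1, 0)), seed = 1)
  m0 <- bl$motor; w0 <- bl$omega
  res <- centerToFlat(bl, noCentering = TRUE)
  expect_equal(centeringStatus(res), "disabled")
  expect_identical(bl$motor, m0)
  expect_identical(bl$omega, w0)
  expect_true(is.na(flatFaceOmega(res)))

  bl2 <- virtualBeamline(cfg)
  bl2$mountSample(loopScene(tipOffset = c(0, 3, 3)), seed = 1)
  res2 <- centerToFlat(bl2)
  expect_equal(centeringStatus(res2), "not_found")
})

test_that("grid generation follows the ceil rule with exact spacing and serpentine order", {
  cam <- beamlineConfig()$cameras$microscope
  mk <- function(wMm, hMm, ppm = 200) {
    # bbox centered on the beam marker with the requested metric size
    bx <- beamMarker(cam)[1]; by <- beamMarker(cam)[2]
    new("CenteringResult", tipMotor = c(0, 0, 0), flatFaceOmega = 0,
        thicknessPx = 10,
        bbox = c(bx - wMm * ppm / 2, by - hMm * ppm / 2,
                 bx + wMm * ppm / 2 - 1, by + hMm * ppm / 2 - 1),
        status = "centered")
  }
  g <- gridFromResult(mk(0.30, 0.20), 0.10, cam)
  expect_equal(c(g@nrowGrid, g@ncolGrid), c(2, 3))
  xs <- sort(unique(gridPositions(g)$x))
  expect_equal(diff(xs), rep(0.10, 2))
  ys <- sort(unique(gridPositions(g)$y))
  expect_equal(diff(ys), rep(0.10, 1))

  # serpentine: first row left-to-right, second reversed
  p <- gridPositions(g)
  expect_equal(p$ix[p$iy == 0], 0:2)
  expect_equal(p$ix[p$iy == 1], 2:0)

  # ceil rule: 0.25 mm wide at 0.1 mm beam -> 3 columns
  g2 <- gridFromResult(mk(0.25, 0.20), 0.10, cam)
  expect_equal(g2@ncolGrid, 3)

  # coverage: every bbox point within beamSize/2 per axis of a grid position
  for (s in 1:40) {
    dims <- withr::with_seed(200 + s,
      c(runif(1, 0.05, 0.6), runif(1, 0.05, 0.5), runif(1, 0.02, 0.12)))
    res <- mk(dims[1], dims[2])
    g3 <- gridFromResult(res, dims[3], cam)
    expect_equal(g3@ncolGrid, ceiling(dims[1] / dims[3]))
    expect_equal(g3@nrowGrid, ceiling(dims[2] / dims[3]))
    # per-axis edge distance check in motor space (bbox centered at 0 here)
    xs <- sort(unique(gridPositions(g3)$x))
    span <- (g3@ncolGrid - 1) * dims[3]
    expect_lte((dims[1] - span) / 2, dims[3] / 2 + 1e-9)
    ys <- sort(unique(gridPositions(g3)$y))
    expect_lte((dims[2] - (g3@nrowGrid - 1) * dims[3]) / 2, dims[3] / 2 + 1e-9)
  }

  # grid pixel centers land inside the bbox dilated by one step
  res <- mk(0.3, 0.2)
  g4 <- gridFromResult(res, 0.1, cam)
  p4 <- gridPositions(g4)
  step <- 0.1 * 200
  expect_true(all(p4$px >= res@bbox[1] - step & p4$px <= res@bbox[3] + step))
  expect_true(all(p4$py >= res@bbox[2] - step & p4$py <= res@bbox[4] + step))

  expect_error(gridFromResult(new("CenteringResult", tipMotor = c(0, 0, 0),
                                  flatFaceOmega = NA_real_,
                                  thicknessPx = NA_real_,
                                  bbox = rep(NA_real_, 4),
                                  status = "not_found"),
                              0.1, cam),
               class = "beamloop_notCentered")
})

test_that("a centering trace records sweep samples and frames", {
  dir <- withr::local_tempdir()
  tr <- newTrace(frameDir = dir)
  bl <- mountedBeamline(loopScene(flatFaceOmega = 100), seed = 2)
  prelocate(bl)
  res <- centerToFlat(bl, trace = tr)
  expect_equal(centeringStatus(res), "centered")
  kinds <- vapply(tr$events, function(e) e$event, character(1))
  expect_true("sweep" %in% kinds)
  expect_gt(sum(kinds == "frame"), 4)
  jp <- file.path(dir, "trace.json")
  writeTrace(tr, jp)
  expect_true(jsonlite::validate(paste(readLines(jp), collapse = "")))
  # sweep samples exposed on the result
  expect_equal(nrow(attr(res, "sweep")), 5)
})
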