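# Lab frame convention: x along the omega rotation axis (pin direction,
# pointing right in both camera images), y vertical (up), z along the beam at
# omega = 0. Omega rotates the sample about x. The centering motors (y, z)
# ride on the rotation, so a motor displacement is expressed in the omega = 0
# sample frame and rotated into the lab by R(omega); at omega = 0 motor and
# lab frames coincide, which fixes the documented sign convention: moving the
# sample +1 mm in lab y shifts its silhouette by -pxPerMm pixels in image y.

rotYZ <- function(v, omegaDeg) {
  w <- degToRad(omegaDeg)
  c(v[1], cos(w) * v[2] - sin(w) * v[3], sin(w) * v[2] + cos(w) * v[3])
}

# Loop-plane basis in the omega = 0 scene frame. e1 is the pin axis (x); e2
# is chosen so that at omega = flatFaceOmega the plane is parallel to the
# microscope image plane (x-y), i.e. face-on along the beam.
sceneBasis <- function(scene) {
  w0 <- degToRad(-scene@flatFaceOmega)
  list(e1 = c(1, 0, 0), e2 = c(0, cos(w0), sin(w0)))
}

# All scene geometry in the lab frame at the current motor state.
labGeometry <- function(scene, shift, motor, omegaDeg) {
  tipS <- scene@tipOffset + shift + motor
  baseS <- tipS - c(2 * scene@a, 0, 0)          # loop/pin junction
  centerS <- tipS - c(scene@a, 0, 0)            # ellipse center
  th <- degToRad(omegaDeg - scene@flatFaceOmega)
  list(
    tip = rotYZ(tipS, omegaDeg),
    center = rotYZ(centerS, omegaDeg),
    pinAxis = rotYZ(baseS, omegaDeg),           # pin axis passes through this
    pinXRange = c(baseS[1] - scene@pinLength, baseS[1]),
    e2 = c(0, cos(th), sin(th)),                # loop in-plane unit vector
    n = c(0, -sin(th), cos(th))                 # loop-plane normal
  )
}

# Crystal position in the omega = 0 scene frame, motor excluded (the motor
# target that brings it to the beam is exactly -cryst because the motors ride
# the rotation and rotation preserves the origin).
crystalSceneFrame <- function(scene, shift) {
  if (!hasCrystal(scene)) return(NULL)
  bs <- sceneBasis(scene)
  scene@tipOffset + shift +
    scene@crystalCenter[1] * bs$e1 + scene@crystalCenter[2] * bs$e2
}

# Per-camera pixel <-> mm mapping. Horizontal coordinate is lab x for both
# cameras; the image-vertical coordinate is lab y for the microscope (y up =>
# py down) and lab z for the top camera.
camVerticalIndex <- function(cam) if (cam@viewAxis == "horizontal") 2L else 3L

#' Project a lab-frame point into a camera image
#'
#' @param cam a [CameraGeometry-class]
#' @param p numeric(3) lab point (mm)
#' @return numeric(2) continuous (px, py), 0-based
#' @export
projectPoint <- function(cam, p) {
  px <- cam@beamMarker[1] + cam@drift[1] + p[1] * cam@pxPerMm
  v <- p[camVerticalIndex(cam)]
  py <- if (cam@viewAxis == "horizontal") {
    cam@beamMarker[2] + cam@drift[2] - v * cam@pxPerMm
  } else {
    cam@beamMarker[2] + cam@drift[2] + v * cam@pxPerMm
  }
  c(px, py)
}

# mm coordinates of pixel centers along columns (lab x) and rows (lab y or z)
pixelAxes <- function(cam) {
  ppm <- cam@pxPerMm
  xs <- (seq_len(cam@width) - 1 - cam@beamMarker[1] - cam@drift[1]) / ppm
  iy <- seq_len(cam@height) - 1
  vs <- if (cam@viewAxis == "horizontal") {
    (cam@beamMarker[2] + cam@drift[2] - iy) / ppm
  } else {
    (iy - cam@beamMarker[2] - cam@drift[2]) / ppm
  }
  list(x = xs, v = vs)
}

# Exact silhouette membership. The loop body is modeled as a flattened
# ellipsoid (semi-axes a along the pin, b across the loop plane, thickness/2
# along the plane normal): its orthographic shadow is an exact ellipse whose
# vertical semi-axis is sqrt((b e2_v)^2 + (t/2 n_v)^2), so the projected
# area is maximized exactly at the flat face and the edge-on height equals
# the loop thickness. The pin is a cylinder along x (orthographic half-width
# = its radius in any view).
silhouetteMembership <- function(scene, geom, cam) {
  ax <- pixelAxes(cam)
  vi <- camVerticalIndex(cam)
  ppm <- cam@pxPerMm

  a <- scene@a
  bv <- max(sqrt((scene@b * geom$e2[vi])^2 +
                 (scene@thickness / 2 * geom$n[vi])^2), 0.5 / ppm)
  A <- ((ax$x - geom$center[1]) / a)^2
  B <- ((ax$v - geom$center[vi]) / bv)^2
  loop <- outer(B, A, "+") <= 1

  colSel <- ax$x >= geom$pinXRange[1] & ax$x <= geom$pinXRange[2]
  rowSel <- abs(ax$v - geom$pinAxis[vi]) <= scene@pinRadius
  loop | outer(rowSel, colSel, "&")
}

#' Virtual beamline
#'
#' A mutable simulator standing in for all hardware: it holds the goniometer
#' state (x, y, z translations riding on the omega rotation, plus chi and phi
#' orientation axes), the mounted [LoopScene-class], and the camera
#' geometries; it renders silhouette frames, executes motor moves against
#' soft limits and synthesizes Poisson diffraction spot counts for grid
#' positions. All randomness flows through explicit seeds.
#'
#' Methods (Reference Class):
#' \describe{
#'   \item{`$mountSample(scene, seed)`}{attach a scene; applies a seeded
#'     uniform mount error within `captureRangeMm` per axis and switches the
#'     beamline to alignment mode. Raises `mountFailure` with probability
#'     `mountFailureProb`.}
#'   \item{`$dismount()`}{remove the sample, back to idle.}
#'   \item{`$moveTo(x, y, z, omega, chi, phi, relative = FALSE)`}{move motors;
#'     targets outside the soft limits raise `motorLimit` without moving.}
#'   \item{`$render(camera)`}{pure render of the current state; raises
#'     `noSampleMounted` when empty.}
#'   \item{`$applyIceJitter(seed)`}{one-off isotropic Gaussian tip
#'     displacement (sigma from the scene), emulating sample settling between
#'     optical and diffraction centering.}
#'   \item{`$simulateGridScan(positions, seed)`}{Poisson spot counts for a
#'     data.frame of motor targets.}
#'   \item{`$labTip()`, `$labCrystal()`}{ground-truth lab positions for
#'     tests.}
#' }
#'
#' @param config a [beamlineConfig()] list
#' @return a `VirtualBeamline` reference object
#' @examples
#' bl <- virtualBeamline()
#' bl$mountSample(loopScene(flatFaceOmega = 30), seed = 1)
#' fr <- bl$render("microscope")
#' @export
virtualBeamline <- function(config = beamlineConfig()) {
  VirtualBeamline$new(config = config)
}

VirtualBeamline <- setRefClass(
  "VirtualBeamline",
  fields = list(
    scene = "ANY", config = "list", motor = "numeric",
    omega = "numeric", chi = "numeric", phi = "numeric",
    mode = "character", shift = "numeric"),
  methods = list(
    initialize = function(..., config = beamlineConfig()) {
      initFields(scene = NULL, config = config, motor = c(0, 0, 0),
                 omega = 0, chi = 0, phi = 0, mode = "idle",
                 shift = c(0, 0, 0))
      callSuper(...)
    },
    isMounted = function() !is.null(scene),
    mountSample = function(sc, seed,
                           failureProb = config$mountFailureProb) {
      if (!mode %in% c("idle", "sample_exchange"))
        blStop("mountFailure",
               sprintf("cannot mount in mode '%s'", mode))
      r <- config$captureRangeMm
      draws <- withSeed(seed, list(u = stats::runif(1),
                                   pert = stats::runif(3, -r, r)))
      if (draws$u < failureProb)
        blStop("mountFailure", "simulated robot mount failure")
      scene <<- sc
      shift <<- draws$pert
      motor <<- c(0, 0, 0)
      omega <<- 0; chi <<- 0; phi <<- 0
      mode <<- "alignment"
      invisible(.self)
    },
    dismount = function() {
      scene <<- NULL
      shift <<- c(0, 0, 0)
      motor <<- c(0, 0, 0)
      mode <<- "idle"
      invisible(.self)
    },
    moveTo = function(x = NA, y = NA, z = NA, omega = NA, chi = NA,
                      phi = NA, relative = FALSE) {
      cur <- c(x = motor[1], y = motor[2], z = motor[3],
               omega = .self$omega, chi = .self$chi, phi = .self$phi)
      req <- c(x = unname(x)[1], y = unname(y)[1], z = unname(z)[1],
               omega = unname(omega)[1], chi = unname(chi)[1],
               phi = unname(phi)[1])
      tgt <- ifelse(is.na(req), cur, if (relative) cur + req else req)
      names(tgt) <- names(cur)
      for (ax in names(tgt)) {
        lim <- config$limits[[ax]]
        if (tgt[[ax]] < lim[1] || tgt[[ax]] > lim[2])
          blStop("motorLimit",
                 sprintf("%s target %.3f outside soft limits [%g, %g]",
                         ax, tgt[[ax]], lim[1], lim[2]))
      }
      motor <<- unname(tgt[c("x", "y", "z")])
      omega <<- unname(tgt[["omega"]])
      chi <<- unname(tgt[["chi"]])
      phi <<- unname(tgt[["phi"]])
      invisible(.self)
    },
    geom = function() {
      if (!isMounted()) blStop("noSampleMounted", "no sample mounted")
      labGeometry(scene, shift, motor, omega)
    },
    render = function(camera) {
      g <- geom()
      cam <- config$cameras[[camera]]
      if (is.null(cam)) stop("unknown camera: ", camera)
      mask <- silhouetteMembership(scene, g, cam)
      px <- matrix(config$background, nrow = cam@height, ncol = cam@width)
      px[mask] <- config$foreground
      storage.mode(px) <- "integer"
      new("Frame", camera = camera, pixels = px, omegaAtCapture = omega)
    },
    groundTruthMask = function(camera) {
      silhouetteMembership(scene, geom(), config$cameras[[camera]])
    },
    applyIceJitter = function(seed) {
      if (!isMounted()) blStop("noSampleMounted", "no sample mounted")
      s <- scene@iceJitterSigma
      if (s > 0) shift <<- shift + withSeed(seed, stats::rnorm(3, 0, s))
      invisible(.self)
    },
    labTip = function() geom()$tip,
    labCrystal = function() {
      if (!isMounted()) blStop("noSampleMounted", "no sample mounted")
      cs <- crystalSceneFrame(scene, shift)
      if (is.null(cs)) return(NULL)
      rotYZ(cs + motor, omega)
    },
    simulateGridScan = function(positions, seed) {
      if (!isMounted()) blStop("noSampleMounted", "no sample mounted")
      stopifnot(all(c("x", "y", "z") %in% names(positions)))
      for (ax in c("x", "y", "z")) {
        lim <- config$limits[[ax]]
        if (any(positions[[ax]] < lim[1] | positions[[ax]] > lim[2]))
          blStop("motorLimit", "grid position outside soft limits")
      }
      expected <- rep(scene@backgroundSpots, nrow(positions))
      cs <- crystalSceneFrame(scene, shift)
      if (!is.null(cs)) {
        d2 <- (cs[1] + positions$x)^2 + (cs[2] + positions$y)^2 +
              (cs[3] + positions$z)^2
        expected <- expected +
          scene@crystalPeakSpots * exp(-d2 / (2 * scene@crystalSigma^2))
      }
      withSeed(seed, stats::rpois(length(expected), expected))
    },
    show = function() {
      cat("VirtualBeamline: mode =", mode,
          if (isMounted()) "(sample mounted)" else "(empty)", "\n")
      cat("  motor (x,y,z) =", paste(round(motor, 4), collapse = ", "),
          "mm; omega =", round(omega, 2), "chi =", chi, "phi =", phi, "\n")
    }
  )
)

#' Expected spot count at grid positions (noise-free)
#'
#' The deterministic mean of the Poisson spot-count model, exposed for tests
#' and for Monte-Carlo verification of `$simulateGridScan`.
#'
#' @param bl a `VirtualBeamline` with a sample mounted
#' @param positions data.frame with motor targets `x`, `y`, `z` (mm)
#' @return numeric expected counts
#' @export
expectedSpotCounts <- function(bl, positions) {
  scene <- bl$scene
  expected <- rep(scene@backgroundSpots, nrow(positions))
  cs <- crystalSceneFrame(scene, bl$shift)
  if (!is.null(cs)) {
    d2 <- (cs[1] + positions$x)^2 + (cs[2] + positions$y)^2 +
          (cs[3] + positions$z)^2
    expected <- expected +
      scene@crystalPeakSpots * exp(-d2 / (2 * scene@crystalSigma^2))
  }
  expected
}

#' Random loop scene generator
#'
#' Draws a realistic random sample for property tests and acceptance runs:
#' loop semi-axes around 0.35 x 0.25 mm, thickness around 50 um, flat-face
#' angle uniform in [0, 180), small residual tip offset (the dominant mount
#' error is added by `$mountSample`), and optionally a crystal placed
#' uniformly inside the central 80% of the loop ellipse.
#'
#' @param seed integer seed
#' @param crystal logical, embed a crystal?
#' @param crystalSigma Gaussian crystal size (mm)
#' @param crystalPeakSpots,backgroundSpots spot-count model parameters
#' @param iceJitterSigma settling displacement sigma (mm)
#' @return a [LoopScene-class]
#' @export
randomLoopScene <- function(seed, crystal = FALSE, crystalSigma = 0.05,
                            crystalPeakSpots = 100, backgroundSpots = 0,
                            iceJitterSigma = 0) {
  withSeed(seed, {
    a <- stats::runif(1, 0.30, 0.40)
    b <- a * stats::runif(1, 0.58, 0.78)
    th <- stats::runif(1, 0.04, 0.06)
    ffo <- stats::runif(1, 0, 180)
    tip <- stats::runif(3, -0.05, 0.05)
    cc <- c(NA_real_, NA_real_)
    if (crystal) {
      repeat {
        u <- stats::runif(1, -2 * a, 0)
        v <- stats::runif(1, -b, b)
        if (((u + a) / a)^2 + (v / b)^2 <= 0.8^2) break
      }
      cc <- c(u, v)
    }
    loopScene(a = a, b = b, thickness = th, flatFaceOmega = ffo,
              tipOffset = tip, crystalCenter = cc,
              crystalSigma = crystalSigma,
              crystalPeakSpots = crystalPeakSpots,
              backgroundSpots = backgroundSpots,
              iceJitterSigma = iceJitterSigma)
  })
}
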