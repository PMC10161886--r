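# Shared fixtures: everything is generated in code at test time.

# Reduced-resolution config for orchestrator/state-machine tests (smaller
# images, same fields of view and algorithms -- scales runtime, not
# tolerances).
fastConfig <- function(...) {
  beamlineConfig(
    cameras = list(
      microscope = cameraGeometry("microscope", 160, 120, 100,
                                  viewAxis = "horizontal", openingKernel = 3),
      top = cameraGeometry("top", 232, 174, 30,
                           viewAxis = "vertical", openingKernel = 1)
    ),
    minComponentPx = 10,
    ...)
}

mountedBeamline <- function(scene = loopScene(flatFaceOmega = 62),
                            seed = 1, config = beamlineConfig()) {
  bl <- virtualBeamline(config)
  bl$mountSample(scene, seed)
  bl
}

# Synthetic two-level frame from a logical mask (dark sample on light
# background, matching the simulator's convention).
frameFromMask <- function(mask, camera = "microscope", omega = 0,
                          bg = 230L, fg = 25L) {
  px <- matrix(bg, nrow(mask), ncol(mask))
  px[mask] <- fg
  storage.mode(px) <- "integer"
  new("Frame", camera = camera, pixels = px, omegaAtCapture = omega)
}

rectMask <- function(h, w, rows, cols) {
  m <- matrix(FALSE, h, w)
  m[rows, cols] <- TRUE
  m
}

silFromMask <- function(mask, camera = "microscope", omega = 0) {
  new("Silhouette", mask = mask, camera = camera, omegaAtCapture = omega)
}

# Minimal valid spreadsheet data.frame (raw, character form).
makeRawSheet <- function(n = 3, method = "standard",
                         pairs = rep("", n)) {
  data.frame(puck = rep("P1", n), position = as.character(seq_len(n)),
             sample_name = paste0("sample", seq_len(n)),
             method = rep(method, length.out = n),
             orientation_pairs = pairs, stringsAsFactors = FALSE)
}

# Independent brute-force oracle for best-box selection: applies the stated
# rules (threshold on the max count, centroid-distance then row-major
# tie-break) by explicit enumeration.
oracleBestBox <- function(positions, counts, minSpots) {
  if (max(counts) < minSpots) return(NA_integer_)
  centroid <- c(mean(positions$x), mean(positions$y), mean(positions$z))
  best <- NA_integer_
  for (i in seq_along(counts)) {
    if (counts[i] < max(counts)) next
    if (is.na(best)) { best <- i; next }
    di <- sqrt(sum((c(positions$x[i], positions$y[i], positions$z[i]) -
                      centroid)^2))
    db <- sqrt(sum((c(positions$x[best], positions$y[best],
                      positions$z[best]) - centroid)^2))
    if (di < db - 1e-9) best <- i
    else if (abs(di - db) < 1e-9) {
      if (positions$iy[i] < positions$iy[best] ||
          (positions$iy[i] == positions$iy[best] &&
           positions$ix[i] < positions$ix[best])) best <- i
    }
  }
  best
}

# Circular distance between two angles under the 180-degree period.
angDiff180 <- function(a, b) {
  d <- abs(((a - b) %% 180 + 180) %% 180)
  min(d, 180 - d)
}
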