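---
title: "Methods: virtual-beamline loop centering and unattended collection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: virtual-beamline loop centering and unattended collection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(beamloop)
```

This vignette is the package's account of its science: the geometric model
behind the virtual beamline, the centering and decision algorithms, the
parameters that matter and why they default to what they do, and what a
green test does — and does not — establish.

## 1. The virtual beamline

### Coordinate conventions

Lab frame: `x` along the ω rotation axis (the pin direction, pointing right
in both camera images), `y` vertical (up), `z` along the beam at ω = 0.
ω rotates the sample about `x`. The centering motors (y, z) ride on the
rotation stage, so a motor displacement is expressed in the ω = 0 sample
frame and rotated into the lab by `R(ω)`; at ω = 0 the two frames coincide,
which fixes the documented sign convention: moving the sample +1 mm in lab
y shifts its silhouette by −`pxPerMm` pixels in image y (image y grows
downward, origin top-left, 0-based indices). The beam crosses the rotation
axis at the lab origin; each camera's beam-marker pixel is the projection
of that point.

Two cameras view the sample orthographically: the narrow-field
**microscope** along the beam (x–y image plane) and a wide-field **top**
camera looking vertically down (x–z image plane), perpendicular to the
rotation axis, used for prelocation because pins of different lengths and
angles do not fit in the microscope's field.

### The loop model

A scene is a pin (cylinder along x) carrying a planar elliptical loop with
semi-axes `a ≥ b`, whose plane is parallel to the microscope image plane at
ω = `flatFaceOmega` (the angle every centering run must recover). The loop
body is modeled as a **flattened ellipsoid** with semi-axes
(`a`, `b`, `thickness/2`). This choice is deliberate: the orthographic
shadow of an ellipsoid is an exact ellipse whose vertical semi-axis at tilt
θ = ω − ω\* is `sqrt(b²cos²θ + (t/2)²sin²θ)`, so

* the projected area is **maximized exactly at the flat face** (an extruded
  flat plate, by contrast, shows its rim; the rim term grows linearly in θ
  at face-on and shifts the area maximum by `atan(2t/(πb))` — several
  degrees for realistic loops, which would poison any flat-face recovery
  test), and
* the edge-on silhouette height equals the loop `thickness` exactly, which
  is what the thickness-measurement step reports.

An optional Gaussian "crystal" sits in the loop plane at `(u, v)` relative
to the tip (`u` along the pin axis, negative into the loop). It is
invisible to the cameras — only the diffraction simulation sees it —
mirroring the reality that optical centering cannot see the crystal inside
the loop.

Default scene values are chosen once as a realistic cryo-loop and not
revisited: `a = 0.35` mm, `b = 0.25` mm, thickness 50 µm, pin radius
25 µm, pin length 2.5 mm. Cameras: microscope 320×240 px at 200 px/mm
(1.6 × 1.2 mm field), top 384×288 px at 50 px/mm (7.7 × 5.8 mm, ≈ 4.8×
wider — the production magnification ratio is unpublished, so this is
config, not a claim). Beam size 0.05 mm. The mount error is uniform within
±0.5 mm per axis (the "capture range"); ice-settling jitter is an
isotropic Gaussian applied exactly once, between optical and diffraction
centering, with σ = 0 by default.

### The spot-count model

For each grid position the expected count is
`bg + peak · exp(−d²/(2σ²))`, with `d` the 3-D distance from the beam to
the (possibly jitter-displaced) crystal; the observed count is Poisson
with that mean, drawn under an explicit seed. Because the motors ride the
rotation, the motor target that brings a sample point to the beam is
simply the negated sample-frame coordinate — independent of ω — which
keeps the geometry testable in closed form.

### What the simulator does not emulate

Rendering is two-level and noiseless: no depth-of-field blur, shadows,
refraction, frost, or lighting gradients; no real detector images (spot
counts are synthesized, not found on images); no motor backlash or sphere-
of-confusion error. A green centering test therefore establishes that the
*algorithms* are geometrically correct under ideal silhouettes, not that
they are robust to real-world image degradation. The acceptance suite adds
1% multiplicative noise on the area sweep to probe the fit's noise
robustness, but that is a perturbation model, not camera realism.

## 2. Vision primitives

Segmentation is global Otsu thresholding (dark sample on light
background; the threshold level is scene-dependent, so pipelines are
invariant under image-wide intensity rescaling), followed by a
morphological opening and removal of connected components smaller than
`minComponentPx` (default 20 px).

Two numerical choices deserve justification:

* **Cross-shaped opening kernel.** A full 3×3 square erosion eats the
  shallow apex of a near-edge-on loop several pixels inward, biasing tip
  detection in an orientation-dependent way; the 4-neighbour cross halves
  that bias while still deleting 1–2 px specks. On the wide-field top
  camera the opening is disabled entirely (kernel 1): at 50 px/mm a 50 µm
  loop rim is ~2 px and any opening would erase it; the minimum-component
  filter still rejects noise there.
* **Loop region of interest.** Area, vertical extent and bounding box are
  restricted to foreground within 1.2× the expected loop diameter of the
  tip (`roiDepthMm = 0.85` mm), so the pin and gripper do not inflate
  them. The production system's pin-exclusion rule is unpublished; this is
  a documented assumption.

The tip is the extremal foreground pixel along the tip direction (+x; the
pin enters from the left). Ties take the lower-median perpendicular
coordinate — stable and symmetric.

## 3. Optical centering

**Calibration.** The top camera's beam-marker pixel is measured, not
configured: a reference marker is placed at the beam position and located
on the top image. A simulated camera-mount shift is recovered to ≤ 1 px;
the class of shift magnitudes exercised in tests (7 px in x, 2 px in y)
reflects observed long-term camera-mount drift at a real instrument.

**Prelocation** aligns the tip to the calibrated top-camera marker at two
orthogonal ω values (find tip → move to beam → rotate 90° → repeat, two
rounds). Aligning the image-vertical (lab z) coordinate at two orthogonal
angles zeroes both rotating components, so the tip lands on the rotation
axis at the beam — inside the microscope's narrow field and shallow focus
band. Focus is modeled exactly as this |z| bound; there is no blur model.

**centerOnTip** repeats the same two-orientation alignment on the
microscope camera with up to `maxRefineRounds = 3` refinement rounds
(one pass is exact in the noiseless linear model; extra rounds absorb
pixel quantization). Pixel→motor conversion is
`Δmotor = Δpixel / pxPerMm`; at orientation ω an image-vertical
displacement Δv maps to the motor pair `(Δv·cos ω, −Δv·sin ω)`.
One bias-aware detail: silhouette tip detection can only *under-reach*
(a near-edge-on apex erodes inward, never outward), and the along-axis x
coordinate is orientation-independent — so the orientation whose detected
tip extends furthest is authoritative for x, both for the correction and
for the convergence check. Without this, the x correction oscillates
between the face-on and edge-on biases and can exceed the 2 px tolerance.
The tolerance itself (2 px ≈ 10 µm at 200 px/mm, i.e. a fifth of the beam)
is an assumption; the production value is unpublished.

**Flat-face search.** After tip centering the sample is rotated over 180°
with images every 40° — ω offsets {0, 40, 80, 120, 160}; 180° is excluded
as redundant with 0° under the 180° period — and the loop-ROI area is fit
with `area(ω) ≈ c0 + c1 cos 2ω + c2 sin 2ω`. The 2ω harmonic is the
physically forced model for a planar loop. Five equally spaced samples
over one period make the design orthogonal for the constant and first
harmonic, so the phase estimate `ω* = ½ atan2(c2, c1)` is exact on
noiseless data even though `|area(θ)|` contains higher harmonics. The fit
is declared **degenerate** when the modulation amplitude
`sqrt(c1² + c2²)` falls below `degenerateFitFrac = 0.02` of the mean area
(a spherical sample has no flat face); the caller then keeps the entry ω
with a warning rather than failing the sample.

**centerToFlat** chains: centerOnTip → area sweep → sinusoid fit → rotate
to ω\*+90° and measure thickness (one angle; the production choice is
unstated and one suffices for a reporting quantity) → centerOnTip again →
rotate to ω\* and compute the ROI bounding box. The beamline is left at
ω\*, all commanded ω normalized to [0, 360). `noCentering = TRUE`
short-circuits with status `disabled` and zero motor motion (manual/chip
applications); a never-segmented loop yields status `not_found`.

## 4. Grid scans and the collect/skip decision

`gridFromResult` rasters the flat-face bounding box at the beam size:
`n = ceil(extent/step)` boxes per axis, centered on the bbox center, so
every bbox point is within `step/2` of a grid position per axis; ordering
is serpentine from the top-left. The vertical extent spans the **full
bbox height, not the measured thickness**: icy pin bases commonly let the
sample settle slightly between optical and diffraction centering, and a
thickness-restricted vertical scan then misses the crystal. The
acceptance suite reproduces this argument quantitatively (with settling
σ = 1.5× thickness, full-ROI line scans bracket the crystal ≥95/100 while
thickness-restricted ones do so <50/100). The measured thickness remains
in the result for reporting.

`selectBestBox` applies a per-box threshold (the maximum box count decides
collect vs skip) and picks the maximum-count box; ties break by distance
to the grid centroid, then row-major order. Four threshold modes mirror
production practice — `default` (10), `strong` (40, well-diffracting),
`weak` (3, membrane proteins), `always_collect` (0) — the *structure*
(four modes, `strong ≥ default ≥ weak`, always-collect = 0) is the
contract; the numeric defaults are config-overridable placeholders for an
unpublished table. Whether production thresholds are per-box or per-grid
totals is unstated; per-box maxima are assumed, matching the "all boxes
below threshold" skip phrasing. The line scan 90° away reuses the 2-D
policy (no per-scan thresholds are described), sits at the best 2-D box's
x, and resolves the crystal along the former viewing axis. A sample is
skipped iff every count in *both* scans is below threshold; the line scan
only runs when the 2-D scan passes. No sub-box centroid refinement is
performed — box selection by spot count alone is the modeled behavior and
its known limitation (multi-lattice confusion) is out of scope. With
centering disabled there is no grid box, so only the `always_collect`
mode proceeds, at the current position; all other modes skip.

## 5. Orchestration, journal and resume

Per-method execution stacks over the five steps
`safety_check → mount → optical_center → diff_center → daq`:
serial crystallography omits `diff_center`; `robot_test` stops after
`mount` (sample-changer exercise); `alc_test` after `optical_center`
(centering exercise). Step statuses follow the five-state model
(`unknown, in_progress, success, skipped, failed`); every step passes
through `in_progress` before a terminal status. A grid-scan skip marks
`daq` skipped and the run continues; any step failure stops the whole run
immediately, emitting a structured notification event (the stand-in for
production email/SMS alerts — a pluggable `notifySink` function can be
set in the config).

The production design stores experiment state redundantly across a GUI, a
cache and a cloud database so any party can recover; here that triangle
collapses to a **single append-only JSON-lines journal** with the same
recovery contract and no services. Each status transition is one line;
step payloads carry everything resume needs (centering result + motor
state, decision + counts, manifest paths). Replaying the journal — last
status per (row, step) wins — reconstructs the records exactly, so
`runAutomation` itself returns the replay, making run and resume records
structurally identical by construction.

Per-step randomness derives deterministically from the run seed via
`deriveSeed(seed, row, step)` (kept below 2³¹), so a resumed step
re-executes bit-identically. Resume restarts the first incomplete row at
its first non-success step, silently re-establishing physical state for
its already-successful steps (re-mount with the identical derived seed;
motor restore from the centering payload) — no step is ever half-replayed.
Record equivalence is defined up to wall-clock timestamps and the output
root. Pause/stop is honored at step boundaries only.

## 6. Spreadsheet model

One CSV row per sample: mount address (puck + position, unique per run),
method, optional acquisition parameters, threshold mode, `no_centering`
flag, free-form processing tokens (recorded, not executed), and — exactly
for the multi-orientation method — a `(χ,φ)` pair list encoded
`"(0,0);(20,0)"`, with χ ∈ [0, 40]° and φ ∈ [−360, 360]° enforced by the
goniometer's ranges. Validation coerces and checks everything, collecting
*all* errors with row/column coordinates (never fail-fast), and fills
absent acquisition parameters from config defaults (360° range, 0.1°
oscillation, 0.01 s exposure — placeholders for an unpublished defaults
table, clearly config). CSV is the canonical dialect because it
round-trips bit-exactly in tests; multi-orientation `daq` writes one
dataset manifest per pair, moving χ/φ between sets without re-centering
(the goniometer's sphere of confusion at these ranges is a few µm, below
the beam size).

## 7. Numerical choices, degenerate inputs, tie-breaks

| Quantity | Default | Why |
|---|---|---|
| Tip tolerance | 2 px (10 µm) | assumption; ≈ beam/5 |
| Refinement rounds | 3 | 1 is exact noiselessly; margin for quantization |
| Sweep step | 40° | five images over the 180° period |
| Degenerate-fit ratio | 0.02 | amplitude below 2% of mean ⇒ no flat face |
| Min component | 20 px | noise specks vs 2-px top-camera rims |
| ROI depth | 0.85 mm | 1.2 × expected loop diameter |
| Thresholds | 10/40/3/0 | structure fixed, numbers config placeholders |

Tie-breaks are deterministic everywhere: tip ties take the lower-median
perpendicular pixel; best-box ties take centroid distance then row-major
order; grids start top-left. Degenerate inputs never crash a run: empty
masks yield `not_found` (optical failure path), constant areas fall back
to the entry ω, empty grids raise a classed `emptyGrid` error, and a
truncated journal raises `corruptJournal`.

## 8. Known limitations

* Single-loop scenes: no gripper, frost artifacts or multiple objects, so
  the minimum-component filter is exercised only synthetically.
* The two-camera path is the implemented geometry; a wide-field
  single-camera endstation is the config degenerate "skip prelocation",
  not a separately modeled optical layout.
* PNG I/O is a minimal stored-block codec (no external imaging package is
  available): files are valid PNGs readable anywhere, but the *reader*
  handles only this package's own stored-block output, plus grayscale/RGB
  8-bit; use it for round-tripping simulator frames, not arbitrary
  images.
* Machine-learning centering and on-image spot finding are explicitly out
  of scope; the spot-count interface is where such a component would plug
  in.
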