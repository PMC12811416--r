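---
title: "Models and methods behind axoquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind axoquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

axoquant quantifies axonal regeneration experiments from fluorescence
images: outgrowth of axon fields, growth-cone shape, distribution of a
protein along distal axons, microtubule plus-end dynamics, and
colocalization/local-translation readouts. This vignette explains the
models each measurement rests on, the tunable parameters and why their
defaults are what they are, what the synthetic-data generator does and
does not emulate, and the numerical choices a careful reader will want
stated explicitly.

All physical units flow through one `calibration` object (µm per pixel
along x and y, seconds per frame). Setting pixel sizes and frame
interval to 1 makes every output numerically equal to its pixel/frame
counterpart, which the tests exploit. The raster convention is
x = column, y = row, origin top-left, pixel centers at integer
coordinates starting at 1. Movies use the duration convention
*T = n<sub>frames</sub> × Δt*, so a 3-minute acquisition at 2 frames
per second is 360 frames spanning 180 s — this convention, rather than
(n−1)Δt, is what makes a full-height kymograph dash correspond to a
180-s lifetime.

## Sholl analysis by semicircles

Outgrowth is the number of distinct axonal processes crossing
semicircular arcs of increasing radius (step 2 µm, up to
1,200–1,500 µm) centered where axons exit the microgrooves, restricted
to the half-plane they grow into. An *intersection* is a connected run
of foreground pixels along the discretized arc, not a raw pixel count:
a thick process crossing the arc contributes one, matching the intent
of counting crossing processes. Arcs are discretized at sub-pixel
angular steps (0.25 px of arc), so consecutive arc pixels are
8-adjacent and runs are well defined; pixels outside the image count
as background; the radius is converted through the pixel size, and
anisotropic calibrations are rejected because an arc of constant
radius is not a pixel circle then. Bin sums use half-open membership
(lo, hi], so contiguous bins partition the radii and conserve the
total count exactly.

The generator renders ray arbors (digital lines, one 3×3 dilation, as
thresholded axons would look) and computes expected counts by *exact
continuous geometry*: each dilated segment is a capsule of half-width
~1.5 px, its intersection with the circle of radius r is an angular
interval, and the expected count is the number of connected components
of the interval union. Where rays are resolvable this equals the naive
"number of rays longer than r" (kept as `naive_counts`); near the
shared origin, where capsules overlap, the naive count is
geometrically unattainable on any raster and the union count is the
correct expectation. Each radius also carries a rasterization
envelope: counts are recomputed with thinner and fatter capsules
(±1 px), and radii where the variants disagree, or that lie within
about a pixel of a segment's radial extent, are flagged `uncertain`.
Tests demand exact agreement at unflagged radii and containment in the
envelope (±1) at flagged ones.

## Growth-cone morphometry

From a single-object actin mask the package reports: area (foreground
pixel count × pixel area); perimeter (length of the ordered
boundary-pixel contour polygon — a chain-code length that slightly
overestimates smooth shapes, adequate for comparisons at fixed
magnification); and elongation ratio from the ellipse with the same
second central moments as the pixel set, which recovers the axis ratio
of analytic ellipses to well under a percent. "Best-fit ellipse" has
no unique definition; the moment ellipse is the standard deterministic
reading.

Skeleton metrics thin the mask to one pixel width (Zhang–Suen, the
same family of algorithm as FIJI's Skeletonize; like it, it erodes
about half the local width at free ends) and build the 8-connected
pixel graph with steps weighing 1 or √2 pixels times the pixel size.
Endpoints are degree-1 pixels, junctions degree ≥ 3. Spurs — terminal
chains shorter than `prune_len_um` — are removed first; the protocol
mentions pruning noise-induced branchlets without stating a length, so
the default is 0.5 µm, safely below the filopodium threshold, surfaced
in `gc_params` and recorded in outputs. Pruning iterates to a fixed
point (hence is idempotent) and re-thins after each removal because
deleting a spur can leave a redundant pixel attached through mixed
cardinal/diagonal adjacency.

The LSP is the maximum geodesic distance between any two *nodes*
(endpoints and junction pixels; degree-2 pixels carry length but are
not candidates — with both readings possible, the node-only one was
chosen and differs from the all-pixel reading by at most the longest
edge overhang). Exact all-pairs distances are affordable at these
sizes; no double-sweep heuristic is used, and the test suite checks
equality against brute-force Floyd–Warshall on every skeleton it
generates. A filopodium is a terminal branch measured from its
supporting junction to its endpoint, counted when longer than
`min_filopodium_len_um` (default 1.0 µm, the protocol's threshold); a
junction-free skeleton (a bare path or blob) has zero filopodia by
this definition, so a bar-shaped mask reports LSP ≈ its length and no
filopodia. Isolating the growth cone (excluding the axon shaft) is the
caller's responsibility; the module measures the mask it is given.

## Axial intensity profiles

Profiles are sampled every pixel of arc length along a tip-first
polyline, averaging across the perpendicular width with three evenly
spaced bilinear probes per micrometer of width (the averaging kernel
of a "1-µm-wide segmented line" is not standardized; three probes per
µm keeps the estimate unbiased for stripes wider than the line while
staying cheap). Distances accumulate true geometric arc length.
Background measured in a cell-free region is subtracted without
clipping — negative excursions are kept so integrals stay linear and
fold changes unbiased.

Two baseline corrections exist purely for plotting: `tip_anchor`
(subtract the value at 0 µm; corrected trace is exactly zero at the
tip) and `distal_window` (subtract the mean over 45–50 µm; corrected
window mean is zero to float precision). Corrected profiles are
flagged and refused by the fold-change computation, which uses
trapezoidal integrals over 0–50 µm of uncorrected,
background-subtracted profiles, each divided by the mean control
integral. The terminal fraction integrates the piecewise-linear
interpolant exactly from 0 to the window edge (default 10 µm), so a
uniform profile over 50 µm yields exactly 20%.

## Kymograph comet dynamics

Mobile fluorescence is isolated per pixel along time:
out = G<sub>σm</sub>(series) − G<sub>σs</sub>(series), with σ in
frames (the protocol states bare sigmas; frames is the only reading
under which a 50-sigma blur isolates static structure — the axis is
configurable). Defaults σm = 4, σs = 50. Kernels are normalized and
applied with reflect boundary handling, so a time-constant movie maps
to zero at machine precision and early/late events are not dimmed; the
implementation is FFT-based and the test suite pins it to the
closed-form impulse response (that test caught a reversed
negative-lag kernel half during development — the strongest argument
for closed-form oracles).

Kymographs stack the profile sampler's output per frame: rows are
frames, columns arc-length steps (µm per column = pixel size, s per
row = frame interval). Dash → parameters uses endpoint deltas:
track = |Δx|·µm/px, lifetime = Δy/Y·T, rate = track/lifetime. This is
algebraically identical to the L·cosθ / L·sinθ formulation for
isotropic kymograph pixels (a property test verifies both to 1e−9)
but stays exact when the axes are calibrated differently, so no
trigonometry is used in production. Retrograde dashes keep their
signed Δx but report magnitude track lengths. Lifetime normalization
uses total rows Y (not Y−1) so a full-height dash of a 3-min movie
lives exactly 180 s.

Automated dash detection (the protocol traces manually; detection
makes the synthetic pipeline end-to-end, and traced endpoints can be
supplied instead) thresholds the positive part at 2.5× the
kymograph's MAD — after separation the background is zero-centered
with noise correlated over ~σm frames, so a robust global scale is
the natural reference — floored at a tenth of the peak so noise-free
kymographs do not threshold at numerical zero. A 5-px closing bridges
noise dips (the correlation scale), 8-connected components smaller
than 50 px or spanning fewer than 4 rows (2 s — briefer growth events
are unresolvable at 2 fps, and a near-horizontal blob would imply an
unphysical rate) are dropped, and each component is reduced to its
principal axis. Endpoints are the extremal projections of pixels at or
above half the component peak, then extended along the axis on the
unthresholded kymograph to the half-maximum crossing: the
half-amplitude point of a Gaussian-blurred edge sits at the true edge,
which undoes the temporal blur's end-smearing without deconvolution.

## Colocalization and puncta

Manders coefficients use the thresholded variant:
M1 = Σ ch1[ch1 > t1 ∧ ch2 > t2] / Σ ch1[ch1 > t1], symmetric for M2 —
both numerator and denominator respect the reference channel's
threshold, consistent with protocols that fix identical thresholding
parameters per channel across conditions (the classical unthresholded
variant differs only in the denominator; the variant id is recorded in
the result). M1/M2 are invariant under joint rescaling of channels and
thresholds, and M1 is non-increasing in t2.

Puncta counting thresholds the (optionally matched-filtered,
σ = 1 px — standard spot-detection practice that buys a ~2.6× SNR
gain at these spot sizes) image, takes 8-connected components with
area in [min, max] px, and assigns each punctum by whether its
intensity centroid lies on a true mask pixel — deterministic for dots
straddling the boundary, where any-pixel-overlap rules are not. Count,
mask area and their ratio (density per µm²) are returned, plus
per-labeled-region counts when a cell-body label image is supplied.

## The synthetic generator: what it does and does not emulate

Generators render isotropic Gaussian spots (σ default 1.5 px,
diffraction-limited puncta at typical magnifications), digital-line
axons and filopodia with one dilation, filled moment-exact ellipses,
and additive Gaussian noise (optional, seeded; SNR is
amplitude/noise-sd, with study conditions at SNR 5). Every generator
is bit-reproducible from its seed. Three deliberate simplifications
matter for interpreting green tests:

- **Comet placement.** Random comet specs are rejection-sampled so no
  two space-time tracks approach each other on the kymograph. Real
  kymographs contain crossing dashes, which the protocol's *manual*
  tracing resolves; automated component-based detection cannot, so
  recovery tests quantify detection accuracy on resolvable events
  only.
- **Puncta stay off the mask edge** (2 px margin), so the generator's
  center-pixel classification and the counter's centroid rule cannot
  disagree on a boundary-straddling dot; with dots on the edge the
  centroid rule remains deterministic but ground truth becomes a
  matter of convention.
- **No optics.** No PSF model beyond the Gaussian spot, no
  photobleaching, no camera gain or Poisson shot noise by default
  (a Poisson option exists on the movie generator's noise model in
  spirit, but Gaussian-only is the default for deterministic SNR), no
  3-D. Passing tests demonstrate correctness of the *measurements* on
  well-characterized inputs, not robustness to every acquisition
  artifact of a real microscope.

## Problem sizes and runtime choices

The shipped tests and the acceptance script run: 20 random arbors
(3–12 rays, 100–1,400 µm, 1 µm/px, ~1,400×2,800 px fields) for the
Sholl oracle; 30 random skeleton trees (≲ 300 px) for the LSP oracle;
10⁴ random dashes for the parameter identities; one 50-comet,
360-frame, 260×21 px movie at SNR 5 for end-to-end recovery
(recovered mean rate within ~2%, mean lifetime within ~5% of
generator means across seeds); 40-spot coloc pairs at overlap 0,
0.25, 0.5, 1; and 20 puncta fields. These sizes keep a full run in a
few minutes on one core while leaving the statistical checks
comfortably away from their tolerances.

## Known limitations

Perimeter is a chain-code length, a few percent above the true
perimeter of smooth shapes — comparable across conditions but not an
unbiased absolute. Thinning erodes line ends by about half the local
width, so LSP of elongated shapes underestimates the mask extent by
roughly the tip widths. Sholl intersections at radii within a pixel or
two of a ray endpoint (or where two processes nearly touch on the
arc) are rasterization-ambiguous; the generator flags these radii
rather than pretending a unique answer exists. Dash detection assumes
anterograde-or-retrograde runs at roughly constant velocity — pauses,
catastrophes and rescues are neither simulated nor quantified, as in
the underlying assay, and heavily overlapping events require manual
tracing through the `dashes` input of the pipeline. Statistical
comparison of groups (beyond mean ± SE and fold changes) is
deliberately out of scope: the summary tables are the hand-off to
standard statistics packages.
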