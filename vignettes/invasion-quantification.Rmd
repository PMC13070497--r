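---
title: "Quantifying glioblastoma invasion into brain organoids"
author: "invasionquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying glioblastoma invasion into brain organoids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(invasionquant)
```

## The assay and the measurement model

A confrontation assay co-cultures a fluorescently labelled glioblastoma
(GB) tumor sphere with a brain organoid until the two merge. Invasion then
proceeds in two modes with different biology and different drug
sensitivity: contiguous replacement of brain tissue by the main tumor mass
("cell competition"), and detachment of single cells that migrate into the
brain parenchyma. The package reduces a two-channel image (tumor
fluorophore + brightfield-like reference) to three numbers per image and
time point. With $R$ the pixel set of the brain-compartment ellipse, $C$
the tumor-positive pixels 8-connected to the core mass and $S$ the
tumor-positive pixels detached from it:

$$\mathrm{competition} = \frac{|C \cap R|}{|R|}, \qquad
  \mathrm{single\ cell} = \frac{|S \cap R|}{|R|}, \qquad
  \mathrm{total} = \mathrm{competition} + \mathrm{single\ cell}.$$

Three modelling commitments shape everything downstream:

1. **Both ratios share the same denominator**, the rasterized
   brain-ellipse area. The junction region belongs to $R$ and can be
   claimed by the core — that is precisely what "replacement" means. No
   baseline subtraction is applied for tumor fluorescence already inside
   $R$ at the first time point; time courses should be read relative to
   their first frame if that matters.
2. **Every area is a pixel count** on a rasterized mask (exact
   pixel-center evaluation), never an analytic formula, so each ratio is a
   ratio of counts and `total = competition + single_cell` holds to
   machine precision on every record.
3. **Ratios are asserted, not clipped.** A competition ratio outside
   $[0, 1]$ indicates a geometry or segmentation failure and raises an
   error instead of being silently clamped.

## The per-image pipeline and its parameters

**Projection.** Z-stacks are collapsed by maximum-intensity projection
(`max_intensity_projection()`); quantification is 2D throughout.
Calibration is never assumed: a file without pixel-size metadata and
without an explicit override is a hard error. Coordinates are 1-based
pixel centers with $(x, y) = (\mathrm{col}, \mathrm{row})$, the R
convention; anisotropic in-plane pixels are rejected because all areas use
a single pixel-area scalar.

**Cluster delineation** (`region_grow()`). Breadth-first growth from a
seed inside the cluster; a pixel joins when its intensity is within
`tolerance` of the running region mean, updated after every accepted
pixel. The frontier is a FIFO queue with 4-neighbours pushed in row-major
order, so the result is deterministic and an independent flood-fill oracle
can reproduce it pixel for pixel. The criterion uses differences only, so
constant intensity offsets are irrelevant. The default tolerance (2500 on
a 16-bit scale) accepts the synthetic reference-channel contrast between
cluster interior and rim while excluding background; for real data it
should be set per imaging configuration.

**Contour and neck detection** (`extract_contour()`,
`find_neck_points()`). The cluster mask is hole-filled, its largest
4-connected region traced into a closed counter-clockwise boundary
polygon. The two-lobe outline is split at its two concave notches: the
contour is resampled by arc length to 360 vertices, smoothed twice with a
5-vertex moving average (one pass leaves pixel-staircase curvature noise
at the ~1 px vertex spacing), and signed discrete Menger curvature is
computed over a ±2-vertex support. Concave candidates are local curvature
minima at least 1.5× sharper (in magnitude) than the 90th percentile of
the convex curvature — a scale-free criterion that rejects rasterization
ripple on a convex blob while keeping genuine necks, whose curvature is an
order of magnitude above lobe curvature. Among candidates, the pair with
maximal circular arc separation is chosen. A convex contour (no neck — for
example a fully engulfed tumor) raises a typed `no_neck_error`; in batch
mode that image becomes a failed row and the batch proceeds.

**Ellipse decomposition** (`decompose_ellipses()`). One ellipse is fitted
per arc with the numerically stable direct least-squares ellipse-specific
conic fit (quadratic constraint $4AC - B^2 = 1$, data centered and scaled
first), which cannot return a hyperbola — required because the downstream
denominator is an ellipse interior. The reported residual is the RMS
Sampson (gradient-normalised algebraic) distance: a first-order
point-to-ellipse distance that is numerically zero on exact arcs. On the
reference two-circle "snowman" (radii 40 and 30 px, centers 55 px apart)
the decomposition recovers the generating radii within 1.8% and the
centers within 0.2 px. Tumor identity goes to the lobe with the higher
tumor-positive pixel fraction when a fluorescence mask is available,
otherwise to the lobe containing the tumor hint. Users who traced ellipses
manually (the semi-automated workflow) can pass them via `manual =`; they
are used verbatim and flagged in the output.

**Tumor segmentation** (`tumor_mask()`, `classify_components()`).
Thresholding is Otsu's method on the within-cluster histogram by default
(overridable per channel with a fixed value); pixels outside the cluster
are never tumor-positive, and a perfectly flat region yields an empty mask
rather than an all-positive one. Components are labelled with
8-connectivity — thin diagonal links, as formed by tumor microtubes, keep
fragments attached to the mass — whereas cluster growth uses
4-connectivity (compact tissue). "Detached" means: not in the core's
8-connected component. Components below `min_object_um2` (default
20 µm², about a nuclear cross-section) are discarded as noise; the filter
is reported in every output. A detached clump counts once — no
instance splitting of touching cells. Both the area-based single-cell
ratio (the headline metric) and the component count are reported, since
either reading is defensible.

## Track analysis

**Windowed speed** (`window_speeds()`). One speed data point is the path
length travelled in one 40-min window, converted to µm/h — the same unit
as one cell in one short video recording. Windows are non-overlapping and
anchored at each track's first sample. Positions are linearly interpolated
at window boundaries: splitting a straight step pro rata preserves its
length exactly, so a straight constant-speed track yields its speed
exactly in every window regardless of the sampling interval, and crooked
paths are never double-counted across windows. Path length (not net
displacement) is the distance measure; straightness (net/path) is reported
alongside. No smoothing is applied to trajectories. Analysis is 2D; a z
column is dropped with a warning. Windows with fewer than two original
samples are skipped and logged.

**Boundary reversals** (`detect_reversals()`). Invading cells reach the
organoid margin and turn back rather than exiting. An event is scored at a
sample within `margin_um` (default 15 µm, about one cell diameter) of the
brain-ellipse boundary where the radial motion (normalised ellipse radius
$\rho$) turns from outward to inward — a local maximum of $\rho$ with
$\rho_k \ge \rho_{k-1}$ and $\rho_k > \rho_{k+1}$. A track that starts at
the margin already moving inward, or ends there still moving outward, is
scored at that endpoint, since the turn itself falls between samples.
Boundary distance uses the along-ray approximation (exact for circles,
and accurate to well under a micrometre for margins much smaller than the
semi-axes).

**Division behaviour** (`division_check()`). For each parent with exactly
two daughters (lineage via `parent_id`) the angle between the daughters'
initial displacements is reported, with "opposite directions" defined as
> 90° (negative heading dot product). The initial displacement tolerates a
stationary mitotic pause at the start of a daughter track. Parents with
any other number of daughters are flagged, not scored.

## The synthetic generator: what it emulates, and what it does not

The generator exists to give the estimator a known answer; it reproduces
the *structure* the quantification assumes, not the biophysics (no
chemotaxis, no microtube rendering, no intensity texture inside tissue).

**Scenes** (`scene_spec()`, `render_scene()`). Defaults model a 48-h
confrontation on a 256×256 px frame at 1.5 µm/px: a brain lobe of
~185×160 µm and a tumor lobe of ~140×125 µm merged into a snowman (the
geometric lens overlap is kept at ~2% of the brain area), interior
intensity 9000 with a darker 2-px rim at 7000 over background 500
(reference channel), tumor fluorophore signal 3000, and smooth low-order
radial contour jitter of 1%. Noise is signal-dependent Poisson plus a
Gaussian floor (mean 100, SD 8) on a 16-bit scale — arbitrary but fixed
and stated. The replaced region floods outward from the lobe junction in
geodesic-distance order, so it stays connected to the core (mass
replacement is contiguous); when the requested competition fraction is
smaller than the geometric lens, the tumor mass is rendered outside the
brain compartment and only a contiguous tongue of junction pixels is
replaced, so a zero-competition scene truly has zero replaced area.
Detached cells are crisp disks placed uniformly at random in the
unreplaced brain region with ≥3 px clearance (so components stay
distinct under 8-connectivity); per-cell radii are chosen adaptively, the
last from a fine grid, so the realized detached-area fraction lands within
~0.002 of the request. Sub-filter debris disks can be added to exercise
the size filter. All ground truth is recomputed from the rendered
pre-noise masks, never echoed from the specification.

**Tracks** (`walk_spec()`, `simulate_walks()`). Persistent random walks:
the new heading is the normalised blend
$p\,\hat{d}_{\mathrm{prev}} + (1-p)\,\hat{u}$ with persistence $p = 0.6$
by default; step length is `speed_true × step_min / 60` µm,
gamma-jittered with CV 0.15. Defaults are a mean speed of 23.8 µm/h (a
fast-invading GB model), 4-min sampling — a typical time-lapse interval;
the short-video recording convention fixes only the 40-min window — over
120 min (three windows per cell). Steps crossing the organoid boundary
reflect specularly off the ellipse tangent in the original frame, which
preserves the step length exactly. One margin visit is logged as one
reversal event at its deepest excursion; separate visits require the cell
to leave the margin zone in between. Divisions arrive as a Poisson process
per track: the parent ends, and after a stationary pause (default 160 min,
a typical mitotic interval in these cocultures) two non-dividing daughters
leave the division point with exactly antiparallel first steps; divisions
are suppressed within three step lengths of the boundary, where an
immediate reflection would contradict the opposite-departure rule, and on
a track's first step (a parent must exist as a trajectory before it can
end). Daughters inherit the full track duration.

**What passing these tests shows — and does not.** Recovery on synthetic
scenes demonstrates that the estimator is consistent with its own
measurement model: correct compartment geometry from a two-lobe contour,
correct core/detached classification, exact pixel accounting. It does not
certify performance on real microscopy, where out-of-focus light, uneven
illumination, touching organoids of more than two lobes, and genuinely
ambiguous "attachment" of cells to the core all occur and are out of the
generator's scope. The manual-ellipse entry point and the fixed-threshold
option exist precisely for such cases.

## Numerical choices and degenerate inputs

* Region growing: each pixel enters the frontier once and is tested once;
  a rejected pixel is never revisited even if the mean later drifts. The
  seed is always accepted (a singleton region is valid).
* Contour orientation is canonicalized to counter-clockwise before
  curvature analysis; decomposition is invariant to the contour's starting
  vertex and traversal direction.
* A single-pixel mask yields a degenerate contour flagged as such rather
  than an error; fitting a collinear arc raises an error naming the arc.
* Otsu on a flat histogram returns an empty mask (metrics read 0).
* Ellipse fits are performed on data centered and scaled by the mean
  radius; the conic is converted back in closed form.
* Windowed speeds use `floor((t_last - t_0)/W)` complete windows; the
  trailing partial window is dropped.
* All simulation randomness flows from one integer seed per spec;
  identical seeds give bit-identical images, tracks and output tables.
  The generator restores the caller's RNG state.

## Problem sizes used in the shipped validation

The test suite and `scripts/acceptance.R` validate at desk scale, chosen
to exercise every code path at comfortable statistical margins: a 24-scene
sweep (competition 0–0.5 × single-cell 0–0.2, 256×256 px) for metric
recovery (observed mean absolute error ≈ 0.002 against a tolerance of
0.05); 50 random 32×32 images for the region-growing oracle; 40-track
corpora for speed recovery (within 3% of truth) and 100 seeded replicates
of a three-arm ordering comparison (24 / 22 / 19.5 µm/h); ~60–70 logged
reversal and division events per event-detection run. The paper-scale
quantities these mirror — per-cell speeds of roughly 19–24 µm/h measured
from 35–40 tracked cells per model, and treatment effects reported as
percent inhibition — set the regimes the defaults emulate.

## Known limitations

* Exactly two merged lobes are supported; engulfed or multi-organoid
  clusters need manual ellipses.
* The brain compartment is an ellipse by construction; strongly non-
  elliptical organoids bias both denominators.
* No nucleus-level instance segmentation: a detached clump of touching
  cells counts once in `n_single_cells` (its area is fully counted).
* No 3D quantification; projections can overcount overlapping structures.
* Boundary distance in track analysis is the along-ray approximation, not
  the exact point-to-ellipse distance.
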