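---
title: "Spherical volume rendering of brain connectomes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spherical volume rendering of brain connectomes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 7)
library(brainmap)
```

## The problem

Conventional volume rendering of a parcellated brain shows one viewing
direction at a time, and subcortical structures stay hidden behind the
cortex. `brainmap` implements an omnidirectional alternative: a *spherical
camera* encloses the labeled volume, one ray is cast from every
latitude–longitude grid point toward the sphere's center, and the spherical
image is unwrapped into a single planar "brain map" with an equal-area
projection. Because the camera sees all directions at once, the map contains
every cortical region of interest (ROI) in one image; recording the order in
which rays traverse ROIs yields a depth layering that makes subcortical
structures visible in their own maps. Structural (fiber-count) and
functional (time-series correlation) connectivity matrices, per-ROI texture
encodings, and curved network edges complete the picture.

## Rendering model

**Camera.** The default camera centers on the centroid of all labeled
voxels — for a left/right symmetric parcellation this preserves the
symmetry of the map — with radius 1.05 times the largest center-to-voxel
distance, so the whole parcellation sits strictly inside the sphere. Rays
may also be reversed (`direction = "outward"`): the ray for grid point
(lat, lon) then starts at the camera center and travels outward, which
shows the *interior* surfaces of surrounding structures from an
intra-cerebral viewpoint.

**Sampling and shading.** Along each ray, samples are taken every half
voxel (0.5 × the smallest spacing; a fixed step keeps compositing
independent of ray direction). Intensity is interpolated trilinearly;
labels use the nearest voxel, because ROI identity is categorical and must
never be blended. Shading is Blinn–Phong with a headlight (light along the
ray): ambient 0.2, diffuse 0.6, specular 0.2, shininess 16. Normals are
pre-computed per voxel as the negated central-difference intensity
gradient, interpolated trilinearly and renormalized; where the gradient
vanishes (flat interior) the diffuse term is set to 1 rather than 0, so
homogeneous regions render at their nominal color instead of black.
Front-to-back compositing uses `C += (1-A) a c`, `A += (1-A) a`, with early
exit at `A >= 0.999`.

**Transfer functions** combine a piecewise-linear intensity-to-opacity/color
ramp with categorical per-label overrides. A label "counts" for occlusion
purposes only if its sampled opacity exceeds 0.01, which suppresses phantom
hits from near-zero transfer-function tails.

**Planar map.** The Hammer–Aitoff projection maps the sphere onto a 2:1
ellipse and preserves areas (the absolute Jacobian equals `cos(lat)`
exactly), so the map does not exaggerate polar regions. The renderer works
*inverse per pixel*: each pixel center inside the ellipse is mapped back
through the closed-form inverse to (lat, lon) and a ray is cast for it.
This leaves no resampling holes, unlike projecting a finite spherical image
forward. The forward path is still available by casting on the camera's own
lat/lon grid (`cast_camera_grid()`).

## Occlusion layering

Each ray records the distinct nonzero labels it meets, in first-visit
order. Every ordered pair (a before b) adds weight 1 to the directed edge
a→b of the occlusion graph (a switch restricts this to consecutive pairs;
all-pairs is the default because it accumulates denser evidence for the
cycle-breaking rule). Importantly, occlusion recording continues past the
compositing early-exit: an opaque cortex still *occludes* — and therefore
must be sorted in front of — the subcortical ROIs behind it.

`layer_sort()` peels the graph: layer k is the set of nodes with zero
incoming weight from unassigned nodes. When a cycle (from non-convex or
interlocking shapes) leaves no such node, the node with minimum combined
incoming weight is freed by deleting its incoming edges — discarding the
least occlusion evidence — with ties broken by smallest label id for
determinism. On an acyclic graph the result is a topological layering with
zero violated edges, a property the tests check on random DAGs.

Layered rendering draws one layer at a time at opacity 1. Because the
inward spherical projection magnifies interior objects (the reverse of
perspective), per-layer scale factors can shrink deeper layers; the default
is 1.0 (no published values exist to emulate) and the factor magnifies the
map uniformly about its center, bilinear for color and nearest-neighbor for
labels.

## The phantom: what it emulates and what it guarantees

All inputs can be generated synthetically with seeded, pure-function
generators (`make_phantom()`, `make_fibers()`, `make_timeseries()`,
`make_class_attributes()`), so the whole pipeline runs and is tested
without any scan data.

The default phantom is a 64³ voxel grid holding two concentric spherical
structures: an outer "cortical" shell band (radius fraction 0.65–0.85 of
the half-grid) split into 16 angular-Voronoi parcels, and an inner
"subcortical" band (0.25–0.45) split into 6. Seed directions are placed by
seeded best-candidate sampling (each new seed maximizes its minimum angle
to existing seeds), which keeps parcels comparably sized.

Two geometric refinements make the expected occlusion layering *exact*
rather than approximate:

1. **Separation margins.** A voxel joins a parcel only if its direction
   clears the Voronoi bisector by a margin equal to the renderer's
   nearest-voxel flip radius, `1.15 × (sqrt(3)/2 + 0.7) / r_min` radians
   (half a voxel diagonal plus slack for the data-driven camera center,
   divided by the band's inner radius). Without the margin, rays grazing a
   parcel boundary pick up single stray samples of the neighbor parcel and
   the occlusion graph acquires mutual cortical↔cortical edges; with it,
   no ray can sample two same-shell parcels, so every cortical parcel has
   zero incoming occlusion weight and lands in layer 1. The thin background
   gaps play the role of sulci/CSF between regions.
2. **Enclosure.** Inner parcels keep only voxels whose direction lies well
   inside an outer parcel's core (clearing twice the outer margin), so the
   radial ray through any inner voxel is guaranteed to cross an outer ROI
   first. Every inner parcel therefore accumulates incoming weight from
   layer-1 parcels and sorts into layer 2.

Intensity is a radial gradient plus a small per-label offset plus Gaussian
noise (sd 0.02 of the range), giving the shader non-degenerate normals.

Fibers are analytic three-point arcs (quadratic Bézier bowed toward the
volume center) between seeded ROI pairs with non-uniform pair
probabilities; endpoints are exact voxel centers of the chosen ROIs, so
endpoint lookup reproduces the generated pair table exactly. Time series
follow a shared-signal block model: `sqrt(rho)` × community signal +
`sqrt(1-rho)` × private noise, z-scored per ROI; 632 time points and
`rho = 0.8` with two communities are the default study conditions. Class
attributes get one dominant class per ROI at ≥1.5× the others.

What the phantom does *not* emulate: anatomical lobe shapes, partial-volume
effects at ROI borders, tractography curvature or false-positive
streamlines, and BOLD autocorrelation/hemodynamics. Tests passing on the
phantom validate the geometry, bookkeeping and statistics of the pipeline,
not its robustness to real-scan artifacts.

## Connectivity

Structural edge weight is fiber density: the number of fibers whose two
terminal points fall in the two ROIs (nearest-voxel lookup, no tolerance
radius — the criterion is binary and no dilation is stated anywhere),
divided by the mean of the two ROI volumes in mm³ (label voxel count ×
voxel volume). Fibers with an endpoint in background, outside the grid, or
with both ends in one ROI contribute nothing; interior points are ignored.
Functional connectivity is the Pearson correlation matrix of the per-ROI
time series (unit diagonal). Node strength sums |r| for functional
matrices by default so strengths stay nonnegative; the sign convention is a
flag. Edge thresholds may be absolute or a quantile of the upper-triangle
weights.

## Textures

**Offset contours.** An ROI's map region is eroded iteratively with the
3×3 full-square structuring element; ring c is the set of pixels removed at
iteration c (the raster border erodes against background, and an optional
cap folds the remaining interior into the last ring). The time axis is
split evenly across the K rings — bin c covers samples
`[floor(cT/K), floor((c+1)T/K))` — reading outside-in as forward in time
(a fixed, documented convention; nothing in the source material pins the
direction). Ring shade interpolates linearly from white to the ROI's hue
between the *global* activity minimum and maximum, so shades are
comparable across ROIs. A Gaussian blur (σ = 1.5 px) softens ring
boundaries; it is computed as a normalized convolution restricted to the
mask and re-masked, so a constant field stays exactly constant and no
color bleeds across the ROI boundary.

**RYB class noise.** Multi-class attributes (e.g. per-diagnosis mean node
degree) blend in red–yellow–blue space, where mixing behaves like paint
(red+yellow=orange, blue+red=purple); the RYB→RGB conversion is trilinear
interpolation in a color cube whose eight corner colors are configurable
(defaults chosen to honor those mixing semantics). Each class gets an
independent multi-octave value-noise turbulence field (octave o samples a
seeded uniform lattice at `2^o × base_freq` cells, amplitude `1/2^o`;
min–max normalized); per pixel, class weights = attribute value ×
turbulence, normalized, then blended. A class holding all the attribute
mass colors every pixel exactly; comparable classes interleave patches at
the turbulence scale. Pixels where every turbulence field is zero fall
back to the attribute-only blend.

Textures are generated in map space on each ROI's own pixel region (the
`texture_set()` holds recipes, not pixels). For 3D surface texturing the
projection-plane route is also provided: the ROI's voxels project onto the
plane through the ROI center normal to the center-to-brain-centroid line,
in a deterministic in-plane basis (normal crossed with the most orthogonal
coordinate axis), each voxel stamping its half-spacing footprint so the
mask area tracks the projected footprint area.

## Network edges

An edge between two ROIs is a cubic Bézier curve: endpoints at the ROI
centers, inner control points pushed radially outward from the brain
centroid by an `elevation` fraction (default 0.4; no published value
exists) of each center's distance — curves arc above the anatomy instead
of tunneling through it. For the 2D overlay the *same* 3D samples are
projected through the camera (single geometric source of truth), split
wherever consecutive longitudes jump by more than π (the antimeridian
seam), and stroked with 2 px anti-aliased width. Edge colors may encode
per-class weights through the same RYB blend. Cross-layer edges draw on
the later layer's panel.

## Numerical choices and degenerate inputs

- Map raster: row 1 is the top, x grows with column; map coordinates scale
  uniformly; `height = ceiling(width/2)`.
- `hammer_aitoff_inverse` returns NA outside the open ellipse; boundary
  pixels therefore render background.
- Compositing rejects opacities outside [0,1]; constant time series are
  rejected in `functional_connectivity` with the offending ROI named.
- NIfTI affines must be axis-aligned (scaling + translation); oblique
  scans should be resampled upstream. The label grid is authoritative for
  geometry; intensity is shading-only.
- Ties in the cycle-breaking rule go to the smallest label id; all
  generators consume one seeded RNG stream per operation, restoring the
  caller's RNG state (`withr::with_seed`).
- Problem sizes used in the shipped checks: 32³/64³ phantoms, maps of width
  96–400, 2048-ray occlusion grids, 632-point series, 20-seed functional
  replications — sizes at which every stage completes in seconds on one
  core while still exercising multi-layer occlusion.

## Known limitations

- No GPU path; rendering is vectorized base R, suitable for maps up to
  ~1000 px width, not for interactive dragging.
- Layers render alone, without deeper anatomical context; a context
  underlay is a possible extension.
- The published tool's exact noise-blend formula and layer scale factors
  are not recoverable from any source; this package's concretizations are
  documented above and exposed as parameters.
- Projection footprints are used as 2D texture domains only; no
  UV-unwrapping onto 3D meshes, and non-injective projections are not
  resolved.
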