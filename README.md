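# brainmap

Spherical volume rendering of labeled brain volumes into planar, equal-area
connectome maps.

## The problem

A parcellated brain volume (a structural scan plus an integer ROI label
grid) is usually explored one viewing direction at a time, and subcortical
structures stay hidden behind the cortex. `brainmap` renders the whole
parcellation into **one** planar image: a spherical camera encloses the
volume, rays are cast from every latitude–longitude point toward the
center (standard front-to-back compositing with Blinn–Phong shading), and
the spherical image is unwrapped with the **Hammer–Aitoff** equal-area
projection into a 2:1 elliptical "brain map". Because every ray records
the order in which it meets ROIs, the package builds a weighted
**occlusion graph**, sorts ROIs into depth **layers** by topological
peeling (cycles broken at the node with minimum incoming weight), and
renders one layer at a time — cortex in layer 1, subcortical structures in
later layers.

On top of the maps it builds and draws connectomes:

- **structural networks** — fiber density `w_ij = count_ij /
  mean(vol_i, vol_j)`, where a fiber counts for pair (i, j) iff its two
  endpoints fall in ROIs i and j;
- **functional networks** — Pearson correlation of per-ROI time series;
- **textures** — time series encoded as shaded offset contours (iterative
  3×3 erosion rings = time bins, outside-in), and multi-class attributes
  encoded as red–yellow–blue turbulence noise (RYB→RGB by trilinear
  interpolation in a color cube);
- **edges** — cubic Bézier curves elevated above the anatomy in 3D and
  projected onto the map with antimeridian-seam splitting.

A deterministic two-shell **phantom generator** produces every input
(labeled volume, fibers, time series, class attributes) with exact ground
truth, so the full pipeline runs without any scan data. It is intended for
neuroimaging researchers and visualization developers who need a
scriptable, testable implementation of these methods.

## Worked example

```r
library(brainmap)

ph  <- make_phantom(phantom_spec(seed = 1))      # 64^3, 16 outer + 6 inner ROIs
cam <- default_camera(ph$volume)
tf  <- label_transfer_function(ph$roi$label)

map <- render_map(ph$volume, cam, tf, width = 400)
map
#> brain_map: 200 x 400 px, layer 1, 16 ROIs visible

layers <- layer_sort(build_occlusion_graph(map$records))
layers
#> layer 1 (scale 1.00): 1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 11, 12, 13, 14, 15, 16
#> layer 2 (scale 1.00): 17, 18, 19, 20, 21, 22

fb  <- make_fibers(ph$volume, ph$roi, n_fibers = 400, seed = 2)
net <- build_structural_network(fb$fibers, ph$volume, ph$roi)
net
#> connectivity_matrix (structural): 22 ROIs, 138 nonzero edges

ts <- make_timeseries(ph$roi, n_time = 632, n_blocks = 2, rho = 0.8, seed = 3)
fc <- functional_connectivity(ts$series)
round(fc$weights[1:3, 1:3], 2)
#>       1     2    3
#> 1  1.00 -0.01 0.79
#> 2 -0.01  1.00 0.01
#> 3  0.79  0.01 1.00
```

The layer assignment is exactly the phantom's construction: all 16 outer
(cortical) ROIs in layer 1, all 6 inner (subcortical) ROIs in layer 2. In
the functional matrix, ROIs 1 and 3 share a community (correlation ≈ 0.8,
the generator's target), ROI 2 belongs to the other one (≈ 0).

`run_demo("out/", seed = 1, width = 400)` executes the whole pipeline —
phantom → networks → single + layered maps → both texture styles → edge
overlay — writing PNGs and TSVs to `out/`. The same is available from a
shell via the CLI wrapper:

```sh
Rscript inst/cli/brainmap demo --out out --seed 1 --width 400
Rscript inst/cli/brainmap phantom --out data --seed 1
Rscript inst/cli/brainmap render --volume data/phantom.nii.gz \
    --labels data/phantom_labels.nii.gz --mode layered --out out/map
```

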