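Package: brainmap
Title: Spherical Volume Rendering of Labeled Brain Volumes into Planar
    Connectome Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Renders labeled 3D brain volumes into planar, equal-area brain
    maps by spherical ray casting (omnidirectional volume rendering from a
    latitude-longitude camera sphere) followed by a Hammer-Aitoff unwrap.
    Records per-ray occlusion order of regions of interest (ROIs), sorts
    ROIs into depth layers by weighted topological peeling of the occlusion
    graph, and renders one layer at a time. Builds structural (fiber-density)
    and functional (time-series correlation) connectivity matrices, encodes
    per-ROI attributes as textures (offset-contour time-series shading and
    multi-class red-yellow-blue turbulence noise), and overlays network
    edges as cubic Bezier curves in 3D and as seam-aware polylines on the
    2D map. Ships a deterministic two-shell phantom generator that produces
    every input with ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    png,
    EBImage,
    jsonlite,
    withr,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
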