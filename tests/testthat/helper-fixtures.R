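# Shared fixtures, built once per test run.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_env))
    assign(name, build(), envir = .fixture_env)
  get(name, envir = .fixture_env)
}

# small two-shell phantom: 32^3, 8 outer + 3 inner ROIs
small_phantom <- function() {
  fixture("small_phantom", function()
    make_phantom(phantom_spec(grid = 32, n_cortical = 8, n_subcortical = 3,
                              seed = 7)))
}

# default-condition phantom: 64^3, 16 outer + 6 inner ROIs
default_phantom <- function() {
  fixture("default_phantom", function() make_phantom(phantom_spec(seed = 1)))
}

# a tiny hand-made two-ROI volume: ROI 1 = 10 voxels, ROI 2 = 20 voxels
two_roi_volume <- function() {
  labels <- array(0L, c(12, 8, 8))
  labels[2:6, 2:3, 2] <- 1L   # 10 voxels
  labels[8:11, 2:6, 3] <- 2L  # 20 voxels
  labeled_volume(array(0, c(12, 8, 8)), labels)
}

# straight fiber between two world points
straight_fiber <- function(p, q, n = 5) {
  t <- seq(0, 1, length.out = n)
  cbind(p[1] + t * (q[1] - p[1]), p[2] + t * (q[2] - p[2]),
        p[3] + t * (q[3] - p[3]))
}
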