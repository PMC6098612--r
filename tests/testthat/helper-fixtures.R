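# fixtures built in code; every helper is deterministic under its seed

# plain 3D logical array (TRUE = solid) wrapped as a binary volume
solid_array <- function(dims, value = TRUE) array(value, dim = dims)

# solid block with a centered spherical pore, voxel units
sphere_phantom <- function(diameter = 30, grid = 48, voxel = 1) {
  make_single_sphere(phantom_spec("single_sphere", rep(grid, 3), voxel,
                                  list(diameter = diameter)))
}

# slab pore of the given gap (voxels) between two solid half-spaces
slab_volume <- function(gap = 12, grid = 30, voxel = 1) {
  a <- solid_array(rep(grid, 3))
  lo <- floor((grid - gap) / 2) + 1L
  a[, lo:(lo + gap - 1L), ] <- FALSE
  binary_volume(a, voxel)
}

# small overlapping-sphere foam for pipeline tests
foam_volume <- function(seed = 1, grid = 60, voxel = 2, mean_d = 30,
                        sd_d = 5, porosity = 0.4) {
  make_packed_sphere_foam(phantom_spec(
    "packed_spheres", rep(grid, 3), voxel,
    list(mean_diameter = mean_d, sd_diameter = sd_d,
         target_porosity = porosity), seed = seed))$volume
}

# rasterized analytic shapes as pore regions (voxel 1 um unless stated)
shape_region <- function(shape, voxel = 1, ...) {
  ph <- make_shape_2d(phantom_spec("shape2d", NULL, voxel,
                                   c(list(shape = shape), list(...))))
  pore_region(!unclass(ph$volume), voxel)
}

# irregular blob: largest 8-connected component of a thresholded smoothed
# noise field
blob_region <- function(seed, n = 40, porosity = 0.35, voxel = 1) {
  set.seed(seed)
  f <- array(rnorm(n * n), dim = c(1, n, n))
  f <- poremetry:::blur_separable(f, c(0, 2, 2))
  pore <- f[1, , ] < quantile(f, porosity)
  prs <- label_pores_2d(pore, "keep", voxel_size = voxel)
  areas <- vapply(prs$regions, function(r) nrow(r$coords), numeric(1))
  prs$regions[[which.max(areas)]]
}

# random 3D masks for oracle-equivalence checks
random_mask_volume <- function(seed, n = 16, p = 0.5, voxel = 1) {
  set.seed(seed)
  binary_volume(array(runif(n^3) > p, dim = rep(n, 3)), voxel)
}

expect_close <- function(object, expected, tol) {
  expect_lte(abs(object - expected), tol)
}
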