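#' 3D local thickness (maximal-inscribed-sphere) transform
#'
#' For every pore voxel, the diameter in micrometres of the largest ball that
#' lies entirely in the pore phase (clipped to the VOI) and covers the voxel
#' — the sphere-fitting pore-size estimator of micro-CT structure-separation
#' analysis. Computed as an exact Euclidean distance transform followed by
#' distance-ridge reduction and sphere painting. The effective ball radius at
#' a candidate center is its distance to the nearest non-pore voxel center
#' minus half a voxel, so a spherical pore of diameter d recovers d, an
#' infinite slab of gap t recovers t, and a lone pore voxel has thickness of
#' one voxel. The VOI boundary (and the grid border) counts as solid for ball
#' containment, which biases peripheral pores low rather than letting them
#' inflate into open space.
#'
#' @param vol a `binary_volume` (TRUE = solid)
#' @param voi optional `voi_mask`; defaults to the whole grid
#' @return a `thickness_field`: numeric array in micrometres, zero on solid
#'   and outside the VOI
#' @export
local_thickness_3d <- function(vol, voi = NULL) {
  stopifnot(inherits(vol, "binary_volume"))
  solid <- as_plain(vol)
  if (!is.null(voi)) {
    m <- as_plain(voi)
    if (!identical(dim(m), dim(solid))) stop("VOI shape does not match volume")
  } else m <- array(TRUE, dim = dim(solid))
  pore <- !solid & m
  if (!any(pore)) stop("no pore voxels inside the VOI")
  th <- thickness_transform(pore, border_bg = TRUE)
  thickness_field(th * voxel_size(vol), voxel_size(vol))
}

#' Brute-force local thickness oracle
#'
#' Defines the ground truth for [local_thickness_3d()] by exhaustive search:
#' distances are recomputed by scanning every non-pore voxel, and every pore
#' voxel is tested against a ball centered at every candidate center (pore
#' voxel centers and the midpoints of axis-adjacent pore pairs — the same
#' candidate-set definition as the fast path, evaluated without distance
#' transforms, ridge reduction or painting). Quadratic in the voxel count and
#' therefore restricted to small grids.
#'
#' @param vol a `binary_volume`
#' @param max_voxels refusal limit (default `32^3`)
#' @return a `thickness_field` in micrometres
#' @export
local_thickness_bruteforce <- function(vol, max_voxels = 32^3) {
  stopifnot(inherits(vol, "binary_volume"))
  solid <- as_plain(vol)
  if (prod(dim(solid)) > max_voxels)
    stop(sprintf("brute-force oracle refuses grids over %d voxels", max_voxels))
  th <- thickness_bruteforce_cpp(as.logical(!solid), as.integer(dim(solid)),
                                 TRUE)
  thickness_field(array(th, dim = dim(solid)) * voxel_size(vol),
                  voxel_size(vol))
}

#' Thickness field container
#'
#' Per-voxel local thickness in micrometres; zero on solid and outside the
#' VOI.
#'
#' @param data numeric 3D array (micrometres)
#' @param voxel_size voxel pitch in micrometres
#' @export
thickness_field <- function(data, voxel_size) {
  new_grid3d(data, voxel_size, "thickness_field", logical = FALSE)
}

#' @export
print.thickness_field <- function(x, ...) {
  v <- x[x > 0]
  d <- dim(x)
  cat(sprintf("<thickness_field> %d x %d x %d @ %g um; %d pore voxels, median %.1f um\n",
              d[1], d[2], d[3], voxel_size(x), length(v),
              if (length(v)) median(v) else NA))
  invisible(x)
}

#' Voxel-weighted 3D pore-size sample
#'
#' One value per pore voxel of the thickness field (the standard weighting of
#' structure-separation outputs), tagged `"3D"`.
#'
#' @param tf a `thickness_field`
#' @param weighting `"per_voxel"` (default) or `"per_region"`, which instead
#'   records one value — the maximum thickness — per 26-connected pore region
#' @return a `size_sample`
#' @export
size_sample_3d <- function(tf, weighting = c("per_voxel", "per_region")) {
  stopifnot(inherits(tf, "thickness_field"))
  weighting <- match.arg(weighting)
  pore <- as_plain(tf) > 0
  if (!any(pore)) stop("empty thickness field")
  if (weighting == "per_voxel") {
    size_sample(as_plain(tf)[pore], tag = "3D", weighting = "per_voxel")
  } else {
    lab <- label_components(pore, 26)
    vals <- vapply(seq_len(max(lab)), function(l) max(as_plain(tf)[lab == l]),
                   numeric(1))
    size_sample(vals, tag = "3D", weighting = "per_region")
  }
}

#' Color-coded rendering of a thickness field
#'
#' Linear value-to-color mapping over a stated range, one RGB raster per
#' cross-section, with the legend endpoints attached — the conventional
#' color-coded pore-size visualization of micro-CT reports. Solid voxels
#' render black.
#'
#' @param tf a `thickness_field`
#' @param range value range in micrometres mapped onto the palette; defaults
#'   to `c(0, max(tf))`; must be non-degenerate
#' @param palette a palette name understood by [grDevices::hcl.colors()]
#' @param n_colors palette resolution
#' @return list with `sections` (list of H x W x 3 arrays in `[0, 1]`),
#'   `legend` (range endpoints, um) and `colors` (the palette)
#' @export
export_colorcoded <- function(tf, range = NULL, palette = "viridis",
                              n_colors = 256L) {
  stopifnot(inherits(tf, "thickness_field"))
  a <- as_plain(tf)
  if (is.null(range)) range <- c(0, max(a))
  if (diff(range) <= 0) stop("degenerate color range")
  cols <- hcl.colors(n_colors, palette)
  rgb <- t(col2rgb(cols)) / 255
  g <- dim(a)
  sections <- lapply(seq_len(g[1]), function(i) {
    sl <- a[i, , , drop = TRUE]
    idx <- pmin(n_colors, pmax(1L,
      1L + as.integer(floor((sl - range[1]) / diff(range) * (n_colors - 1L)))))
    out <- array(0, dim = c(g[2], g[3], 3))
    pore <- sl > 0
    for (ch in 1:3) {
      plane <- out[, , ch]
      plane[pore] <- rgb[idx[pore], ch]
      out[, , ch] <- plane
    }
    out
  })
  list(sections = sections, legend = range, colors = cols)
}
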