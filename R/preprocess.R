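# windowed sum along one axis with truncated borders (no padding)
box_sum_axis <- function(arr, r, ax) {
  g <- dim(arr)
  n <- g[ax]
  perm <- c(ax, setdiff(1:3, ax))
  m <- matrix(aperm(arr, perm), nrow = n)
  cs <- apply(m, 2, cumsum)
  if (n == 1) cs <- matrix(cs, nrow = 1)
  hi <- pmin(seq_len(n) + r, n)
  lo <- seq_len(n) - r
  out <- cs[hi, , drop = FALSE]
  pos <- lo >= 2
  if (any(pos)) out[pos, ] <- out[pos, , drop = FALSE] - cs[lo[pos] - 1, , drop = FALSE]
  back <- array(out, dim = g[perm])
  aperm(back, order(perm))
}

# windowed min/max along one axis (truncated borders) via shifts
box_extreme_axis <- function(arr, r, ax, maximum) {
  g <- dim(arr)
  out <- arr
  for (s in c(-(1:r), 1:r)) {
    n <- g[ax]
    src <- seq_len(n) + s
    keep <- src >= 1 & src <= n
    dst <- which(keep); sidx <- src[keep]
    slab <- function(a, idx) {
      if (ax == 1) a[idx, , , drop = FALSE]
      else if (ax == 2) a[, idx, , drop = FALSE]
      else a[, , idx, drop = FALSE]
    }
    cmp <- if (maximum) pmax else pmin
    upd <- cmp(slab(out, dst), slab(arr, sidx))
    if (ax == 1) out[dst, , ] <- upd
    else if (ax == 2) out[, dst, ] <- upd
    else out[, , dst] <- upd
  }
  out
}

box_filter <- function(arr, r, what = c("mean", "min", "max")) {
  what <- match.arg(what)
  if (what == "mean") {
    s <- arr
    cnt <- array(1, dim = dim(arr))
    for (ax in 1:3) {
      s <- box_sum_axis(s, r, ax)
      cnt <- box_sum_axis(cnt, r, ax)
    }
    s / cnt
  } else {
    out <- arr
    for (ax in 1:3) out <- box_extreme_axis(out, r, ax, what == "max")
    out
  }
}

#' Adaptive-threshold binarization
#'
#' Marks a voxel solid iff its intensity strictly exceeds the mean intensity
#' over a cubic window of half-width `window_radius` centered on it, plus
#' `offset`. Windows are truncated at the grid border (never padded with
#' invented intensities). A window with zero intensity range carries no local
#' contrast; such voxels are compared against the volume-wide mean instead,
#' so that a noise-free two-valued volume round-trips exactly while a
#' constant volume stays all-pore under the strict inequality.
#'
#' @param vol a `gray_volume`
#' @param window_radius window half-width in voxels (>= 1); the window is a
#'   cube of side `2 * window_radius + 1`
#' @param offset added to the local mean before comparison (intensity units)
#' @return a `binary_volume` (TRUE = solid)
#' @export
binarize_adaptive <- function(vol, window_radius = 2L, offset = 0) {
  stopifnot(inherits(vol, "gray_volume"))
  window_radius <- as.integer(window_radius)
  if (window_radius < 1) stop("window_radius must be >= 1")
  a <- as_plain(vol)
  rng <- range(a)
  if (rng[1] == rng[2] && offset == 0)
    warning("constant-intensity volume with offset 0: every voxel classified as pore")
  local_mean <- box_filter(a, window_radius, "mean")
  flat <- box_filter(a, window_radius, "max") == box_filter(a, window_radius, "min")
  thr <- local_mean
  thr[flat] <- mean(a)
  binary_volume(a > thr + offset, voxel_size(vol))
}

#' Remove small solid and pore speckles
#'
#' Connected solid components (26-connected) smaller than `min_solid_voxels`
#' are flipped to pore; then connected pore components smaller than
#' `min_pore_voxels` are flipped to solid, except the background-connected
#' pore space (any pore component touching the grid boundary). Components
#' exactly at a threshold are retained. Idempotent.
#'
#' @param vol a `binary_volume`
#' @param min_solid_voxels,min_pore_voxels minimum surviving component sizes
#'   in voxels (>= 0)
#' @param connectivity 26 (default) or 6
#' @return a despeckled `binary_volume`
#' @export
despeckle <- function(vol, min_solid_voxels = 2L, min_pore_voxels = 0L,
                      connectivity = 26) {
  stopifnot(inherits(vol, "binary_volume"))
  if (min_solid_voxels < 0 || min_pore_voxels < 0)
    stop("component-size thresholds must be >= 0")
  solid <- as_plain(vol)
  if (min_solid_voxels > 0 && any(solid)) {
    lab <- label_components(solid, connectivity)
    sizes <- tabulate(lab)
    drop <- which(sizes < min_solid_voxels)
    if (length(drop)) solid[lab %in% drop] <- FALSE
  }
  if (min_pore_voxels > 0 && any(!solid)) {
    lab <- label_components(!solid, connectivity)
    sizes <- tabulate(lab)
    g <- dim(solid)
    border <- unique(c(lab[c(1, g[1]), , ], lab[, c(1, g[2]), ],
                       lab[, , c(1, g[3])]))
    border <- border[border > 0]
    fill <- setdiff(which(sizes < min_pore_voxels), border)
    if (length(fill)) solid[lab %in% fill] <- TRUE
  }
  binary_volume(solid, voxel_size(vol))
}

# complement voxels 6-connected to the grid border
outside_region <- function(mask) {
  lab <- label_components(!mask, connectivity = 6)
  g <- dim(mask)
  border <- unique(c(lab[c(1, g[1]), , ], lab[, c(1, g[2]), ],
                     lab[, , c(1, g[3])]))
  border <- border[border > 0]
  array(lab %in% border, dim = g)
}

#' Shrink-wrap volume of interest
#'
#' Wraps the specimen in a tight envelope: the solid phase is dilated with a
#' Euclidean ball of the given radius, everything not reachable from the grid
#' border through the complement of that envelope is taken as inside, and the
#' envelope is then pulled back by the same radius (a morphological closing
#' combined with cavity filling). A voxel survives the pull-back when its
#' distance to the exterior is at least the radius (rather than strictly
#' greater), which makes the operation extensive on the voxel grid — the wrap
#' never drops solid voxels — and lets a radius-r closing bridge surface gaps
#' of up to about 2r voxels. Internal pore space stays inside the wrap even
#' when it communicates with the exterior through throats the closing seals;
#' a specimen that fills the whole grid wraps to the whole grid.
#'
#' @param vol a `binary_volume` with at least one solid voxel
#' @param closing_radius ball radius in voxels (>= 0)
#' @return a `voi_mask` covering the wrapped envelope including its internal
#'   pores
#' @export
shrink_wrap_voi <- function(vol, closing_radius = 4) {
  stopifnot(inherits(vol, "binary_volume"))
  solid <- as_plain(vol)
  if (!any(solid)) stop("cannot shrink-wrap an empty solid phase")
  r <- closing_radius
  if (r < 0) stop("closing_radius must be >= 0")
  g <- dim(solid)
  if (r > 0) {
    d_solid <- edt_squared(!solid, border_bg = FALSE)  # dist to nearest solid
    dilated <- solid | d_solid <= r^2
  } else dilated <- solid
  # exterior = complement of the dilated envelope reachable from the border;
  # internal pore space (even when boundary-connected through narrow throats
  # that the closing seals) stays inside the wrap
  background <- outside_region(dilated)
  voi0 <- !background
  if (any(background)) {
    # pull the wrap back onto the specimen: keep voxels at distance >= r
    # from the exterior (>=, not >, so the wrap never drops solid voxels)
    d_out <- edt_squared(voi0, border_bg = FALSE)
    voi <- solid | (voi0 & d_out >= r^2)
    # re-fill any cavity the pull-back opened
    voi <- voi | (!outside_region(voi) & !voi)
  } else voi <- array(TRUE, dim = g)
  voi_mask(voi, voxel_size(vol))
}

#' Total porosity within a volume of interest
#'
#' @param vol a `binary_volume`
#' @param voi a `voi_mask` of the same shape (defaults to the whole grid)
#' @return pore-voxel fraction of the VOI, in `[0, 1]`
#' @export
total_porosity <- function(vol, voi = NULL) {
  stopifnot(inherits(vol, "binary_volume"))
  solid <- as_plain(vol)
  if (is.null(voi)) voi <- voi_mask(array(TRUE, dim = dim(solid)), voxel_size(vol))
  m <- as_plain(voi)
  if (!identical(dim(m), dim(solid))) stop("VOI shape does not match volume")
  n <- sum(m)
  if (n == 0) stop("VOI is empty")
  sum(!solid & m) / n
}
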