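#' Image volume containers
#'
#' Light S3 containers around 3D arrays with a physical voxel size. The axis
#' order is (section, row, column): the first index walks the cross-sections
#' perpendicular to the specimen axis. Voxels are isotropic; `voxel_size` is
#' the pitch in micrometres.
#'
#' * `gray_volume()` — intensities in `[0, 1]`.
#' * `binary_volume()` — logical, `TRUE` marks the solid scaffold phase,
#'   `FALSE` the pore/background phase.
#' * `voi_mask()` — logical, `TRUE` marks voxels inside the volume of
#'   interest.
#' * `binary_image()` — a single 2D section, logical, `TRUE` = solid.
#'
#' @param data numeric or logical array (3D; matrix for `binary_image`)
#' @param voxel_size voxel pitch in micrometres (> 0)
#' @return an object of the corresponding class
#' @name volumes
NULL

check_voxel_size <- function(voxel_size) {
  if (!is.numeric(voxel_size) || length(voxel_size) != 1 ||
      !is.finite(voxel_size) || voxel_size <= 0)
    stop("voxel_size must be a single positive number (micrometres)")
  as.numeric(voxel_size)
}

new_grid3d <- function(data, voxel_size, class, logical = TRUE) {
  if (length(dim(data)) != 3) stop(class, " requires a 3D array")
  if (logical) {
    storage.mode(data) <- "logical"
    if (anyNA(data)) stop(class, " must not contain NA")
  } else {
    storage.mode(data) <- "double"
    if (!all(is.finite(data))) stop(class, " intensities must be finite")
  }
  structure(data, voxel_size = check_voxel_size(voxel_size), class = class)
}

#' @rdname volumes
#' @export
gray_volume <- function(data, voxel_size) {
  new_grid3d(data, voxel_size, "gray_volume", logical = FALSE)
}

#' @rdname volumes
#' @export
binary_volume <- function(data, voxel_size) {
  new_grid3d(data, voxel_size, "binary_volume")
}

#' @rdname volumes
#' @export
voi_mask <- function(data, voxel_size) {
  new_grid3d(data, voxel_size, "voi_mask")
}

#' @rdname volumes
#' @export
binary_image <- function(data, voxel_size) {
  if (is.null(dim(data)) || length(dim(data)) != 2)
    stop("binary_image requires a matrix")
  storage.mode(data) <- "logical"
  structure(data, voxel_size = check_voxel_size(voxel_size),
            class = "binary_image")
}

#' Voxel pitch of a volume or field
#'
#' @param x any poremetry grid object
#' @return voxel size in micrometres
#' @export
voxel_size <- function(x) {
  v <- attr(x, "voxel_size")
  if (is.null(v)) stop("object carries no voxel_size")
  v
}

#' @export
print.binary_volume <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<binary_volume> %d x %d x %d voxels @ %g um, solid fraction %.3f\n",
              d[1], d[2], d[3], voxel_size(x), mean(x)))
  invisible(x)
}

#' @export
print.gray_volume <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<gray_volume> %d x %d x %d voxels @ %g um, range [%.3f, %.3f]\n",
              d[1], d[2], d[3], voxel_size(x), min(x), max(x)))
  invisible(x)
}

#' @export
print.voi_mask <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<voi_mask> %d x %d x %d voxels @ %g um, VOI fraction %.3f\n",
              d[1], d[2], d[3], voxel_size(x), mean(x)))
  invisible(x)
}

# strip attributes down to a plain array/matrix
as_plain <- function(x) {
  a <- unclass(x)
  attr(a, "voxel_size") <- NULL
  a
}

# promote a 2D mask to a one-section 3D array (for the shared kernels)
as3d <- function(m) {
  if (length(dim(m)) == 3) return(m)
  array(m, dim = c(1L, dim(m)))
}

# ---- low-level kernel wrappers ------------------------------------------

# squared Euclidean distance (voxel units) from each TRUE voxel of `fg` to
# the nearest FALSE voxel center; grid borders count as background when
# border_bg (the VOI boundary is treated as solid)
edt_squared <- function(fg, border_bg = TRUE) {
  a <- as3d(fg)
  d <- edt_sq_cpp(as.logical(a), as.integer(dim(a)), isTRUE(border_bg), -1L)
  array(d, dim = dim(a))
}

# local thickness transform in voxel units (diameter), with half-offset
# midpoint candidates along every non-singleton axis
thickness_transform <- function(pore, border_bg = TRUE) {
  a <- as3d(pore)
  dm <- as.integer(dim(a))
  lg <- as.logical(a)
  d2 <- edt_sq_cpp(lg, dm, border_bg, -1L)
  halves <- lapply(0:2, function(ax) {
    if (dm[ax + 1] < 2) NULL
    else edt_sq_cpp(lg, dm, border_bg, as.integer(ax))
  })
  th <- local_thickness_cpp(d2, lg, dm, halves[[1]], halves[[2]], halves[[3]])
  array(th, dim = dim(a))
}

# connected-component labels; connectivity 26/6 in 3D maps to 8/4 in 2D
label_components <- function(mask, connectivity = 26) {
  a <- as3d(mask)
  lab <- cc_label_cpp(as.logical(a), as.integer(dim(a)),
                      as.integer(connectivity))
  out <- array(lab, dim = dim(a))
  if (length(dim(mask)) == 2) out <- out[1, , , drop = TRUE]
  out
}

# ---- TIFF stack I/O ------------------------------------------------------

#' Read or write a volume as a multi-page TIFF stack
#'
#' One TIFF page per cross-section (the first array axis). Binary volumes are
#' stored as 0/1 grayscale pages; grayscale volumes keep their `[0, 1]`
#' intensities. TIFF files carry no micrometre calibration, so the voxel size
#' must be declared on read.
#'
#' @param path file path
#' @param voxel_size voxel pitch in micrometres
#' @param binarize if `TRUE`, pages are thresholded at 0.5 and a
#'   `binary_volume` (pixel > 0.5 = solid) is returned
#' @param vol a `binary_volume` or `gray_volume`
#' @return `read_volume_tiff`: a `gray_volume` or `binary_volume`;
#'   `write_volume_tiff`: the path, invisibly
#' @export
read_volume_tiff <- function(path, voxel_size, binarize = FALSE) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3) p <- p[, , 1]  # drop color channels
    p
  })
  d <- dim(pages[[1]])
  arr <- array(0, dim = c(length(pages), d[1], d[2]))
  for (i in seq_along(pages)) arr[i, , ] <- pages[[i]]
  if (binarize) binary_volume(arr > 0.5, voxel_size)
  else gray_volume(arr, voxel_size)
}

#' @rdname read_volume_tiff
#' @export
write_volume_tiff <- function(vol, path) {
  a <- as_plain(vol)
  if (is.logical(a)) a <- a * 1.0
  a[a < 0] <- 0; a[a > 1] <- 1
  pages <- lapply(seq_len(dim(a)[1]), function(i) a[i, , , drop = TRUE])
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  invisible(path)
}
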