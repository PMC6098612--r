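#' Extract evenly spaced cross-sections from a volume
#'
#' Selects `n_sections` section indices evenly spaced across the VOI extent
#' along the section axis, excluding the first and last 5% of the extent
#' (peripheral sections clip pores against the specimen surface). Each
#' returned section carries the pore mask restricted to the VOI and the VOI
#' slice itself.
#'
#' @param vol a `binary_volume`
#' @param voi optional `voi_mask` (defaults to the whole grid)
#' @param n_sections number of sections (>= 1, at most the usable depth)
#' @return a `pore_sections` list; each element has `index` (1-based section
#'   index), `pore` (logical matrix, TRUE = pore), `voi` (logical matrix) and
#'   the voxel size
#' @export
extract_sections <- function(vol, voi = NULL, n_sections = 5L) {
  stopifnot(inherits(vol, "binary_volume"))
  solid <- as_plain(vol)
  m <- if (is.null(voi)) array(TRUE, dim = dim(solid)) else as_plain(voi)
  if (!identical(dim(m), dim(solid))) stop("VOI shape does not match volume")
  n_sections <- as.integer(n_sections)
  if (n_sections < 1) stop("n_sections must be >= 1")
  zs <- which(apply(m, 1, any))
  if (!length(zs)) stop("empty VOI")
  zmin <- min(zs); zmax <- max(zs)
  depth <- zmax - zmin + 1L
  lo <- floor(0.05 * depth)            # 0-based offsets within the extent
  hi <- depth - 1L - lo
  if (hi < lo || (hi - lo + 1L) < n_sections)
    stop("VOI is thinner than the requested section spacing")
  off <- if (n_sections == 1L) round((lo + hi) / 2)
         else round(seq(lo, hi, length.out = n_sections))
  idx <- zmin + as.integer(off)
  out <- lapply(idx, function(z) {
    list(index = z,
         pore = !solid[z, , , drop = TRUE] & m[z, , , drop = TRUE],
         voi = m[z, , , drop = TRUE],
         voxel_size = voxel_size(vol))
  })
  structure(out, class = "pore_sections", voxel_size = voxel_size(vol))
}

#' @export
print.pore_sections <- function(x, ...) {
  cat(sprintf("<pore_sections> %d sections at indices %s\n", length(x),
              paste(vapply(x, `[[`, 1L, "index"), collapse = ", ")))
  invisible(x)
}

#' A single labeled pore region
#'
#' @param mask logical matrix, TRUE = pore pixels of this region
#' @param voxel_size pixel pitch in micrometres
#' @param label optional region label
#' @param border whether the region touches the VOI/image boundary
#' @return a `pore_region` holding the pixel coordinates
#' @export
pore_region <- function(mask, voxel_size, label = 1L, border = FALSE) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("empty pore region")
  structure(list(coords = idx, voxel_size = check_voxel_size(voxel_size),
                 label = as.integer(label), border = isTRUE(border)),
            class = "pore_region")
}

#' Label the pore regions of a 2D section
#'
#' 8-connected components of the pore phase. A region is border-touching when
#' any of its pixels lies on the image border or is 4-adjacent to a pixel
#' outside the VOI; under `border_policy = "exclude"` (the default used by
#' the samplers) those truncated regions are dropped, since a clipped pore
#' biases every size parameter low.
#'
#' @param section an element of [extract_sections()] output, or a logical
#'   matrix (TRUE = pore) — then `voxel_size` must be given
#' @param border_policy `"exclude"` or `"keep"`
#' @param voxel_size pixel pitch when `section` is a plain matrix
#' @return a `pore_region_set`: list of [pore_region()] objects plus the
#'   label matrix
#' @export
label_pores_2d <- function(section, border_policy = c("exclude", "keep"),
                           voxel_size = NULL) {
  border_policy <- match.arg(border_policy)
  if (is.matrix(section)) {
    if (is.null(voxel_size)) stop("voxel_size required for a plain matrix")
    section <- list(index = NA_integer_, pore = section,
                    voi = array(TRUE, dim = dim(section)),
                    voxel_size = check_voxel_size(voxel_size))
  }
  pore <- section$pore
  lab <- label_components(pore, 26)   # 8-connectivity in 2D
  g <- dim(pore)
  outside <- !section$voi
  # pixels adjacent (4-neighborhood) to outside-VOI pixels, or on the border
  near_out <- matrix(FALSE, g[1], g[2])
  near_out[1, ] <- near_out[g[1], ] <- TRUE
  near_out[, 1] <- near_out[, g[2]] <- TRUE
  if (any(outside)) {
    near_out[-1, ] <- near_out[-1, ] | outside[-g[1], ]
    near_out[-g[1], ] <- near_out[-g[1], ] | outside[-1, ]
    near_out[, -1] <- near_out[, -1] | outside[, -g[2]]
    near_out[, -g[2]] <- near_out[, -g[2]] | outside[, -1]
  }
  nlab <- max(lab)
  regions <- list()
  for (l in seq_len(nlab)) {
    msk <- lab == l
    brd <- any(msk & near_out)
    if (brd && border_policy == "exclude") next
    regions[[length(regions) + 1]] <-
      pore_region(msk, section$voxel_size, label = l, border = brd)
  }
  structure(list(section_index = section$index, labels = lab,
                 regions = regions, voxel_size = section$voxel_size,
                 border_policy = border_policy),
            class = "pore_region_set")
}

#' @export
print.pore_region_set <- function(x, ...) {
  cat(sprintf("<pore_region_set> section %s: %d regions (%s borders)\n",
              x$section_index, length(x$regions), x$border_policy))
  invisible(x)
}

# convex hull of pixel centers as (col, row) coordinates; handles n <= 2 and
# collinear sets
hull_points <- function(coords) {
  pts <- cbind(coords[, 2], coords[, 1])
  if (nrow(pts) <= 2) return(pts)
  h <- chull(pts[, 1], pts[, 2])
  pts[h, , drop = FALSE]
}

#' Major diameter (maximum Feret) of a pore region
#'
#' The farthest straight-line distance between two points of the pore: the
#' maximum pairwise Euclidean distance between pixel centers plus one pixel
#' pitch (extent correction, so a single pixel measures one pitch), computed
#' over the convex hull.
#'
#' @param region a `pore_region`
#' @return micrometres
#' @export
major_diameter <- function(region) {
  stopifnot(inherits(region, "pore_region"))
  pts <- hull_points(region$coords)
  d <- if (nrow(pts) == 1) 0 else max(dist(pts))
  (d + 1) * region$voxel_size
}

# region mask on its padded bounding box
region_mask <- function(region, pad = 1L) {
  co <- region$coords
  r0 <- min(co[, 1]) - pad; c0 <- min(co[, 2]) - pad
  nr <- max(co[, 1]) - r0 + 1L + pad
  nc <- max(co[, 2]) - c0 + 1L + pad
  m <- matrix(FALSE, nr, nc)
  m[cbind(co[, 1] - r0, co[, 2] - c0)] <- TRUE
  m
}

#' Biggest inner circle diameter of a pore region
#'
#' Diameter of the single largest circle fitting inside the pore, with the
#' region complement as background: the maximum of the interior
#' circle-fitting (local thickness) transform, equivalently twice the
#' maximum of the Euclidean distance transform up to the half-pixel
#' discretization of the circle center.
#'
#' @param region a `pore_region`
#' @return micrometres
#' @export
biggest_inner_circle_diameter <- function(region) {
  stopifnot(inherits(region, "pore_region"))
  m <- region_mask(region)
  th <- thickness_transform(m, border_bg = TRUE)
  max(th) * region$voxel_size
}

#' Area-equivalent circle diameter of a pore region
#'
#' Diameter of the circle whose area equals the pore area
#' (pixel count x pitch^2): `2 * sqrt(A / pi)`.
#'
#' @param region a `pore_region`
#' @return micrometres
#' @export
area_equivalent_circle_diameter <- function(region) {
  stopifnot(inherits(region, "pore_region"))
  2 * sqrt(nrow(region$coords) / pi) * region$voxel_size
}

#' Mean thickness of a pore region
#'
#' The 2D analogue of the sphere-fitting estimator: the mean over region
#' pixels of the local thickness (diameter of the largest inscribed circle
#' covering each pixel).
#'
#' @param region a `pore_region`
#' @return micrometres
#' @export
mean_thickness_2d <- function(region) {
  stopifnot(inherits(region, "pore_region"))
  m <- region_mask(region)
  th <- thickness_transform(m, border_bg = TRUE)
  mean(th[as3d(m)]) * region$voxel_size
}

#' All four planar parameters for every region of a set
#'
#' @param prs a `pore_region_set`
#' @return data.frame with one row per region: section, label, area (um^2),
#'   MD, BICD, AECD, MT (um) and the border flag
#' @export
region_metrics <- function(prs) {
  stopifnot(inherits(prs, "pore_region_set"))
  rows <- lapply(prs$regions, function(r) {
    data.frame(section = prs$section_index, label = r$label,
               area = nrow(r$coords) * r$voxel_size^2,
               MD = major_diameter(r),
               BICD = biggest_inner_circle_diameter(r),
               AECD = area_equivalent_circle_diameter(r),
               MT = mean_thickness_2d(r),
               border = r$border)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Planar pore-size sample across sections
#'
#' One value per labeled pore region per section (per-region weighting) for
#' the requested parameter. With `merge_regions = TRUE` the whole pore phase
#' of each section is treated as a single object — the merged-network mode
#' under which area-based parameters inflate strongly when pores
#' interconnect.
#'
#' @param sections a `pore_sections` list
#' @param parameter_tag `"MT"`, `"MD"`, `"BICD"` or `"AECD"`
#' @param border_policy passed to [label_pores_2d()]
#' @param merge_regions merge each section's pore phase into one region
#' @return a `size_sample`
#' @export
size_sample_2d <- function(sections, parameter_tag,
                           border_policy = c("exclude", "keep"),
                           merge_regions = FALSE) {
  stopifnot(inherits(sections, "pore_sections"))
  parameter_tag <- match.arg(parameter_tag, c("MT", "MD", "BICD", "AECD"))
  border_policy <- match.arg(border_policy)
  fn <- switch(parameter_tag, MT = mean_thickness_2d, MD = major_diameter,
               BICD = biggest_inner_circle_diameter,
               AECD = area_equivalent_circle_diameter)
  vals <- numeric(0)
  used <- integer(0)
  for (sec in sections) {
    if (merge_regions) {
      if (!any(sec$pore)) next
      regs <- list(pore_region(sec$pore, sec$voxel_size))
    } else {
      regs <- label_pores_2d(sec, border_policy)$regions
    }
    if (length(regs)) used <- c(used, sec$index)
    vals <- c(vals, vapply(regs, fn, numeric(1)))
  }
  if (!length(vals))
    stop("no pore regions found in the selected sections")
  size_sample(vals, tag = parameter_tag, weighting = "per_region",
              provenance = list(sections = used,
                                border_policy = border_policy,
                                merged = merge_regions))
}
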