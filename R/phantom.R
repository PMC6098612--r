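#' Phantom specification
#'
#' Describes a synthetic scaffold phantom with known ground truth. Phantoms
#' stand in for lyophilized-foam scaffold scans, which are essentially never
#' deposited alongside publications: they emulate the structural features that
#' drive pore-size estimators (interconnected irregular pores, thin walls,
#' bright particle speckles, partial-volume blur) without any claim to the
#' chemistry or acquisition physics of a real specimen.
#'
#' @param kind one of `"single_sphere"`, `"packed_spheres"`, `"random_foam"`,
#'   `"shape2d"`
#' @param grid_shape integer vector of voxel counts, `(sections, rows, cols)`
#'   (3D kinds) or `(rows, cols)` (`shape2d`); every extent must be >= 8
#' @param voxel_size isotropic voxel pitch in micrometres
#' @param geometry named list of kind-specific parameters:
#'   \describe{
#'     \item{single_sphere}{`diameter` (um)}
#'     \item{packed_spheres}{`mean_diameter`, `sd_diameter` (um),
#'       `target_porosity` in (0, 0.95)}
#'     \item{random_foam}{`target_porosity` in (0,1), `correlation_length`
#'       (um, >= 2 voxels), optional `anisotropy` (>= 1, stretches the
#'       section axis)}
#'     \item{shape2d}{`shape` in circle/rectangle/ellipse/lobulated plus its
#'       dimensions in um (see [make_shape_2d()])}
#'   }
#' @param seed integer seed for any stochastic generation; a fixed seed makes
#'   the phantom bit-identical across runs
#' @return a `phantom_spec` object
#' @export
phantom_spec <- function(kind, grid_shape, voxel_size, geometry = list(),
                         seed = NULL) {
  kind <- match.arg(kind, c("single_sphere", "packed_spheres", "random_foam",
                            "shape2d"))
  voxel_size <- check_voxel_size(voxel_size)
  nd <- if (kind == "shape2d") 2L else 3L
  if (is.null(grid_shape) && kind == "shape2d") {
    # auto-sized around the shape at generation time
  } else {
    grid_shape <- as.integer(grid_shape)
    if (length(grid_shape) != nd)
      stop(sprintf("grid_shape must have %d extents for kind '%s'", nd, kind))
    if (any(grid_shape < 8L))
      stop("grid_shape extents must all be >= 8 voxels")
  }
  tp <- geometry$target_porosity
  if (!is.null(tp) && (tp <= 0 || tp >= 1))
    stop("target_porosity must lie in (0, 1)")
  structure(list(kind = kind, grid_shape = grid_shape,
                 voxel_size = voxel_size, geometry = geometry,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("<phantom_spec> kind=%s grid=%s @ %g um, seed=%s\n", x$kind,
              paste(x$grid_shape, collapse = "x"), x$voxel_size,
              if (is.null(x$seed)) "none" else x$seed))
  invisible(x)
}

new_ground_truth <- function(...) structure(list(...), class = "ground_truth")

#' @export
print.ground_truth <- function(x, ...) {
  cat("<ground_truth>\n")
  if (!is.null(x$porosity)) cat(sprintf("  porosity: %.4f\n", x$porosity))
  if (!is.null(x$diameters))
    cat(sprintf("  pore diameters (um): %s%s\n",
                paste(signif(head(x$diameters, 6), 4), collapse = ", "),
                if (length(x$diameters) > 6) ", ..." else ""))
  if (!is.null(x$analytic))
    cat(sprintf("  analytic [um]: MD=%.2f BICD=%.2f AECD=%.2f MT=%.2f\n",
                x$analytic$MD, x$analytic$BICD, x$analytic$AECD,
                x$analytic$MT))
  invisible(x)
}

#' Generate a phantom from its specification
#'
#' Dispatches to the kind-specific generator. All generators are pure
#' functions of the spec (including its seed).
#'
#' @param spec a [phantom_spec()]
#' @return a list with elements `volume` (a `binary_volume`, or a
#'   `binary_image` for `shape2d`) and `truth` (a `ground_truth`)
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  switch(spec$kind,
         single_sphere = make_single_sphere(spec),
         packed_spheres = make_packed_sphere_foam(spec),
         random_foam = make_random_foam(spec),
         shape2d = make_shape_2d(spec))
}

# voxel-center coordinate grids in voxel units (1-based centers)
coord_grids <- function(g) {
  list(z = array(rep(seq_len(g[1]), times = g[2] * g[3]), dim = g),
       y = array(rep(rep(seq_len(g[2]), each = g[1]), times = g[3]), dim = g),
       x = array(rep(seq_len(g[3]), each = g[1] * g[2]), dim = g))
}

#' Solid block with a single spherical pore
#'
#' The simplest closure phantom for the sphere-fitting estimator: a solid
#' grid with one spherical pore of known diameter centered in it. A voxel is
#' pore iff its center lies inside the sphere (center-sampling
#' rasterization).
#'
#' @param spec a [phantom_spec()] with `kind = "single_sphere"` and
#'   `geometry$diameter` in micrometres; the sphere plus a 2-voxel shell must
#'   fit inside the grid
#' @return list(volume = `binary_volume`, truth = `ground_truth`) where the
#'   truth records the diameter and the analytic porosity
#' @export
make_single_sphere <- function(spec) {
  d <- spec$geometry$diameter
  if (is.null(d) || !is.finite(d) || d <= 0)
    stop("sphere diameter must be a positive number of micrometres")
  g <- spec$grid_shape
  r_vox <- d / (2 * spec$voxel_size)
  if (2 * r_vox + 2 > min(g))
    stop(sprintf("sphere of %g um (plus 2 voxels) does not fit a %s grid at %g um/voxel",
                 d, paste(g, collapse = "x"), spec$voxel_size))
  ctr <- floor((g + 1) / 2)  # anchor at a voxel center
  cg <- coord_grids(g)
  pore <- (cg$z - ctr[1])^2 + (cg$y - ctr[2])^2 + (cg$x - ctr[3])^2 <= r_vox^2
  vol <- binary_volume(!pore, spec$voxel_size)
  truth <- new_ground_truth(
    diameters = d,
    porosity = (4 / 3) * pi * r_vox^3 / prod(g))
  list(volume = vol, truth = truth)
}

#' Overlapping-sphere foam phantom
#'
#' Pores are carved as spheres with diameters drawn from a normal
#' distribution (truncated at zero) and centers uniform in the grid, until
#' the target porosity is reached. Emulates the interconnected pore space of
#' a lyophilized foam while keeping a per-pore diameter record.
#'
#' @param spec a [phantom_spec()] with `kind = "packed_spheres"` and geometry
#'   `mean_diameter`, `sd_diameter` (um) and `target_porosity` (< 0.95)
#' @param max_spheres placement budget before giving up
#' @return list(volume, truth); the truth records all sampled diameters and
#'   the achieved porosity (pore voxels / grid voxels, exact)
#' @export
make_packed_sphere_foam <- function(spec, max_spheres = 20000L) {
  geo <- spec$geometry
  mu <- geo$mean_diameter; sdd <- geo$sd_diameter %||% 0
  target <- geo$target_porosity
  if (is.null(mu) || mu <= 0) stop("mean_diameter must be positive")
  if (sdd < 0) stop("sd_diameter must be >= 0")
  if (is.null(target) || target <= 0 || target >= 0.95)
    stop("target_porosity must lie in (0, 0.95)")
  g <- spec$grid_shape
  v <- spec$voxel_size
  with_seed(spec$seed, {
    pore <- array(FALSE, dim = g)
    diameters <- numeric(0)
    n_total <- prod(g)
    repeat {
      if (mean(pore) >= target) break
      if (length(diameters) >= max_spheres)
        stop(sprintf("target porosity %.2f unreachable within %d spheres (achieved %.3f)",
                     target, max_spheres, mean(pore)))
      d <- rnorm(1, mu, sdd)
      while (d <= 0) d <- rnorm(1, mu, sdd)
      r <- d / (2 * v)
      ctr <- runif(3, min = 0.5, max = g + 0.5)
      lo <- pmax(1L, floor(ctr - r)); hi <- pmin(g, ceiling(ctr + r))
      if (any(lo > hi)) next
      zz <- lo[1]:hi[1]; yy <- lo[2]:hi[2]; xx <- lo[3]:hi[3]
      sub <- outer(outer((zz - ctr[1])^2, (yy - ctr[2])^2, "+"),
                   (xx - ctr[3])^2, "+") <= r^2
      pore[zz, yy, xx] <- pore[zz, yy, xx] | sub
      diameters <- c(diameters, d)
    }
    list(volume = binary_volume(!pore, v),
         truth = new_ground_truth(diameters = diameters,
                                  porosity = mean(pore)))
  })
}

#' Thresholded random-field foam phantom
#'
#' A Gaussian white-noise field is smoothed with a Gaussian kernel of the
#' stated correlation length and thresholded at the porosity quantile, giving
#' the irregular lamellar walls and interconnected channels typical of
#' freeze-dried scaffolds. An anisotropy factor > 1 stretches the structure
#' along the section axis (axis 1) geometrically; voxels stay isotropic.
#'
#' @param spec a [phantom_spec()] with `kind = "random_foam"` and geometry
#'   `target_porosity`, `correlation_length` (um, at least 2 voxels),
#'   optional `anisotropy` (default 1)
#' @return list(volume, truth); the truth records the achieved porosity only
#'   (the field has no per-pore ground truth)
#' @export
make_random_foam <- function(spec) {
  geo <- spec$geometry
  target <- geo$target_porosity
  clen <- geo$correlation_length
  aniso <- geo$anisotropy %||% 1
  if (is.null(target) || target <= 0 || target >= 1)
    stop("target_porosity must lie in (0, 1)")
  v <- spec$voxel_size
  if (is.null(clen) || clen < 2 * v)
    stop(sprintf("correlation_length must be >= 2 voxels (%g um)", 2 * v))
  if (aniso < 1) stop("anisotropy must be >= 1")
  g <- spec$grid_shape
  with_seed(spec$seed, {
    field <- array(rnorm(prod(g)), dim = g)
    sigma <- clen / v / 2  # kernel sd in voxels; FWHM-ish ~ correlation length
    field <- blur_separable(field, sigma = c(sigma * aniso, sigma, sigma))
    thr <- quantile(field, probs = target, names = FALSE, type = 7)
    pore <- field <= thr
    list(volume = binary_volume(!pore, v),
         truth = new_ground_truth(porosity = mean(pore)))
  })
}

# closed-form area of two disks (diameter d, centers L apart) joined by a
# rectangular neck of width w spanning the centers; exact for w < d <= L
lobulated_area <- function(d, w, L) {
  r <- d / 2
  strip <- w * sqrt(r^2 - w^2 / 4) + 2 * r^2 * asin(w / (2 * r))
  2 * pi * r^2 + w * L - strip
}

#' Single 2D pore of analytic shape
#'
#' Rasterizes one pore region (circle, rectangle, ellipse or lobulated
#' dumbbell) on a solid background, with closed-form ground truth for MD,
#' BICD and AECD and a brute-force circle-fitting oracle value for MT.
#' These are the shapes on which the four planar parameters diverge as shape
#' irregularity grows.
#'
#' @param spec a [phantom_spec()] with `kind = "shape2d"`; geometry carries
#'   `shape` plus dimensions in micrometres: circle `diameter`; rectangle
#'   `width`, `height`; ellipse `axis_a`, `axis_b` (full axes); lobulated
#'   `lobe_diameter`, `neck_width`, `center_distance`. Grid defaults to the
#'   shape extent plus a 4-voxel margin when `grid_shape` is missing from the
#'   spec; every shape dimension must span at least 8 voxels.
#' @return list(volume = `binary_image` (TRUE = solid), truth =
#'   `ground_truth` with `$analytic` values in micrometres)
#' @export
make_shape_2d <- function(spec) {
  geo <- spec$geometry
  v <- spec$voxel_size
  shape <- geo$shape
  if (is.null(shape) || !shape %in% c("circle", "rectangle", "ellipse", "lobulated"))
    stop("unknown shape: must be one of circle, rectangle, ellipse, lobulated")
  dims_um <- switch(shape,
    circle = c(geo$diameter, geo$diameter),
    rectangle = c(geo$height, geo$width),
    ellipse = c(geo$axis_a, geo$axis_b),
    lobulated = c(geo$lobe_diameter,
                  geo$center_distance + geo$lobe_diameter))
  if (any(!is.finite(dims_um)) || any(dims_um <= 0))
    stop("shape dimensions must be positive")
  small <- switch(shape,
    circle = geo$diameter, rectangle = min(geo$width, geo$height),
    ellipse = min(geo$axis_a, geo$axis_b), lobulated = geo$neck_width)
  if (small / v < 8)
    stop("every shape dimension must span at least 8 voxels")
  g <- spec$grid_shape
  if (is.null(g)) g <- as.integer(ceiling(dims_um / v) + 8L)
  if (any(dims_um / v + 2 > g))
    stop("shape does not fit the grid with a margin")
  # anchoring: curved shapes sit on a voxel center (the inscribed-circle
  # center then coincides with a candidate pixel); rectangles are anchored
  # per axis so each side spans a whole number of pixel footprints
  ctr <- floor((g + 1) / 2)
  if (shape == "rectangle") {
    px <- round(c(geo$height, geo$width) / v)
    ctr <- ctr + ifelse(px %% 2 == 0, 0.5, 0)
  }
  ry <- matrix(seq_len(g[1]), nrow = g[1], ncol = g[2])   # row coord
  cx <- matrix(seq_len(g[2]), nrow = g[1], ncol = g[2], byrow = TRUE)
  yy <- (ry - ctr[1]) * v                                 # um offsets
  xx <- (cx - ctr[2]) * v
  pore <- switch(shape,
    circle = yy^2 + xx^2 <= (geo$diameter / 2)^2,
    rectangle = abs(xx) <= geo$width / 2 & abs(yy) <= geo$height / 2,
    ellipse = (yy / (geo$axis_a / 2))^2 + (xx / (geo$axis_b / 2))^2 <= 1,
    lobulated = {
      L <- geo$center_distance; rl <- geo$lobe_diameter / 2
      (yy^2 + (xx + L / 2)^2 <= rl^2) |
        (yy^2 + (xx - L / 2)^2 <= rl^2) |
        (abs(xx) <= L / 2 & abs(yy) <= geo$neck_width / 2)
    })
  img <- binary_image(!pore, v)
  analytic <- switch(shape,
    circle = {
      d <- geo$diameter
      list(MD = d, BICD = d, AECD = d, MT = d)
    },
    rectangle = {
      a <- geo$width; b <- geo$height
      list(MD = sqrt(a^2 + b^2), BICD = min(a, b),
           AECD = 2 * sqrt(a * b / pi), MT = NA_real_)
    },
    ellipse = {
      a <- geo$axis_a; b <- geo$axis_b
      list(MD = max(a, b), BICD = min(a, b), AECD = sqrt(a * b),
           MT = NA_real_)
    },
    lobulated = {
      d <- geo$lobe_diameter; w <- geo$neck_width; L <- geo$center_distance
      list(MD = L + d, BICD = d,
           AECD = 2 * sqrt(lobulated_area(d, w, L) / pi), MT = NA_real_)
    })
  if (is.na(analytic$MT)) {
    # no closed form off the disk: brute-force circle fitting is the oracle
    tf <- thickness_bruteforce_cpp(as.logical(as3d(pore)),
                                   as.integer(dim(as3d(pore))), TRUE)
    analytic$MT <- mean(tf[tf > 0]) * v
  }
  truth <- new_ground_truth(porosity = mean(pore), analytic = analytic)
  list(volume = img, truth = truth)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# separable Gaussian blur with border renormalization (no invented
# intensities outside the grid); sigma per axis in voxels, 0 = no blur
blur_separable <- function(arr, sigma) {
  g <- dim(arr)
  num <- arr
  den <- array(1, dim = g)
  for (ax in 1:3) {
    s <- sigma[ax]
    if (s <= 0 || g[ax] == 1) next
    r <- max(1L, as.integer(ceiling(3 * s)))
    w <- exp(-(((-r):r)^2) / (2 * s^2))
    num <- conv_axis(num, w, r, ax)
    den <- conv_axis(den, w, r, ax)
  }
  num / den
}

# zero-padded convolution along one axis via index shifts
conv_axis <- function(arr, w, r, ax) {
  g <- dim(arr)
  out <- array(0, dim = g)
  n <- g[ax]
  for (k in seq_along(w)) {
    s <- k - r - 1L  # shift
    src <- seq_len(n) + s
    keep <- src >= 1L & src <= n
    if (!any(keep)) next
    dst_idx <- which(keep)
    src_idx <- src[keep]
    if (ax == 1) out[dst_idx, , ] <- out[dst_idx, , ] + w[k] * arr[src_idx, , ]
    else if (ax == 2) out[, dst_idx, ] <- out[, dst_idx, ] + w[k] * arr[, src_idx, ]
    else out[, , dst_idx] <- out[, , dst_idx] + w[k] * arr[, , src_idx]
  }
  out
}

#' Render a binary phantom as a noisy grayscale volume
#'
#' Models the degradations that matter for pore-size estimation: Gaussian
#' smoothing as a stand-in for the partial-volume effect (thin walls lose
#' apparent density), additive intensity noise, and isolated bright
#' single-voxel speckles inside the pore space, mimicking X-ray-dense
#' particle speckles that sphere-fitting estimators are sensitive to.
#' Speckles are inserted only at pore voxels whose full 26-neighborhood is
#' pore and never adjacent to one another, so each one binarizes to an
#' isolated solid voxel.
#'
#' @param vol a `binary_volume` (TRUE = solid)
#' @param blur_sigma Gaussian sigma in micrometres (>= 0)
#' @param noise_sd additive Gaussian noise sd on the `[0, 1]` intensity scale
#' @param speckle_rate fraction of eligible pore voxels to speckle, in
#'   `[0, 0.05]`
#' @param seed RNG seed; fixed seed gives a bit-identical rendering
#' @param solid_intensity,pore_intensity the two base intensity levels
#' @return a `gray_volume`; the number and linear indices of inserted
#'   speckles are attached as attributes `speckle_count` / `speckle_index`
#' @export
render_grayscale <- function(vol, blur_sigma = 0, noise_sd = 0,
                             speckle_rate = 0, seed = NULL,
                             solid_intensity = 0.75, pore_intensity = 0.25) {
  stopifnot(inherits(vol, "binary_volume"))
  if (blur_sigma < 0) stop("blur_sigma must be >= 0")
  if (speckle_rate < 0 || speckle_rate > 0.05)
    stop("speckle_rate must lie in [0, 0.05]")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  v <- voxel_size(vol)
  solid <- as_plain(vol)
  base <- ifelse(solid, solid_intensity, pore_intensity)
  with_seed(seed, {
    img <- if (blur_sigma > 0)
      blur_separable(base, rep(blur_sigma / v, 3)) else base
    spk <- integer(0)
    if (speckle_rate > 0) {
      # pore voxels with an all-pore 26-neighborhood
      interior <- !solid
      for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
        if (dz == 0 && dy == 0 && dx == 0) next
        interior <- interior & !shift_solid(solid, dz, dy, dx)
      }
      eligible <- which(interior)
      attr_eligible <- length(eligible)
      if (length(eligible)) {
        n_target <- rbinom(1, length(eligible), speckle_rate)
        cand <- sample(eligible)
        taken <- logical(length(base))
        g <- dim(base)
        for (i in cand) {
          if (length(spk) >= n_target) break
          if (taken[i]) next
          spk <- c(spk, i)
          # block the 26-neighborhood so speckles stay isolated
          co <- arrayInd(i, g)
          zz <- max(1, co[1] - 1):min(g[1], co[1] + 1)
          yy <- max(1, co[2] - 1):min(g[2], co[2] + 1)
          xx <- max(1, co[3] - 1):min(g[3], co[3] + 1)
          idx <- as.vector(outer(outer(zz, (yy - 1) * g[1], "+"),
                                 (xx - 1) * g[1] * g[2], "+"))
          taken[idx] <- TRUE
        }
        img[spk] <- solid_intensity
      }
    }
    if (noise_sd > 0) img <- img + rnorm(length(img), 0, noise_sd)
    img[img < 0] <- 0
    img[img > 1] <- 1
    out <- gray_volume(array(img, dim = dim(base)), v)
    attr(out, "speckle_count") <- length(spk)
    attr(out, "speckle_index") <- sort(spk)
    attr(out, "speckle_eligible") <- if (speckle_rate > 0) attr_eligible else 0L
    out
  })
}

# solid mask shifted by (dz, dy, dx), padded with FALSE (outside grid = pore
# for the purpose of speckle eligibility the border is excluded anyway)
shift_solid <- function(solid, dz, dy, dx) {
  g <- dim(solid)
  out <- array(TRUE, dim = g)  # borders count as blocked
  zs <- seq_len(g[1]) + dz; ys <- seq_len(g[2]) + dy; xs <- seq_len(g[3]) + dx
  kz <- zs >= 1 & zs <= g[1]; ky <- ys >= 1 & ys <= g[2]; kx <- xs >= 1 & xs <= g[3]
  out[which(kz), which(ky), which(kx)] <- solid[zs[kz], ys[ky], xs[kx]]
  out
}
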