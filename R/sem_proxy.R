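#' Observer model for manual pore measurement
#'
#' Parameterizes the selection behavior of a human operator measuring pores
#' on micrographs: pores below a visibility cutoff are never picked (small
#' pores tend to be neglected even though they contribute to the pore area),
#' selection may be area-weighted (large pores catch the eye), and a fixed
#' number of pores is measured per image.
#'
#' @param min_visible_diameter pores with AECD below this (um) are never
#'   selected (>= 0)
#' @param selection_weighting `"uniform"` or `"area_proportional"`
#' @param pores_per_image measurements per micrograph (>= 1; 40 is the usual
#'   floor of manual protocols)
#' @param seed RNG seed; fixed seed makes the selection reproducible
#' @return an `observer_model`
#' @export
observer_model <- function(min_visible_diameter = 0,
                           selection_weighting = c("uniform",
                                                   "area_proportional"),
                           pores_per_image = 40L, seed = NULL) {
  selection_weighting <- match.arg(selection_weighting)
  if (min_visible_diameter < 0) stop("min_visible_diameter must be >= 0")
  pores_per_image <- as.integer(pores_per_image)
  if (pores_per_image < 1) stop("pores_per_image must be >= 1")
  structure(list(min_visible_diameter = min_visible_diameter,
                 selection_weighting = selection_weighting,
                 pores_per_image = pores_per_image,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "observer_model")
}

#' @export
print.observer_model <- function(x, ...) {
  cat(sprintf("<observer_model> cutoff %g um, %s selection, %d pores/image, seed=%s\n",
              x$min_visible_diameter, x$selection_weighting,
              x$pores_per_image, if (is.null(x$seed)) "none" else x$seed))
  invisible(x)
}

#' Observer-style pore selection
#'
#' Samples regions without replacement among those whose area-equivalent
#' circle diameter reaches the visibility cutoff, under the model's
#' weighting, until `pores_per_image` pores are drawn or the eligible set is
#' exhausted. Deterministic under the model's seed.
#'
#' @param regions a `pore_region_set`
#' @param model an [observer_model()]
#' @return the selected subset, a list of `pore_region` objects
#' @export
select_pores <- function(regions, model) {
  stopifnot(inherits(regions, "pore_region_set"),
            inherits(model, "observer_model"))
  regs <- regions$regions
  if (!length(regs)) stop("region set is empty")
  aecd <- vapply(regs, area_equivalent_circle_diameter, numeric(1))
  eligible <- which(aecd >= model$min_visible_diameter)
  if (!length(eligible))
    stop(sprintf("no region reaches the visibility cutoff of %g um",
                 model$min_visible_diameter))
  n <- min(model$pores_per_image, length(eligible))
  with_seed(model$seed, {
    w <- if (model$selection_weighting == "area_proportional")
      vapply(regs[eligible], function(r) nrow(r$coords), numeric(1))
    else NULL
    picked <- if (length(eligible) == 1) eligible
      else eligible[sample.int(length(eligible), n, prob = w)]
    regs[picked]
  })
}

#' Feret diameters of a pore region
#'
#' Maximum and minimum caliper diameters over all directions, computed
#' exactly on the convex hull of the pixel centers (the minimum width of a
#' convex polygon is attained perpendicular to one of its edges), each plus
#' one pixel pitch of extent correction.
#'
#' @param region a `pore_region`
#' @return list with `max` and `min` in micrometres
#' @export
feret_diameters <- function(region) {
  stopifnot(inherits(region, "pore_region"))
  pts <- hull_points(region$coords)
  v <- region$voxel_size
  n <- nrow(pts)
  if (n == 1) return(list(max = v, min = v))
  dmax <- max(dist(pts))
  if (n == 2) return(list(max = (dmax + 1) * v, min = 1 * v))
  width <- Inf
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    e <- pts[j, ] - pts[i, ]
    len <- sqrt(sum(e^2))
    if (len == 0) next
    nrm <- c(-e[2], e[1]) / len
    proj <- abs((pts[, 1] - pts[i, 1]) * nrm[1] +
                (pts[, 2] - pts[i, 2]) * nrm[2])
    width <- min(width, max(proj))
  }
  if (!is.finite(width)) width <- 0
  list(max = (dmax + 1) * v, min = (width + 1) * v)
}

#' Long/short axis average diameter
#'
#' The manual-measurement statistic: the mean of the long axis (maximum Feret
#' diameter) and the short axis (minimum Feret diameter) of the pore.
#'
#' @param region a `pore_region`
#' @return micrometres
#' @export
axis_average_diameter <- function(region) {
  f <- feret_diameters(region)
  (f$max + f$min) / 2
}

#' SEM-style pore-size sample
#'
#' Applies the observer model to every section — selecting pores and
#' measuring the long/short axis average — and pools the measurements into a
#' sample tagged `"SEM"`. The per-section seeds are derived from the model
#' seed, so a fixed model gives an identical sample on rerun.
#'
#' @param sections a `pore_sections` list
#' @param model an [observer_model()]
#' @param border_policy passed to [label_pores_2d()]
#' @return a `size_sample` with per-measurement weighting
#' @export
sem_measurement <- function(sections, model = observer_model(),
                            border_policy = c("exclude", "keep")) {
  stopifnot(inherits(sections, "pore_sections"))
  border_policy <- match.arg(border_policy)
  vals <- numeric(0)
  used <- integer(0)
  for (k in seq_along(sections)) {
    sec <- sections[[k]]
    prs <- label_pores_2d(sec, border_policy)
    if (!length(prs$regions)) next
    m <- model
    if (!is.null(model$seed)) m$seed <- model$seed + k - 1L
    sel <- tryCatch(select_pores(prs, m), error = function(e) NULL)
    if (is.null(sel)) next
    vals <- c(vals, vapply(sel, axis_average_diameter, numeric(1)))
    used <- c(used, sec$index)
  }
  if (!length(vals))
    stop(sprintf("no region reaches the visibility cutoff of %g um",
                 model$min_visible_diameter))
  size_sample(vals, tag = "SEM", weighting = "per_measurement",
              provenance = list(sections = used, model = unclass(model)))
}
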