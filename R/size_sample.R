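#' Tagged pore-size sample
#'
#' A collection of pore-size values (micrometres) produced by one estimator,
#' carrying the estimator tag, the weighting mode and provenance. This is the
#' common currency between the measurement modules and the statistics module.
#'
#' @param values positive pore sizes in micrometres
#' @param tag estimator tag: one of `"3D"`, `"MT"`, `"MD"`, `"BICD"`,
#'   `"AECD"`, `"SEM"`
#' @param weighting `"per_voxel"` (one value per pore voxel), `"per_region"`
#'   (one per labeled pore region) or `"per_measurement"` (one per manual
#'   measurement)
#' @param provenance free-form list (section indices, seed, ...)
#' @return a `size_sample`
#' @export
size_sample <- function(values, tag,
                        weighting = c("per_voxel", "per_region",
                                      "per_measurement"),
                        provenance = list()) {
  tag <- match.arg(tag, c("3D", "MT", "MD", "BICD", "AECD", "SEM"))
  weighting <- match.arg(weighting)
  values <- as.numeric(values)
  if (length(values) == 0) stop("a size_sample must hold at least one value")
  if (any(!is.finite(values)) || any(values <= 0))
    stop("pore sizes must be positive and finite")
  structure(list(values = values, tag = tag, weighting = weighting,
                 provenance = provenance), class = "size_sample")
}

#' @export
print.size_sample <- function(x, ...) {
  q <- quantile(x$values, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  cat(sprintf("<size_sample> tag=%s n=%d (%s)\n  median %.1f um [Q1 %.1f, Q3 %.1f]\n",
              x$tag, length(x$values), x$weighting, q[2], q[1], q[3]))
  invisible(x)
}

#' @export
length.size_sample <- function(x) length(x$values)

#' @export
median.size_sample <- function(x, na.rm = FALSE, ...) median(x$values)
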