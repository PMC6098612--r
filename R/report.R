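#' Analysis run configuration
#'
#' Bundles every knob of the pipeline into one serializable object so a run
#' is fully reproducible from its config and seed. Defaults follow common
#' micro-CT practice for scaffold work: 4.5 um pixel pitch, 5 evaluated
#' sections, at least 40 pores per image for the manual proxy, significance
#' at 0.05.
#'
#' @param phantom a [phantom_spec()] to generate the input, or `NULL`
#' @param input path to a multi-page TIFF stack (used when `phantom` is
#'   `NULL`); `input_binary = TRUE` reads it as an already-binarized volume
#' @param input_binary whether `input` is binary (threshold 0.5) or grayscale
#' @param voxel_size voxel pitch in micrometres for TIFF inputs
#' @param render optional list(blur_sigma, noise_sd, speckle_rate) — renders
#'   a phantom to grayscale before preprocessing, exercising the full
#'   segmentation path
#' @param preprocess list of segmentation parameters: `window_radius`,
#'   `offset` (adaptive threshold), `min_solid_voxels`, `min_pore_voxels`
#'   (despeckle), `closing_radius` (shrink-wrap)
#' @param n_sections number of cross-sections for the planar parameters
#' @param border_policy `"exclude"` or `"keep"` truncated border regions
#' @param observer an [observer_model()] (its seed, when `NULL`, is derived
#'   from the run seed)
#' @param quartile_rule quartile convention for summaries
#' @param alpha significance level
#' @param seed run seed; identical config + seed gives an identical report
#' @return a `run_config`
#' @export
run_config <- function(phantom = NULL, input = NULL, input_binary = FALSE,
                       voxel_size = 4.5, render = NULL,
                       preprocess = list(), n_sections = 5L,
                       border_policy = "exclude",
                       observer = observer_model(), quartile_rule = "inclusive",
                       alpha = 0.05, seed = 1L) {
  pp <- utils::modifyList(
    list(window_radius = 2L, offset = 0, min_solid_voxels = 2L,
         min_pore_voxels = 0L, closing_radius = 4), preprocess)
  bad <- setdiff(names(preprocess),
                 c("window_radius", "offset", "min_solid_voxels",
                   "min_pore_voxels", "closing_radius"))
  if (length(bad)) stop("unknown preprocess keys: ", paste(bad, collapse = ", "))
  if (is.null(phantom) && is.null(input))
    stop("config needs either a phantom spec or an input path")
  structure(list(phantom = phantom, input = input,
                 input_binary = isTRUE(input_binary),
                 voxel_size = check_voxel_size(voxel_size), render = render,
                 preprocess = pp, n_sections = as.integer(n_sections),
                 border_policy = match.arg(border_policy,
                                           c("exclude", "keep")),
                 observer = observer, quartile_rule = quartile_rule,
                 alpha = alpha, seed = as.integer(seed)),
            class = "run_config")
}

config_json <- function(config) {
  jsonlite::toJSON(unclass_deep(config), auto_unbox = TRUE, digits = NA,
                   null = "null")
}

unclass_deep <- function(x) {
  if (is.list(x)) {
    x <- unclass(x)
    lapply(x, unclass_deep)
  } else x
}

config_hash <- function(config) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  writeLines(config_json(config), f)
  unname(tools::md5sum(f))
}

#' Run the full pore-size analysis pipeline
#'
#' Generates or loads the input volume, segments it (adaptive threshold,
#' despeckle, shrink-wrap VOI), computes all six pore-size samples (3D, MT,
#' MD, BICD, AECD, SEM), summarizes each with median/quartiles and the
#' quartile CV, and returns one report bundle. With `out_dir` set, writes
#' `report.json`, `summary.csv` and a per-region CSV; identical config and
#' seed give a byte-identical `report.json`. Partial outputs are removed if
#' the run fails.
#'
#' @param config a [run_config()]
#' @param out_dir optional output directory
#' @return a `pore_report`: list with the config, its hash, the achieved
#'   porosity, per-tag summaries and the raw samples
#' @export
run_analyze <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  written <- character(0)
  on.exit(if (length(written)) unlink(written), add = TRUE)

  if (!is.null(config$phantom)) {
    spec <- config$phantom
    if (is.null(spec$seed)) spec$seed <- config$seed
    ph <- make_phantom(spec)
    vol <- ph$volume
    if (inherits(vol, "binary_image"))
      stop("run_analyze needs a 3D input; shape2d phantoms are for the planar metrics")
    if (!is.null(config$render)) {
      rn <- config$render
      gray <- render_grayscale(vol, blur_sigma = rn$blur_sigma %||% 0,
                               noise_sd = rn$noise_sd %||% 0,
                               speckle_rate = rn$speckle_rate %||% 0,
                               seed = config$seed + 1L)
      vol <- despeckle(binarize_adaptive(gray, config$preprocess$window_radius,
                                         config$preprocess$offset),
                       config$preprocess$min_solid_voxels,
                       config$preprocess$min_pore_voxels)
    }
  } else {
    if (!file.exists(config$input)) stop("unreadable input: ", config$input)
    if (config$input_binary) {
      vol <- read_volume_tiff(config$input, config$voxel_size, binarize = TRUE)
    } else {
      gray <- read_volume_tiff(config$input, config$voxel_size)
      vol <- despeckle(binarize_adaptive(gray, config$preprocess$window_radius,
                                         config$preprocess$offset),
                       config$preprocess$min_solid_voxels,
                       config$preprocess$min_pore_voxels)
    }
  }

  voi <- shrink_wrap_voi(vol, config$preprocess$closing_radius)
  porosity <- total_porosity(vol, voi)
  tf <- local_thickness_3d(vol, voi)
  sections <- extract_sections(vol, voi, config$n_sections)

  obs <- config$observer
  if (is.null(obs$seed)) obs$seed <- config$seed + 1000L
  samples <- list(
    `3D` = size_sample_3d(tf),
    MT = size_sample_2d(sections, "MT", config$border_policy),
    MD = size_sample_2d(sections, "MD", config$border_policy),
    BICD = size_sample_2d(sections, "BICD", config$border_policy),
    AECD = size_sample_2d(sections, "AECD", config$border_policy),
    SEM = sem_measurement(sections, obs, config$border_policy))

  summaries <- do.call(rbind, lapply(samples, summarize_sizes,
                                     quartile_rule = config$quartile_rule))
  rownames(summaries) <- NULL

  report <- structure(list(
    config = unclass_deep(config), config_hash = config_hash(config),
    seed = config$seed, porosity = porosity,
    section_indices = vapply(sections, `[[`, 1L, "index"),
    summary = summaries,
    samples = lapply(samples, function(s) s$values)),
    class = "pore_report")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    fj <- file.path(out_dir, "report.json")
    fs <- file.path(out_dir, "summary.csv")
    fr <- file.path(out_dir, "regions.csv")
    written <- c(fj, fs, fr)
    writeLines(jsonlite::toJSON(unclass_deep(report), auto_unbox = TRUE,
                                digits = NA, null = "null", pretty = TRUE), fj)
    write.csv(summaries, fs, row.names = FALSE)
    regs <- do.call(rbind, lapply(sections, function(sec) {
      prs <- label_pores_2d(sec, config$border_policy)
      if (length(prs$regions)) region_metrics(prs) else NULL
    }))
    write.csv(regs, fr, row.names = FALSE)
    written <- character(0)  # success: keep outputs
  }
  report
}

#' @export
print.pore_report <- function(x, ...) {
  cat(sprintf("<pore_report> porosity %.3f, seed %d, hash %s\n", x$porosity,
              x$seed, substr(x$config_hash, 1, 8)))
  print(x$summary[, c("tag", "n", "median", "q1", "q3", "cv")], digits = 4)
  invisible(x)
}

#' Read a run configuration from JSON
#'
#' Reconstructs a [run_config()] (including a nested phantom spec and
#' observer model) from a flat JSON file, so runs can be driven from
#' config files.
#'
#' @param path JSON file with the fields of [run_config()]
#' @return a `run_config`
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("unreadable config: ", path)
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  known <- c("phantom", "input", "input_binary", "voxel_size", "render",
             "preprocess", "n_sections", "border_policy", "observer",
             "quartile_rule", "alpha", "seed")
  bad <- setdiff(names(raw), known)
  if (length(bad)) stop("invalid config keys: ", paste(bad, collapse = ", "))
  if (!is.null(raw$phantom)) {
    p <- raw$phantom
    raw$phantom <- phantom_spec(p$kind, unlist(p$grid_shape), p$voxel_size,
                                as.list(p$geometry), seed = p$seed)
  }
  if (!is.null(raw$observer)) {
    o <- raw$observer
    raw$observer <- observer_model(o$min_visible_diameter %||% 0,
                                   o$selection_weighting %||% "uniform",
                                   o$pores_per_image %||% 40L,
                                   seed = o$seed)
  }
  if (!is.null(raw$preprocess)) raw$preprocess <- as.list(raw$preprocess)
  if (!is.null(raw$render)) raw$render <- as.list(raw$render)
  do.call(run_config, raw)
}

#' Read a report bundle back from disk
#'
#' @param path a `report.json` written by [run_analyze()], or its directory
#' @return a `pore_report`
#' @export
read_report <- function(path) {
  if (dir.exists(path)) path <- file.path(path, "report.json")
  if (!file.exists(path)) stop("unreadable report: ", path)
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  obj$samples <- lapply(obj$samples, as.numeric)
  structure(obj, class = "pore_report")
}

#' Compare pore-size reports across specimens
#'
#' For every shared estimator tag, compares the specimens' samples with a
#' Kruskal-Wallis + Bonferroni post hoc (3+ specimens) or a Mann-Whitney
#' test (2 specimens), and tabulates the quartile CV per tag per specimen.
#'
#' @param reports list of `pore_report` bundles (at least 2), optionally
#'   named by specimen
#' @param alpha significance level
#' @return list with `comparisons` (one `comparison_report` per tag) and
#'   `cv_table` (specimen x tag data.frame of CVs)
#' @export
run_compare <- function(reports, alpha = 0.05) {
  if (length(reports) < 2) stop("need at least 2 reports")
  stopifnot(all(vapply(reports, inherits, logical(1), "pore_report")))
  names(reports) <- names(reports) %||% paste0("specimen", seq_along(reports))
  tag_sets <- lapply(reports, function(r) names(r$samples))
  shared <- Reduce(intersect, tag_sets)
  missing <- setdiff(unique(unlist(tag_sets)), shared)
  if (length(missing))
    stop("tags not shared by all reports: ", paste(missing, collapse = ", "))
  comparisons <- lapply(shared, function(tag) {
    groups <- lapply(reports, function(r) r$samples[[tag]])
    rep_names <- names(reports)
    rep <- if (length(groups) == 2)
      mann_whitney(groups[[1]], groups[[2]], alpha)
    else kruskal_wallis_posthoc(groups, alpha)
    dimnames(rep$p_adjusted) <- list(rep_names, rep_names)
    dimnames(rep$significant) <- list(rep_names, rep_names)
    rep
  })
  names(comparisons) <- shared
  cv_rows <- do.call(rbind, lapply(names(reports), function(nm) {
    s <- reports[[nm]]$summary
    data.frame(specimen = nm, tag = s$tag, cv = s$cv)
  }))
  list(comparisons = comparisons, cv_table = cv_rows)
}
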