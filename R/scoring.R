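#' Load a semi-quantitative score matrix
#'
#' The semi-quantitative comparison grades each pore-size estimator on a set
#' of qualities (non-destructivity, time-efficacy, direct 3D analysis, whole
#' specimen evaluation, high resolution, irregular pore assessment, image
#' processing bias, widespread use) with 2 = very advantageous,
#' 1 = advantageous, 0 = no advantage. The matrix is user-editable data, not
#' code: the weighting is admittedly subjective, so alternative assessments
#' must be expressible without code changes. A reference assessment grid
#' ships as the packaged default.
#'
#' @param source path to a CSV (first column `quality`, one column per
#'   estimator tag) or JSON file (object of quality -> named entries);
#'   `NULL` loads the packaged default
#' @return a `score_matrix`: integer matrix qualities x parameters
#' @export
load_score_matrix <- function(source = NULL) {
  if (is.null(source))
    source <- system.file("extdata", "pore_parameter_scores.csv",
                          package = "poremetry")
  if (grepl("\\.json$", source, ignore.case = TRUE)) {
    obj <- jsonlite::fromJSON(source)
    tags <- unique(unlist(lapply(obj, names)))
    m <- t(vapply(obj, function(row) {
      if (!setequal(names(row), tags)) stop("missing cell in score matrix")
      unlist(row)[tags]
    }, numeric(length(tags))))
    colnames(m) <- tags
  } else {
    df <- read.csv(source, check.names = FALSE)
    if (names(df)[1] != "quality") stop("first column must be 'quality'")
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df$quality
  }
  score_matrix(m)
}

#' Validate a score matrix
#'
#' @param m numeric matrix with quality row names and estimator-tag column
#'   names; entries must be 0, 1 or 2, with no missing cells and no
#'   duplicated qualities
#' @return a validated `score_matrix`
#' @export
score_matrix <- function(m) {
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop("score matrix needs quality row names and parameter column names")
  if (anyDuplicated(rownames(m))) stop("duplicate quality rows")
  if (anyDuplicated(colnames(m))) stop("duplicate parameter columns")
  if (anyNA(m)) stop("missing cell in score matrix")
  if (!all(m %in% 0:2))
    stop("score entries must be 0 (no advantage), 1 (advantageous) or 2 (very advantageous)")
  storage.mode(m) <- "integer"
  structure(m, class = c("score_matrix", "matrix", "array"))
}

#' Total scores and ranking of the estimators
#'
#' Column sums of the score matrix, returned in descending order with ties
#' preserved. Totals are bounded by `[0, 2 * number of qualities]`.
#'
#' @param m a `score_matrix` (or a matrix validated by [score_matrix()])
#' @return list with `totals` (named integer vector, input column order) and
#'   `ranking` (totals sorted descending)
#' @export
total_scores <- function(m) {
  m <- score_matrix(unclass(m))
  totals <- setNames(as.integer(colSums(m)), colnames(m))
  list(totals = totals, ranking = sort(totals, decreasing = TRUE))
}

#' @export
print.score_matrix <- function(x, ...) {
  cat(sprintf("<score_matrix> %d qualities x %d parameters\n", nrow(x), ncol(x)))
  print(unclass(x))
  tot <- colSums(x)
  cat("Total:", paste(sprintf("%s=%d", names(tot), tot), collapse = " "), "\n")
  invisible(x)
}
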