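#' Summary of a pore-size sample
#'
#' Median and quartiles (the robust summary used for skewed pore-size
#' distributions), the quartile-based coefficient of variation
#' CV = (Q3 - Q1) / median, plus mean and sd for reference.
#'
#' @param sample a `size_sample` (or bare numeric vector)
#' @param quartile_rule quantile algorithm: `"inclusive"` (linear
#'   interpolation, R type 7, default) or `"exclusive"` (type 6); the rule
#'   used is named in the output since it moves the CV by a few percent
#' @return a one-row data.frame: tag, n, median, q1, q3, cv, mean, sd,
#'   quartile_rule
#' @export
summarize_sizes <- function(sample, quartile_rule = c("inclusive",
                                                      "exclusive")) {
  quartile_rule <- match.arg(quartile_rule)
  if (inherits(sample, "size_sample")) {
    x <- sample$values; tag <- sample$tag
  } else {
    x <- as.numeric(sample); tag <- NA_character_
  }
  if (!length(x)) stop("cannot summarize an empty sample")
  type <- if (quartile_rule == "inclusive") 7L else 6L
  q <- quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = type)
  data.frame(tag = tag, n = length(x), median = q[2], q1 = q[1], q3 = q[3],
             cv = if (q[2] > 0) (q[3] - q[1]) / q[2] else NA_real_,
             mean = mean(x), sd = if (length(x) > 1) sd(x) else 0,
             quartile_rule = quartile_rule)
}

#' Quartile-based coefficient of variation
#'
#' The interquartile range divided by the median — a robust dispersion
#' measure comparable across estimators whose distributions are far from
#' normal. Scale-invariant: multiplying all sizes by a constant leaves it
#' unchanged.
#'
#' @param x a `size_sample`, a summary row from [summarize_sizes()], or a
#'   numeric vector
#' @param quartile_rule see [summarize_sizes()]
#' @return dimensionless CV
#' @export
coefficient_of_variation <- function(x, quartile_rule = "inclusive") {
  if (is.data.frame(x)) {
    if (x$median <= 0) stop("CV undefined for non-positive median")
    return((x$q3 - x$q1) / x$median)
  }
  row <- summarize_sizes(x, quartile_rule)
  if (row$median <= 0) stop("CV undefined for non-positive median")
  (row$q3 - row$q1) / row$median
}

new_comparison_report <- function(test, omnibus, p_matrix, alpha,
                                  group_n) {
  flags <- !is.na(p_matrix) & p_matrix <= alpha
  structure(list(test = test, omnibus = omnibus, p_adjusted = p_matrix,
                 significant = flags, alpha = alpha, group_n = group_n),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("<comparison_report> %s (alpha = %g)\n", x$test, x$alpha))
  if (!is.null(x$omnibus))
    cat(sprintf("  omnibus: H = %.3f, df = %d, p = %.4g\n",
                x$omnibus$statistic, x$omnibus$df, x$omnibus$p))
  cat("  adjusted pairwise p-values (o = not significant, * = significant):\n")
  m <- x$p_adjusted
  tags <- rownames(m)
  for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m))) {
    if (j <= i) next
    cat(sprintf("    %-5s vs %-5s  p = %.4g %s\n", tags[i], tags[j], m[i, j],
                if (x$significant[i, j]) "*" else "o"))
  }
  invisible(x)
}

sample_values <- function(s) if (inherits(s, "size_sample")) s$values else as.numeric(s)
sample_tag <- function(s, i) {
  if (inherits(s, "size_sample")) s$tag else paste0("group", i)
}

# Dunn's z statistic post hoc on the pooled ranking, with tie correction
dunn_pairwise <- function(groups) {
  x <- unlist(groups)
  g <- rep(seq_along(groups), lengths(groups))
  r <- rank(x)
  N <- length(x)
  ties <- table(x)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  rbar <- tapply(r, g, mean)
  n <- lengths(groups)
  k <- length(groups)
  p <- matrix(NA_real_, k, k)
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    se <- sqrt((N * (N + 1) / 12 - tie_term) * (1 / n[i] + 1 / n[j]))
    z <- (rbar[i] - rbar[j]) / se
    p[i, j] <- p[j, i] <- 2 * pnorm(-abs(z))
  }
  p
}

#' Kruskal-Wallis test with Bonferroni-adjusted post hoc
#'
#' Omnibus rank test across three or more pore-size samples (with tie
#' correction), followed by pairwise rank-based comparisons adjusted by
#' Bonferroni multiplication (capped at 1). The default post hoc is Dunn's z
#' on the pooled ranking; `posthoc = "mw"` runs pairwise Mann-Whitney tests
#' instead.
#'
#' @param samples list of `size_sample` objects (or numeric vectors), each of
#'   size >= 2; at least 3 groups
#' @param alpha significance level for flagging (default 0.05)
#' @param posthoc `"dunn"` or `"mw"`
#' @return a `comparison_report` with the omnibus result, the symmetric
#'   adjusted-p matrix and significance flags (p <= alpha)
#' @export
kruskal_wallis_posthoc <- function(samples, alpha = 0.05,
                                   posthoc = c("dunn", "mw")) {
  posthoc <- match.arg(posthoc)
  if (length(samples) < 3)
    stop("need at least 3 groups; use mann_whitney() for two-sample comparisons")
  groups <- lapply(samples, sample_values)
  if (any(lengths(groups) < 2)) stop("every group needs n >= 2")
  tags <- vapply(seq_along(samples), function(i) sample_tag(samples[[i]], i),
                 character(1))
  kw <- kruskal.test(groups)
  m <- choose(length(groups), 2)
  p <- if (posthoc == "dunn") {
    dunn_pairwise(groups)
  } else {
    k <- length(groups)
    pm <- matrix(NA_real_, k, k)
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      pm[i, j] <- pm[j, i] <- suppressWarnings(
        wilcox.test(groups[[i]], groups[[j]])$p.value)
    }
    pm
  }
  p_adj <- pmin(p * m, 1)
  dimnames(p_adj) <- list(tags, tags)
  new_comparison_report(
    test = sprintf("Kruskal-Wallis + %s post hoc (Bonferroni)",
                   if (posthoc == "dunn") "Dunn" else "pairwise Mann-Whitney"),
    omnibus = list(statistic = unname(kw$statistic),
                   df = unname(kw$parameter), p = kw$p.value),
    p_matrix = p_adj, alpha = alpha, group_n = lengths(groups))
}

#' Two-sample Mann-Whitney comparison
#'
#' Two-sided rank-sum test; exact when both samples are small and tie-free.
#'
#' @param a,b `size_sample` objects or numeric vectors, each n >= 2
#' @param alpha significance level for the flag
#' @return a `comparison_report` with the 2 x 2 p matrix
#' @export
mann_whitney <- function(a, b, alpha = 0.05) {
  xa <- sample_values(a); xb <- sample_values(b)
  if (length(xa) < 2 || length(xb) < 2)
    stop("both samples need n >= 2")
  tags <- c(sample_tag(a, 1), sample_tag(b, 2))
  if (tags[1] == tags[2]) tags <- paste0(tags, c(".1", ".2"))
  wt <- suppressWarnings(wilcox.test(xa, xb))
  p <- matrix(c(NA, wt$p.value, wt$p.value, NA), 2, 2,
              dimnames = list(tags, tags))
  new_comparison_report("Mann-Whitney", NULL, p, alpha,
                        c(length(xa), length(xb)))
}
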