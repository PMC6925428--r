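#' Compute a MEDEA-style deprivation index
#'
#' Builds the composite socioeconomic deprivation score from the five tract
#' indicators: each column is standardized to mean 0 / sd 1, the first
#' principal component of the standardized matrix is extracted, its sign is
#' oriented so the score correlates positively with the unemployment column
#' (higher index = greater deprivation), and the scores are rescaled to
#' mean 0 / sd 1. `variance_explained` is the first eigenvalue of the
#' correlation matrix divided by 5.
#'
#' @param indicators numeric matrix or data.frame, tracts x 5 indicators
#'   (columns in the order manual workers, unemployment, temporary workers,
#'   low education, low education in the young; a column whose name matches
#'   `unemp` is used for orientation, else column 2).
#' @return object of class `deprivation_index`: list with `x` (named score
#'   vector), `septile` (1-7, 7 = most deprived; `NULL` when fewer than 7
#'   tracts), `q5`, `q95`, `variance_explained`.
#' @export
compute_index <- function(indicators) {
  X <- as.matrix(indicators)
  if (!is.numeric(X)) stop("indicators must be numeric")
  if (nrow(X) < 3L) stop("at least 3 tracts are required")
  if (ncol(X) != 5L) stop("exactly 5 indicator columns are required")
  if (anyNA(X) || !all(is.finite(X))) stop("indicators contain missing or non-finite values")
  sds <- apply(X, 2L, stats::sd)
  if (any(sds == 0)) {
    bad <- colnames(X)[sds == 0]
    if (is.null(bad)) bad <- which(sds == 0)
    stop("zero-variance indicator column(s): ", paste(bad, collapse = ", "))
  }
  pca <- stats::prcomp(X, center = TRUE, scale. = TRUE)
  x <- pca$x[, 1L]
  unemp_col <- grep("unemp", colnames(X), ignore.case = TRUE)
  unemp_col <- if (length(unemp_col)) unemp_col[[1L]] else 2L
  if (stats::cor(x, X[, unemp_col]) < 0) x <- -x
  x <- as.vector(scale(x))
  names(x) <- rownames(X)
  ve <- pca$sdev[1L]^2 / 5
  span <- percentile_span(x)
  structure(
    list(x = x,
         septile = if (length(x) >= 7L) assign_septiles(x) else NULL,
         q5 = span[["q5"]], q95 = span[["q95"]],
         variance_explained = ve),
    class = "deprivation_index"
  )
}

#' @export
print.deprivation_index <- function(x, ...) {
  cat("deprivation_index:", length(x$x), "tracts; PC1 explains",
      sprintf("%.1f%%", 100 * x$variance_explained), "of indicator variance\n")
  cat("  q5 =", signif(x$q5, 4), " q95 =", signif(x$q95, 4), "\n")
  invisible(x)
}

#' Assign septiles of deprivation
#'
#' Rank-based split of the scores into seven ordered groups whose sizes
#' differ by at most one; label 7 is the most deprived septile. Ties are
#' broken by stable input order, so labels are a deterministic function of
#' the ranks.
#'
#' @param x numeric score vector, length >= 7.
#' @param k number of groups (default 7).
#' @return integer labels 1..k, in input order.
#' @export
assign_septiles <- function(x, k = 7L) {
  if (length(x) < k) stop("need at least ", k, " tracts for ", k, " groups")
  r <- integer(length(x))
  r[order(x)] <- seq_along(x)  # stable: order() breaks ties by position
  as.integer(ceiling(k * r / length(x)))
}

#' Percentile span of the deprivation index
#'
#' Empirical percentiles by linear interpolation of the order statistics
#' (the default quantile definition, type 7); the span `q95 - q5` is the
#' exposure contrast the relative risks are reported on.
#'
#' @param x numeric vector with at least 2 distinct values.
#' @param lo,hi percentile pair (defaults 5 and 95).
#' @return named numeric vector `c(q5 = ..., q95 = ...)` (names follow
#'   `lo`/`hi`).
#' @export
percentile_span <- function(x, lo = 5, hi = 95) {
  if (length(unique(x)) < 2L)
    stop("index is constant; a percentile span of zero makes the relative risk undefined")
  if (!(lo < hi)) stop("lo must be < hi")
  q <- stats::quantile(x, probs = c(lo, hi) / 100, names = FALSE, type = 7)
  stats::setNames(q, paste0("q", c(lo, hi)))
}
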