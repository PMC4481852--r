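#' Median-scaling normalization
#'
#' Shifts every run by an additive offset so that all runs share the same
#' median log intensity. The common target is the median of the original
#' per-run medians, which makes the operation symmetric across runs and
#' idempotent.
#'
#' @param table An [intensity_table()] of log-scale intensities.
#' @return A list with elements `table` (the normalized [intensity_table()])
#'   and `record` (method, per-run offsets in log-intensity units).
#' @export
median_scale <- function(table) {
  stopifnot(inherits(table, "intensity_table"))
  med <- apply(table, 2L, stats::median, na.rm = TRUE)
  empty <- names(med)[!is.finite(med)]
  if (length(empty))
    stop("run(s) with no non-missing values: ",
         paste(empty, collapse = ", "), call. = FALSE)
  target <- stats::median(med)
  offsets <- target - med
  out <- sweep(unclass(table), 2L, offsets, `+`)
  list(table = intensity_table(out),
       record = list(method = "median_scale", offsets = offsets))
}

#' Variance-stabilizing generalized-log transform
#'
#' Applies the generalized logarithm
#' \deqn{g(x) = \log_2\left(\frac{x + \sqrt{x^2 + c^2}}{2}\right)}
#' elementwise to a linear-scale (non-negative) intensity matrix. For large
#' `x` the transform approaches `log2(x)`; near zero it is approximately
#' linear, which removes the dependence of the signal variance on the mean
#' intensity typical of additive-plus-multiplicative noise. With
#' `c = "auto"` the constant is chosen from a grid of quantiles of the
#' positive intensities so as to minimize the absolute Spearman correlation
#' between per-molecule mean and per-molecule standard deviation of the
#' transformed data.
#'
#' Input must be linear-scale; if the pipeline input is log-scale, callers
#' must exponentiate first (the pipeline driver handles this).
#'
#' @param raw_table An [intensity_table()] holding linear-scale intensities.
#' @param c Positive glog constant (intensity units) or `"auto"`.
#' @return A list with elements `table` (transformed, log2 scale) and
#'   `record` (method and the constant `c` used).
#' @export
vstab_transform <- function(raw_table, c = "auto") {
  stopifnot(inherits(raw_table, "intensity_table"))
  vals <- unclass(raw_table)
  bad <- which(!is.na(vals) & vals < 0, arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("negative intensity at row %d, column %d: vstab requires linear-scale input",
                 bad[1, 1], bad[1, 2]), call. = FALSE)
  if (identical(c, "auto")) {
    c <- .vstab_auto_c(vals)
  } else {
    c <- as.numeric(c)
    if (!is.finite(c) || c <= 0)
      stop("vstab constant c must be positive", call. = FALSE)
  }
  out <- .glog2(vals, c)
  dimnames(out) <- dimnames(vals)
  list(table = intensity_table(out),
       record = list(method = "vstab", c = c))
}

.glog2 <- function(x, c) log2((x + sqrt(x^2 + c^2)) / 2)

# pick c from a fixed quantile grid of the positive values, minimizing the
# absolute Spearman correlation between per-molecule mean and SD
.vstab_auto_c <- function(vals) {
  pos <- vals[!is.na(vals) & vals > 0]
  if (!length(pos)) stop("no positive values to calibrate c from", call. = FALSE)
  grid <- unique(stats::quantile(pos, probs = c(0.001, 0.005, 0.01, 0.025,
                                                0.05, 0.1, 0.25, 0.5, 0.75),
                                 names = FALSE))
  grid <- grid[grid > 0]
  score <- vapply(grid, function(cc) {
    tr <- .glog2(vals, cc)
    m <- rowMeans(tr, na.rm = TRUE)
    s <- apply(tr, 1L, stats::sd, na.rm = TRUE)
    ok <- is.finite(m) & is.finite(s)
    if (sum(ok) < 3L || stats::sd(s[ok]) == 0) return(0)
    abs(stats::cor(m[ok], s[ok], method = "spearman"))
  }, numeric(1))
  grid[which.min(score)]
}
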