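# Post-hoc quality control of the per-cell feature table: per-feature IQR
# outlier detection with a per-cell flag, and multicollinearity pruning via
# variance inflation factors.

#' Flag outlier cells by per-feature IQR fences
#'
#' For every numeric feature, cells outside the fence
#' \code{[Q1 - 1.5 IQR, Q3 + 1.5 IQR]} (quartiles by linear interpolation)
#' are marked; a cell is an outlier iff the fraction of its marked features
#' strictly exceeds \code{frac_cutoff}. A constant feature has IQR 0, its
#' fence collapses to the constant, and cells at the constant are inliers.
#'
#' @param cell_table data.frame; non-numeric columns (identifiers) are
#'   ignored.
#' @param frac_cutoff flagged-feature fraction above which a cell is an
#'   outlier (strict inequality).
#' @return List: \code{outlier_fraction} (per cell), \code{is_outlier_cell}
#'   (logical), \code{flags} (cell x feature logical matrix),
#'   \code{fences} (per-feature lower/upper bounds).
#' @export
flag_outlier_cells <- function(cell_table, frac_cutoff = 0.20) {
  num <- vapply(cell_table, is.numeric, logical(1))
  x <- as.matrix(cell_table[, num, drop = FALSE])
  if (nrow(x) < 4)
    stop("need at least 4 cells for quartile-based outlier detection")
  q1 <- apply(x, 2, quantile, 0.25, type = 7)
  q3 <- apply(x, 2, quantile, 0.75, type = 7)
  iqr <- q3 - q1
  lo <- q1 - 1.5 * iqr; hi <- q3 + 1.5 * iqr
  flags <- sweep(x, 2, lo, "<") | sweep(x, 2, hi, ">")
  frac <- rowMeans(flags)
  list(outlier_fraction = frac,
       is_outlier_cell = frac > frac_cutoff,
       flags = flags,
       fences = data.frame(feature = colnames(x), lower = lo, upper = hi,
                           row.names = NULL))
}

# R^2 of regressing column j on the remaining columns (standardized input)
vif_of <- function(x, j) {
  y <- x[, j]
  others <- x[, -j, drop = FALSE]
  fit <- lm.fit(cbind(1, others), y)
  rss <- sum(fit$residuals^2)
  tss <- sum((y - mean(y))^2)
  if (tss == 0) return(1)            # constant feature: never inflated
  r2 <- 1 - rss / tss
  if (r2 >= 1 - 1e-12) return(Inf)   # perfect collinearity
  1 / (1 - r2)
}

#' Iteratively prune multicollinear features by variance inflation factor
#'
#' Each iteration removes the single feature with the largest
#' VIF = 1 / (1 - R^2) from regressing it (standardized) on all other
#' retained features, until the maximum VIF is at or below \code{vif_cutoff}.
#' Ties (including perfectly collinear pairs with infinite VIF) remove the
#' later column in table order first, making the output a deterministic
#' function of the table and configuration.
#'
#' @param cell_table data.frame; non-numeric columns are ignored.
#' @param vif_cutoff maximum tolerated VIF.
#' @param max_iters iteration cap.
#' @return List: \code{retained} (feature names), \code{removed} (in removal
#'   order), \code{vifs} (final VIF per retained feature).
#' @export
vif_prune <- function(cell_table, vif_cutoff = 10, max_iters = Inf) {
  num <- vapply(cell_table, is.numeric, logical(1))
  x <- as.matrix(cell_table[, num, drop = FALSE])
  # standardize (constant columns stay at 0 and never inflate)
  x <- apply(x, 2, function(v) {
    s <- sd(v)
    if (s == 0) rep(0, length(v)) else (v - mean(v)) / s
  })
  removed <- character(0)
  iter <- 0
  while (ncol(x) > 1 && iter < max_iters) {
    iter <- iter + 1
    vifs <- vapply(seq_len(ncol(x)), function(j) vif_of(x, j), numeric(1))
    worst <- max(vifs)
    if (worst <= vif_cutoff) break
    drop_j <- max(which(vifs == worst))  # later column first on ties
    removed <- c(removed, colnames(x)[drop_j])
    x <- x[, -drop_j, drop = FALSE]
  }
  final_vifs <- if (ncol(x) > 1)
    setNames(vapply(seq_len(ncol(x)), function(j) vif_of(x, j), numeric(1)),
             colnames(x))
  else setNames(rep(1, ncol(x)), colnames(x))
  list(retained = colnames(x), removed = removed, vifs = final_vifs)
}
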