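# Mask-agreement metrics used to validate segmentation against reference
# masks (hand-drawn or ground truth).

#' Compare two binary masks
#'
#' Computes the effective overlap (intersection over union, symmetric), the
#' fraction of the reference mask captured by the other mask, and the content
#' ratio |A| / |B| (how much more or less material one source marked than the
#' other). An optional tolerance dilates both masks by \code{tolerance_px}
#' before comparison (default 0: raw pixel sets).
#'
#' @param a,b logical matrices of equal dimension.
#' @param reference which mask is the reference for \code{fraction_captured}
#'   (\code{"a"} or \code{"b"}).
#' @param tolerance_px boundary tolerance radius, px.
#' @return Object of class \code{mask_comparison}: \code{effective_overlap},
#'   \code{fraction_captured}, \code{content_ratio}, plus raw counts.
#' @export
compare_masks <- function(a, b, reference = c("b", "a"), tolerance_px = 0) {
  reference <- match.arg(reference)
  stopifnot(all(dim(a) == dim(b)))
  a <- a != 0; b <- b != 0
  if (!any(a) && !any(b))
    stop("both masks are empty: agreement metrics undefined")
  if (tolerance_px > 0) {
    a <- dilate_mask(a, tolerance_px)
    b <- dilate_mask(b, tolerance_px)
  }
  n_int <- sum(a & b); n_uni <- sum(a | b)
  ref_n <- if (reference == "a") sum(a) else sum(b)
  structure(list(
    effective_overlap = n_int / n_uni,
    fraction_captured = if (ref_n > 0) n_int / ref_n else NA_real_,
    content_ratio = if (sum(b) > 0) sum(a) / sum(b) else NA_real_,
    n_intersection = n_int, n_union = n_uni, n_a = sum(a), n_b = sum(b),
    reference = reference), class = "mask_comparison")
}

#' @export
print.mask_comparison <- function(x, ...) {
  cat(sprintf(
    "<mask_comparison IoU=%.4f captured(ref=%s)=%.4f ratio=%.4f>\n",
    x$effective_overlap, x$reference, x$fraction_captured, x$content_ratio))
  invisible(x)
}

#' Relative performance of a tool against two human raters
#'
#' Per metric: the mean of the two tool-vs-user values divided by the
#' user-vs-user value. A ratio of 1 means the tool agrees with each user as
#' well as the users agree with each other; above 1, better.
#'
#' @param tool_vs_u1,tool_vs_u2,u1_vs_u2 \code{mask_comparison} objects for
#'   the same image.
#' @return Named list of per-metric ratios (NA, with a warning, where the
#'   user-vs-user value is zero).
#' @export
relative_performance <- function(tool_vs_u1, tool_vs_u2, u1_vs_u2) {
  metrics <- c("effective_overlap", "fraction_captured", "content_ratio")
  out <- lapply(metrics, function(m) {
    denom <- u1_vs_u2[[m]]
    if (is.na(denom) || denom == 0) {
      warning("user-vs-user ", m, " is zero; relative value undefined")
      return(NA_real_)
    }
    mean(c(tool_vs_u1[[m]], tool_vs_u2[[m]])) / denom
  })
  setNames(out, metrics)
}
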