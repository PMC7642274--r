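# Mito Catcher: binarize the mitochondrial network of a single-cell image.
# The nuclear zone is the background-sampling region: it lies inside the
# cell, and the mitochondrial signal there is out-of-plane glow that is also
# present across the whole cell, so its intensity statistics estimate the
# background everywhere. Optionally, AdaMM corrects the global threshold
# tile by tile through a generalized logistic transfer function of the tile
# mean, inflected at the background mean.

#' Mito Catcher preprocessing parameters
#'
#' @param tophat_radius white top-hat structuring-element radius, px. The
#'   element must be larger than the correlation scale of the out-of-plane
#'   (defocused) glow: the nuclear-zone threshold samples that glow as
#'   background, and a smaller element would flatten it while leaving the
#'   periphery unchanged, biasing the threshold low.
#' @param clahe whether to apply contrast-limited adaptive histogram
#'   equalization (off by default: it can amplify noise).
#' @param clahe_clip CLAHE clip limit.
#' @param clahe_tiles CLAHE tile grid count per side.
#' @param median_radius median-filter radius, px (salt-and-pepper removal).
#' @return Parameter list.
#' @export
preprocess_params <- function(tophat_radius = 30, clahe = FALSE,
                              clahe_clip = 2, clahe_tiles = 8,
                              median_radius = 1) {
  list(tophat_radius = tophat_radius, clahe = clahe, clahe_clip = clahe_clip,
       clahe_tiles = clahe_tiles, median_radius = median_radius)
}

#' Preprocess the mitochondrial channel of a single cell
#'
#' Fixed order: white top-hat, optional CLAHE, median filter.
#'
#' @param mito intensity matrix (8-bit).
#' @param params list from \code{\link{preprocess_params}}.
#' @return Intensity matrix, same dimensions.
#' @export
preprocess_mito <- function(mito, params = preprocess_params()) {
  x <- mito / 255
  if (params$tophat_radius > 0)
    x <- EBImage::whiteTopHat(x, disc_brush(params$tophat_radius))
  if (isTRUE(params$clahe))
    x <- EBImage::clahe(x, nx = params$clahe_tiles, ny = params$clahe_tiles,
                        limit = params$clahe_clip)
  if (params$median_radius > 0)
    x <- EBImage::medianFilter(pmin(pmax(x, 0), 1), params$median_radius)
  pmin(pmax(as.matrix(x), 0), 1) * 255
}

#' Fit the nuclear-zone background model
#'
#' Quartiles (linear interpolation between order statistics) and IQR of the
#' mitochondrial intensities under the nucleus mask; pixels outside the
#' closed fence \code{[Q1 - 1.5 IQR, Q3 + 1.5 IQR]} are discarded as outliers
#' (in-plane signal leaking into the zone), and the clean mean and population
#' standard deviation of the inliers give the global signal threshold
#' \code{clean_mean + 2 * clean_sd}.
#'
#' @param mito (preprocessed) intensity matrix.
#' @param nucleus_mask logical matrix.
#' @return Object of class \code{background_model}: \code{q1}, \code{q3},
#'   \code{iqr}, \code{clean_mean}, \code{clean_sd}, \code{global_threshold},
#'   \code{n_inliers}, \code{n_total}.
#' @export
fit_background <- function(mito, nucleus_mask) {
  stopifnot(all(dim(mito) == dim(nucleus_mask)))
  v <- mito[nucleus_mask]
  if (length(v) == 0)
    stop("empty nucleus mask: supply a manual threshold instead")
  q <- unname(quantile(v, c(0.25, 0.75), type = 7))
  iqr <- q[2] - q[1]
  lo <- q[1] - 1.5 * iqr; hi <- q[2] + 1.5 * iqr
  inl <- v[v >= lo & v <= hi]
  m <- mean(inl); s <- pop_sd(inl)
  structure(list(q1 = q[1], q3 = q[2], iqr = iqr,
                 clean_mean = m, clean_sd = s,
                 global_threshold = min(max(m + 2 * s, 0), 255),
                 n_inliers = length(inl), n_total = length(v)),
            class = "background_model")
}

#' @export
print.background_model <- function(x, ...) {
  cat(sprintf(
    "<background_model Q1=%.2f Q3=%.2f IQR=%.2f mean=%.3f sd=%.3f thr=%.3f (%d/%d inliers)>\n",
    x$q1, x$q3, x$iqr, x$clean_mean, x$clean_sd, x$global_threshold,
    x$n_inliers, x$n_total))
  invisible(x)
}

#' Binarize at the global background threshold
#'
#' Foreground iff intensity strictly exceeds the global threshold.
#'
#' @param mito intensity matrix.
#' @param model a \code{background_model}.
#' @return Logical mask.
#' @export
binarize_global <- function(mito, model) {
  mito > model$global_threshold
}

#' Generalized logistic threshold correction
#'
#' \deqn{c(x) = L_{low} + \frac{L_{high} - L_{low}}{(1 + e^{-k (x - x_0)})^{1/\nu}} + offset}
#' shifted so that \code{correction(x0) = 0}: tiles whose mean equals the
#' background mean are not corrected; dimmer tiles get a lower threshold,
#' brighter tiles a higher one. After the shift the correction is bounded
#' by \code{(L_low - L_high)/2} below and \code{(L_high - L_low)/2} above
#' (for \code{nu = 1}), so the asymptote separation sets the total
#' correction range.
#'
#' @param x tile mean intensity (vectorized).
#' @param x0 inflection point (background mean).
#' @param k growth rate per intensity unit (> 0).
#' @param asym_low,asym_high lower/upper horizontal asymptotes.
#' @param offset additive offset of the fit.
#' @param nu shape exponent (default 1).
#' @return Correction values, same length as \code{x}.
#' @export
logistic_correction <- function(x, x0, k, asym_low, asym_high, offset = 0,
                                nu = 1) {
  stopifnot(k > 0, is.finite(asym_low), is.finite(asym_high))
  raw <- function(z)
    asym_low + (asym_high - asym_low) / (1 + exp(-k * (z - x0)))^(1 / nu) +
      offset
  raw(x) - raw(x0)
}

#' AdaMM logistic parameters
#'
#' Default asymptotes are \code{+/- asym_sd_factor * clean_sd} of the fitted
#' background model, so the local threshold never moves by more than half a
#' background standard deviation by default.
#'
#' @param k growth rate per intensity unit.
#' @param asym_sd_factor asymptote magnitude in units of the background sd
#'   (used when \code{asym_low}/\code{asym_high} are NA).
#' @param asym_low,asym_high explicit asymptotes (intensity units).
#' @param offset additive offset.
#' @param nu shape exponent.
#' @return Parameter list.
#' @export
logistic_params <- function(k = 0.1, asym_sd_factor = 0.5,
                            asym_low = NA_real_, asym_high = NA_real_,
                            offset = 0, nu = 1) {
  list(k = k, asym_sd_factor = asym_sd_factor, asym_low = asym_low,
       asym_high = asym_high, offset = offset, nu = nu)
}

resolve_asymptotes <- function(logistic, model) {
  lo <- logistic$asym_low; hi <- logistic$asym_high
  if (is.na(lo)) lo <- -logistic$asym_sd_factor * model$clean_sd
  if (is.na(hi)) hi <- logistic$asym_sd_factor * model$clean_sd
  list(lo = lo, hi = hi)
}

#' Adaptive tile-wise segmentation (AdaMM)
#'
#' The image is partitioned into \code{tile_size} x \code{tile_size} tiles
#' (edge tiles may be smaller). Empty tiles (no nonzero pixel after
#' preprocessing) are removed: they binarize to all-background. Each occupied
#' tile is thresholded at \code{global_threshold + correction(tile mean)}
#' with the generalized logistic correction inflected at the background
#' mean, then the tiles are reassembled into one mask.
#'
#' @param mito (preprocessed) intensity matrix.
#' @param model a \code{background_model}.
#' @param tile_size tile side length, px (>= 8); a tile size exceeding the
#'   image degenerates to global thresholding.
#' @param logistic list from \code{\link{logistic_params}}.
#' @return Logical mask with attribute \code{"tiles"}: a data.frame of tile
#'   bounds, means, occupancy and local thresholds.
#' @export
adamm_segment <- function(mito, model, tile_size = 32,
                          logistic = logistic_params()) {
  stopifnot(tile_size >= 8)
  nr <- nrow(mito); nc <- ncol(mito)
  if (tile_size >= nr && tile_size >= nc) {
    # single-tile degenerate case: the whole image is one tile whose mean
    # carries no local information, so fall back to the global threshold
    out <- binarize_global(mito, model)
    attr(out, "tiles") <- data.frame(
      row0 = 1, row1 = nr, col0 = 1, col1 = nc, mean = mean(mito),
      occupied = any(mito > 0), threshold = model$global_threshold)
    return(out)
  }
  asym <- resolve_asymptotes(logistic, model)
  r_starts <- seq(1, nr, by = tile_size)
  c_starts <- seq(1, nc, by = tile_size)
  out <- matrix(FALSE, nr, nc)
  tiles <- list()
  for (r0 in r_starts) for (c0 in c_starts) {
    r1 <- min(r0 + tile_size - 1, nr); c1 <- min(c0 + tile_size - 1, nc)
    tl <- mito[r0:r1, c0:c1]
    occupied <- any(tl > 0)
    mu <- mean(tl)
    thr <- NA_real_
    if (occupied) {
      corr <- logistic_correction(mu, x0 = model$clean_mean, k = logistic$k,
                                  asym_low = asym$lo, asym_high = asym$hi,
                                  offset = logistic$offset, nu = logistic$nu)
      thr <- model$global_threshold + corr
      out[r0:r1, c0:c1] <- tl > thr
    }
    tiles[[length(tiles) + 1]] <- data.frame(
      row0 = r0, row1 = r1, col0 = c0, col1 = c1,
      mean = mu, occupied = occupied, threshold = thr)
  }
  attr(out, "tiles") <- do.call(rbind, tiles)
  out
}

#' Mito Catcher configuration
#'
#' @param preprocess list from \code{\link{preprocess_params}}.
#' @param adamm enable adaptive tile-wise threshold correction.
#' @param tile_size AdaMM tile side, px.
#' @param logistic list from \code{\link{logistic_params}}.
#' @param nuclear nucleus segmentation parameters
#'   (\code{\link{nuclear_params}}) used to locate the background zone.
#' @param manual_threshold optional fixed threshold overriding the background
#'   model (for images without a detectable nucleus).
#' @param min_object_area connected components smaller than this are removed
#'   from the final mask (residual noise), px.
#' @return Configuration list.
#' @export
mito_catcher_config <- function(preprocess = preprocess_params(),
                                adamm = TRUE, tile_size = 32,
                                logistic = logistic_params(),
                                nuclear = nuclear_params(),
                                manual_threshold = NA_real_,
                                min_object_area = 4) {
  list(preprocess = preprocess, adamm = adamm, tile_size = tile_size,
       logistic = logistic, nuclear = nuclear,
       manual_threshold = manual_threshold,
       min_object_area = min_object_area)
}

#' Segment the mitochondrial network of a single-cell image
#'
#' Full chain: preprocess, fit the nuclear-zone background, binarize
#' (adaptive tile-wise correction if enabled, else global threshold), remove
#' sub-minimum components, and exclude the nucleus interior from the network
#' mask (no in-plane mitochondria within the nucleus).
#'
#' @param img a \code{\link{fluor_image}} of a single cell.
#' @param config list from \code{\link{mito_catcher_config}}.
#' @param nucleus_mask optional logical matrix; when missing, the nucleus is
#'   segmented from the blue channel.
#' @return List: \code{mask} (logical network mask), \code{overlay} (RGB
#'   array: mask over the original mito channel), \code{model}
#'   (\code{background_model} or NULL under a manual threshold),
#'   \code{preprocessed}.
#' @export
segment_cell <- function(img, config = mito_catcher_config(),
                         nucleus_mask = NULL) {
  ch <- split_channels(img)
  pre <- tryCatch(preprocess_mito(ch$mito, config$preprocess),
                  error = function(e) stop("preprocess: ",
                                           conditionMessage(e)))
  if (is.null(nucleus_mask)) {
    labs <- process_nuclear_channel(ch$nuclei, config$nuclear)
    nucleus_mask <- labs > 0
  }
  model <- NULL
  if (is.na(config$manual_threshold)) {
    if (!any(nucleus_mask))
      stop("fit_background: no detectable nucleus; supply manual_threshold")
    model <- tryCatch(fit_background(pre, nucleus_mask),
                      error = function(e) stop("fit_background: ",
                                               conditionMessage(e)))
  } else {
    model <- structure(list(q1 = NA, q3 = NA, iqr = NA,
                            clean_mean = config$manual_threshold / 2,
                            clean_sd = 0,
                            global_threshold = config$manual_threshold,
                            n_inliers = 0, n_total = 0),
                       class = "background_model")
  }
  mask <- if (isTRUE(config$adamm))
    adamm_segment(pre, model, tile_size = config$tile_size,
                  logistic = config$logistic)
  else binarize_global(pre, model)
  tiles <- attr(mask, "tiles")
  mask[nucleus_mask] <- FALSE
  if (config$min_object_area > 1)
    mask <- label_components(mask, min_area = config$min_object_area) > 0
  overlay <- array(0, c(nrow(mask), ncol(mask), 3))
  overlay[, , channel_index(img$mito_channel)] <- ch$mito
  overlay[, , 3][nucleus_mask] <- 255
  ovl1 <- overlay[, , 1]; ovl1[mask] <- 255
  overlay[, , 1] <- ovl1
  list(mask = mask, overlay = overlay, model = model, preprocessed = pre,
       tiles = tiles, nucleus_mask = nucleus_mask)
}
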