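# Cell Catcher: separate a multi-cell image into single cells. Nuclei are
# segmented from the blue channel and used as seeds; the mitochondrial
# background is estimated under the nuclei (no in-plane mitochondria inside
# the nucleus); ghost cells (nucleus without mitochondrial signal) are
# dropped; every above-background mitochondrial blob is linked to a nucleus
# by expectation-maximization over 2D Gaussian seed distributions; outlier
# linkages are pruned by Mahalanobis distance; cells truncated by the frame
# are flagged and exported separately.

#' Nuclear-channel processing parameters
#'
#' @param tophat_radius structuring-element radius of the white top-hat
#'   (illumination flattening), px.
#' @param blur_sigma Gaussian blur sigma, px.
#' @param open_radius,close_radius radii of the morphological opening and
#'   closing applied to the binary nuclei mask, px.
#' @param min_area minimum nucleus area, px (size filter for non-specific
#'   staining).
#' @return Parameter list.
#' @export
nuclear_params <- function(tophat_radius = 15, blur_sigma = 2,
                           open_radius = 2, close_radius = 2, min_area = 40) {
  list(tophat_radius = tophat_radius, blur_sigma = blur_sigma,
       open_radius = open_radius, close_radius = close_radius,
       min_area = min_area)
}

# Otsu threshold restricted to a vector of (non-zero) 8-bit intensities
otsu_nonzero <- function(x, levels = 256L) {
  x <- as.integer(round(x))
  h <- tabulate(x + 1L, nbins = levels)
  n <- sum(h)
  if (n == 0) return(0)
  lev <- 0:(levels - 1L)
  w0 <- cumsum(h); w1 <- n - w0
  mu <- cumsum(h * lev)
  mu0 <- mu / pmax(w0, 1); mu1 <- (mu[levels] - mu) / pmax(w1, 1)
  between <- w0 * w1 * (mu0 - mu1)^2
  between[w0 == 0 | w1 == 0] <- -Inf
  lev[which.max(between)]
}

#' Segment nuclei from the nuclear (blue) channel
#'
#' Fixed pipeline: white top-hat, Gaussian blur, dynamic threshold (Otsu's
#' criterion over the non-zero pixel intensities), morphological opening then
#' closing, contour fill, size filter. Returns an 8-connected labeled mask;
#' zero surviving nuclei yields an empty mask, not an error.
#'
#' @param nuclei numeric matrix, 8-bit intensities.
#' @param params list from \code{\link{nuclear_params}}.
#' @return Integer label matrix.
#' @export
process_nuclear_channel <- function(nuclei, params = nuclear_params()) {
  x <- nuclei / 255
  if (params$tophat_radius > 0)
    x <- EBImage::whiteTopHat(x, disc_brush(params$tophat_radius))
  if (params$blur_sigma > 0)
    x <- EBImage::gblur(x, sigma = params$blur_sigma)
  x <- pmin(pmax(as.matrix(x), 0), 1) * 255
  nz <- x[x > 0]
  if (length(nz) == 0) return(matrix(0L, nrow(nuclei), ncol(nuclei)))
  thr <- otsu_nonzero(nz)
  bw <- x > thr
  if (params$open_radius > 0)
    bw <- EBImage::opening(bw * 1, disc_brush(params$open_radius)) > 0
  if (params$close_radius > 0)
    bw <- EBImage::closing(bw * 1, disc_brush(params$close_radius)) > 0
  bw <- EBImage::fillHull(bw * 1) > 0
  label_components(bw, min_area = params$min_area)
}

#' Mitochondrial background from the nuclear zone (multi-cell stage)
#'
#' Mean and population standard deviation of the mitochondrial intensities
#' under the nuclei mask; the global removal threshold is
#' \code{mean + 2 * sd} (95\% probability that a brighter pixel is signal),
#' clipped to \code{[0, 255]}.
#'
#' @param mito mitochondrial intensity matrix.
#' @param nuclei_mask logical matrix (union of nucleus interiors).
#' @return List \code{mean}, \code{sd}, \code{threshold}.
#' @export
estimate_mito_background <- function(mito, nuclei_mask) {
  stopifnot(all(dim(mito) == dim(nuclei_mask)))
  v <- mito[nuclei_mask]
  if (length(v) == 0)
    stop("empty nuclei mask: supply synthetic nuclei or a manual threshold")
  m <- mean(v); s <- pop_sd(v)
  list(mean = m, sd = s, threshold = min(max(m + 2 * s, 0), 255))
}

#' Globally remove background from the mitochondrial channel
#'
#' Pixels at or below the threshold are zeroed; brighter pixels keep their
#' original intensity.
#'
#' @param mito intensity matrix.
#' @param threshold scalar in \code{[0, 255]}.
#' @return Intensity matrix.
#' @export
global_background_removal <- function(mito, threshold) {
  stopifnot(threshold >= 0, threshold <= 255)
  mito[mito <= threshold] <- 0
  mito
}

#' Detect ghost cells (nuclei without mitochondrial signal)
#'
#' A nucleus is a ghost iff the summed background-cleaned mitochondrial
#' intensity within \code{radius} of its mask (morphological dilation) is
#' below \code{min_content}.
#'
#' @param nuclei_labels integer nucleus label matrix.
#' @param cleaned_mito background-removed mitochondrial intensities.
#' @param radius neighborhood radius, px.
#' @param min_content minimum summed intensity for a stained cell.
#' @return Integer vector of ghost labels.
#' @export
detect_ghost_cells <- function(nuclei_labels, cleaned_mito, radius = 30,
                               min_content = 5000) {
  stopifnot(radius > 0, min_content >= 0)
  labs <- setdiff(sort(unique(as.vector(nuclei_labels))), 0L)
  ghosts <- integer(0)
  for (l in labs) {
    zone <- dilate_mask(nuclei_labels == l, radius)
    if (sum(cleaned_mito[zone]) < min_content) ghosts <- c(ghosts, l)
  }
  ghosts
}

# ---------------------------------------------------------------------------
# Blobs and groups

# linear indices of the 8-neighbourhood of a pixel index set (clipped, unique)
neighbor_indices <- function(idx, nr, nc) {
  r <- (idx - 1L) %% nr + 1L
  cc <- (idx - 1L) %/% nr + 1L
  out <- integer(0)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    rr <- r + dr; ccn <- cc + dc
    ok <- rr >= 1L & rr <= nr & ccn >= 1L & ccn <= nc
    out <- c(out, (ccn[ok] - 1L) * nr + rr[ok])
  }
  unique(out)
}

#' Extract mitochondrial blobs from a background-cleaned channel
#'
#' Every 8-connected component of positive intensity is one blob.
#'
#' @param cleaned_mito background-removed intensity matrix.
#' @param min_area blobs below this size are discarded as residual noise.
#' @return List of blobs: \code{pixels} (linear indices), \code{centroid}
#'   (row, col), \code{area}, \code{total_intensity}.
#' @export
extract_blobs <- function(cleaned_mito, min_area = 1) {
  labs <- label_components(cleaned_mito > 0, min_area = min_area)
  nr <- nrow(cleaned_mito)
  sets <- label_pixel_sets(labs)
  lapply(sets, function(px) {
    list(pixels = px, centroid = pixel_centroid(px, nr),
         area = length(px), total_intensity = sum(cleaned_mito[px]))
  })
}

#' Classify blobs into linking groups
#'
#' Group 1: small blobs (area below \code{small_area_cutoff}) in direct
#' contact (8-adjacency) with exactly one nucleus. Group 2: blobs touching at
#' least one nucleus that are either large or touch several nuclei. Group 3:
#' free-floating blobs touching no nucleus. The three groups are mutually
#' exclusive and collectively exhaustive.
#'
#' @param blobs list from \code{\link{extract_blobs}}.
#' @param nuclei_labels nucleus label matrix (ghosts already removed).
#' @param small_area_cutoff area cutoff for group 1, px.
#' @return The blob list with \code{$group} (1, 2 or 3) and
#'   \code{$touched} (integer vector of touched nucleus labels) set.
#' @export
classify_mito_groups <- function(blobs, nuclei_labels, small_area_cutoff = 50) {
  nr <- nrow(nuclei_labels); nc <- ncol(nuclei_labels)
  lapply(blobs, function(b) {
    nb <- c(b$pixels, neighbor_indices(b$pixels, nr, nc))
    touched <- setdiff(unique(nuclei_labels[nb]), 0L)
    b$touched <- sort(touched)
    b$group <- if (length(touched) == 0) 3L
      else if (length(touched) == 1 && b$area < small_area_cutoff) 1L
      else 2L
    b
  })
}

# ---------------------------------------------------------------------------
# Seeds and EM

seed_from_pixels <- function(idx, nr, eps = 1.0) {
  r <- (idx - 1) %% nr + 1
  cc <- (idx - 1) %/% nr + 1
  mu <- c(mean(r), mean(cc))
  n <- length(idx)
  S <- matrix(c(mean((r - mu[1])^2), mean((r - mu[1]) * (cc - mu[2])),
                mean((r - mu[1]) * (cc - mu[2])), mean((cc - mu[2])^2)), 2, 2)
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-6) S <- S + diag(eps, 2)
  list(mean = mu, cov = S)
}

# log N(x; mu, S) for an n x 2 coordinate matrix
gauss_loglik <- function(xy, seed) {
  S <- seed$cov
  det_s <- S[1, 1] * S[2, 2] - S[1, 2] * S[2, 1]
  inv <- matrix(c(S[2, 2], -S[1, 2], -S[2, 1], S[1, 1]), 2, 2) / det_s
  d <- sweep(xy, 2, seed$mean)
  q <- inv[1, 1] * d[, 1]^2 + 2 * inv[1, 2] * d[, 1] * d[, 2] +
    inv[2, 2] * d[, 2]^2
  -log(2 * pi) - 0.5 * log(det_s) - 0.5 * q
}

idx_to_xy <- function(idx, nr) {
  cbind((idx - 1) %% nr + 1, (idx - 1) %/% nr + 1)
}

#' Link mitochondrial blobs to nucleus seeds by expectation-maximization
#'
#' Nuclei initialize 2D Gaussian seed distributions (mean and covariance of
#' owned pixel coordinates). Round A adds group 1 blobs wholesale to the
#' nucleus they touch. Round B assigns group 2 blobs pixel by pixel to the
#' seed of maximum Gaussian log-likelihood. Round C assigns each remaining
#' free blob wholesale by maximum average per-pixel log-likelihood; blobs
#' whose best average log-likelihood falls below \code{loglik_floor} are left
#' unassigned (mitochondria of off-frame cells). Seeds are re-estimated after
#' every round and round C repeats until no new assignments occur. Likelihood
#' ties break toward the lower nucleus label.
#'
#' @param blobs classified blob list (\code{\link{classify_mito_groups}}).
#' @param nuclei_labels nucleus label matrix (ghosts removed).
#' @param loglik_floor average log-likelihood floor for free-blob assignment.
#' @param cov_eps covariance regularization added when a seed is degenerate.
#' @return List: \code{assignment} (integer matrix over mito pixels, 0 =
#'   unassigned), \code{blob_table} (data.frame: blob, group, assigned label
#'   or NA, centroid), \code{seeds} (final seed list indexed by label).
#' @export
em_link_mitochondria <- function(blobs, nuclei_labels, loglik_floor = -50,
                                 cov_eps = 1.0) {
  nr <- nrow(nuclei_labels); nc <- ncol(nuclei_labels)
  labs <- setdiff(sort(unique(as.vector(nuclei_labels))), 0L)
  if (length(labs) == 0) stop("no seeds: all nuclei removed")
  owned <- lapply(labs, function(l) which(nuclei_labels == l))
  names(owned) <- labs
  seeds <- lapply(owned, seed_from_pixels, nr = nr, eps = cov_eps)
  assignment <- matrix(0L, nr, nc)
  n_blobs <- length(blobs)
  blob_assigned <- rep(NA_integer_, n_blobs)
  groups <- vapply(blobs, `[[`, integer(1), "group")

  update_seeds <- function() {
    seeds <<- lapply(owned, seed_from_pixels, nr = nr, eps = cov_eps)
  }
  add_pixels <- function(lab, px) {
    owned[[as.character(lab)]] <<- c(owned[[as.character(lab)]], px)
    assignment[px] <<- lab
  }

  # Round A: small touching blobs, wholesale
  for (i in which(groups == 1L)) {
    lab <- blobs[[i]]$touched[1]
    add_pixels(lab, blobs[[i]]$pixels)
    blob_assigned[i] <- lab
  }
  update_seeds()

  # Round B: multi-contact blobs, pixel by pixel
  b2 <- which(groups == 2L)
  if (length(b2)) {
    for (i in b2) {
      px <- blobs[[i]]$pixels
      xy <- idx_to_xy(px, nr)
      ll <- vapply(seeds, function(s) gauss_loglik(xy, s),
                   numeric(length(px)))
      if (length(px) == 1) ll <- matrix(ll, nrow = 1)
      pick <- max.col(ll, ties.method = "first")  # lower label on ties
      for (k in seq_along(labs)) {
        sel <- pick == k
        if (any(sel)) add_pixels(labs[k], px[sel])
      }
      # record the dominant owner for the blob table
      blob_assigned[i] <- labs[which.max(tabulate(pick, length(labs)))]
    }
    update_seeds()
  }

  # Round C: free blobs by average likelihood, repeated until stable
  repeat {
    pending <- which(groups == 3L & is.na(blob_assigned))
    if (!length(pending)) break
    newly <- 0L
    for (i in pending) {
      px <- blobs[[i]]$pixels
      xy <- idx_to_xy(px, nr)
      avg <- vapply(seeds, function(s) mean(gauss_loglik(xy, s)), numeric(1))
      best <- which.max(avg)
      if (avg[best] < loglik_floor) next
      add_pixels(labs[best], px)
      blob_assigned[i] <- labs[best]
      newly <- newly + 1L
    }
    if (newly == 0L) break
    update_seeds()
  }

  cent <- t(vapply(blobs, `[[`, numeric(2), "centroid"))
  blob_table <- data.frame(
    blob = seq_len(n_blobs), group = groups,
    assigned = blob_assigned,
    centroid_row = cent[, 1], centroid_col = cent[, 2])
  list(assignment = assignment, blob_table = blob_table, seeds = seeds)
}

# ---------------------------------------------------------------------------
# Linking validation

#' Squared Mahalanobis distances of 2D points to their own distribution
#'
#' Mean and population covariance are estimated from the points themselves;
#' a degenerate covariance (smaller eigenvalue below 1e-6) is regularized by
#' adding \code{eps} to the diagonal.
#'
#' @param xy n x 2 matrix of (row, col) centroids.
#' @param eps covariance regularization, px^2.
#' @return Numeric vector of squared distances (NA if the covariance stays
#'   rank-deficient after regularization).
#' @export
mahalanobis_sq <- function(xy, eps = 1.0) {
  xy <- as.matrix(xy)
  mu <- colMeans(xy)
  d <- sweep(xy, 2, mu)
  S <- crossprod(d) / nrow(xy)
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-6) S <- S + diag(eps, 2)
  det_s <- S[1, 1] * S[2, 2] - S[1, 2]^2
  if (det_s <= 0) return(rep(NA_real_, nrow(xy)))
  inv <- matrix(c(S[2, 2], -S[1, 2], -S[1, 2], S[1, 1]), 2, 2) / det_s
  inv[1, 1] * d[, 1]^2 + 2 * inv[1, 2] * d[, 1] * d[, 2] + inv[2, 2] * d[, 2]^2
}

#' Prune outlier mitochondria of one cell by Mahalanobis distance
#'
#' Uses the 2D distribution of the mitochondrion centroids within the cell;
#' blobs whose squared distance exceeds the chi-square(df = 2, p = 0.05)
#' cutoff 5.99 are dropped, in a single pass. Cells with fewer than three
#' mitochondria are left untouched.
#'
#' @param centroids n x 2 matrix of blob centroids (row, col).
#' @param cutoff squared-distance threshold (default
#'   \code{qchisq(0.95, 2)} rounded to 5.99).
#' @param eps covariance regularization, px^2.
#' @return List: \code{keep} (logical), \code{d2} (squared distances, NA when
#'   pruning was skipped).
#' @export
mahalanobis_prune <- function(centroids, cutoff = 5.99, eps = 1.0) {
  centroids <- as.matrix(centroids)
  n <- nrow(centroids)
  if (n < 3)
    return(list(keep = rep(TRUE, n), d2 = rep(NA_real_, n)))
  d2 <- mahalanobis_sq(centroids, eps = eps)
  if (anyNA(d2))  # degenerate even after regularization: skip pruning
    return(list(keep = rep(TRUE, n), d2 = d2))
  list(keep = d2 <= cutoff, d2 = d2)
}

#' Flag cells truncated by the frame border
#'
#' The cell's combined nucleus-plus-mitochondria bounding box is symmetrized
#' about the cell's center (the nucleus centroid when supplied, else the
#' pixel centroid): the half-extent per axis is the larger of the two
#' center-to-edge distances, so the visible extent is reflected to estimate
#' the part of a truncated cell lying outside the frame. The flag is raised
#' iff the fraction of that box clipped off by the frame exceeds
#' \code{max_edge_fraction}; a cell cut in half by the border loses about
#' half of its symmetrized box.
#'
#' @param pixel_idx linear indices of the cell's nucleus and mitochondria.
#' @param dims image dimensions \code{c(nrow, ncol)}.
#' @param max_edge_fraction tolerated clipped fraction, in \code{(0, 1]}.
#' @param center optional (row, col) anchor, typically the nucleus centroid.
#' @return Logical.
#' @export
flag_edge_cell <- function(pixel_idx, dims, max_edge_fraction = 0.2,
                           center = NULL) {
  stopifnot(max_edge_fraction > 0, max_edge_fraction <= 1)
  nr <- dims[1]; nc <- dims[2]
  r <- (pixel_idx - 1) %% nr + 1
  cc <- (pixel_idx - 1) %/% nr + 1
  ctr <- if (is.null(center)) c(mean(r), mean(cc)) else center
  hr <- max(ctr[1] - min(r), max(r) - ctr[1]) + 0.5
  hc <- max(ctr[2] - min(cc), max(cc) - ctr[2]) + 0.5
  full <- (2 * hr) * (2 * hc)
  vis_r <- min(ctr[1] + hr, nr + 0.5) - max(ctr[1] - hr, 0.5)
  vis_c <- min(ctr[2] + hc, nc + 0.5) - max(ctr[2] - hc, 0.5)
  clipped <- 1 - (max(vis_r, 0) * max(vis_c, 0)) / full
  clipped > max_edge_fraction
}

# ---------------------------------------------------------------------------
# Orchestrator and export

#' Cell Catcher parameters
#'
#' @param nuclear nuclear-channel processing parameters
#'   (\code{\link{nuclear_params}}).
#' @param ghost_radius neighborhood radius for ghost detection, px.
#' @param ghost_min_content minimum mitochondrial content of a stained cell,
#'   summed 8-bit intensity.
#' @param small_area_cutoff group-1 blob area cutoff, px.
#' @param loglik_floor free-blob average log-likelihood floor.
#' @param mahalanobis_cutoff squared-distance pruning threshold.
#' @param max_edge_fraction tolerated clipped fraction of the symmetrized
#'   cell bounding box.
#' @param blob_min_area minimum blob size kept after background removal, px.
#' @return Parameter list.
#' @export
cell_catcher_params <- function(nuclear = nuclear_params(),
                                ghost_radius = 30, ghost_min_content = 5000,
                                small_area_cutoff = 50, loglik_floor = -50,
                                mahalanobis_cutoff = 5.99,
                                max_edge_fraction = 0.2, blob_min_area = 2) {
  list(nuclear = nuclear, ghost_radius = ghost_radius,
       ghost_min_content = ghost_min_content,
       small_area_cutoff = small_area_cutoff, loglik_floor = loglik_floor,
       mahalanobis_cutoff = mahalanobis_cutoff,
       max_edge_fraction = max_edge_fraction, blob_min_area = blob_min_area)
}

#' Separate a multi-cell image into single cells
#'
#' Full Cell Catcher chain: nucleus segmentation, background estimation under
#' the nuclei, global background removal, ghost-cell removal, blob grouping,
#' EM linking, Mahalanobis pruning and edge flagging.
#'
#' @param img a \code{\link{fluor_image}}.
#' @param params list from \code{\link{cell_catcher_params}}.
#' @return List: \code{cells} (per retained nucleus: label, nucleus pixel
#'   indices, mito pixel indices, \code{is_bad_edge_cell}), \code{ghosts}
#'   (labels), \code{nuclei_labels}, \code{assignment} (pixel owner matrix),
#'   \code{blob_table} (blob, group, assigned, Mahalanobis d2, pruned),
#'   \code{background} (mean/sd/threshold), \code{log} (named counts).
#' @export
catch_cells <- function(img, params = cell_catcher_params()) {
  ch <- split_channels(img)
  nuclei_labels <- process_nuclear_channel(ch$nuclei, params$nuclear)
  if (max(nuclei_labels) == 0)
    stop("no nuclei detected; cannot seed cell separation")
  bg <- estimate_mito_background(ch$mito, nuclei_labels > 0)
  cleaned <- global_background_removal(ch$mito, bg$threshold)
  ghosts <- detect_ghost_cells(nuclei_labels, cleaned,
                               radius = params$ghost_radius,
                               min_content = params$ghost_min_content)
  seeds_labels <- nuclei_labels
  seeds_labels[seeds_labels %in% ghosts] <- 0L
  if (max(seeds_labels) == 0)
    stop("all nuclei are ghosts; nothing to link")
  blobs <- extract_blobs(cleaned, min_area = params$blob_min_area)
  blobs <- classify_mito_groups(blobs, seeds_labels,
                                small_area_cutoff = params$small_area_cutoff)
  em <- em_link_mitochondria(blobs, seeds_labels,
                             loglik_floor = params$loglik_floor)
  nr <- nrow(seeds_labels)
  labs <- setdiff(sort(unique(as.vector(seeds_labels))), 0L)

  # per-cell mitochondrion centroids: wholesale blobs contribute their own
  # centroid; pixel-split (group 2) blobs contribute one fragment per cell
  frag <- vector("list", length(labs)); names(frag) <- labs
  bt <- em$blob_table
  bt$d2 <- NA_real_; bt$pruned <- FALSE
  for (i in seq_len(nrow(bt))) {
    if (is.na(bt$assigned[i])) next
    if (bt$group[i] == 2L) {
      px <- blobs[[i]]$pixels
      for (l in unique(em$assignment[px])) {
        if (l == 0) next
        sub <- px[em$assignment[px] == l]
        frag[[as.character(l)]] <- rbind(
          frag[[as.character(l)]],
          cbind(i, pixel_centroid(sub, nr)[1], pixel_centroid(sub, nr)[2]))
      }
    } else {
      l <- bt$assigned[i]
      frag[[as.character(l)]] <- rbind(
        frag[[as.character(l)]],
        cbind(i, bt$centroid_row[i], bt$centroid_col[i]))
    }
  }

  assignment <- em$assignment
  cells <- list()
  for (l in labs) {
    fr <- frag[[as.character(l)]]
    mito_px <- which(assignment == l)
    if (!is.null(fr) && nrow(fr) >= 3) {
      pr <- mahalanobis_prune(fr[, 2:3, drop = FALSE],
                              cutoff = params$mahalanobis_cutoff)
      wholesale <- fr[, 1][bt$group[fr[, 1]] != 2L]
      for (k in which(!pr$keep)) {
        bi <- fr[k, 1]
        if (bt$group[bi] != 2L) {
          bt$pruned[bi] <- TRUE
          assignment[blobs[[bi]]$pixels] <- 0L
        } else {
          sub <- blobs[[bi]]$pixels
          assignment[sub[assignment[sub] == l]] <- 0L
        }
      }
      keep_rows <- which(pr$keep)
      for (k in seq_len(nrow(fr)))
        if (bt$group[fr[k, 1]] != 2L) bt$d2[fr[k, 1]] <- pr$d2[k]
      mito_px <- which(assignment == l)
    }
    nuc_px <- which(nuclei_labels == l)
    cell_px <- c(nuc_px, mito_px)
    cells[[as.character(l)]] <- list(
      label = l, nucleus = nuc_px, mito = mito_px,
      is_bad_edge_cell = flag_edge_cell(
        cell_px, dim(assignment), params$max_edge_fraction,
        center = pixel_centroid(nuc_px, nrow(assignment))))
  }
  n_bad <- sum(vapply(cells, `[[`, logical(1), "is_bad_edge_cell"))
  list(cells = cells, ghosts = ghosts, nuclei_labels = nuclei_labels,
       assignment = assignment, blob_table = bt, background = bg,
       log = c(nuclei_found = max(nuclei_labels), ghosts = length(ghosts),
               cells = length(cells), bad_edge_cells = n_bad,
               blobs = nrow(bt),
               blobs_assigned = sum(!is.na(bt$assigned) & !bt$pruned)))
}

#' Export per-cell RGB crops
#'
#' One RGB PNG per cell containing only that cell's nucleus (blue) and its
#' assigned mitochondrial pixels (mito channel); all other pixels are zeroed.
#' Edge-flagged cells go to \code{outdir/excluded} and remain available to
#' the user. An assignment report CSV is written alongside.
#'
#' @param img the source \code{\link{fluor_image}}.
#' @param result output of \code{\link{catch_cells}}.
#' @param outdir output directory (created if needed).
#' @param pad crop padding, px.
#' @return Character vector of written crop paths (invisibly).
#' @export
export_single_cells <- function(img, result, outdir, pad = 10) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(outdir, "excluded"), showWarnings = FALSE)
  ch <- split_channels(img)
  nr <- img$height; nc <- img$width
  paths <- character(0)
  for (cell in result$cells) {
    px <- c(cell$nucleus, cell$mito)
    if (!length(px)) next
    r <- (px - 1) %% nr + 1; cc <- (px - 1) %/% nr + 1
    r0 <- max(1, min(r) - pad); r1 <- min(nr, max(r) + pad)
    c0 <- max(1, min(cc) - pad); c1 <- min(nc, max(cc) + pad)
    nup <- matrix(0, nr, nc); nup[cell$nucleus] <- ch$nuclei[cell$nucleus]
    mip <- matrix(0, nr, nc); mip[cell$mito] <- ch$mito[cell$mito]
    crop <- merge_channels(nup[r0:r1, c0:c1], mip[r0:r1, c0:c1],
                           img$mito_channel)
    sub <- if (cell$is_bad_edge_cell) file.path(outdir, "excluded") else outdir
    path <- file.path(sub, sprintf("cell_%03d.png", cell$label))
    tryCatch(write_image(crop, path),
             error = function(e) stop("failed to write crop for cell ",
                                      cell$label, ": ", conditionMessage(e)))
    paths <- c(paths, path)
  }
  write_table(result$blob_table, file.path(outdir, "assignment_report.csv"),
              "csv", allow_na = TRUE)
  invisible(paths)
}
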