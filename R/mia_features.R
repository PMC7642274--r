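# MiA: morphometric feature extraction from binarized single-cell
# mitochondrial network masks. 31 features per mitochondrion (23 geometry +
# 8 branch aggregates from the thinned skeleton) and 110 per cell (90
# mean/median/sd aggregations of the 30 aggregatable per-mitochondrion
# features -- orientation, a circular quantity, is excluded -- plus 20
# population-level features of the whole network).

# -- feature schema (stable column order) ------------------------------------

MITO_GEOMETRY_FEATURES <- c(
  "area", "perimeter", "convex_area", "solidity",
  "bbox_width", "bbox_height", "bbox_area", "extent",
  "major_axis", "minor_axis", "aspect_ratio", "orientation",
  "equivalent_diameter", "eccentricity", "roundness", "form_factor",
  "compactness", "convex_perimeter", "convexity",
  "mean_density", "max_density", "centroid_row", "centroid_col")

MITO_BRANCH_FEATURES <- c(
  "branch_count", "junction_count", "endpoint_count",
  "total_branch_length", "mean_branch_length", "median_branch_length",
  "sd_branch_length", "max_branch_length")

#' Per-mitochondrion feature names (31: 23 geometry + 8 branch)
#' @return Character vector of column names in table order.
#' @export
mito_feature_names <- function() c(MITO_GEOMETRY_FEATURES,
                                   MITO_BRANCH_FEATURES)

CELL_POPULATION_FEATURES <- c(
  "mito_count", "net_area", "net_perimeter", "net_convex_area",
  "net_solidity", "net_bbox_area", "net_extent", "net_skeleton_length",
  "net_branch_count", "net_junction_count", "net_endpoint_count",
  "mean_nn_distance", "sd_nn_distance", "centroid_dispersion",
  "largest_area_fraction", "above_median_area_fraction",
  "fractal_dimension", "lacunarity", "net_major_axis", "net_aspect_ratio")

#' Per-cell feature names (110: 90 aggregations + 20 population)
#' @return Character vector of column names in table order.
#' @export
cell_feature_names <- function() {
  agg_base <- setdiff(mito_feature_names(), "orientation")
  c(as.vector(t(outer(agg_base, c("mean", "median", "sd"), paste,
                      sep = "_"))),
    CELL_POPULATION_FEATURES)
}

# -- labeling ----------------------------------------------------------------

#' Label individual mitochondria in a binary network mask
#'
#' 8-connected components; components below \code{min_area} pixels are
#' dropped (residual noise) and the rest renumbered 1..n.
#'
#' @param mask logical matrix.
#' @param min_area minimum component area, px.
#' @return Integer label matrix.
#' @export
label_mitochondria <- function(mask, min_area = 4) {
  label_components(mask != 0, min_area = min_area)
}

# -- skeletonization ---------------------------------------------------------

shift_mat <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0L, nr, nc)
  rs <- max(1, 1 - dr):min(nr, nr - dr)
  cs <- max(1, 1 - dc):min(nc, nc - dc)
  out[rs + dr, cs + dc] <- m[rs, cs]
  out
}

#' Topology-preserving thinning of a binary blob to a 1-px skeleton
#'
#' Iterative two-subiteration thinning (Zhang-Suen): the blob is eroded from
#' the outside until further erosion would break connectivity, leaving its
#' 1-pixel-wide wireframe. A blob whose pixels would all be removed (tiny
#' compact blobs) keeps its innermost pixel (distance-transform maximum), so
#' the component count is always preserved.
#'
#' @param mask logical matrix containing one (or more) blobs.
#' @return Logical skeleton matrix of the same dimensions.
#' @export
skeletonize <- function(mask) {
  m <- (mask != 0) * 1L
  if (!any(m == 1L)) return(mask & FALSE)
  repeat {
    changed <- FALSE
    for (phase in 1:2) {
      # neighbours P2..P9 clockwise from north (row-1)
      p2 <- shift_mat(m, -1, 0);  p3 <- shift_mat(m, -1, 1)
      p4 <- shift_mat(m, 0, 1);   p5 <- shift_mat(m, 1, 1)
      p6 <- shift_mat(m, 1, 0);   p7 <- shift_mat(m, 1, -1)
      p8 <- shift_mat(m, 0, -1);  p9 <- shift_mat(m, -1, -1)
      b <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      a <- (p2 == 0 & p3 == 1) + (p3 == 0 & p4 == 1) + (p4 == 0 & p5 == 1) +
        (p5 == 0 & p6 == 1) + (p6 == 0 & p7 == 1) + (p7 == 0 & p8 == 1) +
        (p8 == 0 & p9 == 1) + (p9 == 0 & p2 == 1)
      if (phase == 1)
        cond <- m == 1L & b >= 2 & b <= 6 & a == 1 &
          p2 * p4 * p6 == 0 & p4 * p6 * p8 == 0
      else
        cond <- m == 1L & b >= 2 & b <= 6 & a == 1 &
          p2 * p4 * p8 == 0 & p2 * p6 * p8 == 0
      if (any(cond)) {
        m[cond] <- 0L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  if (!any(m == 1L)) {
    # compact blob fully eroded: keep its innermost pixel
    pad <- matrix(0, nrow(mask) + 2, ncol(mask) + 2)
    pad[2:(nrow(mask) + 1), 2:(ncol(mask) + 1)] <- (mask != 0) * 1
    dm <- EBImage::distmap(pad)[2:(nrow(mask) + 1), 2:(ncol(mask) + 1)]
    m[which.max(dm)] <- 1L
  }
  m == 1L
}

# -- branch analysis ---------------------------------------------------------

# 8-adjacency graph of skeleton pixels with diagonal-shortcut pruning:
# a diagonal edge is dropped when the two pixels share an orthogonal
# skeleton neighbour (otherwise corners would create spurious triangles).
skeleton_graph <- function(skel) {
  nr <- nrow(skel); nc <- ncol(skel)
  idx <- which(skel)
  n <- length(idx)
  lookup <- matrix(0L, nr, nc); lookup[idx] <- seq_len(n)
  r <- (idx - 1L) %% nr + 1L; cc <- (idx - 1L) %/% nr + 1L
  from <- integer(0); to <- integer(0); w <- numeric(0)
  at <- function(rr, ccn) {
    ok <- rr >= 1L & rr <= nr & ccn >= 1L & ccn <= nc
    v <- integer(length(rr)); v[ok] <- lookup[cbind(rr[ok], ccn[ok])]
    v
  }
  # orthogonal edges (weight 1): to east and south
  for (o in list(c(0L, 1L), c(1L, 0L))) {
    nb <- at(r + o[1], cc + o[2])
    hit <- nb > 0L
    from <- c(from, which(hit)); to <- c(to, nb[hit])
    w <- c(w, rep(1, sum(hit)))
  }
  # diagonal edges (weight sqrt 2), pruned when an orthogonal shortcut exists
  for (o in list(c(1L, 1L), c(1L, -1L))) {
    nb <- at(r + o[1], cc + o[2])
    hit <- which(nb > 0L)
    if (length(hit)) {
      via1 <- at(r[hit] + o[1], cc[hit])      # shared vertical neighbour
      via2 <- at(r[hit], cc[hit] + o[2])      # shared horizontal neighbour
      keep <- via1 == 0L & via2 == 0L
      from <- c(from, hit[keep]); to <- c(to, nb[hit][keep])
      w <- c(w, rep(sqrt(2), sum(keep)))
    }
  }
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (length(from))
    g <- igraph::add_edges(g, rbind(from, to), weight = w)
  list(graph = g, idx = idx, nr = nr)
}

#' Skeleton branch, junction and endpoint statistics
#'
#' Endpoints are skeleton pixels with exactly one neighbour; junction pixels
#' have three or more (adjacent junction pixels are merged into one
#' junction). Branches are the wire segments between nodes (endpoints or
#' junctions); lengths count orthogonal steps as 1 and diagonal steps as
#' sqrt(2). A node-free cycle (ring) counts as one closed branch of the
#' cycle length. A single-pixel skeleton has no branches.
#'
#' @param skel logical skeleton matrix (one connected component expected,
#'   but any skeleton works).
#' @return List: \code{n_endpoints}, \code{n_junctions},
#'   \code{branch_lengths} (numeric vector), \code{total_length}.
#' @export
skeleton_branches <- function(skel) {
  sg <- skeleton_graph(skel)
  g <- sg$graph
  n <- length(sg$idx)
  if (n == 0)
    return(list(n_endpoints = 0L, n_junctions = 0L,
                branch_lengths = numeric(0), total_length = 0))
  deg <- igraph::degree(g)
  n_end <- sum(deg == 1)
  junction_v <- which(deg >= 3)
  n_junc <- if (length(junction_v)) {
    igraph::components(
      igraph::induced_subgraph(g, junction_v))$no
  } else 0L
  node_v <- which(deg != 2)
  lens <- numeric(0)
  ew <- igraph::E(g)$weight
  if (length(node_v) == 0) {
    # pure cycle (or isolated chain-free vertices)
    comp <- igraph::components(g)
    for (k in seq_len(comp$no)) {
      vs <- which(comp$membership == k)
      if (length(vs) < 2) next
      sub <- igraph::induced_subgraph(g, vs)
      lens <- c(lens, sum(igraph::E(sub)$weight))
    }
  } else {
    # branches with interior: components of degree-2 vertices, plus their
    # connections to adjacent nodes
    interior <- which(deg == 2)
    used_edge <- rep(FALSE, igraph::ecount(g))
    if (length(interior)) {
      sub <- igraph::induced_subgraph(g, interior)
      comp <- igraph::components(sub)
      for (k in seq_len(comp$no)) {
        vs_local <- which(comp$membership == k)
        vs <- interior[vs_local]
        inner_sub <- igraph::induced_subgraph(g, vs)
        len <- sum(igraph::E(inner_sub)$weight)
        # attach edges from chain ends to node vertices
        inc <- igraph::incident_edges(g, vs)
        for (es in inc) for (e in es) {
          ends <- igraph::ends(g, e)
          other <- setdiff(as.integer(ends), vs)
          if (length(other)) {
            if (!used_edge[as.integer(e)]) {
              len <- len + ew[as.integer(e)]
              used_edge[as.integer(e)] <- TRUE
            }
          }
        }
        lens <- c(lens, len)
      }
    }
    # direct node-node edges are branches of their own
    el <- igraph::as_edgelist(g, names = FALSE)
    direct <- which(el[, 1] %in% node_v & el[, 2] %in% node_v)
    lens <- c(lens, ew[direct])
  }
  list(n_endpoints = as.integer(n_end), n_junctions = as.integer(n_junc),
       branch_lengths = lens, total_length = sum(lens))
}

# -- geometry helpers --------------------------------------------------------

polygon_area <- function(x, y) {
  n <- length(x)
  abs(sum(x * y[c(2:n, 1)] - x[c(2:n, 1)] * y)) / 2
}

polygon_perimeter <- function(x, y) {
  n <- length(x)
  sum(sqrt(diff(c(x, x[1]))^2 + diff(c(y, y[1]))^2))
}

# chain-code perimeter from an ordered boundary (EBImage::ocontour);
# orthogonal steps count 1, diagonal steps sqrt(2)
chain_perimeter <- function(blob) {
  oc <- EBImage::ocontour(blob * 1)
  if (!length(oc)) return(0)
  sum(vapply(oc, function(pts) {
    if (nrow(pts) < 2) return(0)
    closed <- rbind(pts, pts[1, ])
    sum(sqrt(rowSums(diff(closed)^2)))
  }, numeric(1)))
}

# convex hull of the blob: perimeter of the hull polygon through pixel
# centers; area as the count of pixel centers inside that polygon (the
# rasterized-hull convention, so solidity of convex digital shapes is ~1)
hull_of_pixels <- function(r, cc) {
  h <- chull(cc, r)
  hx <- cc[h]; hy <- r[h]
  if (length(h) < 3) {
    # collinear blob: hull degenerates to the pixel set itself
    return(list(area = length(r),
                perimeter = 2 * max(polygon_perimeter(hx, hy) / 2, 1)))
  }
  # count grid points of the bounding box inside the convex polygon
  gr <- seq(min(r), max(r)); gc <- seq(min(cc), max(cc))
  py <- rep(gr, times = length(gc)); px <- rep(gc, each = length(gr))
  n <- length(hx)
  sa <- sum(hx * hy[c(2:n, 1)] - hx[c(2:n, 1)] * hy) / 2  # signed area
  sgn <- if (sa >= 0) 1 else -1
  inside <- rep(TRUE, length(px))
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    cross <- (hx[j] - hx[i]) * (py - hy[i]) - (hy[j] - hy[i]) * (px - hx[i])
    inside <- inside & sgn * cross >= -1e-9
  }
  list(area = sum(inside), perimeter = polygon_perimeter(hx, hy))
}

# second-moment ellipse of pixel coordinates (pixel quantization variance
# 1/12 added per axis so 1-px-wide shapes stay non-degenerate)
moment_ellipse <- function(r, cc) {
  mu <- c(mean(r), mean(cc))
  vr <- mean((r - mu[1])^2) + 1 / 12
  vc <- mean((cc - mu[2])^2) + 1 / 12
  vrc <- mean((r - mu[1]) * (cc - mu[2]))
  tr <- vr + vc; det_ <- vr * vc - vrc^2
  disc <- sqrt(max(tr^2 / 4 - det_, 0))
  l1 <- tr / 2 + disc; l2 <- max(tr / 2 - disc, 0)
  major <- 4 * sqrt(l1); minor <- 4 * sqrt(l2)
  # orientation: angle of the major axis w.r.t. the column (x) axis,
  # degrees in (-90, 90]
  ang <- 0.5 * atan2(2 * vrc, vc - vr) * 180 / pi
  if (ang <= -90) ang <- ang + 180
  if (ang > 90) ang <- ang - 180
  ecc <- if (l1 > 0) sqrt(max(1 - l2 / l1, 0)) else 0
  list(major = major, minor = minor, orientation = ang, eccentricity = ecc)
}

# Euclidean distance-to-boundary over blob pixels (crop padded so the frame
# border never counts as interior)
density_map <- function(blob) {
  pad <- matrix(0, nrow(blob) + 2, ncol(blob) + 2)
  pad[2:(nrow(blob) + 1), 2:(ncol(blob) + 1)] <- (blob != 0) * 1
  dm <- EBImage::distmap(pad)
  dm[2:(nrow(blob) + 1), 2:(ncol(blob) + 1)]
}

crop_blob <- function(px, dims, pad = 1L) {
  nr <- dims[1]
  r <- (px - 1L) %% nr + 1L; cc <- (px - 1L) %/% nr + 1L
  r0 <- min(r) - pad; c0 <- min(cc) - pad
  m <- matrix(FALSE, max(r) - min(r) + 1 + 2 * pad,
              max(cc) - min(cc) + 1 + 2 * pad)
  m[cbind(r - r0 + 1L, cc - c0 + 1L)] <- TRUE
  list(mask = m, r = r, cc = cc, r0 = r0, c0 = c0)
}

# -- per-mitochondrion features ---------------------------------------------

#' Morphometric features of one mitochondrion
#'
#' Computes the 31-feature row: 23 geometry features (areas in px^2, lengths
#' in px, orientation in degrees in (-90, 90], centroid in 0-based image
#' coordinates) and 8 aggregates of the branch lengths of the thinned
#' skeleton. Perimeters follow the chain-code convention (orthogonal step 1,
#' diagonal sqrt(2)); dimensionless shape factors (solidity, extent, form
#' factor, roundness) are bounded by 1. A single-pixel blob takes the
#' closed-form fallbacks: perimeter 4, major = minor = 1, orientation 0,
#' no branches.
#'
#' @param px linear pixel indices of the blob.
#' @param dims dimensions of the parent mask \code{c(nrow, ncol)}.
#' @return Named numeric vector of length 31 (\code{\link{mito_feature_names}}).
#' @export
mito_features <- function(px, dims) {
  nr <- dims[1]
  area <- length(px)
  cb <- crop_blob(px, dims)
  r <- cb$r; cc <- cb$cc
  bbox_h <- max(r) - min(r) + 1L; bbox_w <- max(cc) - min(cc) + 1L
  centroid <- c(mean(r), mean(cc))

  if (area == 1) {
    geo <- c(area = 1, perimeter = 4, convex_area = 1, solidity = 1,
             bbox_width = 1, bbox_height = 1, bbox_area = 1, extent = 1,
             major_axis = 1, minor_axis = 1, aspect_ratio = 1,
             orientation = 0, equivalent_diameter = 2 / sqrt(pi),
             eccentricity = 0, roundness = 1, form_factor = 1,
             compactness = 2 / sqrt(pi), convex_perimeter = 4, convexity = 1,
             mean_density = 1, max_density = 1,
             centroid_row = centroid[1] - 1, centroid_col = centroid[2] - 1)
    br <- c(branch_count = 0, junction_count = 0, endpoint_count = 0,
            total_branch_length = 0, mean_branch_length = 0,
            median_branch_length = 0, sd_branch_length = 0,
            max_branch_length = 0)
    return(c(geo, br))
  }

  per <- chain_perimeter(cb$mask)
  if (per <= 0) per <- 4  # degenerate contour (should not happen for area>1)
  hull <- hull_of_pixels(r, cc)
  ell <- moment_ellipse(r, cc)
  dm <- density_map(cb$mask)
  dens <- dm[cb$mask]

  eq_d <- 2 * sqrt(area / pi)
  geo <- c(
    area = area, perimeter = per,
    convex_area = hull$area, solidity = min(area / hull$area, 1),
    bbox_width = bbox_w, bbox_height = bbox_h,
    bbox_area = bbox_w * bbox_h, extent = area / (bbox_w * bbox_h),
    major_axis = ell$major, minor_axis = ell$minor,
    aspect_ratio = ell$major / ell$minor, orientation = ell$orientation,
    equivalent_diameter = eq_d, eccentricity = ell$eccentricity,
    roundness = min(4 * area / (pi * ell$major^2), 1),
    form_factor = min(4 * pi * area / per^2, 1),
    compactness = eq_d / ell$major,
    convex_perimeter = hull$perimeter,
    convexity = min(hull$perimeter / per, 1),
    mean_density = mean(dens), max_density = max(dens),
    centroid_row = centroid[1] - 1, centroid_col = centroid[2] - 1)

  skel <- skeletonize(cb$mask)
  sb <- skeleton_branches(skel)
  bl <- sb$branch_lengths
  br <- c(
    branch_count = length(bl), junction_count = sb$n_junctions,
    endpoint_count = sb$n_endpoints,
    total_branch_length = sb$total_length,
    mean_branch_length = if (length(bl)) mean(bl) else 0,
    median_branch_length = if (length(bl)) median(bl) else 0,
    sd_branch_length = if (length(bl)) pop_sd(bl) else 0,
    max_branch_length = if (length(bl)) max(bl) else 0)
  c(geo, br)
}

# -- fractal dimension and lacunarity ---------------------------------------

bbox_long_side <- function(mask) {
  idx <- which(mask)
  nr <- nrow(mask)
  r <- (idx - 1L) %% nr + 1L; cc <- (idx - 1L) %/% nr + 1L
  max(max(r) - min(r) + 1L, max(cc) - min(cc) + 1L)
}

box_counts <- function(mask, scale) {
  idx <- which(mask)
  nr <- nrow(mask)
  r <- (idx - 1L) %% nr + 1L; cc <- (idx - 1L) %/% nr + 1L
  r0 <- min(r); c0 <- min(cc)
  br <- (r - r0) %/% scale; bc <- (cc - c0) %/% scale
  key <- br * (max(bc) + 1L) + bc
  tabulate(match(key, unique(key)))
}

#' Box-counting fractal dimension of a binary mask
#'
#' Least-squares slope of log(occupied box count) against log(1 / box size)
#' over a ladder of box sizes (dyadic by default: 2, 4, 8, ... up to a
#' quarter of the longest bounding-box side, so that elongated 1-px
#' structures still support the ladder). Boxes are anchored at the mask's
#' bounding-box origin. Scales larger than the mask are trimmed with a
#' warning; at least three scales are required.
#'
#' @param mask logical matrix, non-empty.
#' @param scales integer vector of box sizes (optional).
#' @return Estimated dimension (scalar).
#' @export
box_counting_dimension <- function(mask, scales = NULL) {
  if (!any(mask)) stop("empty mask: fractal dimension undefined")
  long <- bbox_long_side(mask)
  if (is.null(scales))
    scales <- 2^(1:max(1, floor(log2(long / 4))))
  over <- scales > long
  if (any(over)) {
    warning("trimming box scales larger than the mask")
    scales <- scales[!over]
  }
  if (length(scales) < 3)
    stop("need at least three box scales")
  n_boxes <- vapply(scales, function(s) length(box_counts(mask, s)),
                    numeric(1))
  fit <- lm(log(n_boxes) ~ log(1 / scales))
  unname(coef(fit)[2])
}

# coefficient of variation of per-box occupancy at the mid scale (boxes
# tile the mask bounding box; empty boxes included)
lacunarity_proxy <- function(mask, scales = NULL) {
  if (!any(mask)) return(0)
  long <- bbox_long_side(mask)
  if (is.null(scales))
    scales <- 2^(1:max(1, floor(log2(long / 4))))
  scales <- scales[scales <= long]
  if (!length(scales)) return(0)
  s <- scales[ceiling(length(scales) / 2)]
  idx <- which(mask)
  nr <- nrow(mask)
  r <- (idx - 1L) %% nr + 1L; cc <- (idx - 1L) %/% nr + 1L
  nbr <- (max(r) - min(r)) %/% s + 1L
  nbc <- (max(cc) - min(cc)) %/% s + 1L
  occ <- numeric(nbr * nbc)
  key <- ((r - min(r)) %/% s) * nbc + ((cc - min(cc)) %/% s) + 1L
  tab <- table(key)
  occ[as.integer(names(tab))] <- as.numeric(tab)
  if (mean(occ) == 0) return(0)
  pop_sd(occ) / mean(occ)
}

# -- per-cell features -------------------------------------------------------

#' Cell-level features from a mitochondrion table and its network mask
#'
#' 90 aggregations (mean, median, population sd of each aggregatable
#' per-mitochondrion feature) plus 20 population features of the whole
#' network. A single mitochondrion yields sd = 0, not missing. An empty
#' network yields a row of zeros (callers flag it via the
#' \code{empty_network} indicator).
#'
#' @param mito_rows data.frame of per-mitochondrion features (31 columns).
#' @param mask the cell's binary network mask.
#' @return Named numeric vector of length 110
#'   (\code{\link{cell_feature_names}}).
#' @export
cell_features <- function(mito_rows, mask) {
  out <- setNames(numeric(length(cell_feature_names())),
                  cell_feature_names())
  n <- nrow(mito_rows)
  if (is.null(n) || n == 0) return(out)
  agg_base <- setdiff(mito_feature_names(), "orientation")
  for (f in agg_base) {
    v <- mito_rows[[f]]
    out[paste0(f, "_mean")] <- mean(v)
    out[paste0(f, "_median")] <- median(v)
    out[paste0(f, "_sd")] <- pop_sd(v)
  }
  nr <- nrow(mask)
  px <- which(mask)
  r <- (px - 1L) %% nr + 1L; cc <- (px - 1L) %/% nr + 1L
  hull <- hull_of_pixels(r, cc)
  ell <- moment_ellipse(r, cc)
  bbox_area <- (max(r) - min(r) + 1) * (max(cc) - min(cc) + 1)
  cents <- cbind(mito_rows$centroid_row, mito_rows$centroid_col)
  if (n > 1) {
    dd <- as.matrix(dist(cents))
    diag(dd) <- Inf
    nn <- apply(dd, 1, min)
  } else nn <- 0
  net_ctr <- c(mean(r), mean(cc)) - 1  # 0-based like centroids
  disp <- sqrt(mean((cents[, 1] - net_ctr[1])^2 +
                    (cents[, 2] - net_ctr[2])^2))
  areas <- mito_rows$area
  fd <- tryCatch(box_counting_dimension(mask), error = function(e) NA,
                 warning = function(w) suppressWarnings(
                   box_counting_dimension(mask)))
  if (is.na(fd)) fd <- 0
  out["mito_count"] <- n
  out["net_area"] <- length(px)
  out["net_perimeter"] <- sum(mito_rows$perimeter)
  out["net_convex_area"] <- hull$area
  out["net_solidity"] <- min(length(px) / hull$area, 1)
  out["net_bbox_area"] <- bbox_area
  out["net_extent"] <- length(px) / bbox_area
  out["net_skeleton_length"] <- sum(mito_rows$total_branch_length)
  out["net_branch_count"] <- sum(mito_rows$branch_count)
  out["net_junction_count"] <- sum(mito_rows$junction_count)
  out["net_endpoint_count"] <- sum(mito_rows$endpoint_count)
  out["mean_nn_distance"] <- mean(nn)
  out["sd_nn_distance"] <- pop_sd(nn)
  out["centroid_dispersion"] <- disp
  out["largest_area_fraction"] <- max(areas) / sum(areas)
  out["above_median_area_fraction"] <- mean(areas > median(areas))
  out["fractal_dimension"] <- fd
  out["lacunarity"] <- lacunarity_proxy(mask)
  out["net_major_axis"] <- ell$major
  out["net_aspect_ratio"] <- ell$major / ell$minor
  out
}

# -- directory-level analysis ------------------------------------------------

#' Analyze a set of binary single-cell network masks
#'
#' @param masks named list of logical matrices (one per cell).
#' @param min_blob_area minimum mitochondrion area, px.
#' @return List: \code{mitochondria} (raw per-mitochondrion table:
#'   \code{cell_id}, \code{mito_id}, 31 features) and \code{cells}
#'   (processed per-cell table: \code{cell_id}, \code{empty_network},
#'   110 features).
#' @export
analyze_masks <- function(masks, min_blob_area = 4) {
  stopifnot(length(masks) > 0)
  if (is.null(names(masks)) || any(names(masks) == ""))
    names(masks) <- sprintf("cell_%03d", seq_along(masks))
  mito_rows <- list(); cell_rows <- list()
  for (id in names(masks)) {
    mask <- masks[[id]] != 0
    labs <- label_mitochondria(mask, min_area = min_blob_area)
    sets <- label_pixel_sets(labs)
    rows <- NULL
    if (length(sets)) {
      rows <- do.call(rbind, lapply(sets, mito_features, dims = dim(mask)))
      rows <- as.data.frame(rows)
      mito_rows[[id]] <- cbind(data.frame(cell_id = id,
                                          mito_id = seq_len(nrow(rows))),
                               rows)
    }
    cf <- cell_features(rows, labs > 0)
    cell_rows[[id]] <- cbind(data.frame(cell_id = id,
                                        empty_network = as.integer(
                                          length(sets) == 0)),
                             as.data.frame(as.list(cf)))
  }
  mito_tab <- if (length(mito_rows)) do.call(rbind, mito_rows) else
    cbind(data.frame(cell_id = character(0), mito_id = integer(0)),
          as.data.frame(matrix(numeric(0), 0, 31,
                               dimnames = list(NULL, mito_feature_names()))))
  cell_tab <- do.call(rbind, cell_rows)
  rownames(mito_tab) <- NULL; rownames(cell_tab) <- NULL
  list(mitochondria = mito_tab, cells = cell_tab)
}

#' Analyze a directory of binary mask images and export feature tables
#'
#' Reads every PNG/TIFF mask under \code{indir}, computes the raw
#' per-mitochondrion table and the processed per-cell table, validates all
#' values finite, and writes \code{<prefix>_mitochondria.<ext>} and
#' \code{<prefix>_cells.<ext>}. Unreadable masks are skipped with a warning.
#'
#' @param indir directory of mask rasters.
#' @param out_prefix output path prefix.
#' @param dialect \code{"csv"} or \code{"tsv"}.
#' @param min_blob_area minimum mitochondrion area, px.
#' @return The \code{\link{analyze_masks}} result, invisibly.
#' @export
analyze_directory <- function(indir, out_prefix, dialect = c("csv", "tsv"),
                              min_blob_area = 4) {
  dialect <- match.arg(dialect)
  files <- sort(list.files(indir, pattern = "\\.(png|tif|tiff)$",
                           ignore.case = TRUE, full.names = TRUE))
  if (!length(files)) stop("no mask images found in ", indir)
  masks <- list()
  for (f in files) {
    m <- tryCatch(read_mask(f), error = function(e) {
      warning("skipping unreadable mask ", f, ": ", conditionMessage(e))
      NULL
    })
    if (!is.null(m))
      masks[[tools::file_path_sans_ext(basename(f))]] <- m
  }
  if (!length(masks)) stop("no readable masks in ", indir)
  res <- analyze_masks(masks, min_blob_area = min_blob_area)
  ext <- dialect
  write_table(res$mitochondria,
              paste0(out_prefix, "_mitochondria.", ext), dialect)
  write_table(res$cells, paste0(out_prefix, "_cells.", ext), dialect)
  invisible(res)
}
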