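# Synthetic fluorescence images and shape phantoms with exhaustive ground
# truth. The imaging model: filled elliptical nuclei in the blue channel;
# curvilinear filamentous mitochondria (smoothed random walks with Gaussian
# cross-section) clustered around each nucleus in the mito channel; a diffuse
# out-of-focus halo of mitochondrial signal over each stained cell (this is
# what makes the nuclear zone a representative background-sampling region);
# additive Gaussian background; salt-and-pepper noise. Ghost cells carry a
# nucleus but no mitochondrial signal; edge cells have their nucleus center
# outside the frame.

#' Default parameters of the synthetic multi-cell image generator
#'
#' Units: lengths in pixels, intensities in 8-bit units. \code{snr} is the
#' nominal filament peak height above the background mean, in units of the
#' background standard deviation; \code{snr = Inf} paints a noise-free image
#' (zero background). Each stained cell also carries out-of-plane
#' (defocused) mitochondrial glow: wide, dim filaments that may cross the
#' nucleus. This textured glow pervades the whole cell, which is what makes
#' the nuclear zone a representative background-sampling region.
#' \code{oop_amplitude} is its peak (units of \code{bg_sd}) and
#' \code{oop_width} its cross-section FWHM.
#'
#' @param ... overrides of any default.
#' @return Named list of generator parameters.
#' @export
synth_params <- function(...) {
  p <- list(
    n_cells = 5L, n_ghosts = 0L, n_edge_cells = 0L,
    size = c(384L, 384L),
    nucleus_radius = c(9, 13),        # semi-axis range of nuclear ellipses
    filaments_per_cell = c(6L, 10L),
    filament_length = c(30L, 60L),    # random-walk steps
    filament_width = c(2, 4),         # FWHM range of the Gaussian cross-section
    filament_curvature = 0.25,        # sd of per-step heading increments (rad)
    cluster_radius = 40,              # filaments stay within this of nucleus
    min_spacing = 110,                # minimum nucleus center separation
    nucleus_intensity = 210,
    bg_mean = 20, bg_sd = 5,
    snr = 8,
    oop_amplitude = 1.5, oop_width = 10,
    salt_pepper = 0.002,
    dim_fraction = 0,                 # fraction of cells painted dim (AdaMM)
    dim_snr = NA_real_,
    mito_channel = "green")
  over <- list(...)
  unknown <- setdiff(names(over), names(p))
  if (length(unknown)) stop("unknown generator parameters: ",
                            paste(unknown, collapse = ", "))
  p[names(over)] <- over
  p
}

# rasterize a filled ellipse; returns linear indices inside the frame
ellipse_pixels <- function(center, semi, angle, nr, nc) {
  rmax <- max(semi)
  r0 <- floor(center[1] - rmax - 1); r1 <- ceiling(center[1] + rmax + 1)
  c0 <- floor(center[2] - rmax - 1); c1 <- ceiling(center[2] + rmax + 1)
  rows <- max(1, r0):min(nr, r1); cols <- max(1, c0):min(nc, c1)
  if (!length(rows) || !length(cols)) return(integer(0))
  gr <- rep(rows, times = length(cols)); gc <- rep(cols, each = length(rows))
  dr <- gr - center[1]; dc <- gc - center[2]
  u <- dr * cos(angle) + dc * sin(angle)
  v <- -dr * sin(angle) + dc * cos(angle)
  ok <- (u / semi[1])^2 + (v / semi[2])^2 <= 1
  (gc[ok] - 1L) * nr + gr[ok]
}

# stamp a Gaussian kernel centered at a sub-pixel position into canvas by
# max; values below cut * peak are not deposited, so with cut = 0.5 the
# painted support is exactly the full-width-at-half-maximum region (the
# compact apparent width of a diffraction-limited tubule at 8-bit depth)
stamp_gaussian <- function(canvas, center, sigma, peak, cut = 0) {
  nr <- nrow(canvas); nc <- ncol(canvas)
  rad <- ceiling(3 * sigma)
  rows <- max(1, floor(center[1]) - rad):min(nr, ceiling(center[1]) + rad)
  cols <- max(1, floor(center[2]) - rad):min(nc, ceiling(center[2]) + rad)
  if (!length(rows) || !length(cols)) return(canvas)
  d2 <- outer((rows - center[1])^2, (cols - center[2])^2, "+")
  val <- peak * exp(-d2 / (2 * sigma^2))
  if (cut > 0) val[val < cut * peak] <- 0
  canvas[rows, cols] <- pmax(canvas[rows, cols], val)
  canvas
}

# paint one cell's filaments on a fresh canvas; returns the deposit matrix.
# In-plane filaments (default) avoid the nucleus and are cut at half
# maximum; out-of-plane (defocused) filaments are painted wide, uncut, and
# may cross the nucleus.
paint_filaments <- function(nr, nc, center, n_fil, p, peak, nucleus_semi,
                            nucleus_angle, width_range = p$filament_width,
                            cut = 0.5, avoid_nucleus = TRUE,
                            start_range = NULL) {
  canvas <- matrix(0, nr, nc)
  if (is.null(start_range)) {
    lo <- max(nucleus_semi) + 2
    start_range <- c(lo, max(lo + 2, 0.6 * p$cluster_radius))
  }
  for (f in seq_len(n_fil)) {
    len <- sample(p$filament_length[1]:p$filament_length[2], 1)
    fwhm <- runif(1, width_range[1], width_range[2])
    sigma <- fwhm / 2.355
    start_r <- runif(1, start_range[1], start_range[2])
    theta <- runif(1, 0, 2 * pi)
    pos <- center + start_r * c(cos(theta), sin(theta))
    heading <- runif(1, 0, 2 * pi)
    for (s in seq_len(len)) {
      heading <- heading + rnorm(1, 0, p$filament_curvature)
      pos2 <- pos + c(cos(heading), sin(heading))
      # stay within the cluster: steer back toward the nucleus center
      if (sqrt(sum((pos2 - center)^2)) > p$cluster_radius) {
        heading <- atan2(center[2] - pos[2], center[1] - pos[1]) +
          rnorm(1, 0, 0.3)
        pos2 <- pos + c(cos(heading), sin(heading))
      }
      pos <- pos2
      # no in-plane mitochondria within the nucleus: skip stamps inside
      inside_nuc <- FALSE
      if (avoid_nucleus) {
        dr <- pos[1] - center[1]; dc <- pos[2] - center[2]
        u <- dr * cos(nucleus_angle) + dc * sin(nucleus_angle)
        v <- -dr * sin(nucleus_angle) + dc * cos(nucleus_angle)
        inside_nuc <- (u / (nucleus_semi[1] + sigma))^2 +
          (v / (nucleus_semi[2] + sigma))^2 <= 1
      }
      if (!inside_nuc &&
          pos[1] > -3 && pos[1] < nr + 3 && pos[2] > -3 && pos[2] < nc + 3)
        canvas <- stamp_gaussian(canvas, pos, sigma, peak, cut = cut)
    }
  }
  canvas
}

# out-of-plane (defocused) mitochondrial glow: a dense virtual z-plane of
# filaments painted across the whole cell (nucleus included -- the signal
# originates above or below the focal plane) and convolved with a Gaussian
# defocus kernel, then scaled to the requested peak amplitude
defocused_plane <- function(nr, nc, center, p, nucleus_semi, nucleus_angle,
                            peak) {
  n_fil <- 2L * sample(p$filaments_per_cell[1]:p$filaments_per_cell[2], 1)
  plane <- paint_filaments(nr, nc, center, n_fil, p, 1, nucleus_semi,
                           nucleus_angle, cut = 0.5, avoid_nucleus = FALSE,
                           start_range = c(0, 0.6 * p$cluster_radius))
  blur <- EBImage::gblur(plane, sigma = p$oop_width / 2.355)
  blur <- pmax(as.matrix(blur), 0)
  mx <- max(blur)
  if (mx > 0) blur * (peak / mx) else blur
}

place_centers <- function(n, nr, nc, margin, min_spacing, max_tries = 600,
                          max_restarts = 20) {
  if (2 * margin >= min(nr, nc))
    stop("infeasible packing: margin exceeds the frame")
  for (round in seq_len(max_restarts)) {
    centers <- matrix(numeric(0), 0, 2)
    tries <- 0
    while (nrow(centers) < n && tries < max_tries) {
      tries <- tries + 1
      cand <- c(runif(1, margin, nr - margin), runif(1, margin, nc - margin))
      if (nrow(centers) == 0 ||
          min(sqrt(rowSums((centers - matrix(cand, nrow(centers), 2,
                                             byrow = TRUE))^2))) >=
            min_spacing)
        centers <- rbind(centers, cand)
    }
    if (nrow(centers) == n) return(centers)
  }
  stop("infeasible packing: could not place ", n,
       " nuclei at spacing >= ", min_spacing)
}

#' Generate a synthetic multi-cell fluorescence image with ground truth
#'
#' Emulates a 2D single-z-slice 8-bit RGB micrograph: blue nuclei, filamentous
#' mitochondria in the declared mito channel, Gaussian background,
#' salt-and-pepper noise, optional ghost cells (nucleus, no mitochondria) and
#' edge-truncated cells (nucleus center outside the frame). All randomness
#' flows from \code{seed}; regeneration from the same parameters and seed is
#' bit-identical.
#'
#' @param params list from \code{\link{synth_params}}.
#' @param seed integer seed (mandatory).
#' @return List with elements \code{image} (a \code{\link{fluor_image}}) and
#'   \code{truth}: \code{nuclei_labels} (integer matrix over all planted
#'   nuclei), \code{owner} (integer matrix, true owner label of every painted
#'   mitochondrial pixel), \code{cells} (data.frame: label, type in
#'   core/ghost/edge, center_row, center_col), \code{deposit} (noise-free
#'   mitochondrial intensity), \code{params}, \code{seed}.
#' @export
generate_multicell <- function(params = synth_params(), seed) {
  if (missing(seed)) stop("seed is mandatory")
  p <- params
  with_seed(seed, {
    nr <- p$size[1]; nc <- p$size[2]
    noise_free <- !is.finite(p$snr)
    bg_sd <- if (noise_free) 0 else p$bg_sd
    bg_mean <- if (noise_free) 0 else p$bg_mean
    peak_of <- function(snr) if (noise_free) 200 else bg_mean + snr * p$bg_sd

    n_total <- p$n_cells + p$n_ghosts + p$n_edge_cells
    # interior cells stay entirely inside the frame: only deliberately
    # planted edge cells can touch the border
    margin <- max(p$nucleus_radius) + p$cluster_radius + 2
    interior <- place_centers(p$n_cells + p$n_ghosts, nr, nc, margin,
                              p$min_spacing)
    types <- c(rep("core", p$n_cells), rep("ghost", p$n_ghosts))
    # edge cells: nucleus center pushed just outside a random frame side,
    # kept at spacing from every other nucleus so clusters stay distinct
    edge_centers <- matrix(numeric(0), 0, 2)
    for (k in seq_len(p$n_edge_cells)) {
      placed <- FALSE
      for (try in 1:400) {
        side <- sample(4, 1)
        off <- runif(1, 0.3, 0.6) * max(p$nucleus_radius)
        along <- runif(1, 0.2, 0.8)
        cand <- switch(side,
          c(-off, along * nc), c(nr + off, along * nc),
          c(along * nr, -off), c(along * nr, nc + off))
        others <- rbind(interior, edge_centers)
        if (nrow(others) == 0 ||
            min(sqrt(rowSums((others - matrix(cand, nrow(others), 2,
                                              byrow = TRUE))^2))) >=
              p$min_spacing) {
          edge_centers <- rbind(edge_centers, cand)
          placed <- TRUE
          break
        }
      }
      if (!placed) stop("infeasible packing: could not place edge cell")
    }
    centers <- rbind(interior, edge_centers)
    types <- c(types, rep("edge", p$n_edge_cells))

    nuclei_labels <- matrix(0L, nr, nc)
    nuclei_plane <- matrix(0, nr, nc)
    deposit <- matrix(0, nr, nc)
    owner <- matrix(0L, nr, nc)
    best <- matrix(0, nr, nc)
    halo <- matrix(0, nr, nc)
    cells <- data.frame(label = integer(0), type = character(0),
                        center_row = numeric(0), center_col = numeric(0))

    n_dim <- round(p$dim_fraction * p$n_cells)
    dim_flags <- rep(FALSE, n_total)
    if (n_dim > 0) dim_flags[seq_len(n_dim)] <- TRUE  # first core cells dim

    for (i in seq_len(n_total)) {
      ctr <- centers[i, ]
      semi <- sort(runif(2, p$nucleus_radius[1], p$nucleus_radius[2]),
                   decreasing = TRUE)
      ang <- runif(1, 0, pi)
      npx <- ellipse_pixels(ctr, semi, ang, nr, nc)
      nuclei_labels[npx] <- i
      nuclei_plane[npx] <- p$nucleus_intensity
      cells <- rbind(cells, data.frame(
        label = i, type = types[i], center_row = ctr[1], center_col = ctr[2]))
      if (types[i] == "ghost") next
      snr_i <- if (dim_flags[i] && is.finite(p$dim_snr)) p$dim_snr else p$snr
      n_fil <- sample(p$filaments_per_cell[1]:p$filaments_per_cell[2], 1)
      dep_i <- paint_filaments(nr, nc, ctr, n_fil, p, peak_of(snr_i),
                               semi, ang)
      newly <- dep_i > best
      owner[newly] <- i
      best[newly] <- dep_i[newly]
      deposit <- pmax(deposit, dep_i)
      if (p$oop_amplitude > 0 && bg_sd > 0)
        halo <- pmax(halo, defocused_plane(nr, nc, ctr, p, semi, ang,
                                           p$oop_amplitude * bg_sd))
    }
    # painted support is already cut at half-maximum during stamping, so
    # every positive deposit is ground-truth mitochondrial signal

    mito <- deposit + halo
    if (bg_sd > 0) mito <- mito + matrix(rnorm(nr * nc, bg_mean, bg_sd), nr, nc)
    if (!noise_free && p$salt_pepper > 0) {
      n_sp <- round(p$salt_pepper * nr * nc)
      if (n_sp > 0) {
        at <- sample.int(nr * nc, n_sp)
        mito[at] <- ifelse(runif(n_sp) < 0.5, 0, 255)
      }
    }
    mito <- round(pmin(pmax(mito, 0), 255))
    nup <- nuclei_plane
    if (bg_sd > 0)
      nup <- nup + matrix(rnorm(nr * nc, 3, 2), nr, nc)
    nup <- round(pmin(pmax(nup, 0), 255))

    img <- merge_channels(nup, mito, p$mito_channel)
    img$source_path <- sprintf("synthetic(seed=%d)", seed)
    list(image = img,
         truth = list(nuclei_labels = nuclei_labels, owner = owner,
                      cells = cells, deposit = deposit, params = p,
                      seed = seed))
  })
}

#' Named generator presets
#'
#' \code{"separated"}: well-separated stained cells (nucleus spacing well
#' above the filament cluster diameter). \code{"crowded"}: tighter packing.
#' \code{"ghosted"}: three stained cells plus two ghost nuclei.
#' \code{"edge"}: interior cells plus one edge-truncated cell.
#'
#' @param preset preset name.
#' @param seed integer seed.
#' @param ... parameter overrides passed to \code{\link{synth_params}}.
#' @return As \code{\link{generate_multicell}}.
#' @export
synth_preset <- function(preset = c("separated", "crowded", "ghosted", "edge"),
                         seed, ...) {
  preset <- match.arg(preset)
  base <- switch(preset,
    separated = synth_params(n_cells = 4L, size = c(384L, 384L),
                             cluster_radius = 35, min_spacing = 150, ...),
    crowded   = synth_params(n_cells = 6L, size = c(384L, 384L),
                             cluster_radius = 40, min_spacing = 85, ...),
    ghosted   = synth_params(n_cells = 3L, n_ghosts = 2L, ...),
    edge      = synth_params(n_cells = 3L, n_edge_cells = 1L, ...))
  generate_multicell(base, seed = seed)
}

#' Generate a single-cell image for segmentation tests
#'
#' One centered nucleus with its filament cluster, rendered at a given SNR
#' (optionally with a subset of filaments painted at a lower, "dim" SNR to
#' exercise adaptive local threshold correction). Returns the image together
#' with the ground-truth network mask (painted pixels at or above the
#' half-peak cut of the \emph{bright} filaments' nominal peak for the bright
#' set, and of the dim peak for the dim set).
#'
#' @param seed integer seed.
#' @param snr filament peak over background, in background-sd units
#'   (\code{Inf} = noise-free).
#' @param dim_filaments number of additional filaments painted at
#'   \code{dim_snr}.
#' @param dim_snr SNR of the dim filaments.
#' @param cell_masked emulate a cell-separation crop: mitochondrial-channel
#'   pixels outside the cell's footprint (cluster radius plus a small
#'   margin) are zeroed, as in the output of the cell-separation stage.
#' @param shading_min staining-efficiency floor: fluorophore-derived signal
#'   (filaments and glow, not the camera noise) keeps full intensity out to
#'   just over half the cluster radius and then ramps down to this factor,
#'   planting a dim peripheral region (1 = no shading).
#' @param size image side length.
#' @param ... further overrides of \code{\link{synth_params}}.
#' @return List: \code{image}, \code{truth_mask} (logical), \code{nucleus_mask}
#'   (logical), \code{params}.
#' @export
generate_single_cell <- function(seed, snr = 8, dim_filaments = 0L,
                                 dim_snr = 3, shading_min = 1,
                                 cell_masked = FALSE, size = 192L, ...) {
  p <- synth_params(n_cells = 1L, size = c(size, size), snr = snr,
                    cluster_radius = 0.4 * size, min_spacing = 1, ...)
  with_seed(seed, {
    nr <- p$size[1]; nc <- p$size[2]
    noise_free <- !is.finite(snr)
    bg_sd <- if (noise_free) 0 else p$bg_sd
    bg_mean <- if (noise_free) 0 else p$bg_mean
    peak_of <- function(s) if (noise_free) 200 else bg_mean + s * p$bg_sd
    ctr <- c(nr, nc) / 2
    semi <- sort(runif(2, p$nucleus_radius[1], p$nucleus_radius[2]),
                 decreasing = TRUE)
    ang <- runif(1, 0, pi)
    npx <- ellipse_pixels(ctr, semi, ang, nr, nc)
    nucleus_mask <- matrix(FALSE, nr, nc); nucleus_mask[npx] <- TRUE

    n_fil <- sample(p$filaments_per_cell[1]:p$filaments_per_cell[2], 1)
    dep <- paint_filaments(nr, nc, ctr, n_fil, p, peak_of(snr), semi, ang)
    if (dim_filaments > 0) {
      dep_dim <- paint_filaments(nr, nc, ctr, dim_filaments, p,
                                 peak_of(dim_snr), semi, ang)
      dep <- pmax(dep, dep_dim)
    }
    truth <- dep > 0
    truth[npx] <- FALSE

    mito <- dep
    if (p$oop_amplitude > 0 && bg_sd > 0)
      mito <- mito + defocused_plane(nr, nc, ctr, p, semi, ang,
                                     p$oop_amplitude * bg_sd)
    if (shading_min < 1) {
      # peripheral staining falloff: full efficiency out to just over half
      # the cluster radius, then a short ramp down to shading_min
      rg <- matrix(rep(1:nr, nc), nr, nc)
      cg <- matrix(rep(1:nc, each = nr), nr, nc)
      dctr <- sqrt((rg - ctr[1])^2 + (cg - ctr[2])^2)
      ramp <- pmin(pmax((dctr - 0.55 * p$cluster_radius) / 8, 0), 1)
      g <- 1 - (1 - shading_min) * ramp
      mito <- mito * g
    }
    if (bg_sd > 0) mito <- mito + matrix(rnorm(nr * nc, bg_mean, bg_sd), nr, nc)
    if (!noise_free && p$salt_pepper > 0) {
      n_sp <- round(p$salt_pepper * nr * nc)
      if (n_sp > 0) {
        at <- sample.int(nr * nc, n_sp)
        mito[at] <- ifelse(runif(n_sp) < 0.5, 0, 255)
      }
    }
    mito <- round(pmin(pmax(mito, 0), 255))
    if (cell_masked) {
      rg <- matrix(rep(1:nr, nc), nr, nc)
      cg <- matrix(rep(1:nc, each = nr), nr, nc)
      dctr <- sqrt((rg - ctr[1])^2 + (cg - ctr[2])^2)
      mito[dctr > p$cluster_radius + 6] <- 0
    }
    nup <- matrix(0, nr, nc); nup[npx] <- p$nucleus_intensity
    if (bg_sd > 0) nup <- nup + matrix(rnorm(nr * nc, 3, 2), nr, nc)
    nup <- round(pmin(pmax(nup, 0), 255))
    img <- merge_channels(nup, mito, p$mito_channel)
    img$source_path <- sprintf("synthetic-cell(seed=%d)", seed)
    list(image = img, truth_mask = truth, nucleus_mask = nucleus_mask,
         params = p)
  })
}

# ---------------------------------------------------------------------------
# Deterministic shape phantoms

disc_mask <- function(radius, pad = 3L) {
  n <- 2L * (radius + pad) + 1L
  ctr <- (n + 1) / 2
  d2 <- outer((1:n - ctr)^2, (1:n - ctr)^2, "+")
  d2 <= radius^2
}

sierpinski_carpet <- function(depth) {
  m <- matrix(TRUE, 1, 1)
  for (i in seq_len(depth)) {
    n <- nrow(m)
    out <- matrix(FALSE, 3 * n, 3 * n)
    for (bi in 0:2) for (bj in 0:2) {
      if (bi == 1 && bj == 1) next
      out[bi * n + 1:n, bj * n + 1:n] <- m
    }
    m <- out
  }
  m
}

#' Deterministic phantom mask library
#'
#' Named binary masks with closed-form expected morphometry where it exists:
#' filled discs (r = 5, 10, 20), a 20x3 bar, a 1x20 line, a plus-sign (two
#' crossing bars: 4 branches, 1 junction, 4 endpoints after thinning), an
#' annulus, Sierpinski carpets (depths 3-5; box-counting dimension
#' log 8 / log 3), a single-pixel blob, and a full-frame mask.
#'
#' @return Named list of logical matrices.
#' @export
generate_phantoms <- function() {
  pad_into <- function(h, w, fill_fun) {
    m <- matrix(FALSE, h, w); fill_fun(m)
  }
  bar <- matrix(FALSE, 11, 26); bar[5:7, 4:23] <- TRUE       # 20x3 bar
  line1 <- matrix(FALSE, 7, 26); line1[4, 4:23] <- TRUE      # 1x20 line
  line48 <- matrix(FALSE, 7, 54); line48[4, 4:51] <- TRUE    # 1x48 line
  plus <- matrix(FALSE, 31, 31)
  plus[14:16, 6:26] <- TRUE; plus[6:26, 14:16] <- TRUE
  ring <- {
    n <- 33L; ctr <- 17
    d2 <- outer((1:n - ctr)^2, (1:n - ctr)^2, "+")
    d2 <= 12^2 & d2 >= 8^2
  }
  onepx <- matrix(FALSE, 5, 5); onepx[3, 3] <- TRUE
  list(
    disc5 = disc_mask(5), disc10 = disc_mask(10), disc20 = disc_mask(20),
    bar_20x3 = bar, line_1x20 = line1, line_1x48 = line48,
    plus = plus, ring = ring,
    sierpinski3 = sierpinski_carpet(3),
    sierpinski4 = sierpinski_carpet(4),
    sierpinski5 = sierpinski_carpet(5),
    single_pixel = onepx,
    full_frame = matrix(TRUE, 32, 32))
}
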