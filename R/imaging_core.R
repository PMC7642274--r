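#' mitonet: single-cell mitochondrial network morphometry
#'
#' Isolates single cells from multi-cell fluorescence images by
#' expectation-maximization linking of mitochondria to nucleus seeds,
#' binarizes each cell's mitochondrial network from nuclear-zone background
#' statistics (optionally with adaptive tile-wise threshold correction), and
#' extracts per-mitochondrion and per-cell morphometric feature tables.
#'
#' Conventions used throughout: intensity grids are numeric matrices indexed
#' \code{[row, col]} (origin top-left, 0-based in exports), 8-bit range
#' \code{0..255}; binary masks are logical matrices; labeled masks are integer
#' matrices with 0 = background and contiguous labels \code{1..n}; connected
#' components are 8-connected.
#'
#' @importFrom stats median quantile sd rnorm runif lm qchisq setNames
#'   complete.cases dist
#' @importFrom utils write.table read.csv head tail
#' @importFrom grDevices chull
#' @name mitonet-package
#' @keywords internal
"_PACKAGE"

# ---------------------------------------------------------------------------
# FluorescenceImage

#' Construct a fluorescence image object
#'
#' Wraps an 8-bit RGB pixel array with declared channel roles. Nuclei are
#' always carried in the blue channel; mitochondria in green or red.
#'
#' @param pixels numeric array \code{height x width x 3} (R, G, B planes),
#'   values in \code{[0, 255]}.
#' @param mito_channel \code{"green"} or \code{"red"}.
#' @param source_path provenance string.
#' @return An object of class \code{fluor_image}.
#' @export
fluor_image <- function(pixels, mito_channel = c("green", "red"),
                        source_path = NA_character_) {
  mito_channel <- match.arg(mito_channel)
  stopifnot(length(dim(pixels)) == 3, dim(pixels)[3] >= 3)
  if (min(pixels) < 0 || max(pixels) > 255)
    stop("pixel values must lie in [0, 255]")
  structure(
    list(pixels = pixels[, , 1:3, drop = FALSE],
         height = dim(pixels)[1], width = dim(pixels)[2],
         nuclei_channel = "blue", mito_channel = mito_channel,
         source_path = source_path),
    class = "fluor_image")
}

#' @export
print.fluor_image <- function(x, ...) {
  cat(sprintf("<fluor_image %dx%d, nuclei=blue, mito=%s, source=%s>\n",
              x$height, x$width, x$mito_channel, x$source_path))
  invisible(x)
}

channel_index <- function(name) {
  switch(name, red = 1L, green = 2L, blue = 3L,
         stop("unknown channel: ", name))
}

#' Read a fluorescence micrograph
#'
#' Reads an RGB TIFF or PNG raster and resolves channel roles. 16-bit input is
#' linearly rescaled to 8-bit. Under \code{mito_channel = "auto"}, the
#' mitochondrial channel is whichever of green/red carries the greater total
#' intensity; if both are empty the image is rejected as ambiguous. Grayscale
#' input is promoted to RGB only when an explicit mito channel is requested:
#' the gray plane is placed in that channel and the blue (nuclei) plane is
#' left empty.
#'
#' @param path file path (.png, .tif, .tiff).
#' @param mito_channel one of \code{"auto"}, \code{"green"}, \code{"red"}.
#' @return A \code{\link{fluor_image}}.
#' @export
read_image <- function(path, mito_channel = c("auto", "green", "red")) {
  mito_channel <- match.arg(mito_channel)
  if (!file.exists(path)) stop("no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported raster format (need PNG or TIFF): ", path))
  if (is.list(raw)) raw <- raw[[1]]
  # readers return [0,1]; rescale to 8-bit
  px <- raw * 255
  if (length(dim(px)) == 2) {
    if (mito_channel == "auto")
      stop("grayscale input is ambiguous under mito_channel = \"auto\"; ",
           "declare the mitochondrial channel explicitly")
    arr <- array(0, c(dim(px), 3))
    arr[, , channel_index(mito_channel)] <- px
    return(fluor_image(arr, mito_channel, source_path = path))
  }
  if (dim(px)[3] < 3) stop("raster must have >= 3 channels: ", path)
  if (mito_channel == "auto") {
    g <- sum(px[, , 2]); r <- sum(px[, , 1])
    if (g == 0 && r == 0)
      stop("ambiguous mitochondrial channel: green and red are both empty")
    mito_channel <- if (g >= r) "green" else "red"
  }
  fluor_image(px[, , 1:3, drop = FALSE], mito_channel, source_path = path)
}

#' Split an image into nuclei and mitochondria intensity grids
#'
#' @param img a \code{\link{fluor_image}}.
#' @return List with matrices \code{nuclei} and \code{mito} (values preserved
#'   bit-exactly from the source planes).
#' @export
split_channels <- function(img) {
  stopifnot(inherits(img, "fluor_image"))
  list(nuclei = img$pixels[, , channel_index(img$nuclei_channel)],
       mito   = img$pixels[, , channel_index(img$mito_channel)])
}

#' Merge nuclei and mitochondria grids back into an RGB image
#'
#' Inverse of \code{\link{split_channels}} for images whose remaining channel
#' is empty.
#'
#' @param nuclei,mito numeric matrices of equal dimension, values 0..255.
#' @param mito_channel \code{"green"} or \code{"red"}.
#' @return A \code{\link{fluor_image}}.
#' @export
merge_channels <- function(nuclei, mito, mito_channel = c("green", "red")) {
  mito_channel <- match.arg(mito_channel)
  stopifnot(all(dim(nuclei) == dim(mito)))
  arr <- array(0, c(dim(nuclei), 3))
  arr[, , channel_index(mito_channel)] <- mito
  arr[, , 3] <- nuclei
  fluor_image(arr, mito_channel)
}

#' Write an RGB image or a binary mask as PNG
#'
#' Masks are written 8-bit with foreground = 255.
#'
#' @param x a \code{fluor_image}, a logical mask, or a 0..255 matrix/array.
#' @param path output path (.png).
#' @export
write_image <- function(x, path) {
  if (inherits(x, "fluor_image")) x <- x$pixels
  if (is.logical(x)) x <- x * 255
  png::writePNG(x / 255, path)
  invisible(path)
}

#' Read a binary mask from a PNG/TIFF file
#'
#' Any pixel above half-intensity is foreground; RGB masks are collapsed by
#' their maximum channel.
#'
#' @param path raster path.
#' @return Logical matrix.
#' @export
read_mask <- function(path) {
  img <- read_image_raw(path)
  if (length(dim(img)) == 3) img <- apply(img, c(1, 2), max)
  img > 127
}

read_image_raw <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported raster format: ", path))
  if (is.list(raw)) raw <- raw[[1]]
  raw * 255
}

# ---------------------------------------------------------------------------
# Labeling

#' 8-connected component labeling
#'
#' Labels connected components of a binary mask. Components below
#' \code{min_area} pixels are discarded; surviving labels are renumbered
#' contiguously \code{1..n} in raster order of their first pixel.
#'
#' @param mask logical matrix.
#' @param min_area minimum component size in pixels (smaller components are
#'   dropped to background).
#' @param connectivity 8 (default) or 4.
#' @return Integer matrix of labels, 0 = background.
#' @export
label_components <- function(mask, min_area = 0, connectivity = 8) {
  stopifnot(is.matrix(mask), connectivity %in% c(4, 8))
  mask <- mask != 0
  nr <- nrow(mask); nc <- ncol(mask)
  idx <- which(mask)
  out <- matrix(0L, nr, nc)
  if (length(idx) == 0) return(out)
  pos <- match(idx, idx)  # 1..n
  r <- (idx - 1L) %% nr + 1L
  cc <- (idx - 1L) %/% nr + 1L
  # edges to neighbours at +row, +col, and two diagonals (undirected graph)
  offs <- list(c(1L, 0L), c(0L, 1L))
  if (connectivity == 8) offs <- c(offs, list(c(1L, 1L), c(1L, -1L)))
  from <- integer(0); to <- integer(0)
  lookup <- matrix(0L, nr, nc); lookup[idx] <- seq_along(idx)
  for (o in offs) {
    rr <- r + o[1]; ccn <- cc + o[2]
    ok <- rr >= 1L & rr <= nr & ccn >= 1L & ccn <= nc
    if (!any(ok)) next
    nb <- lookup[cbind(rr[ok], ccn[ok])]
    hit <- nb > 0L
    from <- c(from, pos[ok][hit]); to <- c(to, nb[hit])
  }
  g <- igraph::graph_from_edgelist(cbind(from, to), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(idx) - igraph::vcount(g)))
  comp <- igraph::components(g)$membership
  if (min_area > 0) {
    sizes <- tabulate(comp)
    comp[sizes[comp] < min_area] <- NA
  }
  keep <- !is.na(comp)
  # renumber in raster order of first occurrence
  relab <- match(comp[keep], unique(comp[keep]))
  out[idx[keep]] <- relab
  out
}

#' Per-label pixel index lists
#'
#' @param labels integer label matrix.
#' @return List of integer vectors of linear pixel indices, one per label.
#' @keywords internal
label_pixel_sets <- function(labels) {
  idx <- which(labels > 0)
  split(idx, labels[idx])
}

#' Centroid of a set of linear pixel indices
#' @keywords internal
pixel_centroid <- function(idx, nr) {
  c(row = mean((idx - 1L) %% nr + 1L), col = mean((idx - 1L) %/% nr + 1L))
}

# ---------------------------------------------------------------------------
# Tables

#' Write a feature table as CSV or TSV
#'
#' Every value is validated finite before anything is written; a missing or
#' infinite cell aborts the export naming the offending row and column, so
#' downstream tables are guaranteed clean. Numeric formatting is
#' locale-independent (period decimal separator).
#'
#' @param table data.frame with a header of stable snake_case names.
#' @param path output path.
#' @param dialect \code{"csv"} or \code{"tsv"}.
#' @param allow_na permit missing values (diagnostic reports only; feature
#'   tables keep the strict no-missing contract).
#' @export
write_table <- function(table, path, dialect = c("csv", "tsv"),
                        allow_na = FALSE) {
  dialect <- match.arg(dialect)
  stopifnot(is.data.frame(table))
  for (j in seq_along(table)) {
    col <- table[[j]]
    if (is.numeric(col) && any(!is.finite(col) & (!allow_na | !is.na(col)))) {
      i <- which(!is.finite(col))[1]
      stop(sprintf("non-finite value at row %d, column '%s'; nothing written",
                   i, names(table)[j]))
    }
  }
  sep <- if (dialect == "csv") "," else "\t"
  old <- Sys.getlocale("LC_NUMERIC")
  on.exit(suppressWarnings(Sys.setlocale("LC_NUMERIC", old)), add = TRUE)
  suppressWarnings(Sys.setlocale("LC_NUMERIC", "C"))
  write.table(table, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Small shared helpers

#' Population standard deviation (divide by n)
#'
#' Pixel sets are censuses, not samples; all internal moments use the
#' population convention.
#' @param x numeric vector.
#' @keywords internal
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Disc-shaped structuring element of a given radius
#' @keywords internal
disc_brush <- function(radius) {
  size <- 2L * as.integer(radius) + 1L
  EBImage::makeBrush(size, shape = "disc")
}

#' Dilate a logical mask with a disc of the given radius
#' @keywords internal
dilate_mask <- function(mask, radius) {
  if (radius <= 0) return(mask)
  EBImage::dilate(mask * 1, disc_brush(radius)) > 0
}

#' Run an expression with a temporary RNG seed, restoring prior RNG state
#' @keywords internal
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  force(expr)
}
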