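# End-to-end orchestration: catch-cells -> catch-mito -> analyze -> qc.
# Every stage is independently invocable; the pipeline wires their file
# interfaces together and records a manifest. A thin command-line wrapper
# over these functions ships in inst/cli/mitonet.R.

#' Default pipeline configuration
#'
#' Per-stage parameter blocks mirroring every tunable, plus a global seed
#' and input/output roots. Unknown keys in overrides are rejected.
#'
#' @param input input directory of multi-cell images.
#' @param output output root directory.
#' @param seed global seed.
#' @param mito_channel \code{"auto"}, \code{"green"} or \code{"red"}.
#' @param cell_catcher list from \code{\link{cell_catcher_params}}.
#' @param mito_catcher list from \code{\link{mito_catcher_config}}.
#' @param min_blob_area minimum mitochondrion area for morphometry, px.
#' @param table_dialect \code{"csv"} or \code{"tsv"}.
#' @param qc_frac_cutoff outlier-cell feature fraction cutoff.
#' @param qc_vif_cutoff VIF pruning cutoff.
#' @return Configuration list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(input, output, seed = 1L,
                            mito_channel = "auto",
                            cell_catcher = cell_catcher_params(),
                            mito_catcher = mito_catcher_config(),
                            min_blob_area = 4,
                            table_dialect = "csv",
                            qc_frac_cutoff = 0.20, qc_vif_cutoff = 10) {
  structure(list(input = input, output = output, seed = seed,
                 mito_channel = mito_channel, cell_catcher = cell_catcher,
                 mito_catcher = mito_catcher, min_blob_area = min_blob_area,
                 table_dialect = table_dialect,
                 qc_frac_cutoff = qc_frac_cutoff,
                 qc_vif_cutoff = qc_vif_cutoff),
            class = "pipeline_config")
}

#' Read a pipeline configuration from JSON
#'
#' Keys mirror the arguments of \code{\link{pipeline_config}} and the
#' parameter constructors of each stage; unknown keys are rejected (typo
#' safety).
#'
#' @param path JSON file.
#' @return A \code{pipeline_config}.
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  nested <- list(cell_catcher = cell_catcher_params,
                 mito_catcher = mito_catcher_config)
  for (k in names(nested)) {
    if (!is.null(raw[[k]])) {
      sub <- raw[[k]]
      kn <- names(formals(nested[[k]]))
      bad <- setdiff(names(sub), kn)
      if (length(bad))
        stop("unknown ", k, " keys: ", paste(bad, collapse = ", "))
      raw[[k]] <- do.call(nested[[k]], sub)
    }
  }
  do.call(pipeline_config, raw)
}

#' Run the full pipeline on a directory of multi-cell images
#'
#' For each image: cell separation, per-cell network segmentation, and
#' morphometry; then cohort QC over the pooled cell table. Per-image
#' failures are logged and skipped; the pipeline fails only when no image
#' succeeds. The serialized configuration and a manifest of produced files
#' are written under the output root for provenance.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @return Manifest list (invisibly): per-image counts, table paths, QC
#'   summary.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  files <- sort(list.files(config$input,
                           pattern = "\\.(png|tif|tiff)$",
                           ignore.case = TRUE, full.names = TRUE))
  if (!length(files)) stop("empty input directory: ", config$input)
  dir.create(config$output, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(unclass(config),
                       file.path(config$output, "config.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE,
                       digits = NA)
  manifest <- list(images = list())
  all_masks <- list()
  for (f in files) {
    name <- tools::file_path_sans_ext(basename(f))
    rec <- tryCatch({
      img <- read_image(f, mito_channel = config$mito_channel)
      caught <- catch_cells(img, config$cell_catcher)
      cell_dir <- file.path(config$output, "cells", name)
      export_single_cells(img, caught, cell_dir)
      mask_dir <- file.path(config$output, "masks", name)
      dir.create(mask_dir, showWarnings = FALSE, recursive = TRUE)
      n_seg <- 0
      for (cell in caught$cells) {
        if (cell$is_bad_edge_cell) next
        nr <- img$height
        numask <- matrix(FALSE, img$height, img$width)
        numask[cell$nucleus] <- TRUE
        ch <- split_channels(img)
        mito <- matrix(0, img$height, img$width)
        mito[cell$mito] <- ch$mito[cell$mito]
        sub <- merge_channels(ch$nuclei * numask, mito, img$mito_channel)
        seg <- segment_cell(sub, config$mito_catcher,
                            nucleus_mask = numask)
        mask_path <- file.path(mask_dir,
                               sprintf("%s_cell_%03d.png", name, cell$label))
        write_image(seg$mask, mask_path)
        all_masks[[sprintf("%s_cell_%03d", name, cell$label)]] <- seg$mask
        n_seg <- n_seg + 1
      }
      c(as.list(caught$log), cells_segmented = n_seg, status = "ok")
    }, error = function(e) {
      message("pipeline: skipping ", name, ": ", conditionMessage(e))
      list(status = paste("failed:", conditionMessage(e)))
    })
    manifest$images[[name]] <- rec
  }
  ok <- vapply(manifest$images, function(x) identical(x$status, "ok"),
               logical(1))
  if (!any(ok)) stop("pipeline failed on every input image")
  if (length(all_masks)) {
    res <- analyze_masks(all_masks, min_blob_area = config$min_blob_area)
    prefix <- file.path(config$output, "features")
    write_table(res$mitochondria,
                paste0(prefix, "_mitochondria.", config$table_dialect),
                config$table_dialect)
    write_table(res$cells, paste0(prefix, "_cells.", config$table_dialect),
                config$table_dialect)
    manifest$tables <- paste0(prefix, c("_mitochondria.", "_cells."),
                              config$table_dialect)
    manifest$n_cells <- nrow(res$cells)
    manifest$n_mitochondria <- nrow(res$mitochondria)
    if (nrow(res$cells) >= 4) {
      qc <- flag_outlier_cells(res$cells,
                               frac_cutoff = config$qc_frac_cutoff)
      manifest$qc <- list(n_outlier_cells = sum(qc$is_outlier_cell))
    }
  }
  jsonlite::write_json(manifest, file.path(config$output, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE,
                       digits = NA)
  invisible(manifest)
}
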