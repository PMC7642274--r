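make_ellipse_image <- function(centers, semi = c(8, 11), nr = 96, nc = 96,
                               value = 210) {
  m <- matrix(0, nr, nc)
  for (i in seq_len(nrow(centers))) {
    d2 <- outer((1:nr - centers[i, 1])^2 / semi[2]^2,
                (1:nc - centers[i, 2])^2 / semi[1]^2, "+")
    m[d2 <= 1] <- value
  }
  m
}

test_that("nuclear processing finds filled, size-filtered nuclei", {
  nuc <- make_ellipse_image(rbind(c(30, 30), c(70, 65)))
  lab <- process_nuclear_channel(nuc)
  expect_equal(max(lab), 2)

  # speckles below the size filter do not add labels
  nuc2 <- nuc
  nuc2[cbind(c(5, 6, 90), c(90, 91, 5))] <- 255
  expect_equal(max(process_nuclear_channel(nuc2)), 2)

  # an interior dark hole is filled: label area matches the flood-fill
  # oracle applied to the filled shape
  nuc3 <- make_ellipse_image(rbind(c(48, 48)))
  hole <- outer((1:96 - 48)^2, (1:96 - 48)^2, "+") <= 9
  nuc3[hole] <- 0
  lab3 <- process_nuclear_channel(nuc3)
  expect_equal(max(lab3), 1)
  filled_oracle <- flood_fill_labels(make_ellipse_image(rbind(c(48, 48))) > 0)
  expect_gte(sum(lab3 > 0), 0.95 * sum(filled_oracle > 0))

  # an empty channel yields an empty labeling, not an error
  expect_equal(max(process_nuclear_channel(matrix(0, 32, 32))), 0)
})

test_that("mito background follows the population mean + 2 sd rule", {
  m <- matrix(7, 4, 4)
  mask <- matrix(TRUE, 4, 4)
  bg <- estimate_mito_background(m, mask)
  expect_equal(bg$threshold, 7)

  vals <- matrix(0, 1, 5); vals[1, ] <- 1:5
  bg2 <- estimate_mito_background(vals, matrix(TRUE, 1, 5))
  expect_equal(bg2$mean, 3)
  expect_equal(bg2$sd, sqrt(2))
  expect_equal(bg2$threshold, 3 + 2 * sqrt(2), tolerance = 1e-12)

  set.seed(4)
  draw <- matrix(rnorm(1e4, 20, 5), 100, 100)
  bg3 <- estimate_mito_background(draw, matrix(TRUE, 100, 100))
  expect_lt(abs(bg3$threshold - 30), 0.5)

  expect_error(estimate_mito_background(m, matrix(FALSE, 4, 4)),
               "synthetic nuclei|manual threshold")
})

test_that("global background removal zeroes at-or-below-threshold pixels", {
  g <- matrix(1:20, 4, 5)
  expect_equal(global_background_removal(g, 0), g)
  expect_true(all(global_background_removal(g, 255) == 0))
  set.seed(2)
  r <- matrix(sample(0:255, 200, replace = TRUE), 10, 20)
  out <- global_background_removal(r, 97)
  expect_equal(sum(out > 0), sum(r > 97))
  expect_equal(out[out > 0], r[r > 97])
})

test_that("ghost cells are exactly the nuclei without nearby signal", {
  lab <- matrix(0L, 60, 60)
  lab[10:18, 10:18] <- 1L
  lab[40:48, 40:48] <- 2L
  mito <- matrix(0, 60, 60)
  mito[20:24, 12:16] <- 80   # near nucleus 1 only
  expect_equal(detect_ghost_cells(lab, mito, radius = 10, min_content = 1), 2L)
  expect_equal(detect_ghost_cells(lab, mito, radius = 10, min_content = 1e7),
               c(1L, 2L))

  # synthetic image with 3 stained + 2 unstained cells
  g <- fix_ghosted()
  res <- catch_cells(g$image)
  truth_map <- map_truth_labels(g$truth, res$nuclei_labels)
  planted <- sort(truth_map[g$truth$cells$label[g$truth$cells$type == "ghost"]])
  expect_equal(sort(res$ghosts), planted)
})

test_that("blob groups partition all blobs by nucleus contact", {
  lab <- matrix(0L, 50, 50)
  lab[10:20, 10:20] <- 1L
  lab[10:20, 35:45] <- 2L
  mito <- matrix(0, 50, 50)
  mito[22, 15] <- 50              # tiny blob touching nucleus 1 (diagonal)
  mito[21, 15] <- 50
  mito[15, 21:34] <- 60           # filament bridging both nuclei
  mito[45, 5:10] <- 70            # distant free blob
  blobs <- extract_blobs(mito)
  blobs <- classify_mito_groups(blobs, lab, small_area_cutoff = 50)
  groups <- sort(unname(vapply(blobs, `[[`, integer(1), "group")))
  expect_equal(groups, c(1L, 2L, 3L))
  by_group <- split(blobs, vapply(blobs, `[[`, integer(1), "group"))
  expect_equal(by_group[["1"]][[1]]$touched, 1L)
  expect_equal(by_group[["2"]][[1]]$touched, c(1L, 2L))
  expect_length(by_group[["3"]][[1]]$touched, 0)
})

test_that("EM assigns well-separated clusters to their nearest nucleus", {
  lab <- matrix(0L, 80, 80)
  lab[10:20, 10:20] <- 1L
  lab[60:70, 60:70] <- 2L
  mito <- matrix(0, 80, 80)
  mito[25:30, 12:18] <- 90    # private cluster of nucleus 1
  mito[50:55, 62:68] <- 90    # private cluster of nucleus 2
  blobs <- classify_mito_groups(extract_blobs(mito), lab)
  em <- em_link_mitochondria(blobs, lab)
  expect_equal(sort(unique(em$assignment[mito > 0])), c(1L, 2L))
  expect_true(all(em$assignment[25:30, 12:18] == 1L))
  expect_true(all(em$assignment[50:55, 62:68] == 2L))
})

test_that("group 2 pixel splitting matches the per-pixel likelihood oracle", {
  lab <- matrix(0L, 60, 90)
  lab[25:35, 10:20] <- 1L
  lab[25:35, 70:80] <- 2L
  mito <- matrix(0, 60, 90)
  mito[30, 21:69] <- 100   # one filament spanning both nuclei
  blobs <- classify_mito_groups(extract_blobs(mito), lab)
  expect_equal(blobs[[1]]$group, 2L)
  em <- em_link_mitochondria(blobs, lab)

  # oracle: evaluate the full Gaussian log-density under each initial seed
  seed_of <- function(l) {
    idx <- which(lab == l)
    r <- (idx - 1) %% 60 + 1; cc <- (idx - 1) %/% 60 + 1
    mu <- c(mean(r), mean(cc))
    S <- cov(cbind(r, cc)) * (length(idx) - 1) / length(idx)
    list(mu = mu, S = S)
  }
  s1 <- seed_of(1); s2 <- seed_of(2)
  dens <- function(x, s)
    -log(2 * pi) - 0.5 * log(det(s$S)) -
      0.5 * mahalanobis(x, s$mu, s$S)
  px <- which(mito > 0)
  xy <- cbind((px - 1) %% 60 + 1, (px - 1) %/% 60 + 1)
  oracle <- ifelse(dens(xy, s1) >= dens(xy, s2), 1L, 2L)
  expect_equal(unname(em$assignment[px]), oracle)
})

test_that("EM terminates with every blob resolved on synthetic images", {
  res <- fix_separated_caught()
  bt <- res$blob_table
  expect_true(all(!is.na(bt$assigned) | bt$group == 3L))
  # partition property: each assigned mitochondrial pixel has one owner
  expect_true(all(res$assignment %in% c(0L, seq_len(max(res$nuclei_labels)))))
})

test_that("squared Mahalanobis distances match the quadratic-form oracle", {
  # the pruning cutoff is the chi-square(2) 95% quantile to two decimals
  expect_equal(round(qchisq(0.95, df = 2), 2), 5.99)

  for (seed in 1:5) {
    set.seed(seed)
    xy <- matrix(rnorm(40, sd = 3), 20, 2) %*%
      matrix(c(2, 0.7, 0.7, 1), 2, 2)
    d2 <- mahalanobis_sq(xy)
    mu <- colMeans(xy)
    S <- cov(xy) * (nrow(xy) - 1) / nrow(xy)
    oracle <- mahalanobis(xy, mu, S)
    expect_equal(d2, unname(oracle), tolerance = 1e-9)
  }
})

test_that("pruning drops only far outliers, one pass, in degenerate cases", {
  # nine coincident centroids plus one far blob: only the far blob leaves
  xy <- rbind(matrix(rep(c(10, 10), 9), ncol = 2, byrow = TRUE), c(60, 60))
  pr <- mahalanobis_prune(xy)
  expect_equal(pr$keep, c(rep(TRUE, 9), FALSE))

  # a point at squared distance just under the cutoff is retained
  set.seed(8)
  base <- matrix(rnorm(60), 30, 2)
  d2 <- mahalanobis_sq(base)
  expect_true(all(pr$d2[!pr$keep] > 5.99))
  expect_true(all(mahalanobis_prune(base)$keep[d2 <= 5.99]))

  # fewer than three mitochondria: no pruning
  expect_true(all(mahalanobis_prune(rbind(c(0, 0), c(9, 9)))$keep))
})

test_that("pruning is invariant under translation and rotation", {
  set.seed(12)
  xy <- cbind(rnorm(25, sd = 2), rnorm(25, sd = 5))
  xy[25, ] <- c(30, 40)
  base <- mahalanobis_prune(xy)
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  moved <- xy %*% R + matrix(c(100, -50), 25, 2, byrow = TRUE)
  rot <- mahalanobis_prune(moved)
  expect_equal(rot$keep, base$keep)
  expect_equal(rot$d2, base$d2, tolerance = 1e-6)
})

test_that("edge flagging reflects the clipped fraction of the cell box", {
  dims <- c(100, 100)
  # fully interior cell
  interior <- as.vector(outer(40:60, (40:60 - 1) * 100, "+"))
  expect_false(flag_edge_cell(interior, dims, 0.25))
  # cell with half its (symmetrized) box outside: rows 1..10 against the
  # top border with center on row 1
  half_out <- as.vector(outer(1:10, (40:60 - 1) * 100, "+"))
  expect_true(flag_edge_cell(half_out, dims, 0.25, center = c(1, 50)))

  # fixture: exactly the planted truncated cell is flagged
  eg <- fix_edge()
  res <- catch_cells(eg$image)
  flags <- vapply(res$cells, `[[`, logical(1), "is_bad_edge_cell")
  flagged <- as.integer(names(flags)[flags])
  truth_map <- map_truth_labels(eg$truth, res$nuclei_labels)
  edge_lab <- truth_map[eg$truth$cells$label[eg$truth$cells$type == "edge"]]
  expect_equal(flagged, unname(edge_lab))
})

test_that("single-cell export conserves assigned intensity and splits bad cells", {
  eg <- fix_edge()
  res <- catch_cells(eg$image)
  outdir <- tempfile()
  paths <- export_single_cells(eg$image, res, outdir)
  ch <- split_channels(eg$image)
  n_bad <- sum(vapply(res$cells, `[[`, logical(1), "is_bad_edge_cell"))
  expect_equal(sum(dirname(paths) == file.path(outdir, "excluded")), n_bad)
  expect_true(file.exists(file.path(outdir, "assignment_report.csv")))

  # crop intensities equal the intensities of the assigned pixel sets
  good <- Filter(function(x) !x$is_bad_edge_cell, res$cells)
  crop_files <- setdiff(paths, paths[dirname(paths) ==
                                       file.path(outdir, "excluded")])
  total_crop <- 0
  for (f in crop_files) {
    px <- png::readPNG(f) * 255
    total_crop <- total_crop + sum(px[, , 2])
  }
  total_assigned <- sum(vapply(good, function(x) sum(ch$mito[x$mito]),
                               numeric(1)))
  expect_equal(total_crop, total_assigned)
})

test_that("linking recovers planted ownership on the separated preset", {
  sep <- fix_separated()
  res <- fix_separated_caught()
  truth_map <- map_truth_labels(sep$truth, res$nuclei_labels)
  painted <- which(sep$truth$owner > 0)
  acc <- mean(res$assignment[painted] ==
                truth_map[sep$truth$owner[painted]])
  expect_gte(acc, 0.95)
})
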