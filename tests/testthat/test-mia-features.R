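feat <- function(mask) mito_features(which(mask), dim(mask))

test_that("the feature schema honors the 23+8 and 90+20 decompositions", {
  expect_length(mito_feature_names(), 31)
  expect_length(cell_feature_names(), 110)
  branch <- c("branch_count", "junction_count", "endpoint_count",
              "total_branch_length", "mean_branch_length",
              "median_branch_length", "sd_branch_length",
              "max_branch_length")
  expect_length(setdiff(mito_feature_names(), branch), 23)
  expect_true(all(branch %in% mito_feature_names()))
  agg <- grep("_(mean|median|sd)$", cell_feature_names(), value = TRUE)
  expect_length(agg, 90)
  expect_length(setdiff(cell_feature_names(), agg), 20)
  # orientation, a circular quantity, is not aggregated
  expect_false(any(grepl("^orientation_", cell_feature_names())))
})

test_that("labeling uses 8-connectivity and the min-area filter", {
  m <- matrix(FALSE, 12, 12)
  m[2:3, 2:3] <- TRUE; m[6:8, 6:8] <- TRUE; m[11, 11] <- TRUE
  expect_equal(max(label_mitochondria(m, min_area = 4)), 2)
  diagchain <- matrix(FALSE, 8, 8); diagchain[cbind(1:6, 1:6)] <- TRUE
  expect_equal(max(label_mitochondria(diagchain, min_area = 1)), 1)
  set.seed(7)
  r <- matrix(runif(625) < 0.3, 25, 25)
  expect_equal(max(label_mitochondria(r, min_area = 1)),
               max(flood_fill_labels(r)))
})

test_that("skeletons of canonical shapes have the expected topology", {
  ph <- fix_phantoms()
  bar <- skeleton_branches(skeletonize(ph$bar_20x3))
  expect_equal(bar$n_endpoints, 2)
  expect_equal(bar$n_junctions, 0)
  expect_length(bar$branch_lengths, 1)

  plus <- skeleton_branches(skeletonize(ph$plus))
  expect_equal(plus$n_junctions, 1)
  expect_equal(plus$n_endpoints, 4)
  expect_length(plus$branch_lengths, 4)

  ring <- skeleton_branches(skeletonize(ph$ring))
  expect_equal(ring$n_endpoints, 0)
  expect_equal(ring$n_junctions, 0)
  expect_length(ring$branch_lengths, 1)
  expect_gt(ring$total_length, 2 * pi * 8)   # at least the inner circumference

  # thinning preserves the component count, including compact blobs
  expect_equal(max(label_components(skeletonize(ph$disc5))), 1)
  two <- matrix(FALSE, 20, 20); two[3:5, 3:5] <- TRUE; two[14:16, 14:16] <- TRUE
  expect_equal(max(label_components(skeletonize(two))), 2)
})

test_that("disc morphometry approaches its closed forms", {
  ph <- fix_phantoms()
  d <- feat(ph$disc10)
  expect_gte(d[["solidity"]], 0.98)
  expect_lt(abs(d[["form_factor"]] - 1), 0.15)
  expect_lt(abs(d[["mean_density"]] - 10 / 3) / (10 / 3), 0.15)
  expect_lt(abs(d[["equivalent_diameter"]] - 20) / 20, 0.02)
  expect_lt(abs(d[["major_axis"]] - 20) / 20, 0.10)
  expect_gte(d[["roundness"]], 0.95)
  expect_equal(d[["max_density"]], 10, tolerance = 0.1)
})

test_that("bars and single pixels take their documented values", {
  ph <- fix_phantoms()
  bar <- feat(ph$line_1x20)
  expect_equal(bar[["aspect_ratio"]], 20, tolerance = 0.2)
  expect_equal(bar[["extent"]], 1)
  expect_equal(bar[["total_branch_length"]], 19, tolerance = 0.01)
  expect_equal(bar[["area"]], 20)

  px <- feat(ph$single_pixel)
  expect_equal(px[["perimeter"]], 4)
  expect_equal(px[["major_axis"]], 1)
  expect_equal(px[["minor_axis"]], 1)
  expect_equal(px[["orientation"]], 0)
  expect_equal(px[["branch_count"]], 0)
  expect_true(all(is.finite(px)))
})

test_that("dimensionless features are bounded on arbitrary blobs", {
  for (seed in 1:6) {
    b <- random_blob(seed)
    f <- feat(b)
    expect_true(all(is.finite(f)))
    expect_lte(f[["solidity"]], 1); expect_gt(f[["solidity"]], 0)
    expect_lte(f[["extent"]], 1); expect_gt(f[["extent"]], 0)
    expect_lte(f[["form_factor"]], 1)
    expect_gte(f[["aspect_ratio"]], 1)
    expect_true(f[["orientation"]] > -90 && f[["orientation"]] <= 90)
  }
})

test_that("box-counting dimension separates lines, areas and fractals", {
  ph <- fix_phantoms()
  expect_lt(abs(box_counting_dimension(ph$full_frame) - 2), 0.1)
  expect_lt(abs(box_counting_dimension(ph$line_1x48) - 1), 0.1)
  # the carpet is exactly self-similar at ratio 3, so the scale ladder
  # samples powers of three
  d <- box_counting_dimension(ph$sierpinski5, scales = c(3, 9, 27, 81))
  expect_lt(abs(d - log(8) / log(3)), 0.05)
  expect_warning(box_counting_dimension(ph$disc5, scales = c(2, 4, 8, 999)),
                 "trimming")
  expect_error(box_counting_dimension(matrix(FALSE, 8, 8)), "empty")
})

test_that("cell aggregation matches a brute-force recomputation", {
  ph <- fix_phantoms()
  masks <- list(ph$disc10, ph$bar_20x3, ph$ring)
  canvas <- matrix(FALSE, 140, 140)
  offs <- list(c(10, 10), c(60, 70), c(95, 30))
  for (i in 1:3) {
    m <- masks[[i]]
    canvas[offs[[i]][1] + seq_len(nrow(m)) - 1,
           offs[[i]][2] + seq_len(ncol(m)) - 1] <- m
  }
  labs <- label_mitochondria(canvas)
  rows <- do.call(rbind, lapply(split(which(labs > 0), labs[labs > 0]),
                                mito_features, dims = dim(canvas)))
  rows <- as.data.frame(rows)
  cf <- cell_features(rows, labs > 0)
  for (f in c("area", "perimeter", "solidity", "branch_count")) {
    expect_equal(cf[[paste0(f, "_mean")]], mean(rows[[f]]))
    expect_equal(cf[[paste0(f, "_median")]], median(rows[[f]]))
    expect_equal(cf[[paste0(f, "_sd")]],
                 sqrt(mean((rows[[f]] - mean(rows[[f]]))^2)))
  }
  expect_equal(cf[["mito_count"]], 3)
  expect_equal(cf[["net_area"]], sum(canvas))
  expect_equal(cf[["net_skeleton_length"]], sum(rows$total_branch_length))
  expect_equal(cf[["largest_area_fraction"]], max(rows$area) / sum(rows$area))
})

test_that("single-mitochondrion cells degrade gracefully", {
  ph <- fix_phantoms()
  labs <- label_mitochondria(ph$disc10)
  row <- as.data.frame(t(mito_features(which(labs == 1), dim(labs))))
  cf <- cell_features(row, labs > 0)
  expect_equal(cf[["area_mean"]], row$area)
  expect_equal(cf[["area_median"]], row$area)
  expect_equal(cf[["area_sd"]], 0)
  expect_equal(cf[["mean_nn_distance"]], 0)
  expect_equal(cf[["net_solidity"]], row$solidity, tolerance = 0.02)
  expect_true(all(is.finite(cf)))
})

test_that("two distant discs keep mito means but dilute network solidity", {
  disc <- fix_phantoms()$disc10
  canvas <- matrix(FALSE, 160, 160)
  canvas[10 + seq_len(nrow(disc)) - 1, 10 + seq_len(ncol(disc)) - 1] <- disc
  canvas[120 + seq_len(nrow(disc)) - 1, 120 + seq_len(ncol(disc)) - 1] <- disc
  labs <- label_mitochondria(canvas)
  rows <- as.data.frame(do.call(rbind,
    lapply(split(which(labs > 0), labs[labs > 0]), mito_features,
           dims = dim(labs))))
  cf <- cell_features(rows, labs > 0)
  expect_equal(cf[["area_mean"]], sum(disc))
  expect_lt(cf[["net_solidity"]], rows$solidity[1] / 2)
})

test_that("features scale correctly under resolution doubling and rotation", {
  # a disc rendered at double resolution is the disc of double radius:
  # areas scale by 4, lengths by 2, dimensionless features stay put
  ph <- fix_phantoms()
  f1 <- feat(ph$disc10)
  f2 <- feat(ph$disc20)
  expect_lt(abs(f2[["area"]] / f1[["area"]] - 4) / 4, 0.05)
  expect_lt(abs(f2[["perimeter"]] / f1[["perimeter"]] - 2) / 2, 0.05)
  expect_lt(abs(f2[["major_axis"]] / f1[["major_axis"]] - 2) / 2, 0.05)
  for (nm in c("solidity", "extent", "form_factor", "aspect_ratio"))
    expect_lt(abs(f2[[nm]] - f1[[nm]]) / f1[[nm]], 0.05)

  rot <- t(ph$bar_20x3)[ncol(ph$bar_20x3):1, ]   # 90 degree rotation
  f3 <- feat(rot); f0 <- feat(ph$bar_20x3)
  for (nm in c("area", "perimeter", "solidity", "extent", "form_factor",
               "aspect_ratio", "eccentricity"))
    expect_lt(abs(f3[[nm]] - f0[[nm]]) / max(f0[[nm]], 1e-9), 0.10)

  # and on an irregular blob the 90-degree rotation is exact as well
  b <- random_blob(3)
  fb <- feat(b); fr <- feat(t(b)[ncol(b):1, ])
  for (nm in c("area", "perimeter", "solidity", "form_factor"))
    expect_equal(fr[[nm]], fb[[nm]])
})

test_that("mask analysis produces validated, reproducible tables", {
  ph <- fix_phantoms()
  masks <- list(c1 = ph$disc10, c2 = ph$plus, c3 = matrix(FALSE, 16, 16))
  res <- analyze_masks(masks)
  expect_equal(ncol(res$mitochondria), 33)  # cell_id, mito_id + 31
  expect_equal(ncol(res$cells), 112)        # cell_id, empty_network + 110
  expect_equal(nrow(res$cells), 3)
  expect_equal(res$cells$empty_network, c(0, 0, 1))
  expect_true(all(vapply(res$cells[-1], function(x) all(is.finite(x)),
                         logical(1))))
  # an empty-network cell emits an all-zero feature row, not a dropout
  expect_true(all(unlist(res$cells[3, -(1:2)]) == 0))

  # rerun is byte-identical through the file interface
  d <- tempfile(); dir.create(d)
  for (nm in c("c1", "c2")) write_image(masks[[nm]],
                                        file.path(d, paste0(nm, ".png")))
  out1 <- tempfile(); out2 <- tempfile()
  analyze_directory(d, out1, "csv")
  analyze_directory(d, out2, "csv")
  expect_identical(readLines(paste0(out1, "_cells.csv")),
                   readLines(paste0(out2, "_cells.csv")))
  expect_identical(readLines(paste0(out1, "_mitochondria.csv")),
                   readLines(paste0(out2, "_mitochondria.csv")))
})

test_that("painted fixture areas are conserved through the feature table", {
  sep <- fix_separated()
  own <- sep$truth$owner
  masks <- lapply(sort(unique(own[own > 0])), function(l) own == l)
  names(masks) <- paste0("cell", seq_along(masks))
  res <- analyze_masks(masks, min_blob_area = 1)
  got <- res$cells$net_area
  truth <- vapply(masks, sum, numeric(1))
  expect_equal(unname(got), unname(truth))
})
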