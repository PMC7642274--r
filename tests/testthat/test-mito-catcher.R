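test_that("preprocessing removes flat background and salt noise", {
  flat <- matrix(120, 64, 64)
  out <- preprocess_mito(flat, preprocess_params(median_radius = 0))
  expect_true(all(out == 0))

  hot <- matrix(0, 32, 32); hot[16, 16] <- 255
  out2 <- preprocess_mito(hot, preprocess_params(tophat_radius = 0,
                                                 median_radius = 1))
  expect_equal(out2[16, 16], 0)

  # CLAHE path runs and keeps dimensions
  out3 <- preprocess_mito(matrix(runif(64 * 64) * 255, 64, 64),
                          preprocess_params(clahe = TRUE))
  expect_equal(dim(out3), c(64, 64))
})

test_that("background model reproduces hand-computed fences and thresholds", {
  const <- matrix(9, 5, 5)
  bm <- fit_background(const, matrix(TRUE, 5, 5))
  expect_equal(bm$q1, 9); expect_equal(bm$q3, 9)
  expect_equal(bm$global_threshold, 9)

  # ten 5s and one 200: the 200 is fenced out, threshold collapses to 5
  v <- matrix(c(rep(5, 10), 200), 1, 11)
  bm2 <- fit_background(v, matrix(TRUE, 1, 11))
  expect_equal(bm2$q1, 5); expect_equal(bm2$q3, 5); expect_equal(bm2$iqr, 0)
  expect_equal(bm2$n_inliers, 10)
  expect_equal(bm2$global_threshold, 5)

  # quartiles follow linear interpolation between order statistics
  v3 <- matrix(c(1, 2, 3, 4, 5, 6, 7, 100), 1, 8)
  bm3 <- fit_background(v3, matrix(TRUE, 1, 8))
  expect_equal(bm3$q1, unname(quantile(c(1:7, 100), 0.25, type = 7)))

  expect_error(fit_background(const, matrix(FALSE, 5, 5)),
               "manual threshold")
})

test_that("the inlier fence matches a brute-force filter", {
  for (seed in 1:4) {
    set.seed(seed)
    vals <- c(rnorm(300, 20, 4), runif(12, 100, 255))
    m <- matrix(vals, 1)
    bm <- fit_background(m, matrix(TRUE, 1, length(vals)))
    q <- quantile(vals, c(0.25, 0.75), type = 7)
    fence <- c(q[1] - 1.5 * (q[2] - q[1]), q[2] + 1.5 * (q[2] - q[1]))
    inl <- vals[vals >= fence[1] & vals <= fence[2]]
    expect_equal(bm$n_inliers, length(inl))
    expect_equal(bm$clean_mean, mean(inl))
    expect_equal(bm$global_threshold,
                 min(mean(inl) + 2 * sqrt(mean((inl - mean(inl))^2)), 255))
  }
})

test_that("global binarization obeys the threshold exactly", {
  g <- matrix(sample(0:255, 400, replace = TRUE), 20, 20)
  model <- structure(list(global_threshold = 300, clean_mean = 0,
                          clean_sd = 0), class = "background_model")
  expect_false(any(binarize_global(g, model)))
  model$global_threshold <- 0
  expect_equal(sum(binarize_global(g, model)), sum(g > 0))
  model$global_threshold <- 123
  expect_equal(sum(binarize_global(g, model)), sum(g > 123))
  # monotonicity: raising the threshold never adds foreground
  m1 <- binarize_global(g, structure(list(global_threshold = 50),
                                     class = "background_model"))
  m2 <- binarize_global(g, structure(list(global_threshold = 120),
                                     class = "background_model"))
  expect_true(all(m1 | !m2))
})

test_that("logistic correction is pinned, bounded and monotone", {
  x0 <- 20; k <- 0.3; lo <- -4; hi <- 6
  expect_identical(logistic_correction(x0, x0, k, lo, hi), 0)
  xs <- seq(-50, 90, by = 0.5)
  cor <- logistic_correction(xs, x0, k, lo, hi, offset = 2)
  expect_true(all(diff(cor) >= 0))
  expect_true(all(cor >= (lo - hi) / 2 - 1e-12))
  expect_true(all(cor <= (hi - lo) / 2 + 1e-12))

  # independent evaluation of the generalized logistic formula
  raw <- function(z, nu) lo + (hi - lo) / (1 + exp(-k * (z - x0)))^(1 / nu)
  for (nu in c(1, 2)) {
    expect_equal(logistic_correction(xs, x0, k, lo, hi, nu = nu),
                 raw(xs, nu) - raw(x0, nu), tolerance = 1e-12)
  }
})

test_that("AdaMM tiles partition the image and thresholds match the formula", {
  set.seed(5)
  img <- matrix(runif(96 * 80, 0, 60), 96, 80)
  img[10:20, 5:15] <- 0  # one empty tile region will stay occupied=FALSE?
  model <- fit_background(img, matrix(TRUE, 96, 80))
  lg <- logistic_params(k = 0.2, asym_low = -3, asym_high = 5)
  mask <- adamm_segment(img, model, tile_size = 16, logistic = lg)
  tiles <- attr(mask, "tiles")
  # partition: tile areas tile the full image exactly once
  expect_equal(sum((tiles$row1 - tiles$row0 + 1) *
                   (tiles$col1 - tiles$col0 + 1)), 96 * 80)
  # per-tile threshold equals an independent logistic evaluation
  raw <- function(z) -3 + (5 - -3) / (1 + exp(-0.2 * (z - model$clean_mean)))
  occ <- tiles[tiles$occupied, ]
  expect_equal(occ$threshold,
               model$global_threshold + raw(occ$mean) - raw(model$clean_mean),
               tolerance = 1e-9)
  # reassembly: every foreground pixel exceeds its own tile threshold
  for (i in sample(nrow(occ), 10)) {
    tl <- img[occ$row0[i]:occ$row1[i], occ$col0[i]:occ$col1[i]]
    sub <- mask[occ$row0[i]:occ$row1[i], occ$col0[i]:occ$col1[i]]
    expect_equal(sub, tl > occ$threshold[i])
  }
})

test_that("AdaMM degenerates to the global threshold when it should", {
  set.seed(6)
  img <- matrix(runif(64 * 64, 0, 40), 64, 64)
  model <- fit_background(img, matrix(TRUE, 64, 64))

  # zero asymptotes: identical to global thresholding
  lg0 <- logistic_params(asym_low = 0, asym_high = 0)
  expect_equal(unclass(adamm_segment(img, model, 16, lg0))[, ],
               unclass(binarize_global(img, model))[, ],
               ignore_attr = TRUE)

  # constant image: every tile mean equals the background mean, so no tile
  # is corrected
  cimg <- matrix(30, 64, 64)
  cmodel <- fit_background(cimg, matrix(TRUE, 64, 64))
  mask_c <- adamm_segment(cimg, cmodel, 16, logistic_params())
  tiles <- attr(mask_c, "tiles")
  expect_true(all(abs(tiles$threshold - cmodel$global_threshold) < 1e-12))

  # tile size exceeding the image: single-tile fallback = global threshold
  big <- adamm_segment(img, model, tile_size = 128)
  expect_equal(unclass(big)[, ], unclass(binarize_global(img, model))[, ],
               ignore_attr = TRUE)

  # empty tiles binarize to all-background
  img2 <- img; img2[1:16, 1:16] <- 0
  m2 <- adamm_segment(img2, model, 16,
                      logistic_params(asym_low = -100, asym_high = 0))
  expect_false(any(m2[1:16, 1:16]))
})

test_that("segment_cell is deterministic and empty on nucleus-only images", {
  sc <- generate_single_cell(seed = 31, snr = 6)
  a <- segment_cell(sc$image, nucleus_mask = sc$nucleus_mask)
  b <- segment_cell(sc$image, nucleus_mask = sc$nucleus_mask)
  expect_identical(a$mask, b$mask)
  # the nucleus interior is excluded from the network mask
  expect_false(any(a$mask & sc$nucleus_mask))

  blank <- merge_channels(make_blank_nucleus(), matrix(0, 96, 96), "green")
  seg <- segment_cell(blank)
  expect_equal(sum(seg$mask), 0)
})

test_that("segmentation recovers the painted network on clean fixtures", {
  cfg <- mito_catcher_config(preprocess = preprocess_params(median_radius = 0))
  for (s in c(3, 8, 21)) {
    sc <- generate_single_cell(seed = s, snr = Inf)
    seg <- segment_cell(sc$image, cfg, nucleus_mask = sc$nucleus_mask)
    ov <- compare_masks(seg$mask, sc$truth_mask)$effective_overlap
    expect_gte(ov, 0.95)
  }
})
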