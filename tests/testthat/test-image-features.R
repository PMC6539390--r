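test_that("preprocessing recovers the rendered spots as 12 components", {
  pair <- render_image_pair(rep(0, 36), seed = 1)
  mask <- preprocess(pair$before)
  lab <- EBImage::bwlabel(t(mask))
  expect_equal(max(lab), 12L)

  # uniform black image: empty mask with a no-spots condition
  black <- array(0L, dim = c(60, 60, 3))
  expect_warning(m <- preprocess(black), class = "odsensor_no_spots")
  expect_false(any(m))

  # a single disc keeps its area through the pipeline (within 5% of pi r^2)
  img <- array(10L, dim = c(101, 101, 3))
  dm <- (outer((1:101 - 51)^2, (1:101 - 51)^2, `+`) <= 400)
  for (ch in 1:3) { p <- img[, , ch]; p[dm] <- 200L; img[, , ch] <- p }
  m1 <- preprocess(img)
  expect_lt(abs(sum(m1) - pi * 400) / (pi * 400), 0.05)
})

test_that("preprocessing is idempotent on its own output", {
  pair <- render_image_pair(simulate_feature_vector(3, seed = 1), seed = 2)
  mask <- preprocess(pair$before)
  as_img <- array(as.integer(mask) * 255L, dim = c(dim(mask), 3L))
  expect_equal(preprocess(as_img), mask)
})

test_that("spot localization finds rendered centers within 1 px, row-major", {
  layout <- sensor_layout()
  pair <- render_image_pair(rep(0, 36), layout, seed = 4)
  spots <- locate_spots(preprocess(pair$before))
  expect_equal(spots$dye, sensor_dyes())
  expect_lt(max(abs(spots$x - layout$spot_centers[, "x"])), 1)
  expect_lt(max(abs(spots$y - layout$spot_centers[, "y"])), 1)

  # random geometries: centers recovered within 1 px across layouts
  set.seed(42)
  for (i in 1:20) {
    lay <- sensor_layout(spacing = sample(55:70, 1), margin = sample(25:35, 1),
                         spot_radius_render = sample(17:21, 1))
    p <- render_image_pair(rep(0, 36), lay, seed = i)
    sp <- locate_spots(preprocess(p$before))
    expect_lt(max(abs(sp$x - lay$spot_centers[, "x"]),
                  abs(sp$y - lay$spot_centers[, "y"])), 1)
  }
})

test_that("localization falls back to the layout hint when spots are missing", {
  layout <- sensor_layout()
  pair <- render_image_pair(rep(0, 36), layout, seed = 4)
  mask <- preprocess(pair$before)
  # erase one spot from the mask
  cx <- unname(layout$spot_centers[5, "x"])
  cy <- unname(layout$spot_centers[5, "y"])
  mask[abs(row(mask) - cy) < 25 & abs(col(mask) - cx) < 25] <- FALSE
  expect_error(locate_spots(mask), "11")
  sp <- locate_spots(mask, layout_hint = layout)
  expect_equal(nrow(sp), 12L)
  expect_equal(sp$x[5], cx)
  expect_equal(sp$y[5], cy)
  # the other spots still come from their centroids, in order
  expect_lt(max(abs(sp$x[-5] - layout$spot_centers[-5, "x"])), 1)
})

test_that("circular ROI means match the brute-force pixel oracle", {
  # constant image is exact
  img <- array(0L, dim = c(40, 40, 3))
  img[, , 1] <- 10L; img[, , 2] <- 20L; img[, , 3] <- 30L
  expect_equal(roi_mean_rgb(img, 20, 20, 10), c(R = 10, G = 20, B = 30))

  # radius-15 membership (inclusive boundary, integer centers) matches an
  # exhaustive lattice enumeration
  cnt <- 0
  for (yy in 1:64) for (xx in 1:64)
    if ((xx - 32)^2 + (yy - 32)^2 <= 225) cnt <- cnt + 1
  expect_equal(sum(odsensor:::disc_mask(32, 32, 15, 64, 64)), cnt)

  # random images and ROIs: exact agreement with the enumeration oracle
  set.seed(7)
  for (i in 1:25) {
    w <- sample(40:70, 1); h <- sample(40:70, 1); r <- sample(3:15, 1)
    im <- array(sample(0:255, w * h * 3, replace = TRUE), dim = c(h, w, 3))
    roi <- random_roi(w, h, r)
    expect_identical(roi_mean_rgb(im, roi$x, roi$y, r),
                     roi_mean_oracle(im, roi$x, roi$y, r))
  }

  # a disc straddling a two-tone boundary is still exact
  tt <- array(0L, dim = c(50, 50, 3)); tt[, 26:50, ] <- 200L
  expect_identical(roi_mean_rgb(tt, 25, 25, 10), roi_mean_oracle(tt, 25, 25, 10))

  expect_error(roi_mean_rgb(img, 5, 20, 10), "clipped")
})

test_that("feature extraction is a faithful inverse of rendering", {
  # identical pair: zero vector
  pair0 <- render_image_pair(rep(0, 36), seed = 2)
  expect_equal(max(abs(extract_features(pair0))), 0)

  # round trip within 1 gray level per component
  set.seed(31)
  for (i in 1:10) {
    v <- simulate_feature_vector(runif(1, 0.1, 9), seed = i)
    pair <- render_image_pair(v, seed = 100 + i)
    got <- extract_features(pair)
    expect_lt(max(abs(got - v)), 1)
  }

  # swapping before and after negates every component
  v <- simulate_feature_vector(5, seed = 77)
  pair <- render_image_pair(v, seed = 78)
  swapped <- structure(list(before = pair$after, after = pair$before,
                            layout = pair$layout), class = "image_pair")
  expect_equal(extract_features(swapped), -extract_features(pair),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("the difference map normalizes per-spot responses for display", {
  pair0 <- render_image_pair(rep(0, 36), seed = 3)
  expect_true(all(difference_map(pair0) == 0))

  v <- numeric(36); v[14] <- 40  # TPPCu:G
  pair <- render_image_pair(v, seed = 5)
  dm <- difference_map(pair)
  expect_equal(max(dm[, , 2]), 255)          # the G channel of spot 5 saturates
  expect_true(all(dm[, , c(1, 3)] <= 1))     # everything else stays black
                                             # (within rounding of render noise)
  # scale invariance: proportional responses give identical maps
  v2 <- numeric(36); v2[14] <- 80
  dm2 <- difference_map(render_image_pair(v2, seed = 5))
  expect_equal(dm2[, , 2] == 255, dm[, , 2] == 255)
})

test_that("image pairs survive a PNG round trip", {
  skip_if_not_installed("png")
  v <- simulate_feature_vector(4, seed = 12)
  pair <- render_image_pair(v, seed = 13)
  dir <- file.path(tempdir(), "pairio")
  on.exit(unlink(dir, recursive = TRUE))
  write_image_pair(pair, dir, "S001")
  back <- read_image_pair(file.path(dir, "S001_pre.png"),
                          file.path(dir, "S001_post.png"),
                          layout = pair$layout)
  expect_identical(back$before, pair$before)
  expect_identical(back$after, pair$after)
  expect_lt(max(abs(extract_features(back) - v)), 1)
})
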