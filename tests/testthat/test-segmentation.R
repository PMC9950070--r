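# Adaptive thresholding, mask cleanup, watershed splitting, blob analysis.

test_that("the default neighborhood follows the per-dimension window formula", {
  expect_identical(default_neighborhood(c(1280, 1024)), c(161L, 129L))
  expect_identical(default_neighborhood(c(16, 16)), c(3L, 3L))
  expect_identical(default_neighborhood(c(15, 15)), c(1L, 1L))
})

test_that("a flat field thresholds to an empty mask for every statistic", {
  img <- matrix(0.7, 40, 40)
  for (s in c("median", "mean", "gaussian")) {
    m <- adaptive_threshold(img, threshold_params(statistic = s,
                                                  neighborhood = c(15, 15)))
    expect_false(any(m), info = s)
  }
})

test_that("local statistics agree with direct computation on an interior window", {
  set.seed(42)
  img <- matrix(runif(900), 30, 30)
  st_mean <- local_statistic(img, "mean", c(5, 5))
  expect_equal(st_mean[15, 15], mean(img[13:17, 13:17]), tolerance = 1e-12)
  st_med <- local_statistic(img, "median", c(5, 5))
  q <- round(img * 255)
  win <- sort(q[13:17, 13:17])
  expect_equal(st_med[15, 15] * 255, win[[13]])  # lower median of 25 values
})

test_that("a dark disc on a bright field segments with high overlap, shaded or not", {
  jac <- vapply(c(0, 0.2), function(g) {
    out <- render_scene(disc_scene(radius = 20, size = 256, gradient = g))
    p <- threshold_params(neighborhood = c(65, 65))
    raw <- adaptive_threshold(out$image, p)
    # foreground must cover the disc interior (eroded truth)
    interior <- EBImage::erode(out$mask * 1, EBImage::makeBrush(5, "disc")) > 0
    cleaned <- clean_mask(raw, 6)
    expect_true(all(cleaned[interior]))
    jaccard(cleaned, out$mask)
  }, numeric(1))
  expect_gte(jac[1], 0.9)
  expect_gte(jac[2], 0.9)
  # shading invariance: within 0.02 of the unshaded overlap
  expect_lt(abs(jac[1] - jac[2]), 0.02)
})

test_that("neighborhoods larger than the image clamp with a warning", {
  img <- matrix(runif(100), 10, 10)
  expect_warning(adaptive_threshold(img, threshold_params(neighborhood = c(21, 21))),
                 "clamp")
})

test_that("clean_mask fills holes, removes specks and preserves smooth blobs", {
  m <- matrix(FALSE, 80, 80)
  m[(row(m) - 40)^2 + (col(m) - 40)^2 <= 30^2] <- TRUE
  holed <- m
  holed[39:41, 39:41] <- FALSE                  # 3 px hole
  expect_true(all(clean_mask(holed, 6)[39:41, 39:41]))
  speck <- matrix(FALSE, 40, 40)
  speck[10, 10:11] <- TRUE                      # 2 px speck
  expect_false(any(clean_mask(speck, 6)))
  # opening is nearly the identity on a smooth disc
  cleaned <- clean_mask(m, 6)
  expect_lt(abs(sum(cleaned) - sum(m)) / sum(m), 0.02)
})

test_that("border-touching holes are filled via the padding trick", {
  m <- matrix(TRUE, 30, 30)
  m[1:5, 10:15] <- FALSE    # bay open to the top border only
  filled <- clean_mask(m, 0)
  expect_true(all(filled))
})

test_that("watershed splits touching discs but leaves single blobs intact", {
  two <- matrix(FALSE, 40, 60)
  two[(row(two) - 20)^2 + (col(two) - 19)^2 <= 15^2] <- TRUE
  two[(row(two) - 20)^2 + (col(two) - 44)^2 <= 15^2] <- TRUE
  expect_equal(nrow(blob_analysis(two)), 1)     # they touch
  split <- split_touching(two, 1)
  expect_equal(nrow(blob_analysis(split)), 2)
  one <- matrix(FALSE, 40, 40)
  one[(row(one) - 20)^2 + (col(one) - 20)^2 <= 15^2] <- TRUE
  expect_equal(nrow(blob_analysis(split_touching(one, 1))), 1)
  empty <- matrix(FALSE, 10, 10)
  expect_identical(split_touching(empty), empty)
  # splitting never adds foreground
  expect_true(all(two[split] | !split[split]))
  expect_lte(sum(split), sum(two))
})

test_that("blob analysis returns closed-form properties and honours min_area", {
  m <- matrix(FALSE, 20, 20)
  m[6:15, 6:15] <- TRUE                        # 10x10 square at (5,5) 0-based
  b <- blob_analysis(m)
  expect_equal(b$area, 100L)
  expect_equal(c(b$cx, b$cy), c(9.5, 9.5))
  expect_equal(c(b$x, b$y, b$w, b$h), c(5L, 5L, 10L, 10L))
  m2 <- matrix(FALSE, 40, 40)
  m2[2:10, 2:12] <- TRUE                        # 9 x 11 = 99 px
  m2[25:34, 25:34] <- TRUE                      # 100 px
  b2 <- blob_analysis(m2, min_area = 100)
  expect_equal(nrow(b2), 1)
  expect_equal(b2$area, 100L)
  expect_equal(nrow(blob_analysis(matrix(FALSE, 5, 5))), 0)
})

test_that("blob analysis agrees with a flood-fill oracle on random masks", {
  for (s in 1:25) {
    set.seed(s)
    m <- matrix(runif(32 * 32) < 0.35, 32, 32)
    got <- blob_analysis(m)
    want <- flood_fill_blobs(m)
    expect_equal(nrow(got), nrow(want), info = paste("seed", s))
    expect_equal(got$area, want$area, info = paste("seed", s))
    expect_equal(got$cx, want$cx, info = paste("seed", s))
    expect_equal(got$cy, want$cy, info = paste("seed", s))
    expect_equal(got$x, want$x, info = paste("seed", s))
    expect_equal(got$w, want$w, info = paste("seed", s))
  }
})

test_that("segment_frame recovers the true cell count on synthetic scenes", {
  sc <- random_scene(20, c(384, 384), seed = 11)
  fr <- render_scene(sc)
  expect_equal(nrow(segment_frame(fr$image)), 20)
  expect_equal(nrow(segment_frame(matrix(0.85, 128, 128))), 0)
  # a deliberately touching pair is split back to two cells
  cells <- dplyr::bind_rows(cell_spec("S", 60, 64), cell_spec("S", 87, 64))
  tf <- render_scene(scene_spec(c(128, 160), cells, seed = 5))
  expect_equal(nrow(segment_frame(tf$image, threshold_params(neighborhood = c(65, 65)))), 2)
})

test_that("threshold parameters round-trip through YAML", {
  p <- threshold_params(statistic = "gaussian", neighborhood = c(33, 65),
                        sensitivity = 0.02, h_minima = 2)
  f <- withr::local_tempfile(fileext = ".yaml")
  write_threshold_params(p, f)
  expect_equal(read_threshold_params(f), p)
})

test_that("masks stay binary through the whole chain", {
  out <- render_scene(disc_scene(radius = 16, size = 128))
  m <- adaptive_threshold(out$image, threshold_params(neighborhood = c(17, 17)))
  expect_type(m, "logical")
  expect_type(clean_mask(m), "logical")
  expect_type(split_touching(clean_mask(m)), "logical")
})
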