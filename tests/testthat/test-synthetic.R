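# The fixture generator: rendering, ground truth, noise, sequences, wells.

test_that("empty scenes render flat backgrounds with empty truth", {
  out <- render_scene(scene_spec(c(32, 48), background_level = 0.8, seed = 1))
  expect_equal(dim(out$image), c(32, 48))
  expect_true(all(out$image == 0.8))
  expect_false(any(out$mask))
  expect_equal(nrow(out$blobs), 0)
})

test_that("a rendered disc matches its analytic area and mask equals truth", {
  out <- render_scene(disc_scene(radius = 20, size = 96))
  expect_equal(nrow(out$blobs), 1)
  expect_lt(abs(out$blobs$area - pi * 20^2) / (pi * 20^2), 0.05)
  expect_equal(out$blobs$area, sum(out$mask))
  expect_false(out$blobs$overlapping)
  # centroid at the specified centre
  expect_equal(out$blobs$x, 48, tolerance = 0.02)
  expect_equal(out$blobs$y, 48, tolerance = 0.02)
})

test_that("rendering is byte-identical under a fixed seed", {
  sp <- scene_spec(c(64, 64), cell_spec("E2", 32, 32),
                   noise = noise_spec("gaussian", 0.001), seed = 99)
  a <- render_scene(sp); b <- render_scene(sp)
  expect_identical(a$image, b$image)
  expect_identical(a$mask, b$mask)
})

test_that("cell centres outside the frame reject the spec", {
  expect_error(scene_spec(c(64, 64), cell_spec("D", 100, 10)), "inside")
})

test_that("overlapping cells are flagged and blob areas sum to the mask otherwise", {
  cells <- dplyr::bind_rows(cell_spec("S", 20, 20), cell_spec("S", 26, 20))
  out <- render_scene(scene_spec(c(64, 64), cells, seed = 1))
  expect_true(all(out$blobs$overlapping))
  cells2 <- dplyr::bind_rows(cell_spec("S", 18, 18), cell_spec("S", 46, 46))
  out2 <- render_scene(scene_spec(c(64, 64), cells2, seed = 1))
  expect_false(any(out2$blobs$overlapping))
  expect_equal(sum(out2$blobs$area), sum(out2$mask))
})

test_that("noise: level zero is identity, variance matches, seeds reproduce", {
  img <- matrix(0.5, 200, 200)
  expect_identical(add_noise(img, noise_spec("gaussian", 0)), img)
  noisy <- add_noise(img, noise_spec("gaussian", 0.01), seed = 3)
  expect_equal(var(as.numeric(noisy)), 0.01, tolerance = 0.1)
  expect_identical(noisy, add_noise(img, noise_spec("gaussian", 0.01), seed = 3))
  sp <- add_noise(img, noise_spec("speckle", 0.004), seed = 5)
  # multiplicative: variance scales with the squared signal
  expect_equal(var(as.numeric(sp)), 0.25 * 0.004, tolerance = 0.1)
  expect_error(noise_spec("gaussian", -1), "non-negative")
})

test_that("sequences obey the constant-velocity kinematics and exit rule", {
  sp <- scene_spec(c(64, 64), cell_spec("D", 32, 32), seed = 2)
  st <- render_sequence(sp, 5, jitter_sd = 0)
  expect_equal(unique(st$truth$x), 32)
  mv <- scene_spec(c(64, 128), cell_spec("D", 10, 32, vx = 2), seed = 2)
  tr <- render_sequence(mv, 10, jitter_sd = 0)$truth
  expect_equal(tr$x, 10 + 2 * (0:9))
  # exits at the right edge and never comes back
  ex <- render_sequence(scene_spec(c(32, 32), cell_spec("S", 28, 16, vx = 5),
                                   seed = 1), 6, jitter_sd = 0)$truth
  expect_false(any(ex$present[2:6]))
})

test_that("a 1024-frame longitudinal run yields a full-length ground-truth track", {
  sp <- scene_spec(c(48, 48), cell_spec("SE", 24, 24), seed = 8)
  tr <- render_sequence(sp, 1024, jitter_sd = 0.3)$truth
  expect_equal(nrow(tr), 1024)
  expect_true(all(tr$present))
})

test_that("well scenes confine cells and render one rim per well", {
  wells <- tibble::tibble(x = c(10, 110, 10, 110), y = c(10, 10, 110, 110),
                          w = 80, h = 80)
  cells <- dplyr::bind_rows(
    cell_spec("D", 50, 50), cell_spec("S", 150, 50),
    cell_spec("E2", 50, 150), cell_spec("ST", 150, 150))
  ws <- render_well_scene(scene_spec(c(200, 200), cells, seed = 3), wells)
  expect_equal(max(EBImage::bwlabel(ws$well_mask * 1)), 4)
  expect_equal(length(ws$cell_masks), 4)
  expect_true(all(vapply(ws$cell_masks, sum, numeric(1)) > 0))
  # a 170 x 170 padded crop of any well contains its full cell mask
  expect_true(all(wells$w <= 170 & wells$h <= 170))
  expect_error(
    render_well_scene(scene_spec(c(200, 200), cell_spec("D", 5, 100), seed = 1),
                      wells),
    "inside a well")
  expect_error(
    render_well_scene(scene_spec(c(200, 200), seed = 1),
                      tibble::tibble(x = c(0, 20), y = c(0, 10), w = 40, h = 40)),
    "overlap")
})

test_that("class geometry ordering is visible in rendered cell sizes", {
  geom <- class_geometry()
  d_mean <- numeric(7); names(d_mean) <- rbc_classes()
  for (cl in rbc_classes()) {
    areas <- vapply(1:100, function(i) {
      g <- geom[match(cl, as.character(geom$class)), ]
      sp <- scene_spec(c(64, 64),
                       cell_spec(cl, 32, 32,
                                 base_radius = g$base_radius * 0.7 *
                                   (1 + 0.02 * ((i %% 5) - 2))),
                       seed = i)
      render_scene(sp)$blobs$area
    }, numeric(1))
    d_mean[cl] <- mean(2 * sqrt(areas / pi))
  }
  # D ~ E1 > E2 > ST > E3 > SE ~ S
  expect_lt(abs(d_mean["D"] - d_mean["E1"]) / d_mean["D"], 0.03)
  expect_gt(d_mean["E1"], d_mean["E2"])
  expect_gt(d_mean["E2"], d_mean["ST"])
  expect_gt(d_mean["ST"], d_mean["E3"])
  expect_gt(d_mean["E3"], d_mean["SE"])
  expect_lt(abs(d_mean["SE"] - d_mean["S"]) / d_mean["S"], 0.03)
})

test_that("crop sets honour per-class counts and are reproducible", {
  crops <- render_crop_set(c(D = 5, E2 = 3), crop_size = 48, seed = 4)
  expect_equal(as.integer(table(crops$class)[c("D", "E2")]), c(5L, 3L))
  crops2 <- render_crop_set(c(D = 5, E2 = 3), crop_size = 48, seed = 4)
  expect_identical(crops$image, crops2$image)
})
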