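# Score algebra, imbalance handling, focal loss, augmentation and the
# trainable members.

unit_scores <- function(k) { p <- rep(0, 7); p[k] <- 1; p }

test_that("ensemble averaging is the unweighted mean with canonical tie-break", {
  one <- c(0.1, 0.2, 0.3, 0.1, 0.1, 0.1, 0.1)
  expect_equal(as.numeric(ensemble_average(list(one))), one)
  tie <- ensemble_average(rbind(unit_scores(1), unit_scores(2)))
  expect_equal(as.numeric(tie[1:2]), c(0.5, 0.5))
  expect_equal(predicted_class(tie), "D")       # canonical order wins ties
  # an under-confident wrong member is outvoted by a confident correct one
  weak_wrong <- c(0.4, 0.3, 0.3, 0, 0, 0, 0) ; weak_wrong <- weak_wrong / sum(weak_wrong)
  strong_right <- c(0.05, 0.9, 0.05, 0, 0, 0, 0)
  avg <- ensemble_average(rbind(weak_wrong, strong_right))
  expect_equal(predicted_class(avg), "E1")
  expect_error(ensemble_average(list()), "at least one")
})

test_that("averaged scores stay distributions and are order-invariant", {
  set.seed(1)
  for (i in 1:20) {
    m <- matrix(rexp(4 * 7), 4, 7); m <- m / rowSums(m)
    avg <- ensemble_average(m)
    expect_equal(sum(avg), 1, tolerance = 1e-9)
    expect_true(all(avg >= 0))
    perm <- ensemble_average(m[sample(4), ])
    expect_equal(as.numeric(avg), as.numeric(perm))
  }
})

test_that("moving averages window correctly and tolerate gap markers", {
  h <- matrix(rep(unit_scores(3), 150), ncol = 7, byrow = TRUE)
  expect_equal(as.numeric(moving_average_scores(h)), unit_scores(3))
  expect_equal(as.numeric(moving_average_scores(h[1, , drop = FALSE])), unit_scores(3))
  short <- rbind(matrix(rep(unit_scores(1), 5), ncol = 7, byrow = TRUE),
                 matrix(rep(unit_scores(2), 5), ncol = 7, byrow = TRUE))
  avg <- moving_average_scores(short, window = 100)  # mean over the 10 available
  expect_equal(as.numeric(avg[1:2]), c(0.5, 0.5))
  gap <- rbind(unit_scores(2), rep(NA_real_, 7), unit_scores(2))
  expect_equal(predicted_class(moving_average_scores(gap)), "E1")
  # windowing: last 100 of a history that switches class
  hist <- rbind(matrix(rep(unit_scores(5), 200), ncol = 7, byrow = TRUE),
                matrix(rep(unit_scores(3), 100), ncol = 7, byrow = TRUE))
  expect_equal(predicted_class(moving_average_scores(hist, 100)), "E2")
})

test_that("minority oversampling balances counts, keeps originals, reproduces", {
  labels <- rep(c("A", "B", "C"), c(5, 3, 2))
  idx <- oversample_minority(labels, seed = 7)
  expect_equal(length(idx), 15)
  expect_true(all(table(labels[idx]) == 5))
  expect_true(all(seq_along(labels) %in% idx))
  expect_identical(idx, oversample_minority(labels, seed = 7))
  expect_identical(sort(oversample_minority(rep("A", 4))), 1:4)
  expect_error(oversample_minority(character(0)), "Empty")
})

test_that("focal loss matches hand values and limits", {
  half <- c(0.5, 0.5, 0, 0, 0, 0, 0)
  expect_equal(focal_loss(half, "D"), -0.25 * 0.25 * log(0.5), tolerance = 1e-12)
  expect_equal(focal_loss(unit_scores(1), "D"), 0)
  expect_equal(focal_loss(half, "D", alpha = 1, gamma = 0), -log(0.5))
  # monotone decreasing in p_t
  pts <- seq(0.05, 0.95, by = 0.05)
  losses <- vapply(pts, function(p) {
    focal_loss(c(p, 1 - p, 0, 0, 0, 0, 0), "D")
  }, numeric(1))
  expect_true(all(diff(losses) < 0))
  expect_error(focal_loss(half, "XX"), "Unknown")
})

test_that("augmentation is seeded, identity-stable and masks duplicates", {
  crop <- render_crop_set(1, crop_size = 64, seed = 3)$image[[1]]
  cfg <- train_config(translate = 0, rotate = c(0, 0), scale = c(1, 1))
  expect_identical(augment_crop(crop, cfg = cfg, seed = 1), crop)
  cfg2 <- train_config(translate = 10, rotate = c(0, 360), scale = c(0.75, 1.3))
  a1 <- augment_crop(crop, cfg = cfg2, seed = 5)
  expect_identical(a1, augment_crop(crop, cfg = cfg2, seed = 5))
  expect_false(identical(a1, crop))
  mask <- crop < 0.6
  md <- augment_crop(crop, mask, masked = TRUE)
  expect_identical(md[mask], crop[mask])
  expect_equal(length(unique(md[!mask])), 1L)   # background is one constant
})

test_that("members train deterministically and learn the synthetic classes", {
  crops <- render_crop_set(25, crop_size = 64, seed = 12)
  arch <- member_arch("test-polar", grid = 0, polar = c(12, 72), hidden = 0)
  cfg <- train_config(seed = 3, max_epochs = 60)
  m1 <- train_member(crops, arch, cfg)
  m2 <- train_member(crops, arch, cfg)
  expect_identical(m1$holdout_accuracy, m2$holdout_accuracy)
  expect_identical(m1$weights, m2$weights)
  expect_gte(m1$holdout_accuracy, 0.8)
  expect_s3_class(tidy(m1), "tbl_df")
  expect_true(all(c("epoch", "train_loss", "holdout_accuracy") %in% names(tidy(m1))))
  pred <- predict(m1, crops[1:10, ])
  expect_equal(nrow(pred), 10)
  expect_equal(rowSums(as.matrix(pred[, rbc_classes()])), rep(1, 10),
               tolerance = 1e-9)
})

test_that("the oversampling strategy trains through class imbalance", {
  crops <- render_crop_set(c(D = 60, E1 = 60, E2 = 60, E3 = 20, SE = 20,
                             S = 20, ST = 10), crop_size = 64, seed = 13)
  arch <- member_arch("imb", grid = 0, polar = c(12, 72), hidden = 0,
                      imbalance = "oversample")
  m <- train_member(crops, arch, train_config(seed = 4, max_epochs = 80))
  pred <- predict(m, crops)
  cm <- confusion_matrix(crops$class, pred$predicted)
  expect_gte(min(cm$by_class$recall, na.rm = TRUE), 0.5)
})

test_that("classify_crops standardises, scores and skips degenerate boxes", {
  crops <- render_crop_set(20, crop_size = 64, seed = 14)
  ens <- train_ensemble(crops,
                        list(member_arch("a", grid = 0, polar = c(12, 72), hidden = 0)),
                        train_config(seed = 2, max_epochs = 60))
  sc <- random_scene(6, c(256, 256), seed = 31)
  fr <- render_scene(sc)
  blobs <- segment_frame(fr$image)
  out <- classify_crops(fr$image, blobs, ens)
  expect_equal(nrow(out), nrow(blobs))
  expect_true(all(rbc_classes() %in% names(out)))
  expect_true(all(out$confidence > 1 / 7))
  empty <- classify_crops(fr$image, blobs[0, ], ens)
  expect_equal(nrow(empty), 0)
  bad <- blobs[1, ]; bad$w <- 1L
  expect_warning(classify_crops(fr$image, bad, ens), "Degenerate")
  expect_equal(nrow(glance(ens)), 1)
})
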