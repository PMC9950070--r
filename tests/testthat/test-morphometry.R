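# Effective diameters, histograms, bias-corrected bootstrap, effect sizes,
# group tests and record cleaning.

test_that("effective diameter follows the equivalent-circle formula", {
  expect_equal(effective_diameter(400 * pi, 0.1), 4)
  expect_equal(effective_diameter(100, 0.2), 2 * effective_diameter(100, 0.1))
  # a rendered disc of known physical size is recovered
  um_per_px <- 0.195
  r_px <- 7.8 / 2 / um_per_px
  out <- render_scene(disc_scene(radius = r_px, size = 128))
  expect_equal(effective_diameter(out$blobs$area, um_per_px), 7.8,
               tolerance = 0.1 / 7.8)
  expect_error(effective_diameter(-1, 0.1), "positive")
})

test_that("diameter histograms bin half-open, normalise, report out-of-range", {
  h <- diameter_histogram(c(4.05, 4.05, 9.95, 9.95))
  expect_equal(nrow(h), 60)
  expect_equal(sum(h$frequency), 1)
  occ <- h[h$count > 0, ]
  expect_equal(occ$center, c(4.05, 9.95))
  expect_equal(occ$frequency, c(0.5, 0.5))
  # a value on a bin edge joins the upper bin [4.1, 4.2)
  edge <- diameter_histogram(4.10)
  expect_equal(edge$center[edge$count > 0], 4.15)
  oo <- diameter_histogram(c(5, 3, 12))
  expect_equal(attr(oo, "n_below"), 1)
  expect_equal(attr(oo, "n_above"), 1)
  expect_equal(sum(oo$frequency), 1)
  expect_error(diameter_histogram(c(1, 11)), "outside")
})

test_that("bias-corrected bootstrap intervals behave and reproduce", {
  x <- rep(5, 10)
  ci <- bootstrap_ci(x, "mean", B = 200)
  expect_equal(as.numeric(ci), c(5, 5))
  expect_true(attr(ci, "degenerate"))
  set.seed(8); y <- rnorm(300, 10, 2)
  ci1 <- bootstrap_ci(y, "mean", B = 2000, seed = 4)
  expect_identical(ci1, bootstrap_ci(y, "mean", B = 2000, seed = 4))
  expect_lt(ci1[1], mean(y)); expect_gt(ci1[2], mean(y))
  for (s in c("sd", "median", "iqr")) {
    ci_s <- bootstrap_ci(y, s, B = 500, seed = 1)
    expect_lt(ci_s[1], ci_s[2])
  }
})

test_that("bootstrap CI width shrinks like 1/sqrt(n)", {
  set.seed(3)
  widths <- vapply(c(100, 400, 1600), function(n) {
    x <- rnorm(n, 7.8, 0.43)
    ci <- bootstrap_ci(x, "mean", B = 2000, seed = n)
    unname(ci[2] - ci[1])
  }, numeric(1))
  expect_equal(widths[1] / widths[2], 2, tolerance = 0.35)
  expect_equal(widths[2] / widths[3], 2, tolerance = 0.35)
})

test_that("Cohen's d and the common-language effect size obey their algebra", {
  expect_equal(cohens_d(5, 1, 50, 5, 1, 50), 0)
  expect_equal(cohens_d(6, 1, 30, 5, 1.2, 40),
               -cohens_d(5, 1.2, 40, 6, 1, 30))
  expect_equal(common_language_es(5, 1, 5, 1), 0.5)
  expect_equal(common_language_es(6, 1.1, 5, 0.9) +
                 common_language_es(5, 0.9, 6, 1.1), 1)
})

test_that("the effect-size matrix is a complement-symmetric probability matrix", {
  ref <- reference_diameter_stats()
  M <- cl_matrix(ref)
  expect_equal(diag(M), setNames(rep(0.5, 7), rbc_classes()))
  expect_equal(M + t(M), matrix(1, 7, 7, dimnames = dimnames(M)))
  expect_true(all(M >= 0 & M <= 1))
  # identical distributions give a flat 0.5 matrix
  same <- ref; same$mean <- 6; same$sd <- 0.4
  expect_true(all(cl_matrix(same) == 0.5))
  expect_warning(Mp <- cl_matrix(ref[1:5, ]), "missing")
  expect_true(all(is.na(Mp["S", ])))
})

test_that("group tests run the omnibus and all 21 Bonferroni pairs", {
  set.seed(6)
  ref <- reference_diameter_stats()
  d <- purrr::map_dfr(seq_len(7), function(i) {
    tibble::tibble(class = as.character(ref$class[i]),
                   diameter = rnorm(80, ref$mean[i], ref$sd[i]))
  })
  gt <- group_tests(d)
  expect_equal(nrow(gt$pairwise), choose(7, 2))
  expect_lt(gt$omnibus$p, 0.05)
  expect_true(all(gt$pairwise$p_adjusted >= gt$pairwise$p_raw))
  # identical groups: omnibus non-significant
  d0 <- tibble::tibble(class = rep(c("D", "S"), each = 50),
                       diameter = rnorm(100, 7, 0.5))
  expect_gt(group_tests(d0)$omnibus$p, 0.05)
  # two groups five SDs apart are significant after adjustment
  d5 <- tibble::tibble(class = rep(c("D", "S"), each = 100),
                       diameter = c(rnorm(100, 7, 0.4), rnorm(100, 5, 0.4)))
  expect_true(all(group_tests(d5)$pairwise$p_adjusted < 0.05))
  expect_warning(group_tests(dplyr::bind_rows(d0, tibble::tibble(class = "E1",
                                                                 diameter = 7))),
                 "n < 2")
})

test_that("low-resolution cleaning removes planted outliers, keeps clean data", {
  set.seed(9)
  clean <- tibble::tibble(class = rep(rbc_classes(), each = 400),
                          diameter = rnorm(2800,
                                           rep(reference_diameter_stats()$mean, each = 400),
                                           rep(reference_diameter_stats()$sd, each = 400) / 3))
  planted <- dplyr::mutate(clean, id = dplyr::row_number())
  out_idx <- sample(nrow(planted), round(0.05 * nrow(planted)))
  iqr_by_class <- tapply(clean$diameter, clean$class, IQR)
  planted$diameter[out_idx] <- planted$diameter[out_idx] +
    6 * iqr_by_class[as.character(planted$class[out_idx])]
  res <- clean_low_res(planted)
  removed_idx <- res$removed$id
  expect_gte(sum(out_idx %in% removed_idx) / length(out_idx), 0.95)
  false_pos <- setdiff(removed_idx, out_idx)
  expect_lte(length(false_pos) / (nrow(planted) - length(out_idx)), 0.01)
  # rule tagging
  rec <- tibble::tibble(class = "D", diameter = c(7.8, 15))
  r2 <- clean_low_res(rec)
  expect_equal(r2$removed$rule, "physical bounds")
  expect_equal(r2$kept$diameter, 7.8)
})

test_that("the good/bad filter is pass-through by default and auditable", {
  crops <- render_crop_set(3, crop_size = 48, seed = 2)
  res <- good_bad_filter(crops)
  expect_equal(nrow(res$kept), nrow(crops))
  expect_true(all(res$decisions$good))
  # an oracle filter drops dark-poor (truncated) crops
  res2 <- good_bad_filter(crops, filter = function(img) mean(img < 0.6) > 0.02)
  expect_equal(nrow(res2$decisions), nrow(crops))
})

test_that("class summary tables carry the full descriptive set", {
  set.seed(10)
  d <- tibble::tibble(class = rep(c("D", "S"), each = 200),
                      diameter = c(rnorm(200, 7.8, 0.4), rnorm(200, 5.9, 0.3)))
  st <- class_diameter_stats(d, B = 300, seed = 2)
  expect_equal(nrow(st), 2)
  expect_true(all(c("mean", "sd", "median", "iqr", "mad_mean", "mad_median",
                    "mean_lo", "iqr_hi") %in% names(st)))
  expect_true(all(st$mean_lo <= st$mean & st$mean <= st$mean_hi))
  expect_true(all(st$iqr_lo <= st$iqr_hi))
})
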