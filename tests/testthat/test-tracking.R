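# Kalman filtering, Hungarian assignment with non-assignment cost, track
# lifecycle and shape-change detection.

test_that("Kalman initialisation uses the stated state and covariance", {
  kf <- kf_init(c(10, 20))
  expect_equal(kf$x, c(10, 20, 0, 0))
  expect_equal(diag(kf$P), c(200, 200, 50, 50))
  kf2 <- kf_init(c(1, 1))
  kf$x[1] <- 99
  expect_equal(kf2$x[1], 1)      # independent states
})

test_that("prediction follows constant-velocity kinematics and inflates covariance", {
  kf <- kf_init(c(10, 10))
  kf$x[3:4] <- c(2, -1)
  pred <- kf_predict(kf)
  expect_equal(attr(pred, "predicted"), c(12, 9))
  expect_gt(sum(diag(pred$P)), sum(diag(kf$P)))
  pred2 <- kf_predict(pred)
  expect_gt(sum(diag(pred2$P)), sum(diag(pred$P)))
})

test_that("correction pulls the state toward the measurement and shrinks P", {
  kf <- kf_predict(kf_init(c(5, 5)))
  same <- kf_correct(kf, attr(kf, "predicted"))
  expect_equal(same$x[1:2], kf$x[1:2], tolerance = 1e-9)
  expect_lt(sum(diag(same$P)), sum(diag(kf$P)))
  # near-zero measurement noise: posterior ~ measurement
  p0 <- kf_params(measurement_var = 1e-9)
  kf0 <- kf_predict(kf_init(c(0, 0), p0))
  corr <- kf_correct(kf0, c(7, 3))
  expect_equal(corr$x[1:2], c(7, 3), tolerance = 1e-6)
  # posterior lies between prediction and measurement
  mid <- kf_correct(kf, c(20, 20))
  expect_true(all(mid$x[1:2] > kf$x[1:2] & mid$x[1:2] < c(20, 20)))
})

test_that("filtering reduces positional error on noisy constant-velocity runs", {
  set.seed(4)
  truth <- cbind(10 + 2 * (0:49), 100 - 1.5 * (0:49))
  meas <- truth + matrix(rnorm(100, 0, 3), ncol = 2)
  kf <- kf_init(meas[1, ])
  filt <- meas
  for (t in 2:50) {
    kf <- kf_predict(kf)
    kf <- kf_correct(kf, meas[t, ])
    filt[t, ] <- kf$x[1:2]
  }
  rmse <- function(a, b) sqrt(mean((a - b)^2))
  expect_lt(rmse(filt[10:50, ], truth[10:50, ]),
            rmse(meas[10:50, ], truth[10:50, ]))
  # prediction error vanishes with tiny noise
  p <- kf_params(measurement_var = 0.01, motion_noise = c(0.01, 0.01))
  kf <- kf_init(truth[1, ], p)
  for (t in 2:20) {
    kf <- kf_predict(kf)
    err <- attr(kf, "predicted") - truth[t, ]
    kf <- kf_correct(kf, truth[t, ])
  }
  expect_lt(sqrt(sum(err^2)), 0.5)
})

test_that("innovation variance matches R + HPH' when data follow the model", {
  set.seed(11)
  n <- 4000
  # simulate the filter's own generative model: constant-velocity transition
  # with process noise Q = diag(100, 100, 25, 25), measurement noise R = 100
  state <- c(0, 0, 1, 0.5)
  F <- diag(4); F[1, 3] <- 1; F[2, 4] <- 1
  qsd <- sqrt(c(100, 100, 25, 25))
  meas <- matrix(NA_real_, n, 2)
  for (t in 1:n) {
    state <- as.numeric(F %*% state) + rnorm(4, 0, qsd)
    meas[t, ] <- state[1:2] + rnorm(2, 0, 10)
  }
  kf <- kf_init(meas[1, ])
  innov <- matrix(NA_real_, n, 2)
  S_pred <- NA_real_
  for (t in 2:n) {
    kf <- kf_predict(kf)
    innov[t, ] <- meas[t, ] - attr(kf, "predicted")
    S_pred <- kf$P[1, 1] + 100
    kf <- kf_correct(kf, meas[t, ])
  }
  emp <- var(as.numeric(innov[500:n, ]))
  expect_lt(abs(emp - S_pred) / S_pred, 0.2)
})

test_that("cost matrices are Euclidean distances with transpose symmetry", {
  cm <- build_cost_matrix(rbind(c(0, 0)), rbind(c(3, 4)))
  expect_equal(cm[1, 1], 5)
  a <- matrix(runif(6), 3, 2); b <- matrix(runif(4), 2, 2)
  expect_equal(build_cost_matrix(a, b), t(build_cost_matrix(b, a)))
  expect_equal(dim(build_cost_matrix(a, matrix(numeric(0), 0, 2))), c(3L, 0L))
})

test_that("assignment matches the padded-cost semantics on the worked cases", {
  res <- assign_detections(matrix(c(1, 30, 30, 2), 2, 2, byrow = TRUE))
  expect_equal(res$pairs$track, 1:2)
  expect_equal(res$pairs$detection, 1:2)
  expect_equal(sum(res$pairs$cost), 3)
  # a lone pairing is accepted up to twice the non-assignment cost
  expect_equal(nrow(assign_detections(matrix(25, 1, 1))$pairs), 1)
  res45 <- assign_detections(matrix(45, 1, 1))
  expect_equal(nrow(res45$pairs), 0)
  expect_equal(res45$unassigned_tracks, 1L)
  expect_equal(res45$unassigned_detections, 1L)
})

test_that("assignment equals brute-force enumeration on random matrices", {
  set.seed(77)
  for (i in 1:120) {
    nt <- sample(1:4, 1); nd <- sample(1:4, 1)
    cost <- matrix(sample(1:60, nt * nd, replace = TRUE), nt, nd)
    res <- assign_detections(cost, 20)
    total <- sum(res$pairs$cost) +
      20 * (length(res$unassigned_tracks) + length(res$unassigned_detections))
    expect_equal(total, brute_force_assignment(cost, 20)$total,
                 info = paste("case", i))
  }
})

test_that("update_tracks books assignments, gaps and fresh ids", {
  st <- tracker_init()
  st <- update_tracks(st, tibble::tibble(cx = c(10, 50, 90), cy = 10), 1)
  expect_equal(vapply(st$tracks, `[[`, integer(1), "id"), 1:3)
  st <- update_tracks(st, tibble::tibble(cx = c(11, 51, 91), cy = 10.5), 2)
  expect_equal(length(st$tracks), 3)
  expect_true(all(vapply(st$tracks, `[[`, integer(1), "total_visible") == 2L))
  # one missing detection: gap marker + invisibility counter
  st <- update_tracks(st, tibble::tibble(cx = c(12, 52), cy = 11), 3)
  vis <- vapply(st$tracks, `[[`, integer(1), "consecutive_invisible")
  expect_equal(sort(vis), c(0L, 0L, 1L))
  missed <- st$tracks[[which(vis == 1L)]]
  expect_false(missed$centroid_history$visible[3])
  expect_true(is.na(missed$centroid_history$x[3]))
  expect_equal(missed$age, 3L)
})

test_that("pruning fires exactly at the stated boundaries", {
  mk <- function(age, visible, invisible) {
    st <- tracker_init()
    st$tracks <- list(list(id = 1L, kf = kf_init(c(0, 0)),
                           centroid_history = tibble::tibble(),
                           score_history = NULL, age = age,
                           total_visible = visible,
                           consecutive_invisible = invisible))
    st
  }
  expect_equal(length(prune_tracks(mk(100, 50, 51))$tracks), 0)  # > 50 invisible
  expect_equal(length(prune_tracks(mk(100, 50, 50))$tracks), 1)  # exactly 50 kept
  expect_equal(length(prune_tracks(mk(7, 2, 0))$tracks), 0)      # 28.6% < 30%, age < 8
  expect_equal(length(prune_tracks(mk(8, 2, 0))$tracks), 1)      # age 8 exempt
  expect_equal(length(prune_tracks(mk(7, 3, 0))$tracks), 1)      # 42.9% visible
})

test_that("track identities persist through a jittered synthetic sequence", {
  cells <- dplyr::bind_rows(lapply(1:8, function(i) {
    cell_spec("D", 40 + (i - 1) %% 4 * 60, 40 + (i - 1) %/% 4 * 60,
              vx = runif(1, -1, 1), vy = runif(1, -1, 1))
  }))
  sq <- render_sequence(scene_spec(c(160, 256), cells, seed = 5), 40,
                        jitter_sd = 1)
  det <- dplyr::filter(sq$truth, present)
  tr <- track_sequence(dplyr::transmute(det, frame, cx = x, cy = y))
  td <- tidy(tr)
  expect_equal(glance(tr)$n_total, 8)
  # every true cell maps to exactly one track over all 40 frames
  joined <- dplyr::inner_join(dplyr::filter(td, visible), det,
                              by = "frame", relationship = "many-to-many") |>
    dplyr::mutate(d = sqrt((x.x - x.y)^2 + (y.x - y.y)^2)) |>
    dplyr::filter(d < 4)
  map <- dplyr::distinct(joined, track_id, id)
  expect_equal(nrow(map), 8)
})

test_that("shape changes are detected at the 10-minute mark", {
  flat <- matrix(rep(c(0, 0, 0, 0, 1, 0, 0), 700), ncol = 7, byrow = TRUE)
  colnames(flat) <- rbc_classes()
  tr_const <- list(score_history = flat)
  out <- detect_shape_change(tr_const)
  expect_true(out$evaluable)
  expect_false(out$changed)
  # SE -> E2 switch at frame 300 is smoothed but visible by frame 600
  switch_hist <- rbind(
    matrix(rep(c(0, 0, 0, 0, 1, 0, 0), 300), ncol = 7, byrow = TRUE),
    matrix(rep(c(0, 0, 1, 0, 0, 0, 0), 400), ncol = 7, byrow = TRUE))
  colnames(switch_hist) <- rbc_classes()
  out2 <- detect_shape_change(list(score_history = switch_hist))
  expect_true(out2$changed)
  expect_equal(out2$from_class, "SE")
  expect_equal(out2$to_class, "E2")
  short <- detect_shape_change(list(score_history = flat[1:10, ]))
  expect_false(short$evaluable)
})
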