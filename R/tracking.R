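# Multi-object tracking of cells across frames: a constant-velocity Kalman
# filter per track, Euclidean-distance cost matrices, Munkres/Hungarian
# assignment with a non-assignment cost, lifecycle pruning, and per-track
# morphology score histories for shape-change detection.

#' Kalman filter parameters for cell motion
#'
#' The constant-velocity model found effective for cells confined in
#' microfluidic wells: initial location/velocity variances 200 and 50,
#' process (motion) noise `[100, 25]` for the location and velocity blocks,
#' and measurement variance 100, with dt = 1 frame.
#'
#' @param init_location_var,init_velocity_var Initial state variances.
#' @param motion_noise `(location, velocity)` process-noise variances.
#' @param measurement_var Detected-centroid variance.
#' @return A list of class `kf_params`.
#' @export
kf_params <- function(init_location_var = 200, init_velocity_var = 50,
                      motion_noise = c(100, 25), measurement_var = 100) {
  structure(list(init_location_var = init_location_var,
                 init_velocity_var = init_velocity_var,
                 motion_noise = motion_noise,
                 measurement_var = measurement_var),
            class = "kf_params")
}

kf_matrices <- function(params) {
  F <- diag(4); F[1, 3] <- 1; F[2, 4] <- 1          # state (x, y, vx, vy), dt = 1
  H <- matrix(0, 2, 4); H[1, 1] <- 1; H[2, 2] <- 1
  Q <- diag(c(params$motion_noise[1], params$motion_noise[1],
              params$motion_noise[2], params$motion_noise[2]))
  R <- diag(params$measurement_var, 2)
  list(F = F, H = H, Q = Q, R = R)
}

#' Initialise a Kalman state at a detected centroid
#'
#' @param centroid `(x, y)` in px.
#' @param params A [kf_params()].
#' @return A list of class `kf_state` with `x` (4-vector) and `P` (4 x 4
#'   covariance `diag(200, 200, 50, 50)` by default).
#' @export
kf_init <- function(centroid, params = kf_params()) {
  stopifnot(length(centroid) == 2, all(is.finite(centroid)))
  structure(list(
    x = c(centroid[1], centroid[2], 0, 0),
    P = diag(c(params$init_location_var, params$init_location_var,
               params$init_velocity_var, params$init_velocity_var)),
    params = params
  ), class = "kf_state")
}

#' Predict the next centroid
#'
#' Constant-velocity transition over one frame; covariance grows by the
#' process noise.
#'
#' @param kf A `kf_state`.
#' @return Updated `kf_state` with attribute `predicted` = `(x, y)`.
#' @export
kf_predict <- function(kf) {
  m <- kf_matrices(kf$params)
  x <- m$F %*% kf$x
  P <- m$F %*% kf$P %*% t(m$F) + m$Q
  structure(list(x = as.numeric(x), P = P, params = kf$params),
            class = "kf_state", predicted = as.numeric(x)[1:2])
}

#' Correct the state with a detection
#'
#' Standard Kalman measurement update observing `(x, y)`; the posterior
#' position lies between the prediction and the measurement.
#'
#' @param kf A `kf_state` (after [kf_predict()]).
#' @param centroid Detected `(x, y)`.
#' @return Updated `kf_state`.
#' @export
kf_correct <- function(kf, centroid) {
  stopifnot(all(is.finite(centroid)))
  m <- kf_matrices(kf$params)
  S <- m$H %*% kf$P %*% t(m$H) + m$R
  K <- kf$P %*% t(m$H) %*% solve(S)
  innov <- centroid - as.numeric(m$H %*% kf$x)
  x <- kf$x + as.numeric(K %*% innov)
  P <- (diag(4) - K %*% m$H) %*% kf$P
  structure(list(x = x, P = P, params = kf$params), class = "kf_state")
}

#' Distance cost matrix between track predictions and detections
#'
#' @param predictions Matrix/data frame of predicted `(x, y)`, one row per
#'   track.
#' @param detections Matrix/data frame of detected `(x, y)`.
#' @return Numeric matrix (tracks x detections) of Euclidean distances (px).
#' @export
build_cost_matrix <- function(predictions, detections) {
  p <- matrix(as.numeric(as.matrix(predictions)), ncol = 2)
  d <- matrix(as.numeric(as.matrix(detections)), ncol = 2)
  if (nrow(p) == 0 || nrow(d) == 0) {
    return(matrix(numeric(0), nrow(p), nrow(d)))
  }
  outer(seq_len(nrow(p)), seq_len(nrow(d)), function(i, j) {
    sqrt((p[i, 1] - d[j, 1])^2 + (p[i, 2] - d[j, 2])^2)
  })
}

# O(n^3) Jonker-Volgenant shortest-augmenting-path solver for square cost
# matrices; returns the column assigned to each row.
solve_lsap <- function(cost) {
  n <- nrow(cost)
  if (n == 0) return(integer(0))
  u <- numeric(n + 1); v <- numeric(n + 1)
  p <- integer(n + 1)       # p[j]: row assigned to column j (0 = none)
  way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 1
    minv <- rep(Inf, n + 1)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]; delta <- Inf; j1 <- 0
      for (j in 2:(n + 1)) {
        if (!used[j]) {
          cur <- cost[i0, j - 1] - u[i0] - v[j]
          if (cur < minv[j]) { minv[j] <- cur; way[j] <- j0 }
          if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
        }
      }
      for (j in 1:(n + 1)) {
        if (used[j]) { u[p[j]] <- u[p[j]] + delta; v[j] <- v[j] - delta }
        else minv[j] <- minv[j] - delta
      }
      j0 <- j1
      if (p[j0] == 0) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == 1) break
    }
  }
  ans <- integer(n)
  for (j in 2:(n + 1)) if (p[j] > 0) ans[p[j]] <- j - 1L
  ans
}

#' Assign detections to tracks with a non-assignment cost
#'
#' Solves the padded linear assignment problem in which leaving a track
#' unassigned costs `cost_unassigned` and leaving a detection unassigned
#' costs the same, so a lone track-detection pairing is accepted up to twice
#' the non-assignment cost (the padded-matrix semantics of the classic
#' multi-object-tracking formulation). The default cost of 20 px was found
#' effective for well-confined cells at 1 fps.
#'
#' @param cost_matrix Tracks x detections cost matrix (finite).
#' @param cost_unassigned Cost of not assigning (default 20).
#' @return List with `pairs` (tibble `track`, `detection`, `cost`),
#'   `unassigned_tracks`, `unassigned_detections` (integer indices).
#' @export
#' @examples
#' assign_detections(matrix(c(1, 30, 30, 2), 2, 2, byrow = TRUE))
assign_detections <- function(cost_matrix, cost_unassigned = 20) {
  nt <- nrow(cost_matrix); nd <- ncol(cost_matrix)
  if (nt == 0 || nd == 0) {
    return(list(pairs = tibble::tibble(track = integer(), detection = integer(),
                                       cost = numeric()),
                unassigned_tracks = seq_len(nt),
                unassigned_detections = seq_len(nd)))
  }
  stopifnot(all(is.finite(cost_matrix)))
  big <- 2 * (max(cost_matrix, cost_unassigned) + 1) * (nt + nd)
  n <- nt + nd
  padded <- matrix(0, n, n)
  padded[seq_len(nt), seq_len(nd)] <- cost_matrix
  padded[seq_len(nt), nd + seq_len(nt)] <- big
  padded[cbind(seq_len(nt), nd + seq_len(nt))] <- cost_unassigned
  padded[nt + seq_len(nd), seq_len(nd)] <- big
  padded[cbind(nt + seq_len(nd), seq_len(nd))] <- cost_unassigned
  sol <- solve_lsap(padded)
  track <- integer(0); det <- integer(0)
  for (i in seq_len(nt)) {
    if (sol[i] <= nd) { track <- c(track, i); det <- c(det, sol[i]) }
  }
  list(
    pairs = tibble::tibble(track = track, detection = det,
                           cost = cost_matrix[cbind(track, det)]),
    unassigned_tracks = setdiff(seq_len(nt), track),
    unassigned_detections = setdiff(seq_len(nd), det)
  )
}

new_track <- function(id, centroid, scores, frame, params) {
  list(id = id, kf = kf_init(centroid, params),
       centroid_history = tibble::tibble(frame = frame, x = centroid[1],
                                         y = centroid[2], visible = TRUE),
       score_history = if (is.null(scores)) NULL else matrix(scores, 1, 7,
         dimnames = list(NULL, rbc_classes())),
       age = 1L, total_visible = 1L, consecutive_invisible = 0L)
}

#' Advance the track set by one frame
#'
#' Predicts every track, assigns detections by Hungarian assignment on the
#' distance cost matrix, corrects assigned tracks (appending centroid and
#' score history, resetting the invisibility counter), increments the
#' invisibility of unassigned tracks (their history gains an explicit absent
#' marker so histories stay frame-aligned), and opens new tracks with fresh
#' monotonically increasing ids for unassigned detections. Age increments for
#' every track.
#'
#' @param state Tracker state from [tracker_init()].
#' @param detections Tibble with `cx`, `cy` (or `x`, `y`) and optionally the
#'   7 class-score columns.
#' @param frame Frame index (1-based).
#' @return Updated state.
#' @export
update_tracks <- function(state, detections, frame) {
  params <- state$params
  det_xy <- if (nrow(detections) > 0) {
    if (all(c("cx", "cy") %in% names(detections))) {
      cbind(detections$cx, detections$cy)
    } else {
      cbind(detections$x, detections$y)
    }
  } else {
    matrix(numeric(0), 0, 2)
  }
  has_scores <- all(rbc_classes() %in% names(detections))
  preds <- matrix(numeric(0), 0, 2)
  for (i in seq_along(state$tracks)) {
    state$tracks[[i]]$kf <- kf_predict(state$tracks[[i]]$kf)
    preds <- rbind(preds, attr(state$tracks[[i]]$kf, "predicted"))
  }
  res <- assign_detections(build_cost_matrix(preds, det_xy),
                           state$cost_unassigned)
  for (k in seq_len(nrow(res$pairs))) {
    ti <- res$pairs$track[k]; di <- res$pairs$detection[k]
    tr <- state$tracks[[ti]]
    tr$kf <- kf_correct(tr$kf, det_xy[di, ])
    tr$centroid_history <- dplyr::bind_rows(
      tr$centroid_history,
      tibble::tibble(frame = frame, x = det_xy[di, 1], y = det_xy[di, 2],
                     visible = TRUE))
    if (has_scores) {
      tr$score_history <- rbind(tr$score_history,
                                as.numeric(detections[di, rbc_classes()]))
    }
    tr$age <- tr$age + 1L
    tr$total_visible <- tr$total_visible + 1L
    tr$consecutive_invisible <- 0L
    state$tracks[[ti]] <- tr
  }
  for (ti in res$unassigned_tracks) {
    tr <- state$tracks[[ti]]
    tr$centroid_history <- dplyr::bind_rows(
      tr$centroid_history,
      tibble::tibble(frame = frame, x = NA_real_, y = NA_real_, visible = FALSE))
    if (!is.null(tr$score_history)) {
      tr$score_history <- rbind(tr$score_history, rep(NA_real_, 7))  # gap marker
    }
    tr$age <- tr$age + 1L
    tr$consecutive_invisible <- tr$consecutive_invisible + 1L
    state$tracks[[ti]] <- tr
  }
  for (di in res$unassigned_detections) {
    state$next_id <- state$next_id + 1L
    sc <- if (has_scores) as.numeric(detections[di, rbc_classes()]) else NULL
    state$tracks[[length(state$tracks) + 1]] <-
      new_track(state$next_id - 1L, det_xy[di, ], sc, frame, params)
  }
  state
}

#' Delete dead or spurious tracks
#'
#' A track is deleted iff it has been invisible for more than
#' `max_invisible` consecutive frames, or it is younger than `min_age`
#' frames AND visible in under `min_visible_frac` of its frames (a likely
#' segmentation artifact).
#'
#' @param state Tracker state.
#' @param max_invisible Default 50.
#' @param min_age Default 8.
#' @param min_visible_frac Default 0.30.
#' @return State with surviving tracks; deleted tracks are appended to
#'   `state$dead`.
#' @export
prune_tracks <- function(state, max_invisible = 50, min_age = 8,
                         min_visible_frac = 0.30) {
  kill <- vapply(state$tracks, function(tr) {
    tr$consecutive_invisible > max_invisible ||
      (tr$age < min_age && tr$total_visible / tr$age < min_visible_frac)
  }, logical(1))
  state$dead <- c(state$dead, state$tracks[kill])
  state$tracks <- state$tracks[!kill]
  state
}

#' Initialise a tracker
#'
#' @param params A [kf_params()].
#' @param cost_unassigned Non-assignment cost (default 20).
#' @return Tracker state (list).
#' @export
tracker_init <- function(params = kf_params(), cost_unassigned = 20) {
  list(tracks = list(), dead = list(), next_id = 1L, params = params,
       cost_unassigned = cost_unassigned)
}

#' Track detections over a whole sequence
#'
#' Runs predict / assign / update / prune for every frame of a per-frame
#' detection table.
#'
#' @param detections Tibble with a `frame` column, centroids (`cx`/`cy` or
#'   `x`/`y`) and optionally the 7 score columns.
#' @param params A [kf_params()].
#' @param cost_unassigned Non-assignment cost (default 20).
#' @param prune Apply [prune_tracks()] each frame (default TRUE).
#' @return An object of class `rbc_tracks`: the final tracker state with all
#'   tracks (alive + dead).
#' @export
track_sequence <- function(detections, params = kf_params(),
                           cost_unassigned = 20, prune = TRUE) {
  state <- tracker_init(params, cost_unassigned)
  frames <- sort(unique(detections$frame))
  for (f in frames) {
    state <- update_tracks(state, detections[detections$frame == f, ], f)
    if (prune) state <- prune_tracks(state)
  }
  structure(state, class = "rbc_tracks")
}

#' Tidy tracks into a per-frame table
#'
#' @param x An `rbc_tracks`.
#' @param ... Unused.
#' @return Tibble `(track_id, frame, x, y, visible)`.
#' @method tidy rbc_tracks
#' @export
tidy.rbc_tracks <- function(x, ...) {
  all_tracks <- c(x$tracks, x$dead)
  purrr::map_dfr(all_tracks, function(tr) {
    dplyr::mutate(tr$centroid_history, track_id = tr$id, .before = 1)
  })
}

#' @method glance rbc_tracks
#' @export
glance.rbc_tracks <- function(x, ...) {
  tibble::tibble(n_alive = length(x$tracks), n_dead = length(x$dead),
                 n_total = x$next_id - 1L)
}

#' Detect a shape change by a time mark
#'
#' Compares the smoothed class at the start of a track with the smoothed
#' class at the mark: the "from" class is the modal moving-average class over
#' the initial window, the "to" class is the moving-average class (window
#' `window`) at the mark. Tracks not spanning the mark are flagged not
#' evaluable.
#'
#' @param track One track (element of `rbc_tracks$tracks`) with a score
#'   history.
#' @param mark_seconds Time of the comparison point (default 600 s = 10 min).
#' @param fps Frames per second (default 1).
#' @param window Moving-average window in frames (default 100).
#' @param initial_window Frames defining the starting class (default 100).
#' @return Tibble `(evaluable, changed, from_class, to_class)`.
#' @export
detect_shape_change <- function(track, mark_seconds = 600, fps = 1,
                                window = 100, initial_window = 100) {
  mark_frame <- round(mark_seconds * fps)
  sh <- track$score_history
  if (is.null(sh) || nrow(sh) < mark_frame) {
    return(tibble::tibble(evaluable = FALSE, changed = NA,
                          from_class = NA_character_, to_class = NA_character_))
  }
  ini <- seq_len(min(initial_window, nrow(sh)))
  from_per_frame <- vapply(ini, function(i) {
    predicted_class(moving_average_scores(sh[seq_len(i), , drop = FALSE], window))
  }, character(1))
  from <- names(sort(table(from_per_frame), decreasing = TRUE))[1]
  to <- predicted_class(moving_average_scores(sh[seq_len(mark_frame), , drop = FALSE],
                                              window))
  tibble::tibble(evaluable = TRUE, changed = from != to,
                 from_class = from, to_class = to)
}
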