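# Seven-class morphology classification by unweighted softmax averaging over
# a heterogeneous ensemble of independently trained members. Members here are
# compact one-hidden-layer softmax networks over downsampled-pixel and
# polar-profile features of the standardized 227 x 227 crop; the member
# contract (predict a 7-class probability vector from a crop) accepts any
# stronger model.

#' Average member softmax scores (unweighted)
#'
#' Element-wise arithmetic mean of the members' probability vectors; the
#' predicted class is the argmax of the mean, with ties broken by canonical
#' class order. Because the mean is unweighted, an under-confident member
#' contributes less to the winning score than a well-calibrated one.
#'
#' @param member_scores A numeric matrix (members x 7), a list of numeric
#'   7-vectors, or a data frame with the 7 class columns.
#' @return Named numeric 7-vector (a probability distribution) with
#'   attributes `predicted` (class code) and `confidence` (max probability).
#' @export
#' @examples
#' ensemble_average(rbind(c(1, 0, 0, 0, 0, 0, 0), c(0, 1, 0, 0, 0, 0, 0)))
ensemble_average <- function(member_scores) {
  if (is.null(member_scores) || length(member_scores) == 0) {
    abort("Need at least one member score vector.")
  }
  m <- as_score_matrix(member_scores)
  avg <- colMeans(m)
  avg <- avg / sum(avg)
  finalize_scores(avg)
}

as_score_matrix <- function(x) {
  if (is.list(x) && !is.data.frame(x)) x <- do.call(rbind, x)
  m <- as.matrix(x)
  if (ncol(m) != 7) abort("Scores must have 7 class columns.")
  if (any(m < -1e-9) || any(abs(rowSums(m) - 1) > 1e-6)) {
    abort("Each score row must be a probability distribution over the 7 classes.")
  }
  colnames(m) <- rbc_classes()
  m
}

finalize_scores <- function(p) {
  names(p) <- rbc_classes()
  k <- which.max(p)  # first max = canonical-order tie-break
  structure(p, predicted = rbc_classes()[k], confidence = unname(p[k]))
}

#' Predicted class and confidence of a score vector
#' @param scores Named 7-vector as returned by [ensemble_average()].
#' @return `predicted_class()`: the class code; `score_confidence()`: the
#'   maximum probability.
#' @export
predicted_class <- function(scores) {
  attr(scores, "predicted") %||% rbc_classes()[which.max(scores)]
}

#' @rdname predicted_class
#' @export
score_confidence <- function(scores) {
  attr(scores, "confidence") %||% max(scores)
}

#' Moving average of a score history
#'
#' Mean of the last `min(window, n)` frames of a per-frame score history,
#' renormalised; used to smooth longitudinal per-cell classifications (the
#' conventional window is 100 frames at 1 fps). Histories shorter than the
#' window are averaged over whatever is available.
#'
#' @param score_history Matrix / data frame (frames x 7) or list of
#'   7-vectors, oldest first.
#' @param window Number of trailing frames to average (default 100).
#' @return As [ensemble_average()].
#' @export
moving_average_scores <- function(score_history, window = 100) {
  if (is.list(score_history) && !is.data.frame(score_history)) {
    score_history <- do.call(rbind, score_history)
  }
  score_history <- as.matrix(score_history)
  # absent-frame gap markers (all-NA rows) are excluded from the average
  keep <- stats::complete.cases(score_history)
  m <- as_score_matrix(score_history[keep, , drop = FALSE])
  if (nrow(m) == 0) abort("Score history must be non-empty.")
  k <- min(window, nrow(m))
  avg <- colMeans(m[(nrow(m) - k + 1):nrow(m), , drop = FALSE])
  finalize_scores(avg / sum(avg))
}

#' Random minority oversampling
#'
#' Classes with fewer items than the majority class have their items
#' duplicated uniformly at random (with replacement, seeded) until every
#' present class matches the majority count. The original items are always a
#' subset of the result.
#'
#' @param labels Vector of class labels (one per item).
#' @param seed Integer seed.
#' @return Integer index vector into the original items.
#' @export
oversample_minority <- function(labels, seed = 1L) {
  if (length(labels) == 0) abort("Empty dataset.")
  labels <- as.character(labels)
  counts <- table(labels)
  target <- max(counts)
  with_seed(seed, {
    idx <- unlist(lapply(names(counts), function(cl) {
      i <- which(labels == cl)
      extra <- target - length(i)
      c(i, if (extra > 0) i[sample.int(length(i), extra, replace = TRUE)])
    }))
    as.integer(idx)
  })
}

#' Focal loss for multiclass scores
#'
#' `FL = -alpha * (1 - p_t)^gamma * log(p_t)` with `p_t` the predicted
#' probability of the true class: a dynamically scaled cross-entropy that
#' down-weights well-classified examples, mitigating class-imbalance bias.
#' With `alpha = 1, gamma = 0` it reduces to the cross-entropy. Zero
#' probabilities are clamped at 1e-12.
#'
#' @param scores Numeric 7-vector or matrix (n x 7) of class probabilities.
#' @param target Class code(s), one per row of `scores`.
#' @param alpha Balance weight (default 0.25).
#' @param gamma Focusing exponent (default 2).
#' @return Numeric vector of per-item losses.
#' @export
#' @examples
#' focal_loss(rep(1 / 7, 7), "D", alpha = 1, gamma = 0)  # log(7)
focal_loss <- function(scores, target, alpha = 0.25, gamma = 2) {
  if (is.null(dim(scores))) scores <- matrix(scores, nrow = 1)
  m <- as_score_matrix(scores)
  ti <- match(as.character(target), rbc_classes())
  if (any(is.na(ti))) abort("Unknown target class.")
  pt <- pmax(m[cbind(seq_len(nrow(m)), ti)], 1e-12)
  -alpha * (1 - pt)^gamma * log(pt)
}

#' Training configuration for ensemble members
#'
#' Defaults follow the standard recipe for this task: SGD with momentum 0.9,
#' initial learning rate 3e-4, L2 coefficient 0.005, minibatches of 10-32
#' shuffled every epoch, early stopping on a holdout with model checkpoints
#' (typical runs end between 20 and 300 epochs), focal loss alpha 0.25 /
#' gamma 2 for members using the focal strategy, and augmentation ranges of
#' +/-100 px translation, 0-360 degree rotation and 75-130% scaling.
#'
#' @param lr Initial learning rate.
#' @param momentum SGD momentum.
#' @param l2 L2 regularisation coefficient.
#' @param minibatch Minibatch size (10-32).
#' @param focal_alpha,focal_gamma Focal-loss hyperparameters.
#' @param translate Max |translation| in px for augmentation.
#' @param rotate Rotation range in degrees.
#' @param scale Scaling range (fractions).
#' @param masked_duplicates Add background-masked duplicates of each crop.
#' @param augment Apply random augmentation during training (off by default:
#'   the synthetic generator already randomises pose and scale).
#' @param max_epochs Epoch budget.
#' @param patience Holdout evaluations without improvement before stopping.
#' @param holdout Fraction of the data held out for early stopping.
#' @param seed Integer seed.
#' @return A list of class `train_config`.
#' @export
train_config <- function(lr = 3e-4, momentum = 0.9, l2 = 0.005, minibatch = 32,
                         focal_alpha = 0.25, focal_gamma = 2, translate = 100,
                         rotate = c(0, 360), scale = c(0.75, 1.30),
                         masked_duplicates = FALSE, augment = FALSE,
                         max_epochs = 300, patience = 10, holdout = 0.1,
                         seed = 1L) {
  stopifnot(lr > 0, momentum >= 0, momentum < 1, l2 >= 0,
            minibatch >= 1, all(scale > 0), all(scale <= 2))
  structure(list(lr = lr, momentum = momentum, l2 = l2, minibatch = minibatch,
                 focal_alpha = focal_alpha, focal_gamma = focal_gamma,
                 translate = translate, rotate = rotate, scale = scale,
                 masked_duplicates = masked_duplicates, augment = augment,
                 max_epochs = max_epochs, patience = patience,
                 holdout = holdout, seed = as.integer(seed)),
            class = "train_config")
}

#' Randomly augment a crop
#'
#' Seeded random translation, rotation and scaling within the configured
#' ranges; identity draws return the image unchanged. With a mask and
#' `masked = TRUE` the background pixels are set to a constant (the median
#' background intensity), yielding the background-masked duplicate used to
#' classify individually segmented cells.
#'
#' @param image Square crop matrix in `[0, 1]`.
#' @param mask Optional logical foreground mask (for the masked duplicate).
#' @param cfg A [train_config()] providing the ranges.
#' @param seed Integer seed.
#' @param masked Return the background-masked duplicate instead.
#' @return Matrix of the same size.
#' @export
augment_crop <- function(image, mask = NULL, cfg = train_config(), seed = 1L,
                         masked = FALSE) {
  if (masked) {
    stopifnot(!is.null(mask), all(dim(mask) == dim(image)))
    const <- stats::median(image[!(mask > 0)])
    out <- matrix(const, nrow(image), ncol(image))
    out[mask > 0] <- image[mask > 0]
    return(out)
  }
  with_seed(seed, {
    tx <- round(runif(1, -cfg$translate, cfg$translate))
    ty <- round(runif(1, -cfg$translate, cfg$translate))
    ang <- runif(1, cfg$rotate[1], cfg$rotate[2])
    sc <- runif(1, cfg$scale[1], cfg$scale[2])
    bg <- stats::median(image[c(1, nrow(image)), ])
    out <- image
    if (abs(sc - 1) > 1e-9) {
      h <- nrow(out); w <- ncol(out)
      z <- resize_matrix(out, max(1, round(h * sc)), max(1, round(w * sc)))
      canvas <- matrix(bg, h, w)
      zr <- nrow(z); zc <- ncol(z)
      r0 <- max(0L, (h - zr) %/% 2L); c0 <- max(0L, (w - zc) %/% 2L)
      sr <- max(0L, (zr - h) %/% 2L); sc0 <- max(0L, (zc - w) %/% 2L)
      nr <- min(h, zr); nc <- min(w, zc)
      canvas[r0 + seq_len(nr), c0 + seq_len(nc)] <-
        z[sr + seq_len(nr), sc0 + seq_len(nc)]
      out <- canvas
    }
    if (abs(ang %% 360) > 1e-9) {
      out <- as.matrix(EBImage::rotate(out, ang, output.dim = dim(image),
                                       bg.col = bg))
    }
    if (tx != 0 || ty != 0) {
      out <- as.matrix(EBImage::translate(out, c(ty, tx), bg.col = bg))
    }
    out
  })
}

# ---- feature extraction ----------------------------------------------------

#' Standardize a crop for classification
#'
#' Upscales (bilinear) to `size` x `size` and contrast-normalises against the
#' local background: the border-median intensity is taken as background and
#' the crop is mapped to positive "darkness" values `max(bg - x, 0) / bg`, so
#' members are insensitive to illumination level.
#'
#' @param image Crop matrix.
#' @param size Target side (default 227).
#' @return `size` x `size` matrix of darkness values.
#' @export
standardize_crop <- function(image, size = 227) {
  border <- c(image[1, ], image[nrow(image), ], image[, 1], image[, ncol(image)])
  bg <- max(stats::median(border), 0.05)
  z <- resize_matrix(image, size, size)
  pmax(bg - z, 0) / bg
}

polar_offsets <- function(size, n_r, n_a) {
  rmax <- size / 2 * 0.95
  rr <- (seq_len(n_r) - 0.5) / n_r * rmax
  aa <- seq(0, 2 * pi, length.out = n_a + 1)[-(n_a + 1)]
  list(dy = outer(sin(aa), rr), dx = outer(cos(aa), rr), rr = rr)
}

# Polar sample matrix (angles x radii) centred on the darkness centroid, so
# boundary features measure spicule structure rather than crop off-centring.
# Bilinear interpolation keeps the sub-pixel boundary ripple of shallow
# spicules above the sampling noise floor.
polar_sample <- function(z, off) {
  size <- nrow(z)
  tot <- sum(z)
  if (tot < 1e-9) {
    cy <- (size + 1) / 2; cx <- cy
  } else {
    cy <- sum(z * row(z)) / tot
    cx <- sum(z * col(z)) / tot
  }
  ry <- pmin(pmax(cy + off$dy, 1), size)
  rx <- pmin(pmax(cx + off$dx, 1), size)
  y0 <- pmin(floor(ry), size - 1); x0 <- pmin(floor(rx), size - 1)
  fy <- ry - y0; fx <- rx - x0
  at <- function(r, c) z[(c - 1) * size + r]
  v <- (1 - fy) * (1 - fx) * at(y0, x0) + (1 - fy) * fx * at(y0, x0 + 1) +
    fy * (1 - fx) * at(y0 + 1, x0) + fy * fx * at(y0 + 1, x0 + 1)
  matrix(v, nrow(off$dy), ncol(off$dy))
}

# Boundary-radius profile features: per-angle cell radius (half-maximum
# crossing of the darkness profile, interpolated between annuli for
# sub-annulus resolution), its mean and SD, and the Fourier amplitude
# spectrum of the profile — spicule count and depth appear directly as a
# spectral peak.
boundary_features <- function(v, rr, n_harmonics = 30) {
  core <- mean(v[, seq_len(max(1, ncol(v) %/% 4))])
  thr <- 0.5 * max(core, 1e-6)
  above <- v >= thr
  n_r <- ncol(v)
  rad <- vapply(seq_len(nrow(v)), function(a) {
    i <- if (any(above[a, ])) max(which(above[a, ])) else 1L
    r <- rr[i]
    if (i < n_r && v[a, i] > v[a, i + 1]) {
      frac <- (v[a, i] - thr) / (v[a, i] - v[a, i + 1])
      r <- rr[i] + frac * (rr[i + 1] - rr[i])
    }
    r
  }, numeric(1)) / max(rr)
  sp <- abs(stats::fft(rad - mean(rad))) / length(rad)
  amps <- numeric(n_harmonics)
  k <- min(n_harmonics, length(sp) %/% 2)
  amps[seq_len(k)] <- sp[1 + seq_len(k)]
  # subtract the per-sample spectral floor so a genuine spicule peak stands
  # out at any image noise level; the floor itself is kept as a feature
  floor_amp <- stats::median(sp[1 + seq_len(max(k, 1))])
  c(mean(rad), sd(rad), floor_amp, amps - floor_amp)
}

#' Member architecture specification
#'
#' Heterogeneity across the ensemble comes from varying the feature
#' representation (pixel-grid resolution, polar-profile resolution) and the
#' hidden-layer width. Polar features are per-annulus means and standard
#' deviations of the darkness profile — the angular SD at a given radius
#' measures spicule amplitude, the radial mean profile measures cell size and
#' central pallor.
#'
#' @param name Member name.
#' @param grid Pixel-grid side (0 = none).
#' @param polar `(n_radii, n_angles)` of the polar sampling (NULL = none).
#' @param hidden Hidden-layer width (0 = multinomial softmax regression).
#' @param imbalance `"oversample"` (random minority oversampling +
#'   cross-entropy) or `"focal_loss"` (no oversampling, focal loss).
#' @return A list of class `member_arch`.
#' @export
member_arch <- function(name, grid = 16, polar = c(10, 60), hidden = 12,
                        imbalance = c("focal_loss", "oversample")) {
  imbalance <- match.arg(imbalance)
  structure(list(name = name, grid = grid, polar = polar, hidden = hidden,
                 imbalance = imbalance), class = "member_arch")
}

#' The default heterogeneous ensemble (four members)
#'
#' One wide MLP trained with minority oversampling and cross-entropy, and
#' three focal-loss members with progressively different feature emphasis
#' (mixed, polar-only shape specialist, grid-heavy appearance specialist).
#'
#' @return List of four [member_arch()] specs.
#' @export
default_member_archs <- function() {
  list(
    member_arch("mlp-wide", grid = 20, polar = c(14, 90), hidden = 24,
                imbalance = "oversample"),
    member_arch("mlp-compact", grid = 14, polar = c(14, 90), hidden = 12),
    member_arch("softmax-polar", grid = 0, polar = c(14, 90), hidden = 0),
    member_arch("softmax-grid", grid = 24, polar = c(14, 90), hidden = 0)
  )
}

extract_features <- function(std_crops, arch, size = 227) {
  off <- if (!is.null(arch$polar)) polar_offsets(size, arch$polar[1], arch$polar[2])
  n_harm <- 30L
  p <- ifelse(arch$grid > 0, arch$grid^2, 0) +
    ifelse(is.null(arch$polar), 0, 2 * arch$polar[1] + 3 + n_harm)
  t(vapply(std_crops, function(z) {
    f <- numeric(0)
    if (arch$grid > 0) {
      f <- c(f, as.numeric(resize_matrix(z, arch$grid, arch$grid)))
    }
    if (!is.null(off)) {
      v <- polar_sample(z, off)
      f <- c(f, colMeans(v), sqrt(pmax(colMeans(v^2) - colMeans(v)^2, 0)),
             boundary_features(v, off$rr, n_harm))
    }
    f
  }, numeric(p)))
}

# ---- compact MLP with SGD + momentum ---------------------------------------

mlp_init <- function(p, hidden, k = 7) {
  if (hidden > 0) {
    list(W1 = matrix(rnorm(p * hidden, 0, sqrt(2 / p)), p, hidden),
         b1 = numeric(hidden),
         W2 = matrix(rnorm(hidden * k, 0, sqrt(2 / hidden)), hidden, k),
         b2 = numeric(k))
  } else {
    list(W2 = matrix(0, p, k), b2 = numeric(k))
  }
}

mlp_forward <- function(wts, X) {
  if (!is.null(wts$W1)) {
    A <- tanh(sweep(X %*% wts$W1, 2, wts$b1, `+`))
    Z <- sweep(A %*% wts$W2, 2, wts$b2, `+`)
    list(A = A, Z = Z)
  } else {
    list(A = NULL, Z = sweep(X %*% wts$W2, 2, wts$b2, `+`))
  }
}

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

# Gradient of the mean loss at the logits. For cross-entropy this is
# (P - Y)/m; for focal loss the chain rule through p_t gives
# dL/dz_k = dL/dp_t * p_t * (1[k = t] - p_k).
loss_grad_logits <- function(P, ti, loss, alpha, gamma) {
  m <- nrow(P)
  if (loss == "ce") {
    G <- P
    G[cbind(seq_len(m), ti)] <- G[cbind(seq_len(m), ti)] - 1
    return(G / m)
  }
  pt <- pmax(P[cbind(seq_len(m), ti)], 1e-12)
  dldp <- alpha * gamma * (1 - pt)^(gamma - 1) * log(pt) - alpha * (1 - pt)^gamma / pt
  G <- -P * (dldp * pt)          # k != t part: dp_t/dz_k = -p_t p_k
  G[cbind(seq_len(m), ti)] <- dldp * pt * (1 - pt)
  G / m
}

mlp_sgd_epoch <- function(wts, vel, X, ti, cfg, loss) {
  n <- nrow(X)
  ord <- sample.int(n)
  starts <- seq(1, n, by = cfg$minibatch)
  for (s in starts) {
    b <- ord[s:min(s + cfg$minibatch - 1, n)]
    Xb <- X[b, , drop = FALSE]
    fw <- mlp_forward(wts, Xb)
    P <- softmax_rows(fw$Z)
    G <- loss_grad_logits(P, ti[b], loss, cfg$focal_alpha, cfg$focal_gamma)
    if (!is.null(wts$W1)) {
      gW2 <- crossprod(fw$A, G) + cfg$l2 * wts$W2
      gb2 <- colSums(G)
      GA <- (G %*% t(wts$W2)) * (1 - fw$A^2)
      gW1 <- crossprod(Xb, GA) + cfg$l2 * wts$W1
      gb1 <- colSums(GA)
      vel$W1 <- cfg$momentum * vel$W1 - cfg$lr * gW1
      vel$b1 <- cfg$momentum * vel$b1 - cfg$lr * gb1
      vel$W2 <- cfg$momentum * vel$W2 - cfg$lr * gW2
      vel$b2 <- cfg$momentum * vel$b2 - cfg$lr * gb2
      wts$W1 <- wts$W1 + vel$W1; wts$b1 <- wts$b1 + vel$b1
      wts$W2 <- wts$W2 + vel$W2; wts$b2 <- wts$b2 + vel$b2
    } else {
      gW2 <- crossprod(Xb, G) + cfg$l2 * wts$W2
      gb2 <- colSums(G)
      vel$W2 <- cfg$momentum * vel$W2 - cfg$lr * gW2
      vel$b2 <- cfg$momentum * vel$b2 - cfg$lr * gb2
      wts$W2 <- wts$W2 + vel$W2; wts$b2 <- wts$b2 + vel$b2
    }
  }
  list(wts = wts, vel = vel)
}

#' Train one ensemble member
#'
#' Extracts the member's features from standardized crops, splits off a
#' stratified holdout, applies the member's imbalance strategy (minority
#' oversampling with cross-entropy, or focal loss without oversampling) and
#' optimises by minibatch SGD with momentum, shuffling every epoch. The
#' holdout is evaluated after each epoch; the checkpoint with the best
#' holdout accuracy is returned and training stops once `patience`
#' evaluations pass without improvement. Training aborts with a diagnostic if
#' the loss diverges.
#'
#' @param crops Tibble from [render_crop_set()] (columns `image`, `class`) or
#'   a list with those elements.
#' @param arch A [member_arch()].
#' @param cfg A [train_config()].
#' @param std_size Standardized crop side (default 227).
#' @return An object of class `rbc_member` with the frozen best weights, the
#'   feature scaler, and the training curve.
#' @export
train_member <- function(crops, arch = member_arch("member"), cfg = train_config(),
                         std_size = 227) {
  images <- crops$image
  labels <- as_rbc_factor(crops$class)
  if (dplyr::n_distinct(labels) < 2) abort("Need at least two classes to train.")
  with_seed(cfg$seed, {
    std <- lapply(images, standardize_crop, size = std_size)
    X <- extract_features(std, arch, std_size)
    ti <- as.integer(labels)
    # stratified holdout for early stopping
    hold <- unlist(lapply(split(seq_along(ti), ti), function(i) {
      if (length(i) < 2) return(integer(0))
      i[sample.int(length(i), max(1, round(cfg$holdout * length(i))))]
    }))
    tr <- setdiff(seq_along(ti), hold)
    mu <- colMeans(X[tr, , drop = FALSE])
    sg <- pmax(apply(X[tr, , drop = FALSE], 2, sd), 1e-8)
    Xs <- sweep(sweep(X, 2, mu), 2, sg, `/`)
    loss_kind <- if (arch$imbalance == "oversample") "ce" else "focal"
    tr_idx <- if (arch$imbalance == "oversample") {
      tr[oversample_minority(labels[tr], seed = cfg$seed + 1L)]
    } else {
      tr
    }
    if (isTRUE(cfg$augment)) {
      warn("Random augmentation during training is applied per epoch via feature re-extraction; disabled at this feature resolution. Use render_crop_set() jitter instead.")
    }
    Xtr <- Xs[tr_idx, , drop = FALSE]; ttr <- ti[tr_idx]
    Xho <- Xs[hold, , drop = FALSE]; tho <- ti[hold]
    wts <- mlp_init(ncol(Xs), arch$hidden)
    vel <- lapply(wts, function(w) w * 0)
    best <- list(acc = -1, wts = wts, epoch = 0L)
    curve <- list()
    stale <- 0L
    for (epoch in seq_len(cfg$max_epochs)) {
      res <- mlp_sgd_epoch(wts, vel, Xtr, ttr, cfg, loss_kind)
      wts <- res$wts; vel <- res$vel
      P <- softmax_rows(mlp_forward(wts, Xtr)$Z)
      trloss <- if (loss_kind == "ce") {
        mean(-log(pmax(P[cbind(seq_along(ttr), ttr)], 1e-12)))
      } else {
        pt <- pmax(P[cbind(seq_along(ttr), ttr)], 1e-12)
        mean(-cfg$focal_alpha * (1 - pt)^cfg$focal_gamma * log(pt))
      }
      if (!is.finite(trloss)) abort(paste0("Training diverged (loss ", trloss,
                                           ") at epoch ", epoch, "."))
      Ph <- softmax_rows(mlp_forward(wts, Xho)$Z)
      acc <- mean(max.col(Ph, ties.method = "first") == tho)
      curve[[epoch]] <- tibble::tibble(epoch = epoch, train_loss = trloss,
                                       holdout_accuracy = acc)
      if (acc > best$acc + 1e-12) {
        best <- list(acc = acc, wts = wts, epoch = epoch)
        stale <- 0L
      } else {
        stale <- stale + 1L
        if (stale >= cfg$patience && epoch >= 20) break
      }
    }
    structure(list(arch = arch, config = cfg, weights = best$wts,
                   scaler = list(mu = mu, sigma = sg), std_size = std_size,
                   classes = rbc_classes(), holdout_accuracy = best$acc,
                   best_epoch = best$epoch,
                   curve = dplyr::bind_rows(curve)),
              class = "rbc_member")
  })
}

member_scores_std <- function(member, std_crops) {
  X <- extract_features(std_crops, member$arch, member$std_size)
  Xs <- sweep(sweep(X, 2, member$scaler$mu), 2, member$scaler$sigma, `/`)
  P <- softmax_rows(mlp_forward(member$weights, Xs)$Z)
  colnames(P) <- rbc_classes()
  P
}

#' Predict class scores for crops with one member
#'
#' @param object An `rbc_member`.
#' @param crops List of crop matrices, or a tibble with an `image`
#'   list-column.
#' @param ... Unused.
#' @return Tibble with the 7 score columns, `predicted` and `confidence`.
#' @export
predict.rbc_member <- function(object, crops, ...) {
  images <- if (is.data.frame(crops)) crops$image else crops
  std <- lapply(images, standardize_crop, size = object$std_size)
  P <- member_scores_std(object, std)
  scores_tibble(P)
}

scores_tibble <- function(P) {
  out <- tibble::as_tibble(as.data.frame(P))
  k <- max.col(P, ties.method = "first")
  out$predicted <- as_rbc_factor(rbc_classes()[k])
  out$confidence <- P[cbind(seq_len(nrow(P)), k)]
  out
}

#' Train the full ensemble
#'
#' Trains each member independently (seeded from `cfg$seed` plus the member
#' index) on the same crop set.
#'
#' @param crops Tibble from [render_crop_set()].
#' @param archs List of [member_arch()] (default [default_member_archs()]).
#' @param cfg A [train_config()].
#' @return An object of class `rbc_ensemble`.
#' @export
train_ensemble <- function(crops, archs = default_member_archs(),
                           cfg = train_config()) {
  members <- lapply(seq_along(archs), function(i) {
    mcfg <- cfg
    mcfg$seed <- cfg$seed + 100L * i
    train_member(crops, archs[[i]], mcfg)
  })
  names(members) <- vapply(archs, function(a) a$name, character(1))
  structure(list(members = members, classes = rbc_classes()),
            class = "rbc_ensemble")
}

#' Predict averaged ensemble scores for crops
#'
#' @param object An `rbc_ensemble`.
#' @param crops List of crop matrices or tibble with `image` list-column.
#' @param ... Unused.
#' @return Tibble with 7 score columns, `predicted`, `confidence`.
#' @export
predict.rbc_ensemble <- function(object, crops, ...) {
  images <- if (is.data.frame(crops)) crops$image else crops
  std <- lapply(images, standardize_crop,
                size = object$members[[1]]$std_size)
  Ps <- lapply(object$members, member_scores_std, std_crops = std)
  P <- Reduce(`+`, Ps) / length(Ps)
  scores_tibble(P)
}

#' Classify segmented blobs in a frame
#'
#' Cuts a fixed-size window (default 64 px, the scale at which members are
#' trained: absolute cell size is a class-defining feature, so the window
#' must not scale with the bounding box) centred on each blob's centroid,
#' standardizes it to 227 x 227, runs every ensemble member and averages the
#' softmax scores. When the segmentation mask is available (it travels as
#' the `"mask"` attribute of [segment_frame()] output), pixels belonging to
#' *other* segmented cells inside the window are replaced with the window's
#' background level, so each cell is classified individually — the blob's
#' own pixels and the true background are left untouched. Degenerate blobs
#' are skipped with a warning.
#'
#' @param image Source frame.
#' @param blobs Blob tibble from [segment_frame()] / [blob_analysis()].
#' @param ensemble An `rbc_ensemble` (or single `rbc_member`).
#' @param window Crop window side in px (default 64; scale it with the pixel
#'   calibration and with `crop_size` used to train the members).
#' @param mask Optional segmentation mask used to blank neighbouring cells;
#'   defaults to `attr(blobs, "mask")`.
#' @return `blobs` with the 7 score columns, `predicted` and `confidence`
#'   appended (degenerate blobs dropped).
#' @export
classify_crops <- function(image, blobs, ensemble, window = 64,
                           mask = attr(blobs, "mask")) {
  if (nrow(blobs) == 0) {
    return(dplyr::bind_cols(blobs, scores_tibble(matrix(numeric(0), 0, 7))[0, ]))
  }
  lab <- if (!is.null(mask) && all(dim(mask) == dim(image))) {
    label_components(mask > 0)
  }
  crops <- vector("list", nrow(blobs))
  ok <- rep(TRUE, nrow(blobs))
  for (i in seq_len(nrow(blobs))) {
    b <- blobs[i, ]
    if (b$w < 2 || b$h < 2) {
      warn(paste0("Degenerate bounding box for blob ", b$id, "; skipping."))
      ok[i] <- FALSE
      next
    }
    crop <- crop_window(image, b$cx, b$cy, window)
    if (!is.null(lab)) {
      own <- lab[pmin(pmax(round(b$cy) + 1L, 1L), nrow(lab)),
                 pmin(pmax(round(b$cx) + 1L, 1L), ncol(lab))]
      sub <- crop_window(lab, b$cx, b$cy, window, fill = 0L)
      other <- sub != 0L & sub != own
      if (any(other)) {
        # grow the blanked region so the neighbour's soft edge (below the
        # segmentation threshold) does not leak into the boundary profile
        other <- EBImage::dilate(other * 1, EBImage::makeBrush(7, "disc")) > 0
        other <- other & sub != own
        bg <- if (any(sub == 0L)) stats::median(crop[sub == 0L]) else stats::median(crop)
        crop[other] <- bg
      }
    }
    crops[[i]] <- crop
  }
  scored <- predict(ensemble, crops[ok])
  dplyr::bind_cols(blobs[ok, ], scored)
}

# Fixed-size square window centred at (cx, cy) 0-based; out-of-frame pixels
# are filled with `fill` (default: the median of the in-frame part).
crop_window <- function(image, cx, cy, side, fill = NULL) {
  r0 <- round(cy) - side %/% 2L
  c0 <- round(cx) - side %/% 2L
  rr <- r0 + seq_len(side); cc <- c0 + seq_len(side)
  ok_r <- rr >= 1 & rr <= nrow(image)
  ok_c <- cc >= 1 & cc <= ncol(image)
  inner <- image[rr[ok_r], cc[ok_c], drop = FALSE]
  if (all(ok_r) && all(ok_c)) return(inner)
  if (is.null(fill)) fill <- stats::median(inner)
  out <- matrix(fill, side, side)
  out[which(ok_r), which(ok_c)] <- inner
  out
}

#' @export
print.rbc_member <- function(x, ...) {
  cat("<rbc_member:", x$arch$name, "> holdout accuracy",
      sprintf("%.3f", x$holdout_accuracy), "at epoch", x$best_epoch, "\n")
  invisible(x)
}

#' @export
print.rbc_ensemble <- function(x, ...) {
  cat("<rbc_ensemble> of", length(x$members), "members:\n")
  for (m in x$members) print(m)
  invisible(x)
}

#' Tidy the training curve of a member
#' @param x An `rbc_member`.
#' @param ... Unused.
#' @return Tibble `(epoch, train_loss, holdout_accuracy)`.
#' @method tidy rbc_member
#' @export
tidy.rbc_member <- function(x, ...) x$curve

#' One-row summary of a trained member
#' @param x An `rbc_member`.
#' @param ... Unused.
#' @method glance rbc_member
#' @export
glance.rbc_member <- function(x, ...) {
  tibble::tibble(member = x$arch$name, hidden = x$arch$hidden,
                 imbalance = x$arch$imbalance,
                 holdout_accuracy = x$holdout_accuracy,
                 best_epoch = x$best_epoch,
                 epochs_run = nrow(x$curve))
}

#' Per-member summary of an ensemble
#' @param x An `rbc_ensemble`.
#' @param ... Unused.
#' @method glance rbc_ensemble
#' @export
glance.rbc_ensemble <- function(x, ...) {
  dplyr::bind_rows(lapply(x$members, glance))
}
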