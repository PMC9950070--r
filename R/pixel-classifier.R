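# Pluggable per-pixel foreground classifiers for the two-stage well/cell
# segmentation pathway, plus the focal Tversky loss used to fit and evaluate
# them. The interface is a contract: `label(image)` returns a logical raster
# of the same shape; any model (including an external semantic-segmentation
# network) can be wrapped with `pixel_classifier()`.

#' Wrap a labelling function as a pixel classifier
#'
#' @param label Function taking an image matrix and returning a logical
#'   matrix of the same shape (`TRUE` = target class).
#' @param name Human-readable name.
#' @param meta Optional metadata list (training config, thresholds, ...).
#' @return An object of class `pixel_classifier`.
#' @export
pixel_classifier <- function(label, name = "custom", meta = list()) {
  stopifnot(is.function(label))
  structure(list(label = label, name = name, meta = meta),
            class = "pixel_classifier")
}

#' @export
print.pixel_classifier <- function(x, ...) {
  cat("<pixel_classifier:", x$name, ">\n")
  invisible(x)
}

#' Focal Tversky loss for pixel classification
#'
#' The Tversky index generalises Dice/Jaccard by weighting false positives by
#' `alpha` and false negatives by `beta` on soft (probabilistic) counts:
#' `TI = TP / (TP + alpha*FP + beta*FN)`; the focal form raises the
#' complement to `gamma`: `loss = (1 - TI)^gamma`. An empty prediction on an
#' empty target scores `TI = 1` (loss 0) by convention.
#'
#' @param pred Numeric matrix of foreground probabilities in `[0, 1]`.
#' @param target Logical (or 0/1) matrix of the same shape.
#' @param alpha False-positive weight (default 0.7).
#' @param beta False-negative weight (default 0.3).
#' @param gamma Focal exponent (default 0.75).
#' @return Scalar loss `>= 0`.
#' @export
#' @examples
#' t <- matrix(c(1, 1, 0, 0), 2, 2)
#' focal_tversky_loss(t, t)  # 0
focal_tversky_loss <- function(pred, target, alpha = 0.7, beta = 0.3, gamma = 0.75) {
  stopifnot(all(dim(pred) == dim(target)))
  if (any(pred < 0 | pred > 1)) abort("`pred` must be probabilities in [0, 1].")
  t <- as.numeric(target > 0)
  p <- as.numeric(pred)
  tp <- sum(p * t); fp <- sum(p * (1 - t)); fn <- sum((1 - p) * t)
  ti <- if (tp + fp + fn == 0) 1 else tp / (tp + alpha * fp + beta * fn)
  (1 - ti)^gamma
}

# Per-pixel feature stack: intensity plus local means and a local dispersion
# at two scales (windows 15 and 31 px), all with replicate borders.
pixel_features <- function(image) {
  m15 <- local_statistic(image, "mean", c(15L, 15L))
  m31 <- local_statistic(image, "mean", c(31L, 31L))
  v15 <- local_statistic(image^2, "mean", c(15L, 15L)) - m15^2
  cbind(i = as.numeric(image), m15 = as.numeric(m15),
        m31 = as.numeric(m31), s15 = as.numeric(sqrt(pmax(v15, 0))))
}

#' Train the default per-pixel classifier
#'
#' A logistic model over intensity and multi-scale local mean/dispersion
#' features, fitted on a balanced pixel sample from the training pairs. The
#' binarisation threshold on the predicted probability is then chosen to
#' minimise the mean focal Tversky loss over the training images, so the
#' loss's asymmetric false-positive/false-negative weighting shapes the final
#' labelling. Any stronger model can replace it via [pixel_classifier()].
#'
#' @param images List of image matrices.
#' @param masks List of logical target masks, same shapes.
#' @param alpha,beta,gamma Focal Tversky parameters (defaults 0.7 / 0.3 /
#'   0.75).
#' @param sample_per_image Pixels sampled per class per image for the fit.
#' @param seed Integer seed.
#' @return A `pixel_classifier`.
#' @export
train_pixel_classifier <- function(images, masks, alpha = 0.7, beta = 0.3,
                                   gamma = 0.75, sample_per_image = 2000,
                                   seed = 1L) {
  stopifnot(length(images) == length(masks), length(images) >= 1)
  with_seed(seed, {
    feats <- list(); labs <- list()
    for (i in seq_along(images)) {
      f <- pixel_features(images[[i]])
      y <- as.numeric(masks[[i]] > 0)
      fg <- which(y == 1); bg <- which(y == 0)
      take <- c(
        fg[sample.int(length(fg), min(sample_per_image, length(fg)))],
        bg[sample.int(length(bg), min(sample_per_image, length(bg)))]
      )
      feats[[i]] <- f[take, , drop = FALSE]
      labs[[i]] <- y[take]
    }
    X <- do.call(rbind, feats)
    y <- unlist(labs)
    # clean synthetic scenes can be perfectly separable; the resulting
    # non-converged coefficients still rank pixels correctly
    fit <- suppressWarnings(stats::glm.fit(cbind(1, X), y, family = stats::binomial()))
    coefs <- fit$coefficients
    prob_fn <- function(image) {
      eta <- cbind(1, pixel_features(image)) %*% coefs
      matrix(1 / (1 + exp(-eta)), nrow(image), ncol(image))
    }
    # threshold chosen against the focal Tversky loss on the training pairs
    taus <- seq(0.05, 0.95, by = 0.05)
    loss <- vapply(taus, function(tau) {
      mean(vapply(seq_along(images), function(i) {
        focal_tversky_loss((prob_fn(images[[i]]) >= tau) * 1, masks[[i]],
                           alpha, beta, gamma)
      }, numeric(1)))
    }, numeric(1))
    tau <- taus[which.min(loss)]
    pixel_classifier(
      label = function(image) prob_fn(image) >= tau,
      name = "logistic-multiscale",
      meta = list(coefficients = coefs, threshold = tau,
                  loss = list(alpha = alpha, beta = beta, gamma = gamma))
    )
  })
}

resize_matrix <- function(x, nr, nc) {
  as.matrix(EBImage::resize(x, w = nr, h = nc))
}

#' Find microfluidic wells in a frame
#'
#' Classifies pixels at half scale, upscales the mask back to full size,
#' cleans it with a morphological opening, and returns the bounding boxes of
#' the remaining components.
#'
#' @param image Numeric matrix in `[0, 1]`.
#' @param clf A `pixel_classifier` trained to label well pixels.
#' @param open_radius Disk radius for the opening (default 3).
#' @param min_area Minimum well component area in px^2 at full scale.
#' @return Tibble of well boxes `(x, y, w, h)`; empty (with a warning) if no
#'   wells are found.
#' @export
find_wells <- function(image, clf, open_radius = 3, min_area = 400) {
  stopifnot(inherits(clf, "pixel_classifier"))
  half <- resize_matrix(image, nrow(image) %/% 2L, ncol(image) %/% 2L)
  m <- clf$label(half)
  stopifnot(all(dim(m) == dim(half)))
  full <- resize_matrix(m * 1, nrow(image), ncol(image)) > 0.5
  if (open_radius >= 1) {
    kern <- EBImage::makeBrush(2L * as.integer(open_radius) + 1L, "disc")
    full <- EBImage::opening(full * 1, kern) > 0
  }
  blobs <- blob_analysis(full, min_area = min_area)
  if (nrow(blobs) == 0) warn("No wells found.")
  blobs[, c("x", "y", "w", "h")]
}

#' Segment cells inside one well
#'
#' Crops the well, pads the crop to `pad_to` x `pad_to`, resizes it to
#' `model_size` for the pixel classifier, maps the label raster back through
#' the same geometry, cleans it (opening radius 3, dilation radius 2), splits
#' touching cells by watershed and drops blobs below `min_area`. Blob
#' coordinates are mapped back to full-frame 0-based coordinates.
#'
#' @param image Full frame, numeric matrix in `[0, 1]`.
#' @param well One-row data frame / list with `x, y, w, h` (0-based,
#'   half-open).
#' @param clf A `pixel_classifier` trained to label cell pixels in well crops.
#' @param pad_to Padded crop side (default 170).
#' @param model_size Classifier input side (default 224).
#' @param min_area Minimum blob area in px^2 (default 100).
#' @param open_radius,dilate_radius Structuring-element radii (defaults 3
#'   and 2).
#' @return Tibble of blobs as in [blob_analysis()], in full-frame
#'   coordinates.
#' @export
segment_well <- function(image, well, clf, pad_to = 170, model_size = 224,
                         min_area = 100, open_radius = 3, dilate_radius = 2) {
  stopifnot(inherits(clf, "pixel_classifier"))
  x0 <- max(0L, as.integer(well$x)); y0 <- max(0L, as.integer(well$y))
  x1 <- min(ncol(image), as.integer(well$x + well$w))
  y1 <- min(nrow(image), as.integer(well$y + well$h))
  if (x1 - x0 < 2 || y1 - y0 < 2) {
    warn("Degenerate well box; skipping.")
    return(blob_analysis(matrix(FALSE, 1, 1)))
  }
  crop <- image[(y0 + 1):y1, (x0 + 1):x1, drop = FALSE]
  ch <- nrow(crop); cw <- ncol(crop)
  side <- max(pad_to, ch, cw)
  py <- (side - ch) %/% 2L; px <- (side - cw) %/% 2L
  padded <- matrix(stats::median(crop), side, side)
  padded[py + seq_len(ch), px + seq_len(cw)] <- crop
  m <- clf$label(resize_matrix(padded, model_size, model_size))
  stopifnot(all(dim(m) == c(model_size, model_size)))
  m <- resize_matrix(m * 1, side, side) > 0.5
  m <- m[py + seq_len(ch), px + seq_len(cw), drop = FALSE]  # unpad
  if (open_radius >= 1) {
    kern <- EBImage::makeBrush(2L * as.integer(open_radius) + 1L, "disc")
    m <- EBImage::opening(m * 1, kern) > 0
  }
  if (dilate_radius >= 1) {
    kern <- EBImage::makeBrush(2L * as.integer(dilate_radius) + 1L, "disc")
    m <- EBImage::dilate(m * 1, kern) > 0
  }
  m <- split_touching(m, 1)
  blobs <- blob_analysis(m, min_area)
  blobs$cx <- blobs$cx + x0
  blobs$cy <- blobs$cy + y0
  blobs$x <- blobs$x + x0
  blobs$y <- blobs$y + y0
  blobs
}
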