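# Frame segmentation: adaptive thresholding (local mean / median / gaussian),
# mask cleanup (hole filling, erosion/dilation), watershed splitting of
# touching cells, and blob analysis. Coordinates are 0-based, x right / y
# down; bounding boxes are (x, y, w, h) half-open. The published predecessor
# of this pipeline used MATLAB's 1-based convention; subtract 1 from each
# coordinate to convert.

#' Default adaptive-threshold neighborhood for an image size
#'
#' Per dimension, one plus two times the floor of the dimension divided
#' by 16 — so each window side is odd and scales with the frame.
#'
#' @param image_size `(height, width)` in px.
#' @return Integer vector `(height, width)` of odd window sides.
#' @export
#' @examples
#' default_neighborhood(c(1280, 1024))  # 161 129
default_neighborhood <- function(image_size) {
  image_size <- as.integer(image_size)
  stopifnot(length(image_size) == 2, all(image_size >= 1))
  2L * (image_size %/% 16L) + 1L
}

#' Adaptive-thresholding parameters
#'
#' @param statistic Local central-tendency statistic: `"median"` (default,
#'   robust to bright debris), `"mean"`, or `"gaussian"` (Gaussian-weighted
#'   mean with sigma = side/6).
#' @param neighborhood `(height, width)` odd window sides, or `NULL` to use
#'   [default_neighborhood()] of each image.
#' @param polarity `"dark"` (foreground darker than its surroundings — cells
#'   under blue-light bright-field illumination) or `"bright"`.
#' @param sensitivity Offset subtracted from (dark) / added to (bright) the
#'   local statistic before the strict comparison. The default 0.05 (about
#'   two standard deviations of typical sensor noise at this contrast, and
#'   well above one quantisation level) keeps noisy or shaded backgrounds
#'   out of the foreground while costing only a fraction of a pixel at the
#'   steep cell boundary; set 0 for the bare comparison.
#' @param speck_radius Maximum radius (px) of specks removed before watershed
#'   (components of area below pi * r^2 are dropped); 0 disables.
#' @param h_minima H-minima suppression scalar for the watershed split.
#' @param morph_disk_radius Disk radius (px) for the erode + dilate cleanup.
#' @return A list of class `threshold_params`.
#' @export
threshold_params <- function(statistic = c("median", "mean", "gaussian"),
                             neighborhood = NULL, polarity = c("dark", "bright"),
                             sensitivity = 0.05, speck_radius = 0, h_minima = 1,
                             morph_disk_radius = 6) {
  statistic <- match.arg(statistic)
  polarity <- match.arg(polarity)
  if (!is.null(neighborhood)) {
    neighborhood <- as.integer(neighborhood)
    if (length(neighborhood) != 2 || any(neighborhood < 1) || any(neighborhood %% 2 == 0)) {
      abort("`neighborhood` must be two positive odd integers (height, width).")
    }
  }
  structure(list(statistic = statistic, neighborhood = neighborhood,
                 polarity = polarity, sensitivity = sensitivity,
                 speck_radius = speck_radius, h_minima = h_minima,
                 morph_disk_radius = morph_disk_radius),
            class = "threshold_params")
}

pad_replicate <- function(x, ry, rx) {
  h <- nrow(x); w <- ncol(x)
  x[c(rep(1L, ry), seq_len(h), rep(h, ry)),
    c(rep(1L, rx), seq_len(w), rep(w, rx)), drop = FALSE]
}

# Banded smoothing matrix for one dimension with replicate padding folded
# into the edge rows; weights w indexed -r..r.
band_matrix <- function(n, wts) {
  r <- (length(wts) - 1L) %/% 2L
  A <- matrix(0, n, n)
  for (k in seq_along(wts)) {
    off <- k - r - 1L
    j <- pmin(pmax(seq_len(n) + off, 1L), n)   # replicate at the edges
    A[cbind(seq_len(n), j)] <- A[cbind(seq_len(n), j)] + wts[k]
  }
  A
}

#' Local central-tendency image
#'
#' Computes the per-pixel local mean, Gaussian-weighted mean, or (lower)
#' median over a rectangular window with replicate padding at the borders.
#' The median path quantises intensities to 256 levels.
#'
#' @param image Numeric matrix in `[0, 1]`.
#' @param statistic `"mean"`, `"median"` or `"gaussian"`.
#' @param neighborhood `(height, width)` odd window sides.
#' @return Matrix of local statistics, same shape as `image`.
#' @export
local_statistic <- function(image, statistic, neighborhood) {
  ry <- (neighborhood[1] - 1L) %/% 2L
  rx <- (neighborhood[2] - 1L) %/% 2L
  if (statistic == "median") {
    q <- matrix(as.integer(round(clamp01(image) * 255)), nrow(image), ncol(image))
    return(local_median_cpp(pad_replicate(q, ry, rx), ry, rx) / 255)
  }
  wy <- if (statistic == "gaussian") {
    s <- max(neighborhood[1] / 6, 1e-9); k <- exp(-((-ry:ry)^2) / (2 * s^2)); k / sum(k)
  } else {
    rep(1 / neighborhood[1], neighborhood[1])
  }
  wx <- if (statistic == "gaussian") {
    s <- max(neighborhood[2] / 6, 1e-9); k <- exp(-((-rx:rx)^2) / (2 * s^2)); k / sum(k)
  } else {
    rep(1 / neighborhood[2], neighborhood[2])
  }
  band_matrix(nrow(image), wy) %*% image %*% t(band_matrix(ncol(image), wx))
}

#' Adaptive thresholding
#'
#' A different threshold is computed for every pixel from the central
#' tendency of its neighborhood, making the binarisation robust to smooth
#' illumination gradients. With dark polarity a pixel is foreground iff its
#' intensity is strictly below its local statistic minus `sensitivity`.
#'
#' @param image Numeric matrix in `[0, 1]`.
#' @param params A [threshold_params()].
#' @return Logical matrix (`TRUE` = foreground).
#' @export
adaptive_threshold <- function(image, params = threshold_params()) {
  stopifnot(is.matrix(image), inherits(params, "threshold_params"))
  nb <- params$neighborhood %||% default_neighborhood(dim(image))
  if (any(nb > dim(image))) {
    warn("Neighborhood larger than image; clamping to image size.")
    nb <- pmin(nb, dim(image))
    nb <- nb - 1L + nb %% 2L  # keep odd
  }
  stat <- local_statistic(image, params$statistic, nb)
  # the median statistic lives on the 256-level grid; compare the image on
  # the same grid so a flat field stays empty
  cmp <- if (params$statistic == "median") round(image * 255) / 255 else image
  if (params$polarity == "dark") {
    cmp < stat - params$sensitivity
  } else {
    cmp > stat + params$sensitivity
  }
}

# Fill holes, including those touching a single image border (via the
# one-side padding trick); holes touching two or more borders are left open.
fill_holes <- function(mask) {
  m <- EBImage::fillHull(mask) > 0
  h <- nrow(mask); w <- ncol(mask)
  pads <- list(
    function(x) rbind(TRUE, x), function(x) rbind(x, TRUE),
    function(x) cbind(TRUE, x), function(x) cbind(x, TRUE)
  )
  crops <- list(
    function(x) x[-1, , drop = FALSE], function(x) x[-(h + 1), , drop = FALSE],
    function(x) x[, -1, drop = FALSE], function(x) x[, -(w + 1), drop = FALSE]
  )
  for (i in 1:4) {
    filled <- crops[[i]](EBImage::fillHull(pads[[i]](mask)) > 0)
    m <- m | filled
  }
  m
}

#' Clean a binary mask
#'
#' Fills holes (including border-touching ones) and then erodes and dilates
#' the mask with a disk structuring element, which removes specks smaller
#' than the erosion element while approximately preserving smooth blobs.
#'
#' @param mask Logical matrix.
#' @param disk_radius Disk radius in px (default 6).
#' @return Logical matrix.
#' @export
clean_mask <- function(mask, disk_radius = 6) {
  stopifnot(is.matrix(mask))
  mask <- mask > 0
  if (!any(mask)) return(mask)
  m <- fill_holes(mask)
  if (disk_radius >= 1) {
    kern <- EBImage::makeBrush(2L * as.integer(disk_radius) + 1L, "disc")
    m <- EBImage::dilate(EBImage::erode(m * 1, kern), kern) > 0
  }
  m
}

#' Split touching cells by watershed
#'
#' Runs the watershed transform on the distance map of the mask (equivalent
#' to flooding the negative distance transform), with H-minima suppression of
#' shallow basins controlled by `h_minima`, and sets ridge pixels between
#' distinct catchment basins to background so that touching convex blobs
#' become separate 8-connected components. Foreground never grows and
#' components never merge.
#'
#' @param mask Logical matrix.
#' @param h_minima Minimum basin depth for a separate object (default 1).
#' @return Logical matrix with ridge lines removed.
#' @export
split_touching <- function(mask, h_minima = 1) {
  stopifnot(is.matrix(mask))
  mask <- mask > 0
  if (!any(mask)) return(mask)
  d <- EBImage::distmap(mask * 1)
  lab <- EBImage::watershed(d, tolerance = h_minima, ext = 1)
  lab <- matrix(as.integer(lab), nrow(mask), ncol(mask))
  ridge <- matrix(FALSE, nrow(mask), ncol(mask))
  h <- nrow(lab); w <- ncol(lab)
  shifts <- list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1),
                 c(1, 1), c(1, -1), c(-1, 1), c(-1, -1))
  for (s in shifts) {
    rs <- seq_len(h) + s[1]; cs <- seq_len(w) + s[2]
    ok_r <- rs >= 1 & rs <= h; ok_c <- cs >= 1 & cs <= w
    nb <- matrix(0L, h, w)
    nb[ok_r, ok_c] <- lab[rs[ok_r], cs[ok_c]]
    # remove the higher-labelled side of each inter-object adjacency: leaves
    # a thin background ridge and guarantees 8-connected separation
    ridge <- ridge | (lab > 0L & nb > 0L & nb < lab)
  }
  mask & lab > 0L & !ridge
}

# 8-connected labelling: EBImage's 4-connected bwlabel plus union-find
# merging of diagonally adjacent labels.
label_components <- function(mask) {
  lab <- matrix(as.integer(EBImage::bwlabel(mask * 1)), nrow(mask), ncol(mask))
  nl <- max(lab)
  if (nl < 2) return(lab)
  h <- nrow(lab); w <- ncol(lab)
  a1 <- lab[-h, -w]; b1 <- lab[-1, -1]    # down-right diagonal
  a2 <- lab[-1, -w]; b2 <- lab[-h, -1]    # up-right diagonal
  pairs <- rbind(
    cbind(a1[a1 > 0 & b1 > 0 & a1 != b1], b1[a1 > 0 & b1 > 0 & a1 != b1]),
    cbind(a2[a2 > 0 & b2 > 0 & a2 != b2], b2[a2 > 0 & b2 > 0 & a2 != b2])
  )
  parent <- seq_len(nl)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  if (nrow(pairs) > 0) {
    for (k in seq_len(nrow(pairs))) {
      ra <- find(pairs[k, 1]); rb <- find(pairs[k, 2])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  roots <- vapply(seq_len(nl), find, integer(1))
  compact <- match(roots, sort(unique(roots)))
  out <- lab
  out[lab > 0] <- compact[lab[lab > 0]]
  out
}

#' Blob analysis of a binary mask
#'
#' One blob per 8-connected component with area at least `min_area`:
#' pixel area, sub-pixel centroid (mean of 0-based pixel coordinates) and
#' half-open bounding box `(x, y, w, h)`. Blobs are ordered top-left first
#' (by bounding-box y, then x).
#'
#' @param mask Logical matrix.
#' @param min_area Minimum component area in px^2.
#' @return Tibble `(id, area, cx, cy, x, y, w, h)`.
#' @export
#' @examples
#' m <- matrix(FALSE, 20, 20); m[6:15, 6:15] <- TRUE
#' blob_analysis(m)
blob_analysis <- function(mask, min_area = 0) {
  stopifnot(is.matrix(mask))
  mask <- mask > 0
  empty <- tibble::tibble(id = integer(), area = integer(), cx = numeric(),
                          cy = numeric(), x = integer(), y = integer(),
                          w = integer(), h = integer())
  if (!any(mask)) return(empty)
  lab <- label_components(mask)
  idx <- which(lab > 0)
  l <- lab[idx]
  rows <- ((idx - 1L) %% nrow(mask))      # 0-based y
  cols <- ((idx - 1L) %/% nrow(mask))     # 0-based x
  df <- tibble::tibble(
    area = as.integer(tabulate(l)),
    cx = as.numeric(rowsum(cols, l)) / tabulate(l),
    cy = as.numeric(rowsum(rows, l)) / tabulate(l),
    x = as.integer(tapply(cols, l, min)),
    y = as.integer(tapply(rows, l, min)),
    xmax = as.integer(tapply(cols, l, max)),
    ymax = as.integer(tapply(rows, l, max))
  )
  df$w <- df$xmax - df$x + 1L
  df$h <- df$ymax - df$y + 1L
  df <- df[df$area >= min_area, ]
  df <- df[order(df$y, df$x), ]
  if (nrow(df) == 0) return(empty)
  tibble::tibble(id = seq_len(nrow(df)), df[, c("area", "cx", "cy", "x", "y", "w", "h")])
}

#' Segment a frame end to end
#'
#' Adaptive threshold, mask cleanup, watershed splitting, blob analysis.
#'
#' @param image Numeric matrix in `[0, 1]`.
#' @param params A [threshold_params()].
#' @param min_area Minimum blob area in px^2 (default 100, the conventional
#'   floor for a whole cell at this pixel scale).
#' @return A tibble of blobs as in [blob_analysis()], with the final `mask`
#'   attached as attribute `"mask"`.
#' @export
segment_frame <- function(image, params = threshold_params(), min_area = 100) {
  m <- adaptive_threshold(image, params)
  m <- clean_mask(m, params$morph_disk_radius)
  if (params$speck_radius > 0) {
    lab <- label_components(m)
    small <- which(tabulate(lab[lab > 0]) < pi * params$speck_radius^2)
    m[lab %in% small] <- FALSE
  }
  m <- split_touching(m, params$h_minima)
  out <- blob_analysis(m, min_area)
  attr(out, "mask") <- m
  out
}
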