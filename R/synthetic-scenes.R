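# Synthetic bright-field scene generator: dark cells on a bright background
# with smooth illumination gradients, seven separable shape classes, optional
# touching clumps, microfluidic-well foregrounds and constant-velocity motion.
# Ground truth (masks, classes, areas, per-frame identities) is returned with
# every render so downstream modules are testable without microscope data.

clamp01 <- function(x) pmin(pmax(x, 0), 1)

# Run `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards so fixture generation never perturbs user RNG.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

#' Specify one synthetic cell
#'
#' @param class Morphology class code (one of [rbc_classes()]).
#' @param x,y Centre in pixels, 0-based, x right / y down.
#' @param base_radius Base radius in px; `NULL` takes the class default from
#'   [class_geometry()].
#' @param spicule_count,spicule_depth Number of spicules and their depth as a
#'   fraction of the radius; `NULL` takes the class defaults.
#' @param intensity Body intensity of the (dark) cell in `[0, 1]`.
#' @param vx,vy Velocity in px/frame, used by [render_sequence()].
#' @return One-row tibble describing the cell.
#' @export
cell_spec <- function(class, x, y, base_radius = NULL, spicule_count = NULL,
                      spicule_depth = NULL, intensity = 0.35, vx = 0, vy = 0) {
  class <- as.character(class)
  geom <- class_geometry()
  g <- geom[match(class, as.character(geom$class)), ]
  tibble::tibble(
    class = class,
    x = as.numeric(x), y = as.numeric(y),
    base_radius = as.numeric(base_radius %||% g$base_radius),
    spicule_count = as.integer(spicule_count %||% g$spicule_count),
    spicule_depth = as.numeric(spicule_depth %||% g$spicule_depth),
    pallor = g$pallor,
    pallor_offset = g$pallor_offset,
    intensity = intensity,
    vx = as.numeric(vx), vy = as.numeric(vy)
  )
}

#' Specify additive or multiplicative image noise
#'
#' Gaussian noise adds zero-mean normal deviates of the stated variance;
#' speckle multiplies each pixel by `1 + u` with `u` zero-mean normal of the
#' stated variance. Output is always clipped to `[0, 1]`.
#'
#' @param kind `"none"`, `"gaussian"` or `"speckle"`.
#' @param level Variance parameter, `>= 0`. Level 0 leaves the image unchanged.
#' @return A list of class `noise_spec`.
#' @export
noise_spec <- function(kind = c("none", "gaussian", "speckle"), level = 0) {
  kind <- match.arg(kind)
  if (!is.numeric(level) || length(level) != 1 || is.na(level) || level < 0) {
    abort("`level` must be a single non-negative number.")
  }
  structure(list(kind = kind, level = as.numeric(level)), class = "noise_spec")
}

#' Specify a synthetic scene
#'
#' @param image_size `(height, width)` in px.
#' @param cells Tibble of cells, usually `dplyr::bind_rows()` of [cell_spec()]
#'   calls (may be empty).
#' @param background_level Background intensity in `[0, 1]` (cells are dark on
#'   a bright field).
#' @param illumination_gradient Peak-to-centre amplitude of a smooth low-order
#'   polynomial shading added to the background, in intensity units.
#' @param noise A [noise_spec()].
#' @param seed Integer seed; a fixed seed makes every render byte-identical.
#' @return A list of class `scene_spec`.
#' @export
scene_spec <- function(image_size = c(256, 256), cells = NULL,
                       background_level = 0.85, illumination_gradient = 0,
                       noise = noise_spec("none"), seed = 1L) {
  image_size <- as.integer(image_size)
  if (length(image_size) != 2 || any(image_size < 1)) {
    abort("`image_size` must be two positive integers (height, width).")
  }
  if (is.null(cells)) {
    cells <- cell_spec("D", 0, 0)[0, ]
  }
  if (nrow(cells) > 0) {
    inside <- cells$x >= 0 & cells$x <= image_size[2] - 1 &
      cells$y >= 0 & cells$y <= image_size[1] - 1
    if (!all(inside)) {
      abort("All cell centres must lie inside the image frame.")
    }
  }
  structure(
    list(image_size = image_size, cells = cells,
         background_level = background_level,
         illumination_gradient = illumination_gradient,
         noise = noise, seed = as.integer(seed)),
    class = "scene_spec"
  )
}

# Smooth polynomial shading field in [-1, 1] scaled by amplitude.
background_field <- function(h, w, level, gradient) {
  if (gradient == 0) {
    return(matrix(level, h, w))
  }
  ys <- seq(-1, 1, length.out = h)
  xs <- seq(-1, 1, length.out = w)
  shade <- outer(ys, xs, function(y, x) 0.6 * x + 0.3 * y + 0.1 * x * y)
  matrix(level, h, w) + gradient * shade
}

# Render one cell into (image, coverage) within its bounding window.
# Boundary: R(theta) = base_radius * (1 + depth * cos(count * theta + phase)).
render_one_cell <- function(img, coverage, cell, phase, pallor_angle, bg_level) {
  h <- nrow(img); w <- ncol(img)
  rmax <- cell$base_radius * (1 + cell$spicule_depth) + 2
  r0 <- max(1L, floor(cell$y - rmax) + 1L); r1 <- min(h, ceiling(cell$y + rmax) + 1L)
  c0 <- max(1L, floor(cell$x - rmax) + 1L); c1 <- min(w, ceiling(cell$x + rmax) + 1L)
  if (r0 > r1 || c0 > c1) {
    return(list(img = img, coverage = coverage, mask_idx = integer(0)))
  }
  yy <- (r0:r1) - 1 - cell$y
  xx <- (c0:c1) - 1 - cell$x
  dy <- matrix(yy, length(yy), length(xx))
  dx <- matrix(xx, length(yy), length(xx), byrow = TRUE)
  r <- sqrt(dx^2 + dy^2)
  theta <- atan2(dy, dx)
  rb <- cell$base_radius * (1 + cell$spicule_depth * cos(cell$spicule_count * theta + phase))
  rho <- r / pmax(rb, 1e-9)
  inside <- rho <= 1
  if (!any(inside)) {
    return(list(img = img, coverage = coverage, mask_idx = integer(0)))
  }
  # body intensity: dark base + central pallor (offset for stomatocytes) +
  # soft blend into the background over ~1.5 px inside the boundary
  px <- cell$pallor_offset * cell$base_radius * cos(pallor_angle)
  py <- cell$pallor_offset * cell$base_radius * sin(pallor_angle)
  dpall <- sqrt((dx - px)^2 + (dy - py)^2) / pmax(cell$base_radius, 1e-9)
  pall_w <- if (cell$pallor_offset > 0) 0.30 else 0.45   # slit pallor is narrower
  body <- cell$intensity + cell$pallor * (bg_level - cell$intensity) *
    exp(-(dpall / pall_w)^2)
  edge <- clamp01((1 - rho) * rb / 1.5)
  val <- edge * body + (1 - edge) * bg_level
  sub <- img[r0:r1, c0:c1]
  sub[inside] <- pmin(sub[inside], val[inside])
  img[r0:r1, c0:c1] <- sub
  # linear indices of this cell's mask in the full image
  rows <- matrix(r0:r1, length(yy), length(xx))
  cols <- matrix(c0:c1, length(yy), length(xx), byrow = TRUE)
  idx <- (cols[inside] - 1L) * h + rows[inside]
  coverage[idx] <- coverage[idx] + 1L
  list(img = img, coverage = coverage, mask_idx = idx)
}

#' Render a synthetic scene with ground truth
#'
#' Renders dark cells with class-specific size, spicule structure and central
#' pallor on a bright (optionally shaded) background, applies the configured
#' noise, and returns the exact foreground mask and a ground-truth blob table.
#'
#' @param spec A [scene_spec()].
#' @return A list with `image` (numeric matrix in `[0,1]`), `mask` (logical
#'   matrix, the exact rendered foreground), and `blobs`: a tibble with one
#'   row per cell (`id`, `class`, `x`, `y` centre of the rendered mask,
#'   `area` px^2 of the cell's own mask, `overlapping` flag).
#' @export
#' @examples
#' sc <- scene_spec(c(96, 96), cell_spec("D", 48, 48), seed = 7)
#' out <- render_scene(sc)
#' out$blobs
render_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  h <- spec$image_size[1]; w <- spec$image_size[2]
  with_seed(spec$seed, {
    img <- background_field(h, w, spec$background_level, spec$illumination_gradient)
    coverage <- integer(h * w)
    n <- nrow(spec$cells)
    masks <- vector("list", n)
    if (n > 0) {
      phases <- runif(n, 0, 2 * pi)
      pallor_angles <- runif(n, 0, 2 * pi)
      for (i in seq_len(n)) {
        res <- render_one_cell(img, coverage, spec$cells[i, ], phases[i],
                               pallor_angles[i], spec$background_level)
        img <- res$img; coverage <- res$coverage
        masks[[i]] <- res$mask_idx
      }
    }
    img <- add_noise(clamp01(img), spec$noise, seed = spec$seed + 1L)
    mask <- matrix(coverage > 0L, h, w)
    blobs <- purrr::map_dfr(seq_len(n), function(i) {
      idx <- masks[[i]]
      rows <- ((idx - 1L) %% h) + 1L
      cols <- ((idx - 1L) %/% h) + 1L
      tibble::tibble(
        id = i,
        class = spec$cells$class[i],
        x = mean(cols - 1), y = mean(rows - 1),
        area = length(idx),
        overlapping = any(coverage[idx] > 1L)
      )
    })
    list(image = img, mask = mask, blobs = blobs)
  })
}

#' Add seeded noise to an image
#'
#' @param image Numeric matrix in `[0, 1]`.
#' @param noise A [noise_spec()].
#' @param seed Integer seed for the noise draw.
#' @return Matrix of the same shape, clipped to `[0, 1]`.
#' @export
add_noise <- function(image, noise, seed = 1L) {
  stopifnot(is.matrix(image), inherits(noise, "noise_spec"))
  if (noise$kind == "none" || noise$level == 0) {
    return(image)
  }
  with_seed(seed, {
    s <- sqrt(noise$level)
    out <- switch(noise$kind,
      gaussian = image + rnorm(length(image), 0, s),
      speckle = image * (1 + rnorm(length(image), 0, s))
    )
    clamp01(matrix(out, nrow(image), ncol(image)))
  })
}

#' Render a longitudinal image sequence with ground-truth tracks
#'
#' Each cell moves at its constant `(vx, vy)` velocity plus seeded Gaussian
#' positional jitter. A cell whose centre leaves the frame is marked absent
#' from that frame onward (it never re-enters), which exercises track-loss
#' handling downstream.
#'
#' @param spec A [scene_spec()]; cell velocities come from its `cells`.
#' @param n_frames Number of frames, `>= 1`.
#' @param jitter_sd Positional jitter SD in px per frame (default 0.5).
#' @param render Render the pixel frames (default). With `render = FALSE`
#'   only the ground-truth motion table is generated (frames are `NULL`),
#'   which is cheap at any frame size and is what detection-level tracker
#'   benchmarks need.
#' @return A list with `frames` (list of image matrices, or of `NULL`) and
#'   `truth`: tibble `(frame, id, class, x, y, present)` with 1-based frames.
#' @export
render_sequence <- function(spec, n_frames, jitter_sd = 0.5, render = TRUE) {
  stopifnot(inherits(spec, "scene_spec"), n_frames >= 1)
  h <- spec$image_size[1]; w <- spec$image_size[2]
  n <- nrow(spec$cells)
  with_seed(spec$seed, {
    xs <- spec$cells$x; ys <- spec$cells$y
    alive <- rep(TRUE, n)
    frames <- vector("list", n_frames)
    truth <- vector("list", n_frames)
    for (f in seq_len(n_frames)) {
      if (f > 1 && n > 0) {
        xs <- xs + spec$cells$vx + rnorm(n, 0, jitter_sd)
        ys <- ys + spec$cells$vy + rnorm(n, 0, jitter_sd)
        alive <- alive & xs >= 0 & xs <= w - 1 & ys >= 0 & ys <= h - 1
      }
      cells_f <- spec$cells[alive, ]
      if (any(alive)) {
        cells_f$x <- xs[alive]
        cells_f$y <- ys[alive]
      }
      if (render) {
        fspec <- spec
        fspec$cells <- cells_f
        fspec$seed <- spec$seed + f
        # render without re-validating (cells outside were dropped, not rejected)
        frames[[f]] <- render_scene(structure(unclass(fspec), class = "scene_spec"))$image
      }
      truth[[f]] <- tibble::tibble(
        frame = f, id = seq_len(n), class = spec$cells$class,
        x = ifelse(alive, xs, NA_real_), y = ifelse(alive, ys, NA_real_),
        present = alive
      )
    }
    list(frames = frames, truth = dplyr::bind_rows(truth))
  })
}

#' Render a microfluidic-well scene
#'
#' Wells are drawn as darker rectangular rims on the background; every cell
#' must fall inside a well. Emulates longitudinal well-array acquisitions
#' where the well walls dominate the image foreground.
#'
#' @param spec A [scene_spec()]; each cell centre must lie inside some well.
#' @param wells Tibble/data.frame `(x, y, w, h)` of non-overlapping well
#'   boxes, 0-based half-open.
#' @param rim_width Rim thickness in px.
#' @param rim_intensity Rim intensity in `[0, 1]`.
#' @return A list with `image`, `well_mask` (logical, filled well interiors),
#'   `cell_masks` (list of logical matrices, one per well), and `blobs` as in
#'   [render_scene()] plus a `well` column.
#' @export
render_well_scene <- function(spec, wells, rim_width = 3, rim_intensity = 0.4) {
  stopifnot(inherits(spec, "scene_spec"))
  wells <- tibble::as_tibble(wells)
  h <- spec$image_size[1]; w <- spec$image_size[2]
  if (nrow(wells) > 1) {
    for (i in seq_len(nrow(wells) - 1)) {
      for (j in (i + 1):nrow(wells)) {
        ix <- max(wells$x[i], wells$x[j]) <
          min(wells$x[i] + wells$w[i], wells$x[j] + wells$w[j])
        iy <- max(wells$y[i], wells$y[j]) <
          min(wells$y[i] + wells$h[i], wells$y[j] + wells$h[j])
        if (ix && iy) abort("Wells must not overlap.")
      }
    }
  }
  well_of_cell <- integer(nrow(spec$cells))
  if (nrow(spec$cells) > 0) {
    for (i in seq_len(nrow(spec$cells))) {
      inw <- which(spec$cells$x[i] >= wells$x & spec$cells$x[i] < wells$x + wells$w &
                   spec$cells$y[i] >= wells$y & spec$cells$y[i] < wells$y + wells$h)
      if (length(inw) == 0) abort("Every cell must lie inside a well.")
      well_of_cell[i] <- inw[1]
    }
  }
  base <- render_scene(spec)
  img <- base$image
  well_mask <- matrix(FALSE, h, w)
  for (i in seq_len(nrow(wells))) {
    r0 <- wells$y[i] + 1L; r1 <- min(h, wells$y[i] + wells$h[i])
    c0 <- wells$x[i] + 1L; c1 <- min(w, wells$x[i] + wells$w[i])
    well_mask[r0:r1, c0:c1] <- TRUE
    rim <- rim_width
    # darker rim: outline band just inside the box
    sub <- img[r0:r1, c0:c1]
    nr <- nrow(sub); nc <- ncol(sub)
    band <- matrix(FALSE, nr, nc)
    band[c(seq_len(min(rim, nr)), nr - seq_len(min(rim, nr)) + 1), ] <- TRUE
    band[, c(seq_len(min(rim, nc)), nc - seq_len(min(rim, nc)) + 1)] <- TRUE
    sub[band] <- pmin(sub[band], rim_intensity)
    img[r0:r1, c0:c1] <- sub
  }
  cell_masks <- purrr::map(seq_len(nrow(wells)), function(i) {
    m <- base$mask
    keep <- matrix(FALSE, h, w)
    r0 <- wells$y[i] + 1L; r1 <- min(h, wells$y[i] + wells$h[i])
    c0 <- wells$x[i] + 1L; c1 <- min(w, wells$x[i] + wells$w[i])
    keep[r0:r1, c0:c1] <- TRUE
    m & keep
  })
  blobs <- base$blobs
  if (nrow(blobs) > 0) blobs$well <- well_of_cell
  list(image = img, well_mask = well_mask, cell_masks = cell_masks, blobs = blobs)
}

#' Draw a random scene of non-overlapping (or deliberately touching) cells
#'
#' Convenience generator for benchmarks: places `n` cells of random classes
#' uniformly in the frame, by rejection sampling so that no two cells come
#' closer than the sum of their outer radii plus `margin` (negative margins
#' create touching clumps).
#'
#' @param n Number of cells.
#' @param image_size `(height, width)` px.
#' @param classes Classes to sample from (default all seven).
#' @param margin Minimum extra gap between cell boundaries in px.
#' @param noise A [noise_spec()]; the default mild Gaussian sensor noise
#'   (variance 5e-4) matches [render_crop_set()] so scenes and training
#'   crops share one imaging condition.
#' @param illumination_gradient Background shading amplitude; the default
#'   0.02 sits mid-range of the slight illumination variation the crop
#'   generator draws, again keeping the two entry points consistent.
#' @param seed Integer seed.
#' @param ... Passed to [scene_spec()].
#' @return A [scene_spec()].
#' @export
random_scene <- function(n, image_size = c(384, 384), classes = rbc_classes(),
                         margin = 4, noise = noise_spec("gaussian", 5e-4),
                         illumination_gradient = 0.02, seed = 1L, ...) {
  geom <- class_geometry()
  with_seed(seed, {
    cls <- sample(classes, n, replace = TRUE)
    rad <- geom$base_radius[match(cls, as.character(geom$class))] *
      (1 + geom$spicule_depth[match(cls, as.character(geom$class))])
    xs <- numeric(n); ys <- numeric(n)
    for (i in seq_len(n)) {
      for (try in 1:500) {
        x <- runif(1, rad[i] + 2, image_size[2] - rad[i] - 3)
        y <- runif(1, rad[i] + 2, image_size[1] - rad[i] - 3)
        if (i == 1) break
        d <- sqrt((xs[seq_len(i - 1)] - x)^2 + (ys[seq_len(i - 1)] - y)^2)
        if (all(d >= rad[seq_len(i - 1)] + rad[i] + margin)) break
        if (try == 500) abort("Could not place cells without overlap; reduce `n`.")
      }
      xs[i] <- x; ys[i] <- y
    }
    cells <- dplyr::bind_rows(purrr::map(seq_len(n), function(i) {
      cell_spec(cls[i], xs[i], ys[i],
                base_radius = geom$base_radius[match(cls[i], as.character(geom$class))] *
                  runif(1, 0.96, 1.04))
    }))
    scene_spec(image_size, cells, noise = noise,
               illumination_gradient = illumination_gradient, seed = seed, ...)
  })
}

#' Render a labelled set of single-cell crops
#'
#' Generates the classifier benchmark: one cell per crop, centred with small
#' positional and radius jitter, random spicule phase, slight background
#' shading and mild Gaussian noise. Class counts may be imbalanced to
#' exercise oversampling / focal-loss strategies.
#'
#' @param n_per_class Either a single count used for all 7 classes or a named
#'   vector of per-class counts.
#' @param crop_size Side of the square crop in px.
#' @param scale Radius multiplier applied to the class geometry (default 1:
#'   crops share the scene pixel scale, so a discocyte spans ~60% of the
#'   default 64 px crop and absolute size stays a class feature).
#' @param noise_level Gaussian noise variance added to each crop.
#' @param seed Integer seed.
#' @return A tibble with list-column `image`, `class` (factor) and `id`.
#' @export
render_crop_set <- function(n_per_class = 50, crop_size = 64, scale = NULL,
                            noise_level = 5e-4, seed = 1L) {
  classes <- rbc_classes()
  counts <- if (is.null(names(n_per_class))) {
    stopifnot(length(n_per_class) == 1)
    setNames(rep(as.integer(n_per_class), 7), classes)
  } else {
    stopifnot(all(names(n_per_class) %in% classes))
    out <- setNames(rep(0L, 7), classes)
    out[names(n_per_class)] <- as.integer(n_per_class)
    out
  }
  geom <- class_geometry()
  scale <- scale %||% 1
  with_seed(seed, {
    rows <- purrr::map(classes, function(cl) {
      k <- counts[[cl]]
      if (k == 0) return(NULL)
      g <- geom[match(cl, as.character(geom$class)), ]
      purrr::map(seq_len(k), function(i) {
        ctr <- crop_size / 2 - 0.5 + rnorm(2, 0, 1.5)
        cells <- cell_spec(cl, ctr[1], ctr[2],
                           base_radius = g$base_radius * scale * runif(1, 0.94, 1.06),
                           intensity = runif(1, 0.30, 0.40))
        sp <- scene_spec(c(crop_size, crop_size), cells,
                         background_level = runif(1, 0.80, 0.88),
                         illumination_gradient = runif(1, 0, 0.04),
                         noise = noise_spec("gaussian", noise_level),
                         seed = sample.int(.Machine$integer.max %/% 2, 1))
        tibble::tibble(class = cl, image = list(render_scene(sp)$image))
      }) |> dplyr::bind_rows()
    })
    out <- dplyr::bind_rows(rows)
    out$class <- as_rbc_factor(out$class)
    out$id <- seq_len(nrow(out))
    out[, c("id", "class", "image")]
  })
}
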