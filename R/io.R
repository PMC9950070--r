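# Reading and writing the plain formats the pipeline exchanges: grayscale
# PNG/TIFF frames, PNG masks, blob/track CSVs and JSON/YAML configs.

need_pkg <- function(pkg) {
  if (!requireNamespace(pkg, quietly = TRUE)) {
    abort(paste0("Package '", pkg, "' is required for this image format."))
  }
}

#' Read a grayscale image
#'
#' PNG or TIFF; RGB inputs are averaged to gray. Returns a numeric matrix in
#' `[0, 1]` with rows = y (down) and columns = x (right).
#'
#' @param path File path.
#' @return Numeric matrix.
#' @export
read_gray_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- if (ext %in% c("tif", "tiff")) {
    need_pkg("tiff"); tiff::readTIFF(path)
  } else {
    need_pkg("png"); png::readPNG(path)
  }
  if (length(dim(img)) == 3) img <- apply(img[, , 1:min(3, dim(img)[3])], c(1, 2), mean)
  img
}

#' Write a grayscale image or mask as PNG
#'
#' @param image Numeric matrix in `[0, 1]` or logical mask.
#' @param path Output path.
#' @export
write_gray_png <- function(image, path) {
  need_pkg("png")
  png::writePNG(clamp01(image * 1), path)
  invisible(path)
}

#' Write blob detections as CSV
#'
#' Columns `frame, id, x, y, w, h, area, cx, cy` plus any score columns.
#'
#' @param blobs Blob tibble (optionally with a `frame` column).
#' @param path Output path.
#' @export
write_blobs_csv <- function(blobs, path) {
  if (!"frame" %in% names(blobs)) blobs <- dplyr::mutate(blobs, frame = 1L, .before = 1)
  utils::write.csv(blobs, path, row.names = FALSE)
  invisible(path)
}

#' Read/write segmentation parameters as YAML
#'
#' A plain-text round trip for [threshold_params()] so configurations can
#' travel with a run.
#'
#' @param path YAML file path.
#' @return `read_threshold_params()`: a [threshold_params()];
#'   `write_threshold_params()`: `path`, invisibly.
#' @export
read_threshold_params <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(threshold_params, cfg)
}

#' @rdname read_threshold_params
#' @param params A [threshold_params()].
#' @export
write_threshold_params <- function(params, path) {
  stopifnot(inherits(params, "threshold_params"))
  yaml::write_yaml(unclass(params), path)
  invisible(path)
}

#' Write a scene specification as JSON
#'
#' @param spec A [scene_spec()].
#' @param path Output path.
#' @export
write_scene_json <- function(spec, path) {
  jsonlite::write_json(
    list(image_size = spec$image_size, background_level = spec$background_level,
         illumination_gradient = spec$illumination_gradient,
         noise = unclass(spec$noise), seed = spec$seed,
         cells = spec$cells),
    path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}
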