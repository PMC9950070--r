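# End-to-end orchestration: preprocess -> segment -> classify -> track ->
# stats, with seeded determinism, config-hash provenance on every output and
# the expert-curation loop (export crops for relabelling, merge corrections,
# re-split for retraining).

#' Pipeline configuration
#'
#' @param mode `"frames"` (adaptive-threshold segmentation) or `"wells"`
#'   (two-stage well/cell pathway; requires `well_classifier` and
#'   `cell_classifier`).
#' @param segmentation A [threshold_params()].
#' @param min_area Minimum blob area in px^2.
#' @param ensemble A trained `rbc_ensemble` (or `rbc_member`).
#' @param well_classifier,cell_classifier `pixel_classifier`s for wells mode.
#' @param tracking `NULL` to disable, or a list with `params`
#'   ([kf_params()]) and `cost_unassigned`.
#' @param um_per_px Pixel calibration for diameters.
#' @param bootstrap_B Bootstrap replicates for the summary table (default
#'   2000 in the pipeline for turnaround; [class_diameter_stats()] itself
#'   defaults to 10000).
#' @param seed Integer seed propagated to all stochastic stages.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(mode = c("frames", "wells"),
                            segmentation = threshold_params(),
                            min_area = 100, ensemble = NULL,
                            well_classifier = NULL, cell_classifier = NULL,
                            tracking = NULL, um_per_px = 0.195,
                            bootstrap_B = 2000, seed = 1L) {
  mode <- match.arg(mode)
  if (mode == "wells" && (is.null(well_classifier) || is.null(cell_classifier))) {
    abort("Wells mode requires `well_classifier` and `cell_classifier`.")
  }
  structure(list(mode = mode, segmentation = segmentation, min_area = min_area,
                 ensemble = ensemble, well_classifier = well_classifier,
                 cell_classifier = cell_classifier, tracking = tracking,
                 um_per_px = um_per_px, bootstrap_B = bootstrap_B,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

config_hash <- function(config) {
  rlang::hash(config)
}

#' Run the pipeline on a set of frames
#'
#' Segments every frame, classifies every blob with the configured ensemble,
#' tracks detections across frames when tracking is enabled, summarises
#' per-class effective diameters, and (optionally) writes detections, tracks
#' and statistics as CSV plus a JSON provenance summary carrying the config
#' hash and seed. Reruns with the same config and seed are bit-reproducible.
#'
#' @param frames List of image matrices (or a single matrix).
#' @param config A [pipeline_config()] with a trained ensemble.
#' @param output_dir Optional directory for the run's outputs.
#' @return List of class `pipeline_run`: `detections`, `tracks` (or NULL),
#'   `stats`, `summary`, and `paths` when written.
#' @export
run_pipeline <- function(frames, config, output_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.matrix(frames)) frames <- list(frames)
  if (is.null(config$ensemble)) abort("Pipeline stage 'classify': no ensemble configured.")
  detections <- purrr::map_dfr(seq_along(frames), function(f) {
    img <- frames[[f]]
    blobs <- if (config$mode == "frames") {
      segment_frame(img, config$segmentation, config$min_area)
    } else {
      wells <- find_wells(img, config$well_classifier)
      purrr::map_dfr(seq_len(nrow(wells)), function(wi) {
        dplyr::mutate(segment_well(img, wells[wi, ], config$cell_classifier,
                                   min_area = config$min_area),
                      well = wi)
      })
    }
    if (nrow(blobs) == 0) return(NULL)
    blobs$id <- seq_len(nrow(blobs))
    scored <- classify_crops(img, blobs, config$ensemble)
    dplyr::mutate(scored, frame = f, .before = 1)
  })
  if (nrow(detections) == 0) abort("Pipeline stage 'segment': no cells detected in any frame.")
  tracks <- NULL
  if (!is.null(config$tracking) && length(frames) > 1) {
    tr <- track_sequence(detections,
                         params = config$tracking$params %||% kf_params(),
                         cost_unassigned = config$tracking$cost_unassigned %||% 20)
    tracks <- tidy(tr)
  }
  diam <- dplyr::mutate(detections,
                        diameter = effective_diameter(.data$area, config$um_per_px),
                        class = .data$predicted)
  stats_tbl <- class_diameter_stats(diam, B = config$bootstrap_B,
                                    seed = config$seed)
  summary <- list(config_hash = config_hash(config), seed = config$seed,
                  n_frames = length(frames), n_detections = nrow(detections),
                  n_tracks = if (is.null(tracks)) 0L else dplyr::n_distinct(tracks$track_id),
                  classes = as.list(table(as.character(detections$predicted))))
  paths <- NULL
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(
      detections = file.path(output_dir, "detections.csv"),
      stats = file.path(output_dir, "stats.csv"),
      summary = file.path(output_dir, "summary.json")
    )
    utils::write.csv(detections, paths$detections, row.names = FALSE)
    utils::write.csv(stats_tbl, paths$stats, row.names = FALSE)
    if (!is.null(tracks)) {
      paths$tracks <- file.path(output_dir, "tracks.csv")
      utils::write.csv(tracks, paths$tracks, row.names = FALSE)
    }
    jsonlite::write_json(summary, paths$summary, auto_unbox = TRUE, digits = NA)
  }
  structure(list(detections = detections, tracks = tracks, stats = stats_tbl,
                 summary = summary, paths = paths),
            class = "pipeline_run")
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("<pipeline_run>", x$summary$n_detections, "detections in",
      x$summary$n_frames, "frame(s);", x$summary$n_tracks, "tracks\n")
  invisible(x)
}

#' Export a stratified crop sample for expert curation
#'
#' Draws a seeded, class-stratified sample of classified detections (at
#' least one per non-empty class), writes each 227 x 227 crop as PNG and an
#' editable label sheet as CSV. Corrected sheets can be merged back into a
#' training manifest with [merge_curated()] to grow the training set.
#'
#' @param frames The frames the run was computed on.
#' @param detections Detections tibble from [run_pipeline()].
#' @param output_dir Directory for crops and `labels.csv`.
#' @param sample_size Total crops to export.
#' @param seed Integer seed.
#' @return The label-sheet tibble (`file, frame, id, predicted, label`).
#' @export
export_for_curation <- function(frames, detections, output_dir,
                                sample_size = 100, seed = 1L) {
  if (is.matrix(frames)) frames <- list(frames)
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  with_seed(seed, {
    by_class <- split(seq_len(nrow(detections)), as.character(detections$predicted))
    quota <- pmax(round(sample_size * lengths(by_class) / nrow(detections)), 1L)
    take <- unlist(purrr::imap(by_class, function(i, cl) {
      i[sample.int(length(i), min(quota[[cl]], length(i)))]
    }))
    sheet <- purrr::map_dfr(take, function(i) {
      d <- detections[i, ]
      img <- frames[[d$frame]]
      crop <- crop_window(img, d$cx, d$cy, 64)
      fn <- sprintf("crop_f%03d_id%04d.png", d$frame, d$id)
      write_gray_png(resize_matrix(crop, 227, 227), file.path(output_dir, fn))
      tibble::tibble(file = fn, frame = d$frame, id = d$id,
                     predicted = as.character(d$predicted),
                     label = as.character(d$predicted))
    })
    utils::write.csv(sheet, file.path(output_dir, "labels.csv"), row.names = FALSE)
    sheet
  })
}

#' Merge a corrected label sheet into a training manifest
#'
#' @param manifest Tibble with at least `file` and `label` (existing set).
#' @param corrected Label sheet from [export_for_curation()] after editing.
#' @return Manifest grown by exactly the corrected rows.
#' @export
merge_curated <- function(manifest, corrected) {
  dplyr::bind_rows(manifest,
                   dplyr::select(corrected, dplyr::any_of(c("file", "label"))))
}

#' Stratified train/test split of a labelled manifest
#'
#' Seeded, stratified by class, disjoint; the conventional split holds out
#' 10%. A class with a single item goes entirely to the training set with a
#' warning.
#'
#' @param manifest Tibble with a `label` (or `class`) column.
#' @param holdout Holdout fraction (default 0.10).
#' @param seed Integer seed.
#' @return List with `train` and `test` tibbles.
#' @export
split_train_test <- function(manifest, holdout = 0.10, seed = 1L) {
  if (nrow(manifest) == 0) abort("Manifest is empty.")
  lab <- if ("label" %in% names(manifest)) manifest$label else manifest$class
  with_seed(seed, {
    test_idx <- unlist(lapply(split(seq_len(nrow(manifest)), as.character(lab)),
                              function(i) {
      if (length(i) < 2) {
        warn("Class with a single item assigned entirely to the training set.")
        return(integer(0))
      }
      i[sample.int(length(i), max(1L, round(holdout * length(i))))]
    }))
    list(train = manifest[setdiff(seq_len(nrow(manifest)), test_idx), ],
         test = manifest[sort(test_idx), ])
  })
}
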