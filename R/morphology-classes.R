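#' The seven canonical morphology classes
#'
#' Stored red blood cells progress from the healthy biconcave discocyte (D)
#' through increasingly spiculated echinocyte stages (E1, E2, E3) to the
#' sphero-echinocyte (SE) and finally the smooth, rigid spherocyte (S); the
#' cup-shaped stomatocyte (ST) sits outside this echinocytic axis. The order
#' returned here is the canonical class order used everywhere in the package
#' (score columns, confusion matrices, argmax tie-breaking).
#'
#' @return Character vector of the 7 class codes, in canonical order.
#' @export
#' @examples
#' rbc_classes()
rbc_classes <- function() {
  c("D", "E1", "E2", "E3", "SE", "S", "ST")
}

#' The ordinal echinocytic axis
#'
#' The subset of classes that form the ordinal storage-lesion axis
#' (D, E1, E2, E3, SE, S); the stomatocyte is non-ordinal and is excluded.
#' Used by [off_by_one_fraction()] to decide whether a misclassification is
#' "off by one" stage.
#'
#' @return Character vector of the 6 ordinal class codes.
#' @export
rbc_ordinal_axis <- function() {
  c("D", "E1", "E2", "E3", "SE", "S")
}

as_rbc_factor <- function(x) {
  x <- as.character(x)
  bad <- setdiff(unique(x[!is.na(x)]), rbc_classes())
  if (length(bad) > 0) {
    abort(paste0("Unknown morphology class label(s): ", paste(bad, collapse = ", ")))
  }
  factor(x, levels = rbc_classes())
}

#' Published reference statistics for effective-diameter distributions
#'
#' Per-class descriptive statistics of the effective diameter of stored red
#' blood cells (measured on roughly 1.29 million segmented cells), as
#' published for the seven morphology classes: mean +/- SD, median, IQR, mean
#' and median absolute deviations, and sample size. These values serve as
#' reference inputs for effect-size computations and for parameterising the
#' synthetic fixture generator; they are not recomputed by this package.
#'
#' @return A tibble with one row per class: `class`, `mean`, `sd`, `median`,
#'   `iqr`, `mad_mean` (mean absolute deviation about the mean), `mad_median`
#'   (median absolute deviation about the median), `n`, all diameters in
#'   micrometres.
#' @export
#' @examples
#' reference_diameter_stats()
reference_diameter_stats <- function() {
  tibble::tibble(
    class = as_rbc_factor(rbc_classes()),
    mean = c(7.821, 7.800, 7.304, 6.433, 5.963, 5.904, 7.080),
    sd = c(0.429, 0.581, 0.567, 0.490, 0.348, 0.292, 0.522),
    median = c(7.816, 7.798, 7.318, 6.387, 5.948, 5.905, 7.084),
    iqr = c(0.580, 0.753, 0.753, 0.655, 0.433, 0.385, 0.696),
    mad_mean = c(0.342, 0.458, 0.451, 0.390, 0.268, 0.231, 0.415),
    mad_median = c(0.290, 0.377, 0.376, 0.324, 0.216, 0.193, 0.348),
    n = c(121571L, 368292L, 112885L, 167345L, 273332L, 224930L, 26641L)
  )
}

#' Default class-to-geometry map for the synthetic generator
#'
#' Geometry used to render each morphology class: base radius (px, at the
#' default scale where a 7.8 um discocyte is ~40 px across, i.e. 0.195
#' um/px), spicule count and relative spicule depth, and the central-pallor
#' amplitude. Radii follow the published diameter ordering
#' D ~ E1 > E2 > ST > E3 > SE ~ S; spicule counts are 0 for D and ST,
#' increase E1 -> E3, and are small/shallow for SE and S. The stomatocyte is
#' rendered with an offset slit-like pallor instead of the symmetric central
#' pallor of the discocyte.
#'
#' @param um_per_px Pixel calibration in micrometres per pixel. The source
#'   imaging systems never published a calibration, so it is exposed as a
#'   parameter; the default 0.195 makes a 7.8 um disc about 40 px wide.
#' @return A tibble with one row per class: `class`, `base_radius` (px),
#'   `spicule_count`, `spicule_depth` (fraction of radius), `pallor`
#'   (relative brightening of the cell centre), `pallor_offset` (fraction of
#'   radius the pallor centre is displaced, non-zero only for ST).
#' @export
class_geometry <- function(um_per_px = 0.195) {
  stopifnot(um_per_px > 0)
  ref <- reference_diameter_stats()
  tibble::tibble(
    class = ref$class,
    base_radius = ref$mean / 2 / um_per_px,
    spicule_count = c(0L, 6L, 12L, 20L, 26L, 0L, 0L),
    spicule_depth = c(0, 0.08, 0.15, 0.22, 0.06, 0, 0),
    pallor = c(0.30, 0.22, 0.12, 0.05, 0, 0, 0.25),
    pallor_offset = c(0, 0, 0, 0, 0, 0, 0.35)
  )
}
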