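# Calibration diagnostics for any classifier satisfying the member/ensemble
# contract: reliability bins, expected and maximum calibration error,
# confusion matrices with precision/recall margins, off-by-one error
# structure along the echinocytic axis, and noise-robustness curves.

#' Reliability bins for confidence scores
#'
#' Splits `[0, 1]` into `n_bins` equal-width bins (right-closed except the
#' first, so a confidence of exactly 1.0 falls in the last bin) and reports
#' per-bin counts, mean confidence and accuracy. Perfect calibration puts
#' every bin's accuracy on its mean confidence.
#'
#' @param confidences Numeric vector in `[0, 1]`.
#' @param correct Logical vector, `TRUE` where the prediction was right.
#' @param n_bins Number of equal-width bins (default 10).
#' @return Tibble `(bin, lo, hi, count, mean_confidence, accuracy, empty)`;
#'   `accuracy`/`mean_confidence` are `NA` for empty bins.
#' @export
reliability_bins <- function(confidences, correct, n_bins = 10) {
  if (length(confidences) == 0) abort("Need at least one prediction.")
  stopifnot(length(confidences) == length(correct))
  if (any(confidences < 0 | confidences > 1)) {
    abort("Confidences must lie in [0, 1].")
  }
  edges <- seq(0, 1, length.out = n_bins + 1)
  bin <- findInterval(confidences, edges, left.open = TRUE, all.inside = TRUE)
  tibble::tibble(bin = seq_len(n_bins), lo = edges[-(n_bins + 1)], hi = edges[-1]) |>
    dplyr::left_join(
      tibble::tibble(bin = bin, conf = confidences, ok = as.logical(correct)) |>
        dplyr::group_by(.data$bin) |>
        dplyr::summarise(count = dplyr::n(),
                         mean_confidence = mean(.data$conf),
                         accuracy = mean(.data$ok)),
      by = "bin"
    ) |>
    dplyr::mutate(count = dplyr::coalesce(.data$count, 0L),
                  empty = .data$count == 0L)
}

#' Expected calibration error
#'
#' Count-weighted average over bins of the absolute gap between bin accuracy
#' and bin mean confidence, as a percentage.
#'
#' @param bins Tibble from [reliability_bins()].
#' @return Percentage in `[0, 100]`.
#' @export
ece <- function(bins) {
  b <- bins[!bins$empty, ]
  if (nrow(b) == 0) abort("All bins are empty.")
  100 * sum(b$count * abs(b$accuracy - b$mean_confidence)) / sum(b$count)
}

#' Maximum calibration error
#'
#' Largest accuracy-confidence gap over the non-empty bins, as a percentage.
#'
#' @param bins Tibble from [reliability_bins()].
#' @return Percentage in `[0, 100]`.
#' @export
mce <- function(bins) {
  b <- bins[!bins$empty, ]
  if (nrow(b) == 0) abort("All bins are empty.")
  100 * max(abs(b$accuracy - b$mean_confidence))
}

#' Confusion matrix with precision/recall margins
#'
#' Rows are true classes, columns predicted classes. Per-class precision
#' (column-wise), recall (row-wise), false-discovery and false-negative
#' rates, and the overall accuracy (trace over total — where the precision
#' row and recall column meet).
#'
#' @param truth,predicted Vectors of class codes of equal length.
#' @return An object of class `rbc_confusion`: list with `counts` (7 x 7
#'   matrix), `by_class` tibble, and `accuracy`.
#' @export
confusion_matrix <- function(truth, predicted) {
  t <- as_rbc_factor(truth); p <- as_rbc_factor(predicted)
  stopifnot(length(t) == length(p))
  counts <- table(truth = t, predicted = p)
  counts <- matrix(as.integer(counts), 7, 7,
                   dimnames = list(truth = rbc_classes(), predicted = rbc_classes()))
  tp <- diag(counts)
  colt <- colSums(counts); rowt <- rowSums(counts)
  by_class <- tibble::tibble(
    class = as_rbc_factor(rbc_classes()),
    support = unname(as.integer(rowt)),
    precision = unname(ifelse(colt > 0, tp / colt, NA_real_)),
    recall = unname(ifelse(rowt > 0, tp / rowt, NA_real_)),
    false_discovery = unname(ifelse(colt > 0, 1 - tp / colt, NA_real_)),
    false_negative = unname(ifelse(rowt > 0, 1 - tp / rowt, NA_real_))
  )
  structure(list(counts = counts, by_class = by_class,
                 accuracy = sum(tp) / sum(counts)),
            class = "rbc_confusion")
}

#' @export
print.rbc_confusion <- function(x, ...) {
  print(x$counts)
  cat(sprintf("overall accuracy: %.1f%%\n", 100 * x$accuracy))
  invisible(x)
}

#' Tidy a confusion matrix into long counts
#' @param x An `rbc_confusion`.
#' @param ... Unused.
#' @method tidy rbc_confusion
#' @export
tidy.rbc_confusion <- function(x, ...) {
  tibble::as_tibble(as.data.frame.table(x$counts, responseName = "count")) |>
    dplyr::mutate(truth = as_rbc_factor(.data$truth),
                  predicted = as_rbc_factor(.data$predicted))
}

#' @method glance rbc_confusion
#' @export
glance.rbc_confusion <- function(x, ...) {
  tibble::tibble(accuracy = x$accuracy, n = sum(x$counts),
                 macro_recall = mean(x$by_class$recall, na.rm = TRUE),
                 macro_precision = mean(x$by_class$precision, na.rm = TRUE))
}

#' Fraction of errors that are off by a single class
#'
#' The echinocytic transformation is a continuum discretised into classes, so
#' most residual errors fall on an adjacent stage of the ordinal axis
#' (D, E1, E2, E3, SE, S). An error is "off by one" iff both classes lie on
#' the axis and are neighbours; the stomatocyte is non-ordinal, so errors
#' involving ST never count as adjacent. With no errors the fraction is
#' undefined and returned as 1 with attribute `no_errors = TRUE`.
#'
#' @param cm An `rbc_confusion`.
#' @return Fraction in `[0, 1]`.
#' @export
off_by_one_fraction <- function(cm) {
  stopifnot(inherits(cm, "rbc_confusion"))
  axis <- rbc_ordinal_axis()
  counts <- cm$counts
  err <- counts; diag(err) <- 0L
  total <- sum(err)
  if (total == 0) {
    return(structure(1, no_errors = TRUE))
  }
  adj <- 0L
  for (a in rownames(err)) for (b in colnames(err)) {
    ia <- match(a, axis); ib <- match(b, axis)
    if (!is.na(ia) && !is.na(ib) && abs(ia - ib) == 1) adj <- adj + err[a, b]
  }
  adj / total
}

#' Accuracy as a function of injected noise
#'
#' Evaluates a classifier on the same labelled crops under increasing levels
#' of seeded Gaussian or speckle noise. Accuracy at level 0 equals the clean
#' accuracy; the curve is expected to be non-increasing in trend.
#'
#' @param classifier An `rbc_ensemble` or `rbc_member`.
#' @param crops Tibble with `image` list-column and `class`.
#' @param kind `"gaussian"` or `"speckle"`.
#' @param levels Numeric vector of noise variances.
#' @param seed Integer seed for the noise draws.
#' @return Tibble `(level, accuracy)`.
#' @export
noise_robustness <- function(classifier, crops, kind = c("gaussian", "speckle"),
                             levels = c(0, 0.005, 0.02, 0.05), seed = 1L) {
  kind <- match.arg(kind)
  labels <- as_rbc_factor(crops$class)
  purrr::map_dfr(seq_along(levels), function(i) {
    lv <- levels[i]
    noisy <- purrr::imap(crops$image, function(img, j) {
      add_noise(img, noise_spec(kind, lv), seed = seed + 1000L * i + j)
    })
    pred <- predict(classifier, noisy)
    tibble::tibble(level = lv, accuracy = mean(pred$predicted == labels))
  })
}
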