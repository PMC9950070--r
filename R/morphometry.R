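# Effective-diameter morphometry: per-class distribution summaries with
# bias-corrected bootstrap confidence intervals, omnibus and pairwise
# hypothesis tests, Cohen's d and the common-language effect-size matrix,
# plus the rule-based low-resolution data-cleaning filter.

#' Effective diameter from projected area
#'
#' The equivalent-circle diameter of a segmented cell:
#' `2 * sqrt(area / pi) * um_per_px`.
#'
#' @param area Projected area(s) in px^2, `> 0`.
#' @param um_per_px Pixel calibration in um/px, `> 0`.
#' @return Diameter(s) in um.
#' @export
#' @examples
#' effective_diameter(400 * pi, 0.1)  # 4 um
effective_diameter <- function(area, um_per_px) {
  if (any(area <= 0) || um_per_px <= 0) {
    abort("`area` and `um_per_px` must be positive.")
  }
  2 * sqrt(area / pi) * um_per_px
}

#' Normalised diameter histogram
#'
#' Bins diameters on `[lo, hi)` at `width`-um intervals (half-open bins, so a
#' value on an edge belongs to the upper bin) and normalises counts by the
#' total in range. Out-of-range values are excluded from the normalisation
#' but reported via attributes `n_below` / `n_above`.
#'
#' @param values Diameters in um.
#' @param lo,hi,width Bin range and width (defaults 4, 10, 0.1 um).
#' @return Tibble `(center, count, frequency)`; frequencies sum to 1.
#' @export
diameter_histogram <- function(values, lo = 4, hi = 10, width = 0.1) {
  stopifnot(width > 0, hi > lo)
  edges <- seq(lo, hi, by = width)
  inside <- values >= lo & values < hi
  if (!any(inside)) abort("All values fall outside the histogram range.")
  bin <- findInterval(values[inside], edges)   # half-open [e_k, e_{k+1})
  counts <- tabulate(bin, nbins = length(edges) - 1)
  out <- tibble::tibble(
    center = edges[-length(edges)] + width / 2,
    count = counts,
    frequency = counts / sum(counts)
  )
  attr(out, "n_below") <- sum(values < lo)
  attr(out, "n_above") <- sum(values >= hi)
  out
}

boot_stat_fn <- function(statistic) {
  switch(statistic,
    mean = mean, sd = sd, median = stats::median,
    iqr = function(x) stats::IQR(x),
    abort("`statistic` must be one of mean, sd, median, iqr."))
}

#' Bias-corrected bootstrap confidence interval
#'
#' Percentile bootstrap with the bias correction of the BC method: the
#' correction `z0` is the normal quantile of the fraction of bootstrap
#' replicates below the observed statistic, and the interval endpoints are
#' the bootstrap quantiles at `pnorm(2*z0 +/- z_(alpha/2))`. (No acceleration
#' term — BC, not BCa.) Constant samples yield the degenerate interval
#' `[c, c]` with attribute `degenerate = TRUE`.
#'
#' @param values Numeric sample, `n >= 2`.
#' @param statistic `"mean"`, `"sd"`, `"median"` or `"iqr"`.
#' @param B Bootstrap replicates (default 10000).
#' @param level Confidence level (default 0.95).
#' @param seed Integer seed.
#' @return Named numeric `c(lo, hi)` with attributes `estimate`, `z0`.
#' @export
bootstrap_ci <- function(values, statistic = "mean", B = 10000, level = 0.95,
                         seed = 1L) {
  stopifnot(length(values) >= 2, B >= 100, level > 0, level < 1)
  fn <- boot_stat_fn(statistic)
  obs <- fn(values)
  if (max(values) == min(values)) {
    return(structure(c(lo = obs, hi = obs), estimate = obs, z0 = 0,
                     degenerate = TRUE))
  }
  n <- length(values)
  with_seed(seed, {
    stats <- numeric(B)
    chunk <- max(1L, min(B, floor(2e6 / n)))
    done <- 0L
    vectorised <- statistic %in% c("mean", "sd")
    while (done < B) {
      k <- min(chunk, B - done)
      m <- matrix(sample(values, n * k, replace = TRUE), n, k)
      stats[done + seq_len(k)] <- if (statistic == "mean") {
        colMeans(m)
      } else if (statistic == "sd") {
        sqrt((colMeans(m^2) - colMeans(m)^2) * n / (n - 1))
      } else {
        apply(m, 2, fn)
      }
      done <- done + k
    }
    frac <- mean(stats < obs)
    if (frac == 0 || frac == 1) {
      # observed value outside the bootstrap support; fall back to percentile
      frac <- (sum(stats < obs) + 0.5) / (B + 1)
    }
    z0 <- qnorm(frac)
    za <- qnorm(c((1 - level) / 2, 1 - (1 - level) / 2))
    probs <- pnorm(2 * z0 + za)
    ci <- unname(quantile(stats, probs, type = 6))
    structure(c(lo = ci[1], hi = ci[2]), estimate = obs, z0 = z0,
              degenerate = FALSE)
  })
}

#' Per-class diameter summary table
#'
#' The descriptive-statistics table for effective-diameter distributions:
#' per class, n, mean +/- SD, median, IQR, mean/median absolute deviations,
#' and bias-corrected bootstrap 95% CIs for mean, SD, median and IQR.
#'
#' @param data Tibble with a class column and a diameter column.
#' @param class,diameter Column names (defaults `"class"`, `"diameter"`).
#' @param B Bootstrap replicates (default 10000).
#' @param level Confidence level.
#' @param seed Integer seed.
#' @return Tibble, one row per class present.
#' @export
class_diameter_stats <- function(data, class = "class", diameter = "diameter",
                                 B = 10000, level = 0.95, seed = 1L) {
  cls <- as_rbc_factor(data[[class]])
  d <- data[[diameter]]
  purrr::map_dfr(levels(cls)[table(cls) > 0], function(cl) {
    x <- d[cls == cl]
    cis <- lapply(c("mean", "sd", "median", "iqr"), function(s) {
      if (length(x) < 2) {
        return(c(lo = NA_real_, hi = NA_real_))  # singleton class: no CI
      }
      bootstrap_ci(x, s, B = B, level = level,
                   seed = seed + match(cl, rbc_classes()))
    })
    names(cis) <- c("mean", "sd", "median", "iqr")
    tibble::tibble(
      class = cl, n = length(x),
      mean = mean(x), sd = sd(x),
      median = stats::median(x), iqr = stats::IQR(x),
      mad_mean = mean(abs(x - mean(x))),
      mad_median = stats::median(abs(x - stats::median(x))),
      mean_lo = cis$mean[["lo"]], mean_hi = cis$mean[["hi"]],
      sd_lo = cis$sd[["lo"]], sd_hi = cis$sd[["hi"]],
      median_lo = cis$median[["lo"]], median_hi = cis$median[["hi"]],
      iqr_lo = cis$iqr[["lo"]], iqr_hi = cis$iqr[["hi"]]
    )
  })
}

#' Cohen's d (pooled-SD standardised mean difference)
#'
#' @param mean1,sd1,n1 First group summary.
#' @param mean2,sd2,n2 Second group summary.
#' @return Signed effect size; pooled SD uses (n-1) weights.
#' @export
cohens_d <- function(mean1, sd1, n1, mean2, sd2, n2) {
  stopifnot(sd1 > 0, sd2 > 0, n1 >= 2, n2 >= 2)
  pooled <- sqrt(((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2))
  (mean1 - mean2) / pooled
}

#' Common-language effect size
#'
#' The probability that a random draw from group 1 exceeds a random draw
#' from group 2, under the normal model:
#' `pnorm((mean1 - mean2) / sqrt(sd1^2 + sd2^2))`.
#'
#' @param mean1,sd1,mean2,sd2 Group summaries.
#' @return Probability in `[0, 1]`; `CL(a, b) + CL(b, a) = 1`.
#' @export
common_language_es <- function(mean1, sd1, mean2, sd2) {
  stopifnot(sd1 > 0, sd2 > 0)
  pnorm((mean1 - mean2) / sqrt(sd1^2 + sd2^2))
}

#' Common-language effect-size matrix over classes
#'
#' Entry `(a, b)` is the probability that a random cell of class `a` has a
#' greater effective diameter than a random cell of class `b`; the diagonal
#' is 0.5 and `M + t(M) = 1`. With classes missing from `stats` a partial
#' matrix is returned with attribute `partial = TRUE`.
#'
#' @param stats Tibble with columns `class`, `mean`, `sd` (e.g.
#'   [class_diameter_stats()] or [reference_diameter_stats()]).
#' @return 7 x 7 numeric matrix (NA rows/cols for missing classes).
#' @export
cl_matrix <- function(stats) {
  classes <- rbc_classes()
  M <- matrix(NA_real_, 7, 7, dimnames = list(classes, classes))
  idx <- match(classes, as.character(stats$class))
  for (a in seq_len(7)) for (b in seq_len(7)) {
    ia <- idx[a]; ib <- idx[b]
    if (is.na(ia) || is.na(ib)) next
    M[a, b] <- if (a == b) 0.5 else {
      common_language_es(stats$mean[ia], stats$sd[ia], stats$mean[ib], stats$sd[ib])
    }
  }
  if (anyNA(idx)) {
    warn("Some classes missing; returning a partial matrix.")
    attr(M, "partial") <- TRUE
  }
  M
}

#' Omnibus and pairwise group tests
#'
#' Kruskal-Wallis omnibus test across the groups, plus all pairwise Welch
#' two-sample t-tests with Bonferroni adjustment (the factor is the number
#' of pairs, 21 for seven classes). Groups with fewer than 2 values are
#' excluded with a warning.
#'
#' @param data Tibble with a class column and a value column.
#' @param class,value Column names.
#' @param alpha Significance level used for the `significant` flag.
#' @return List of class `rbc_group_tests`: `omnibus` (tibble) and
#'   `pairwise` (tibble with raw and adjusted p).
#' @export
group_tests <- function(data, class = "class", value = "diameter", alpha = 0.05) {
  g <- as.character(data[[class]])
  v <- data[[value]]
  counts <- table(g)
  small <- names(counts)[counts < 2]
  if (length(small) > 0) {
    warn(paste0("Excluding group(s) with n < 2: ", paste(small, collapse = ", ")))
    keep <- !(g %in% small)
    g <- g[keep]; v <- v[keep]
  }
  groups <- sort(unique(g))
  if (length(groups) < 2) abort("Need at least two groups with n >= 2.")
  kw <- kruskal.test(split(v, g))
  pairs <- utils::combn(groups, 2)
  m <- ncol(pairs)
  pw <- purrr::map_dfr(seq_len(m), function(k) {
    a <- pairs[1, k]; b <- pairs[2, k]
    tt <- t.test(v[g == a], v[g == b])
    tibble::tibble(group1 = a, group2 = b, statistic = unname(tt$statistic),
                   p_raw = tt$p.value)
  })
  pw$p_adjusted <- pmin(pw$p_raw * m, 1)   # Bonferroni with m = C(k, 2)
  pw$significant <- pw$p_adjusted < alpha
  structure(list(
    omnibus = tibble::tibble(test = "kruskal-wallis",
                             statistic = unname(kw$statistic),
                             df = unname(kw$parameter), p = kw$p.value),
    pairwise = pw, alpha = alpha
  ), class = "rbc_group_tests")
}

#' @export
print.rbc_group_tests <- function(x, ...) {
  cat("Kruskal-Wallis: chi^2 =", sprintf("%.3f", x$omnibus$statistic),
      "df =", x$omnibus$df, "p =", format.pval(x$omnibus$p), "\n")
  cat(sum(x$pairwise$significant), "of", nrow(x$pairwise),
      "Bonferroni-adjusted pairwise comparisons significant at",
      x$alpha, "\n")
  invisible(x)
}

#' Tidy the pairwise comparisons
#' @param x An `rbc_group_tests`.
#' @param ... Unused.
#' @method tidy rbc_group_tests
#' @export
tidy.rbc_group_tests <- function(x, ...) x$pairwise

#' @method glance rbc_group_tests
#' @export
glance.rbc_group_tests <- function(x, ...) x$omnibus

#' Low-resolution record cleaning
#'
#' A configurable rule chain that removes statistical outliers and likely
#' segmentation artifacts from raw per-cell records before high-resolution
#' review: physical diameter bounds, a per-class k*IQR fence, and optional
#' aspect-ratio / solidity screens for aggregates and partial cells. Every
#' removal is tagged with the rule that fired (first matching rule wins).
#'
#' @param records Tibble with at least `class` and `diameter`; `aspect` and
#'   `solidity` columns enable the corresponding screens.
#' @param bounds Physical diameter bounds in um (default `c(4, 10)`).
#' @param iqr_k Fence multiplier: keep values within `k * IQR` of the
#'   class median (default 3).
#' @param max_aspect Maximum bounding-box aspect ratio (default 2).
#' @param min_solidity Minimum area/bbox-area solidity (default 0.5).
#' @return List with `kept` (tibble) and `removed` (tibble with a `rule`
#'   column).
#' @export
clean_low_res <- function(records, bounds = c(4, 10), iqr_k = 3,
                          max_aspect = 2, min_solidity = 0.5) {
  rule <- rep(NA_character_, nrow(records))
  d <- records$diameter
  rule[is.na(rule) & (d < bounds[1] | d > bounds[2])] <- "physical bounds"
  cls <- as.character(records$class)
  for (cl in unique(cls)) {
    i <- which(cls == cl & is.na(rule))
    if (length(i) < 4) next
    med <- stats::median(d[i]); iq <- stats::IQR(d[i])
    bad <- abs(d[i] - med) > iqr_k * max(iq, 1e-9)
    rule[i[bad]] <- "iqr fence"
  }
  if ("aspect" %in% names(records)) {
    rule[is.na(rule) & records$aspect > max_aspect] <- "aspect"
  }
  if ("solidity" %in% names(records)) {
    rule[is.na(rule) & records$solidity < min_solidity] <- "solidity"
  }
  list(
    kept = tibble::as_tibble(records[is.na(rule), ]),
    removed = dplyr::mutate(tibble::as_tibble(records[!is.na(rule), ]),
                            rule = rule[!is.na(rule)])
  )
}

#' Good/bad crop filter
#'
#' Retains the crops a (pluggable) binary quality filter marks good; the
#' default pass-through keeps everything. The decision for every crop is
#' returned for auditing.
#'
#' @param crops Tibble with an `image` list-column (and any id columns).
#' @param filter Function `(image) -> logical(1)`, `TRUE` = good. Default
#'   passes everything.
#' @return List with `kept` (tibble) and `decisions` (tibble with `good`
#'   flag per crop).
#' @export
good_bad_filter <- function(crops, filter = function(image) TRUE) {
  good <- vapply(crops$image, function(img) isTRUE(filter(img)), logical(1))
  decisions <- dplyr::mutate(crops[, setdiff(names(crops), "image")], good = good)
  list(kept = crops[good, ], decisions = decisions)
}
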