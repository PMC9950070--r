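# The synthetic classification benchmark: renders a labelled crop set,
# splits it 90/10 stratified, trains the heterogeneous ensemble on the
# training portion and scores every member and the averaged ensemble on the
# common holdout.

#' Run the synthetic ensemble benchmark
#'
#' Renders `n_per_class` single-cell crops per morphology class, holds out
#' `holdout` of them (stratified, seeded), trains every member of the
#' ensemble on the remainder and evaluates members and the unweighted
#' ensemble average on the holdout.
#'
#' @param n_per_class Crops per class (default 500).
#' @param holdout Test fraction (default 0.10).
#' @param archs Member architectures (default [default_member_archs()]).
#' @param cfg A [train_config()]; its seed is re-derived from `seed`.
#' @param seed Integer seed controlling rendering, split and training.
#' @return List of class `rbc_benchmark`: `accuracies` (tibble with one row
#'   per member plus the ensemble), `ensemble` (the trained object),
#'   `test` (the holdout crops) and `predictions` (ensemble scores on the
#'   holdout).
#' @export
benchmark_ensemble <- function(n_per_class = 500, holdout = 0.10,
                               archs = default_member_archs(),
                               cfg = train_config(), seed = 1L) {
  crops <- render_crop_set(n_per_class, seed = seed)
  split <- split_train_test(crops, holdout = holdout, seed = seed + 1L)
  cfg$seed <- seed + 2L
  ens <- train_ensemble(split$train, archs, cfg)
  truth <- as_rbc_factor(split$test$class)
  std <- lapply(split$test$image, standardize_crop,
                size = ens$members[[1]]$std_size)
  member_P <- lapply(ens$members, member_scores_std, std_crops = std)
  acc <- purrr::imap_dfr(member_P, function(P, nm) {
    tibble::tibble(model = nm,
                   accuracy = mean(rbc_classes()[max.col(P, ties.method = "first")] ==
                                     truth))
  })
  Pbar <- Reduce(`+`, member_P) / length(member_P)
  ens_pred <- scores_tibble(Pbar)
  acc <- dplyr::bind_rows(acc, tibble::tibble(
    model = "ensemble", accuracy = mean(ens_pred$predicted == truth)))
  structure(list(accuracies = acc, ensemble = ens, test = split$test,
                 predictions = dplyr::mutate(ens_pred, truth = truth)),
            class = "rbc_benchmark")
}

#' @export
print.rbc_benchmark <- function(x, ...) {
  cat("<rbc_benchmark> holdout accuracies:\n")
  print(as.data.frame(x$accuracies), row.names = FALSE)
  invisible(x)
}

#' @method glance rbc_benchmark
#' @export
glance.rbc_benchmark <- function(x, ...) {
  best <- max(x$accuracies$accuracy[x$accuracies$model != "ensemble"])
  tibble::tibble(
    ensemble_accuracy = x$accuracies$accuracy[x$accuracies$model == "ensemble"],
    best_member_accuracy = best,
    n_test = nrow(x$test)
  )
}
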