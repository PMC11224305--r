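#' Rank a model grid by k-fold cross-validated accuracy
#'
#' Scores every model specification by mean accuracy over stratified k-fold
#' cross-validation on the training table, and returns the specs ranked best
#' first. Ranking is deterministic given the seed; ties are broken by fewer
#' hyperparameters, then by registration order in the grid. If a degenerate
#' fold arises (a fold whose training part misses a class), the folds are
#' redrawn with a new derived seed and a warning is issued.
#'
#' @param train A `feature_table` (training split).
#' @param grids List of [model_spec()]s (e.g. [model_grid_table1()]).
#' @param k Folds (default 5); every class needs at least `k` samples.
#' @param seed Integer seed controlling folds and stochastic fits.
#' @return A `cv_ranking`: data.frame (`rank`, `model`, `cv_accuracy`,
#'   `cv_sd`) with the ranked specs in attribute `specs`; element
#'   `[[1]]`-like access via `best_model()`.
#' @export
cross_validate_grid <- function(train, grids, k = 5, seed = 1) {
  y <- train$labels
  if (min(table(y)) < k) {
    stop_hsi("every class needs at least k samples for k-fold CV",
             "hsifluor_parameter_error")
  }
  folds <- make_folds(y, k, seed)
  for (attempt in 1:5) {
    ok <- all(vapply(seq_len(k), function(f) {
      nlevels(droplevels(y[folds != f])) == nlevels(y)
    }, logical(1)))
    if (ok) break
    warning("degenerate fold encountered; redrawing folds")
    seed <- derive_seed(seed, paste0("refold", attempt))
    folds <- make_folds(y, k, seed)
  }

  acc <- matrix(0, length(grids), k)
  for (g in seq_along(grids)) {
    for (f in seq_len(k)) {
      tr <- subset_table(train, which(folds != f))
      va <- subset_table(train, which(folds == f))
      fit <- fit_model(grids[[g]], tr$features, tr$labels,
                       seed = derive_seed(seed, g * 100 + f))
      pred <- predict_model(fit, va$features)
      acc[g, f] <- mean(as.character(pred$class) == as.character(va$labels))
    }
  }
  mean_acc <- rowMeans(acc)
  n_par <- vapply(grids, function(s) length(s$params), integer(1))
  ord <- order(-mean_acc, n_par, seq_along(grids))
  out <- data.frame(rank = seq_along(grids),
                    model = vapply(grids[ord], format, ""),
                    cv_accuracy = mean_acc[ord],
                    cv_sd = apply(acc, 1, stats::sd)[ord],
                    stringsAsFactors = FALSE)
  structure(out, specs = grids[ord], seed = seed, class = c("cv_ranking",
                                                            "data.frame"))
}

# stratified fold assignment: within each class, shuffled samples are dealt
# round-robin over the k folds
make_folds <- function(y, k, seed) {
  folds <- integer(length(y))
  with_seed(seed, {
    for (cl in levels(y)) {
      idx <- sample(which(y == cl))
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

#' Best model of a CV ranking
#' @param ranking A `cv_ranking`.
#' @return The top-ranked [model_spec()].
#' @export
best_model <- function(ranking) attr(ranking, "specs")[[1]]

#' Evaluate a fitted model on the test set
#'
#' Computes test accuracy (correct / total), the K x K confusion matrix
#' (rows = true class), one-vs-rest ROC curves per class from the predicted
#' class scores, per-class AUCs, and their macro average.
#'
#' @param model A fitted `hsif_model` (trained on the training split only).
#' @param test A `feature_table`.
#' @return An `evaluation_report`: list with `accuracy`, `confusion`
#'   (K x K matrix), `roc` (per-class data.frames of `fpr`, `tpr`),
#'   `auc_per_class`, `macro_auc`, `model` (the spec), `n_test`. Classes
#'   absent from the test set get `NA` AUC and are listed in
#'   `missing_classes`.
#' @export
evaluate <- function(model, test) {
  pred <- predict_model(model, test$features)
  truth <- factor(as.character(test$labels), levels = model$levels)
  acc <- mean(as.character(pred$class) == as.character(truth))
  confusion <- table(truth = truth,
                     predicted = factor(as.character(pred$class),
                                        levels = model$levels))
  aucs <- stats::setNames(rep(NA_real_, length(model$levels)), model$levels)
  rocs <- list()
  missing <- character(0)
  for (cl in model$levels) {
    is_cl <- truth == cl
    if (!any(is_cl) || all(is_cl)) {
      missing <- c(missing, cl)
      next
    }
    r <- pROC::roc(response = as.integer(is_cl),
                   predictor = pred$prob[, cl],
                   levels = c(0, 1), direction = "<", quiet = TRUE)
    aucs[cl] <- as.numeric(pROC::auc(r))
    rocs[[cl]] <- data.frame(fpr = 1 - r$specificities,
                             tpr = r$sensitivities)
  }
  structure(list(accuracy = acc,
                 confusion = unclass(confusion),
                 roc = rocs,
                 auc_per_class = aucs,
                 macro_auc = mean(aucs, na.rm = TRUE),
                 missing_classes = missing,
                 model = model$spec,
                 n_test = nrow(test$features)),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> %s\n", format(x$model)))
  cat(sprintf("  accuracy %.3f on %d test samples; macro AUC %.3f\n",
              x$accuracy, x$n_test, x$macro_auc))
  cat("  confusion matrix:\n")
  print(x$confusion)
  invisible(x)
}

#' Run the full selection-and-evaluation protocol on one feature table
#'
#' Convenience wrapper: stratified 80/20 split, k-fold CV ranking of the
#' grid on the training side, refit of the best model on all training data,
#' evaluation on the held-out test side.
#'
#' @param table A `feature_table`.
#' @param grids Model grid (default [model_grid_default()]).
#' @param test_fraction,k,seed,group_by_biopsy Protocol parameters.
#' @return List with `ranking` (`cv_ranking`), `report`
#'   (`evaluation_report`), `split`.
#' @export
train_and_evaluate <- function(table, grids = model_grid_default(),
                               test_fraction = 0.2, k = 5, seed = 1,
                               group_by_biopsy = FALSE) {
  split <- split_train_test(table, test_fraction,
                            seed = derive_seed(seed, "split"),
                            group_by_biopsy = group_by_biopsy)
  ranking <- cross_validate_grid(split$train, grids, k = k,
                                 seed = derive_seed(seed, "cv"))
  best <- best_model(ranking)
  fit <- fit_model(best, split$train$features, split$train$labels,
                   seed = derive_seed(seed, "fit"))
  list(ranking = ranking, report = evaluate(fit, split$test), split = split)
}
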