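# Cross-validated evaluation of one (descriptor, aggregation, model) cell.

# Fold metrics that stay silent when R2 is undefined (single-compound test
# folds under LOOCV); MAE/RMSE are always defined.
.fold_metrics <- function(y, yhat) {
  ss_tot <- sum((y - mean(y))^2)
  list(r2 = if (length(y) < 2L || ss_tot == 0) NA_real_ else
         1 - sum((y - yhat)^2) / ss_tot,
       mae = mean(abs(y - yhat)),
       rmse = sqrt(mean((y - yhat)^2)))
}

#' Cross-validate one descriptor/aggregation/model combination
#'
#' Runs the full compound-level CV loop for one cell: the sparse-descriptor
#' vocabulary and the design matrix are rebuilt per fold from the training
#' compounds only, the chosen aggregation (or the multi-instance
#' nonaggregation scheme, or the ground-truth-conformer descriptor) is
#' applied, the model is fitted, and per-fold R2/MAE/RMSE are recorded.
#'
#' @param dataset a [conformer_dataset()].
#' @param matrices named list of `DescriptorMatrix` from
#'   [featurize_dataset()].
#' @param method an [aggregate_descriptors()] method, or "nonaggregation"
#'   (every conformer an instance, test predictions pooled), or
#'   "ground_truth" (descriptor of the ground-truth conformation, requires
#'   `gt_matrices`).
#' @param model a [model_spec()].
#' @param splits a [make_splits()] plan over the dataset's compound ids.
#' @param seed integer; fans out to per-fold model seeds and per-repeat
#'   random-aggregation draws.
#' @param temperature Kelvin for Boltzmann aggregation.
#' @param gt_matrices ground-truth descriptor matrices (from
#'   `featurize_dataset(..., ground_truth = TRUE)`).
#' @param heavy_only_rmsd use heavy atoms for the RMSD-extreme selections.
#' @return object of class `EvalResult`: data.frame with one row per fold
#'   (`repeat_index`, `fold_index`, `n`, `r2`, `mae`, `rmse`) and a
#'   `predictions` attribute (data.frame compound_id / repeat_index /
#'   fold_index / y / yhat).
#' @export
evaluate_cell <- function(dataset, matrices, method, model, splits,
                          seed = 1L, temperature = 298,
                          gt_matrices = NULL, heavy_only_rmsd = TRUE) {
  stopifnot(inherits(splits, "SplitPlan"), inherits(model, "ModelSpec"))
  ids <- names(dataset$ensembles)
  y_all <- dataset_values(dataset)
  agg_methods <- c("boltzmann", "mean", "global_min", "random",
                   "rmsd_max", "rmsd_min")
  if (!(method %in% c(agg_methods, "nonaggregation", "ground_truth"))) {
    stop("unknown method '", method, "'")
  }
  energies <- NULL
  if (method %in% c("boltzmann", "global_min")) {
    energies <- lapply(dataset$ensembles, conformer_energies)
  }
  rmsds <- NULL
  if (method %in% c("rmsd_max", "rmsd_min")) {
    rmsds <- lapply(dataset$ensembles, function(e) {
      rmsd_to_ground_truth(e, heavy_only = heavy_only_rmsd)$per_conformer_rmsd
    })
  }
  if (method == "ground_truth" && is.null(gt_matrices)) {
    stop("method 'ground_truth' requires gt_matrices")
  }

  fold_rows <- list()
  pred_rows <- list()
  for (fd in splits$folds) {
    train <- fd$train; test <- fd$test
    vocab <- triplet_vocabulary(
      if (method == "ground_truth") gt_matrices[train] else matrices[train])
    row_for <- function(id) {
      if (method == "ground_truth") {
        align_to_vocab(gt_matrices[[id]], vocab)[1L, ]
      } else {
        m <- align_to_vocab(matrices[[id]], vocab)
        aggregate_descriptors(
          m, method = method, energies = energies[[id]], rmsd = rmsds[[id]],
          seed = if (method == "random") {
            derive_seed(seed, paste0("random_r", fd$repeat_index, "_", id))
          } else NULL,
          temperature = temperature)
      }
    }
    fit_seed <- derive_seed(seed, paste0("fit_r", fd$repeat_index,
                                         "_f", fd$fold_index))
    if (method == "nonaggregation") {
      tr_mats <- lapply(train, function(id) align_to_vocab(matrices[[id]], vocab))
      X_train <- do.call(rbind, tr_mats)
      y_train <- rep(y_all[train], vapply(tr_mats, nrow, integer(1)))
      te_mats <- lapply(test, function(id) align_to_vocab(matrices[[id]], vocab))
      X_test <- do.call(rbind, te_mats)
      inst_pred <- fit_predict(model, X_train, y_train, X_test, seed = fit_seed)
      splits_by <- rep(seq_along(test), vapply(te_mats, nrow, integer(1)))
      yhat <- vapply(seq_along(test), function(i) {
        pool_bag_predictions(inst_pred[splits_by == i])
      }, numeric(1))
    } else {
      X_train <- do.call(rbind, lapply(train, row_for))
      X_test <- do.call(rbind, lapply(test, row_for))
      yhat <- fit_predict(model, X_train, y_all[train], X_test,
                          seed = fit_seed)
    }
    y <- unname(y_all[test])
    m <- .fold_metrics(y, yhat)
    fold_rows[[length(fold_rows) + 1L]] <- data.frame(
      repeat_index = fd$repeat_index, fold_index = fd$fold_index,
      n = length(test), r2 = m$r2, mae = m$mae, rmse = m$rmse)
    pred_rows[[length(pred_rows) + 1L]] <- data.frame(
      compound_id = test, repeat_index = fd$repeat_index,
      fold_index = fd$fold_index, y = y, yhat = yhat)
  }
  res <- do.call(rbind, fold_rows)
  attr(res, "predictions") <- do.call(rbind, pred_rows)
  attr(res, "method") <- method
  class(res) <- c("EvalResult", class(res))
  res
}

#' Summarize an evaluation result
#'
#' Repeated k-fold results are summarized as the across-fold mean and SD of
#' each metric; LOOCV results are summarized by pooling all leave-one-out
#' predictions into a single set and computing the metrics once.
#'
#' @param res an `EvalResult` from [evaluate_cell()].
#' @param pooled pool predictions instead of averaging fold metrics
#'   (automatic for LOOCV-like results where every fold has n = 1).
#' @return data.frame with one row: `r2`, `mae`, `rmse` (and `r2_sd` etc.
#'   for the fold-averaged form).
#' @export
summarize_eval <- function(res, pooled = all(res$n == 1L)) {
  if (pooled) {
    pr <- attr(res, "predictions")
    m <- compute_metrics(pr$y, pr$yhat)
    data.frame(r2 = m$r2, mae = m$mae, rmse = m$rmse, n = m$n)
  } else {
    data.frame(r2 = mean(res$r2), r2_sd = stats::sd(res$r2),
               mae = mean(res$mae), mae_sd = stats::sd(res$mae),
               rmse = mean(res$rmse), rmse_sd = stats::sd(res$rmse),
               n_folds = nrow(res))
  }
}
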