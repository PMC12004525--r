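# Compound-level cross-validation, model adapters, regression metrics,
# paired nonparametric comparison, and Tanimoto extrapolation analysis.

#' Compound-level cross-validation split plan
#'
#' Splits are always by compound, so conformers of one compound never
#' straddle a fold boundary. `repeated_kfold` shuffles the compounds
#' independently per repeat (seeded); `loocv` ignores `k` and `repeats`.
#'
#' @param compound_ids character vector of compound ids.
#' @param scheme "repeated_kfold" or "loocv".
#' @param k folds per repeat.
#' @param repeats number of repeats.
#' @param seed integer seed.
#' @return object of class `SplitPlan`: list with `scheme`, `k`, `repeats`,
#'   `seed` and `folds`, each fold a list(train, test, repeat_index,
#'   fold_index).
#' @export
make_splits <- function(compound_ids, scheme = c("repeated_kfold", "loocv"),
                        k = 5L, repeats = 5L, seed = 1L) {
  scheme <- match.arg(scheme)
  n <- length(compound_ids)
  stopifnot(n >= 2L)
  folds <- list()
  if (scheme == "loocv") {
    k <- n; repeats <- 1L
    for (i in seq_len(n)) {
      folds[[i]] <- list(train = compound_ids[-i], test = compound_ids[i],
                         repeat_index = 1L, fold_index = i)
    }
  } else {
    if (k > n) stop("k (", k, ") exceeds the number of compounds (", n, ")")
    for (r in seq_len(repeats)) {
      perm <- with_seed(derive_seed(seed, paste0("repeat_", r)),
                        sample(compound_ids))
      assignment <- rep(seq_len(k), length.out = n)
      for (f in seq_len(k)) {
        test <- perm[assignment == f]
        folds[[length(folds) + 1L]] <-
          list(train = setdiff(compound_ids, test), test = test,
               repeat_index = r, fold_index = f)
      }
    }
  }
  structure(list(scheme = scheme, k = as.integer(k),
                 repeats = as.integer(repeats), seed = as.integer(seed),
                 folds = folds),
            class = "SplitPlan")
}

#' Regression model specification
#'
#' Registered adapters: "rf" (random forest via ranger, single-threaded and
#' seeded for determinism), "mlp" (single-hidden-layer perceptron via nnet,
#' inputs standardized on the training fold), "enet" (elastic net via
#' glmnet, penalty chosen by an internal seeded cross-validation on the
#' training fold), "lm" (ordinary least squares, rank-deficient columns
#' dropped).
#'
#' @param name adapter name.
#' @param ... hyperparameters: `num.trees`, `mtry`, `min.node.size` for
#'   "rf"; `size`, `decay`, `maxit` for "mlp"; `alpha`, `nfolds` for
#'   "enet".
#' @return object of class `ModelSpec`.
#' @export
model_spec <- function(name = c("rf", "mlp", "enet", "lm"), ...) {
  name <- match.arg(name)
  structure(list(name = name, params = list(...)), class = "ModelSpec")
}

#' Fit a model and predict on a test matrix
#'
#' Deterministic given (spec, seed, data). Inputs are validated for
#' non-finite values before fitting.
#'
#' @param spec a [model_spec()].
#' @param X_train,X_test numeric matrices with identical column sets.
#' @param y_train numeric response.
#' @param seed integer seed for stochastic learners.
#' @return numeric vector of predictions, one per test row.
#' @export
fit_predict <- function(spec, X_train, y_train, X_test, seed = 1L) {
  stopifnot(inherits(spec, "ModelSpec"))
  X_train <- as.matrix(X_train); X_test <- as.matrix(X_test)
  if (any(!is.finite(X_train)) || any(!is.finite(X_test)) ||
      any(!is.finite(y_train))) {
    stop("non-finite values in model inputs")
  }
  stopifnot(nrow(X_train) == length(y_train), ncol(X_train) == ncol(X_test))
  cn <- paste0("x", seq_len(ncol(X_train)))
  colnames(X_train) <- cn; colnames(X_test) <- cn
  p <- spec$params
  if (spec$name == "rf") {
    fit <- ranger::ranger(
      x = X_train, y = y_train,
      num.trees = p$num.trees %||% 500L,
      mtry = p$mtry %||% max(1L, floor(ncol(X_train) / 3)),
      min.node.size = p$min.node.size %||% 5L,
      seed = seed, num.threads = 1L, verbose = FALSE)
    stats::predict(fit, data = X_test, num.threads = 1L)$predictions
  } else if (spec$name == "enet") {
    nfolds <- p$nfolds %||% 5L
    foldid <- with_seed(seed, sample(rep(seq_len(nfolds),
                                         length.out = nrow(X_train))))
    fit <- glmnet::cv.glmnet(X_train, y_train, alpha = p$alpha %||% 0.5,
                             foldid = foldid, standardize = TRUE)
    as.numeric(stats::predict(fit, newx = X_test, s = "lambda.min"))
  } else if (spec$name == "mlp") {
    mu <- colMeans(X_train)
    sdv <- apply(X_train, 2, stats::sd)
    sdv[sdv == 0] <- 1
    xs <- sweep(sweep(X_train, 2, mu), 2, sdv, "/")
    xt <- sweep(sweep(X_test, 2, mu), 2, sdv, "/")
    fit <- with_seed(seed, nnet::nnet(
      xs, y_train, size = p$size %||% 8L, decay = p$decay %||% 0.01,
      maxit = p$maxit %||% 300L, linout = TRUE, trace = FALSE,
      MaxNWts = 100000L))
    as.numeric(stats::predict(fit, xt))
  } else {
    fit <- stats::lm.fit(cbind(`(Intercept)` = 1, X_train), y_train)
    beta <- fit$coefficients
    beta[is.na(beta)] <- 0
    as.numeric(cbind(1, X_test) %*% beta)
  }
}

#' Regression accuracy metrics for one test fold
#'
#' R2 = 1 - sum((y - yhat)^2) / sum((y - mean(y))^2), MAE and RMSE. A
#' zero-variance response makes R2 undefined (`NA`, with a warning).
#'
#' @param y observed values.
#' @param yhat predicted values, same length.
#' @return list with `r2`, `mae`, `rmse`, `n`, `ybar`.
#' @export
compute_metrics <- function(y, yhat) {
  if (length(y) != length(yhat)) stop("y and yhat lengths differ")
  if (length(y) == 0L) stop("empty fold")
  ss_res <- sum((y - yhat)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) {
    warning("zero-variance response; R2 undefined")
    NA_real_
  } else 1 - ss_res / ss_tot
  list(r2 = r2, mae = mean(abs(y - yhat)), rmse = sqrt(mean((y - yhat)^2)),
       n = length(y), ybar = mean(y))
}

# Exact null distribution of the (doubled, integer) signed-rank statistic by
# the shift algorithm; handles midrank ties. Returns counts over 0..sum(s2).
.signed_rank_counts <- function(s2) {
  total <- sum(s2)
  f <- numeric(total + 1L)
  f[1L] <- 1
  for (s in s2) {
    g <- f
    g[(s + 1L):(total + 1L)] <- g[(s + 1L):(total + 1L)] + f[1L:(total - s + 1L)]
    f <- g
  }
  f
}

#' Paired Wilcoxon signed-rank comparison of two accuracy vectors
#'
#' Zero differences are discarded; up to 25 nonzero pairs the two-sided p
#' comes from the exact null distribution (shift algorithm, valid under
#' midrank ties), beyond that from the normal approximation with tie
#' correction and continuity correction. No multiplicity correction is
#' applied. With all differences zero the comparison is degenerate and p is
#' reported as 1.
#'
#' @param acc_a,acc_b paired per-fold accuracy values (same folds).
#' @param labels optional character pair naming the two methods.
#' @param alpha significance level (default 0.05).
#' @return object of class `ComparisonReport`: list with `statistic` (W =
#'   rank sum of positive differences), `p_value`, `n_nonzero`,
#'   `significant`, `degenerate`, `exact`, `median_diff`, `labels`.
#' @export
paired_signed_rank <- function(acc_a, acc_b, labels = c("a", "b"),
                               alpha = 0.05) {
  stopifnot(length(acc_a) == length(acc_b))
  d <- acc_a - acc_b
  d <- d[!is.na(d)]
  nz <- d[d != 0]
  n <- length(nz)
  if (n == 0L) {
    return(structure(list(statistic = 0, p_value = 1, n_nonzero = 0L,
                          significant = FALSE, degenerate = TRUE,
                          exact = TRUE, median_diff = 0, labels = labels),
                     class = "ComparisonReport"))
  }
  r <- rank(abs(nz))
  w <- sum(r[nz > 0])
  if (n <= 25L) {
    s2 <- as.integer(round(2 * r))
    counts <- .signed_rank_counts(s2)
    total <- 2^n
    w2 <- round(2 * w)
    lower <- sum(counts[seq_len(w2 + 1L)]) / total        # P(W2 <= w2)
    upper <- sum(counts[(w2 + 1L):length(counts)]) / total # P(W2 >= w2)
    p <- min(1, 2 * min(lower, upper))
    exact <- TRUE
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(ties^3 - ties) / 48
    z <- (w - mu - sign(w - mu) * 0.5) / sqrt(sig2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    exact <- FALSE
  }
  structure(list(statistic = w, p_value = p, n_nonzero = n,
                 significant = p < alpha, degenerate = FALSE, exact = exact,
                 median_diff = stats::median(d), labels = labels),
            class = "ComparisonReport")
}

#' @export
print.ComparisonReport <- function(x, ...) {
  cat(sprintf("Wilcoxon signed-rank: %s vs %s, W = %g, p = %.4g (%s)%s\n",
              x$labels[1], x$labels[2], x$statistic, x$p_value,
              if (x$exact) "exact" else "normal approx.",
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' One-way ANOVA across aggregation methods
#'
#' Pools all accuracy values per method (across folds and, when present,
#' descriptor blocks) and tests equality of the method means. A degenerate
#' table (zero within-group variance) yields `p = NA` with a flag.
#'
#' @param accuracy_table data.frame with columns `accuracy` and `method`
#'   (optionally `descriptor`, ignored for grouping).
#' @return list with `F`, `p_value`, `df_between`, `df_within`,
#'   `degenerate`.
#' @export
aggregation_anova <- function(accuracy_table) {
  stopifnot(is.data.frame(accuracy_table),
            all(c("accuracy", "method") %in% names(accuracy_table)))
  g <- factor(accuracy_table$method)
  if (nlevels(g) < 2L) stop("need at least two methods")
  sizes <- table(g)
  if (any(sizes < 2L)) stop("need at least two values per method")
  within_var <- stats::ave(accuracy_table$accuracy, g,
                           FUN = function(v) v - mean(v))
  if (sum(within_var^2) < 1e-24) {
    return(list(F = NA_real_, p_value = NA_real_,
                df_between = nlevels(g) - 1L,
                df_within = length(g) - nlevels(g), degenerate = TRUE))
  }
  fit <- stats::oneway.test(accuracy ~ method, data = accuracy_table,
                            var.equal = TRUE)
  list(F = unname(fit$statistic), p_value = unname(fit$p.value),
       df_between = unname(fit$parameter[1]),
       df_within = unname(fit$parameter[2]), degenerate = FALSE)
}

#' Maximum Tanimoto similarity of each test compound to the training set
#'
#' Tanimoto(A, B) = |A and B| / |A or B| on fingerprint bit sets, maximized
#' over the training compounds (nearest structural neighbour). An
#' empty-vs-empty comparison counts as similarity 1 by convention (flagged
#' via the `empty_pairs` attribute).
#'
#' @param test_fps,train_fps 0/1 matrices, rows = compounds, identical bit
#'   length.
#' @return numeric vector of per-test-compound maximum similarities.
#' @export
max_tanimoto_to_train <- function(test_fps, train_fps) {
  test_fps <- as.matrix(test_fps); train_fps <- as.matrix(train_fps)
  stopifnot(ncol(test_fps) == ncol(train_fps))
  inter <- test_fps %*% t(train_fps)
  a <- rowSums(test_fps); b <- rowSums(train_fps)
  union_ <- outer(a, b, `+`) - inter
  sim <- ifelse(union_ == 0, 1, inter / pmax(union_, 1e-300))
  out <- apply(sim, 1L, max)
  attr(out, "empty_pairs") <- sum(union_ == 0)
  out
}

#' MAE restricted to structurally novel test compounds
#'
#' For each similarity threshold t, the MAE over test compounds whose
#' maximum Tanimoto similarity to the training set is below t; a threshold
#' of 1.0 (or above) uses every test compound and reproduces the full-test
#' MAE. Empty subsets give `NA`.
#'
#' @param y,yhat observed and predicted values per test compound.
#' @param similarities per-compound maximum train similarity.
#' @param thresholds ascending numeric thresholds in (0, 1].
#' @return data.frame with `threshold`, `n`, `mae`.
#' @export
extrapolation_curve <- function(y, yhat, similarities,
                                thresholds = seq(0.2, 1.0, by = 0.1)) {
  stopifnot(length(y) == length(yhat), length(y) == length(similarities),
            all(diff(thresholds) > 0), all(thresholds > 0))
  rows <- lapply(thresholds, function(t) {
    keep <- if (t >= 1) rep(TRUE, length(y)) else similarities < t
    data.frame(threshold = t, n = sum(keep),
               mae = if (any(keep)) mean(abs(y[keep] - yhat[keep])) else NA_real_)
  })
  do.call(rbind, rows)
}
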