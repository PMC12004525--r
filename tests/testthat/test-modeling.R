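test_that("split plans partition compounds, never straddle, and are reproducible", {
  ids <- sprintf("c%02d", 1:10)
  plan <- make_splits(ids, "repeated_kfold", k = 5, repeats = 3, seed = 2)
  expect_length(plan$folds, 15L)
  for (r in 1:3) {
    folds <- Filter(function(f) f$repeat_index == r, plan$folds)
    tests <- lapply(folds, `[[`, "test")
    expect_setequal(unlist(tests), ids)
    expect_equal(sum(duplicated(unlist(tests))), 0L)
    for (f in folds) {
      expect_length(f$test, 2L)
      expect_length(intersect(f$train, f$test), 0L)
      expect_setequal(c(f$train, f$test), ids)
    }
  }
  plan2 <- make_splits(ids, "repeated_kfold", k = 5, repeats = 3, seed = 2)
  expect_identical(plan, plan2)
  expect_false(identical(plan,
                         make_splits(ids, "repeated_kfold", 5, 3, seed = 3)))
  expect_error(make_splits(ids, "repeated_kfold", k = 11), "exceeds")

  loo <- make_splits(ids, "loocv")
  expect_length(loo$folds, 10L)
  expect_true(all(vapply(loo$folds, function(f) length(f$test), integer(1)) == 1L))
})

test_that("model adapters are deterministic and validate inputs", {
  set.seed(8)
  X <- matrix(rnorm(200), 40, 5)
  y <- X %*% c(1, -2, 0.5, 0, 3) + rnorm(40, sd = 0.1)
  Xt <- matrix(rnorm(50), 10, 5)

  for (nm in c("rf", "lm", "mlp")) {
    spec <- model_spec(nm)
    p1 <- fit_predict(spec, X, y, Xt, seed = 4)
    p2 <- fit_predict(spec, X, y, Xt, seed = 4)
    expect_identical(p1, p2)
    expect_length(p1, 10L)
  }

  # constant response -> constant forest prediction
  pc <- fit_predict(model_spec("rf"), X, rep(2.5, 40), Xt, seed = 1)
  expect_equal(pc, rep(2.5, 10), tolerance = 1e-12)

  # the linear adapter recovers a noiseless linear map
  y_lin <- as.numeric(X %*% c(2, 1, 0, -1, 0.5))
  pl <- fit_predict(model_spec("lm"), X, y_lin, Xt)
  expect_equal(pl, as.numeric(Xt %*% c(2, 1, 0, -1, 0.5)), tolerance = 1e-8)

  Xbad <- X; Xbad[1, 1] <- NaN
  expect_error(fit_predict(model_spec("rf"), Xbad, y, Xt), "non-finite")
})

test_that("metrics match their defining formulas", {
  m <- compute_metrics(c(1, 2, 3), c(1, 2, 3))
  expect_equal(m$r2, 1); expect_equal(m$mae, 0); expect_equal(m$rmse, 0)

  y <- c(0, 1, 4, 2)
  m0 <- compute_metrics(y, rep(mean(y), 4))
  expect_equal(m0$r2, 0)

  m1 <- compute_metrics(c(0, 2), c(1, 1))
  expect_equal(m1$mae, 1); expect_equal(m1$rmse, 1); expect_equal(m1$r2, 0)

  expect_error(compute_metrics(1:3, 1:2), "lengths differ")
  expect_warning(mz <- compute_metrics(c(1, 1), c(1, 2)), "zero-variance")
  expect_true(is.na(mz$r2))

  # RMSE >= MAE on arbitrary folds
  set.seed(10)
  for (k in 1:10) {
    yy <- rnorm(7); pp <- rnorm(7)
    mm <- compute_metrics(yy, pp)
    expect_gte(mm$rmse, mm$mae)
  }
})

test_that("signed-rank test matches enumeration, handles zeros and symmetry", {
  # all six differences positive: p = 2 / 2^6
  a <- c(2, 3, 4, 5, 6, 7); b <- c(1, 2, 3, 4, 5, 6)
  rep1 <- paired_signed_rank(a, b)
  expect_equal(rep1$p_value, 0.03125, tolerance = 1e-12)
  expect_true(rep1$exact)

  # identical vectors: degenerate
  repd <- paired_signed_rank(a, a)
  expect_true(repd$degenerate)
  expect_equal(repd$p_value, 1)

  # swapping arguments preserves p
  set.seed(12)
  x <- rnorm(9); y <- rnorm(9)
  expect_equal(paired_signed_rank(x, y)$p_value,
               paired_signed_rank(y, x)$p_value, tolerance = 1e-12)

  # full-enumeration oracle, including midrank ties, n <= 10
  for (k in 1:12) {
    set.seed(100 + k)
    n <- sample(4:10, 1)
    d <- round(rnorm(n), 1)       # rounding creates ties and zeros
    if (all(d == 0)) d[1] <- 0.5
    p_pkg <- paired_signed_rank(d, rep(0, n))$p_value
    expect_equal(p_pkg, enumerate_signed_rank_p(d), tolerance = 1e-10)
  }

  # tie-free case agrees with the reference library implementation
  set.seed(77)
  x <- rnorm(12); y <- rnorm(12)
  expect_equal(paired_signed_rank(x, y)$p_value,
               stats::wilcox.test(x, y, paired = TRUE, exact = TRUE)$p.value,
               tolerance = 1e-10)

  # large n falls back to the normal approximation
  set.seed(78)
  x2 <- rnorm(40); y2 <- x2 + rnorm(40, 0.3)
  repn <- paired_signed_rank(x2, y2)
  expect_false(repn$exact)
  expect_equal(repn$p_value,
               stats::wilcox.test(x2, y2, paired = TRUE, exact = FALSE,
                                  correct = TRUE)$p.value,
               tolerance = 0.01)
})

test_that("aggregation ANOVA flags degeneracy and ignores labels", {
  tab <- data.frame(accuracy = c(1, 2, 3, 1, 2, 3),
                    method = rep(c("a", "b"), each = 3))
  res <- aggregation_anova(tab)
  expect_equal(res$F, 0)
  expect_equal(res$p_value, 1)

  deg <- data.frame(accuracy = c(0, 0, 0, 1, 1, 1),
                    method = rep(c("a", "b"), each = 3))
  resd <- aggregation_anova(deg)
  expect_true(resd$degenerate)
  expect_true(is.na(resd$p_value))

  set.seed(14)
  tab2 <- data.frame(accuracy = rnorm(12),
                     method = rep(c("m1", "m2", "m3"), each = 4))
  tab3 <- tab2
  tab3$method <- c(m1 = "zz", m2 = "aa", m3 = "mm")[tab2$method]
  expect_equal(aggregation_anova(tab2)$p_value,
               aggregation_anova(tab3)$p_value, tolerance = 1e-12)

  expect_error(aggregation_anova(data.frame(accuracy = 1:3,
                                            method = "only")), "two methods")
})

test_that("Tanimoto similarity and the extrapolation curve follow the set formulas", {
  train <- rbind(c(1, 1, 1, 0), c(0, 1, 1, 1))
  test <- rbind(c(1, 1, 1, 0),   # present in train -> 1
                c(0, 0, 0, 1))   # bits {4} vs {1,2,3}: 0; vs {2,3,4}: 1/3
  sims <- max_tanimoto_to_train(test, train)
  expect_equal(unname(sims[1]), 1)
  expect_equal(unname(sims[2]), 1 / 3)

  a <- matrix(c(1, 1, 1, 0, 0), 1); b <- matrix(c(0, 1, 1, 1, 0), 1)
  expect_equal(unname(max_tanimoto_to_train(a, b)[1]), 0.5)
  disjoint <- max_tanimoto_to_train(matrix(c(1, 0), 1), matrix(c(0, 1), 1))
  expect_equal(unname(disjoint[1]), 0)
  empty <- max_tanimoto_to_train(matrix(0, 1, 2), matrix(0, 1, 2))
  expect_equal(unname(empty[1]), 1)
  expect_equal(attr(empty, "empty_pairs"), 1L)

  y <- c(0, 1, 0, 2); yhat <- c(1, 3, 3, 6)
  sims2 <- c(0.15, 0.35, 0.55, 0.95)
  curve <- extrapolation_curve(y, yhat, sims2, thresholds = c(0.3, 0.6, 1.0))
  err <- abs(y - yhat)
  expect_equal(curve$mae, c(err[1], mean(err[1:3]), mean(err)))
  expect_true(all(diff(curve$n) >= 0))
  low <- extrapolation_curve(y, yhat, sims2, thresholds = c(0.1, 1.0))
  expect_true(is.na(low$mae[1]))
  expect_equal(low$mae[2], compute_metrics(y, yhat)$mae)
})

test_that("cross-validated cells keep fold hygiene and metric inequalities", {
  ds <- tiny_dataset(n = 12L, seed = 171L, conf_range = c(2L, 4L),
                     mode = "geometric_ground_truth", noise_sd = 0.05)
  mats <- featurize_dataset(ds, descriptor_spec(
    "morse", config = morse_config(s_values = 1:8, weight_schemes = "unit")))
  splits <- make_splits(names(ds$ensembles), k = 3, repeats = 2, seed = 5)
  res <- evaluate_cell(ds, mats, "mean", model_spec("lm"), splits, seed = 9)
  expect_equal(nrow(res), 6L)
  expect_true(all(res$rmse >= res$mae - 1e-12))
  preds <- attr(res, "predictions")
  expect_equal(nrow(preds), 24L)   # each compound predicted once per repeat

  # identical rerun
  res2 <- evaluate_cell(ds, mats, "mean", model_spec("lm"), splits, seed = 9)
  expect_equal(res$mae, res2$mae, tolerance = 1e-12)

  # identical conformer rows at test time: pooled prediction equals the
  # single-instance prediction
  X_train <- do.call(rbind, lapply(names(ds$ensembles)[1:8], function(id) {
    colMeans(mats[[id]])
  }))
  y_train <- dataset_values(ds)[1:8]
  row <- mats[[10]][1, , drop = FALSE]
  trip <- row[rep(1, 3), , drop = FALSE]
  p <- fit_predict(model_spec("rf"), X_train, y_train, rbind(row, trip),
                   seed = 3)
  expect_equal(pool_bag_predictions(p[2:4]), p[1], tolerance = 1e-12)

  # LOOCV summarization pools predictions
  loo <- make_splits(names(ds$ensembles), "loocv")
  res_loo <- evaluate_cell(ds, mats, "mean", model_spec("lm"), loo, seed = 9)
  expect_true(all(is.na(res_loo$r2)))
  sm <- summarize_eval(res_loo)
  expect_equal(sm$n, 12L)
  expect_true(is.finite(sm$r2))
})
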