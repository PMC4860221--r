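# Classifiers, fold metrics and cross-validation mechanics.

toy_table <- function(n = 200, margin = 1, seed = 5, p = 2) {
  # linearly separable two-feature toy with the given margin
  set.seed(seed)
  lab <- rep(c("PLM", "non-PLM"), length.out = n)
  shift <- ifelse(lab == "PLM", margin, -margin)
  ft <- data.frame(patient_id = "P", epoch_index = seq_len(n) - 1L,
                   label = lab, check.names = FALSE)
  ft[["f1"]] <- shift + rnorm(n, sd = 0.2)
  for (j in seq_len(p - 1))
    ft[[paste0("f", j + 1)]] <- rnorm(n)
  class(ft) <- c("feature_table", "data.frame")
  ft
}

test_that("model specs default to the published hyperparameters", {
  expect_equal(model_spec("knn")$k, 1L)
  expect_equal(model_spec("random_forest")$n_trees, 100L)
  m <- model_spec("mlp")
  expect_equal(m[c("hidden", "learning_rate", "momentum", "iterations")],
               list(hidden = 42L, learning_rate = 0.3, momentum = 0.2,
                    iterations = 500L))
  expect_equal(model_spec("logistic_regression")$ridge, 1e-8)
  expect_error(model_spec("knn", trees = 5), "unknown hyperparameter")
})

test_that("1-NN returns its training labels with hard probabilities", {
  ft <- toy_table(60)
  m <- train_model(model_spec("knn"), ft)
  pr <- predict_model(m, ft)
  expect_identical(as.character(pr$labels), ft$label)
  expect_true(all(pr$probabilities %in% c(0, 1)))
  expect_equal(rowSums(pr$probabilities), rep(1, 60))
})

test_that("random forest probabilities are tree-vote fractions", {
  ft <- toy_table(80)
  set.seed(6)
  m <- train_model(model_spec("random_forest", n_trees = 5L), ft)
  pr <- predict_model(m, ft)
  # with 5 trees every probability is a multiple of 1/5
  expect_true(all(abs(pr$probabilities * 5 - round(pr$probabilities * 5)) < 1e-9))
  expect_equal(unname(rowSums(pr$probabilities)), rep(1, 80), tolerance = 1e-9)
})

test_that("the MLP learns a separable toy and the ridge keeps LR finite", {
  ft <- toy_table(200, margin = 1)
  set.seed(7)
  m <- train_model(model_spec("mlp", iterations = 100L), ft)
  pr <- predict_model(m, ft)
  expect_gte(mean(pr$labels == ft$label), 0.99)

  # logistic regression with duplicated (collinear) columns stays finite
  ft2 <- toy_table(100)
  ft2[["f1_dup"]] <- ft2[["f1"]]
  m2 <- train_model(model_spec("logistic_regression"), ft2)
  expect_true(all(is.finite(m2$fit)))
  pr2 <- predict_model(m2, ft2)
  expect_gte(mean(pr2$labels == ft2$label), 0.95)
  expect_equal(rowSums(pr2$probabilities), rep(1, 100), tolerance = 1e-9)

  # single-class training is an error
  ft1 <- toy_table(40)
  ft1$label <- "PLM"
  expect_error(train_model(model_spec("knn"), ft1), "single class")
  # column mismatch is a named error
  ftx <- toy_table(40, p = 3)
  expect_error(predict_model(train_model(model_spec("knn"), toy_table(40)), ftx),
               "match")
})

test_that("confusion matrix and metrics follow the stated conventions", {
  actual <- factor(rep(c("PLM", "non-PLM"), c(6, 4)))
  predicted <- factor(c(rep("PLM", 5), "non-PLM", rep("non-PLM", 3), "PLM"))
  fr <- confusion_and_metrics(actual, predicted)
  expect_equal(unname(fr$confusion["PLM", "PLM"]), 5)
  expect_equal(unname(fr$confusion["non-PLM", "PLM"]), 1)
  expect_equal(fr$accuracy, 0.8)

  # perfect hard predictions
  fr2 <- confusion_and_metrics(actual, actual)
  expect_equal(fr2$accuracy, 1)
  expect_equal(fr2$rmse, 0)

  # constant p = 0.5 for both classes gives RMSE 0.5 for any labels
  probs <- matrix(0.5, 10, 2, dimnames = list(NULL, levels(actual)))
  fr3 <- confusion_and_metrics(actual, predicted, probs)
  expect_equal(fr3$rmse, 0.5)
  expect_error(confusion_and_metrics(factor(), factor()), "empty")
})

test_that("cross-validation partitions rows into near-equal stratified folds", {
  ft <- toy_table(9286 %/% 10, margin = 2)  # small but uneven size
  rep_out <- cross_validate(ft, model_spec("knn"), k = 10, repeats = 2, seed = 3)
  folds <- rep_out$folds
  expect_identical(nrow(folds), 20L)
  # fold sizes within 1 of each other and summing to n per repeat
  for (r in 1:2) {
    sz <- folds$n[folds$rep == r]
    expect_equal(sum(sz), nrow(ft))
    expect_lte(diff(range(sz)), 1)
  }
  # stratification: per-fold class counts within 1 of balance
  cls1 <- folds$pred1_act1 + folds$pred2_act1
  cls2 <- folds$pred1_act2 + folds$pred2_act2
  expect_true(all(abs(cls1 - cls2) <= 1))
  # summary aggregates the folds
  expect_equal(rep_out$summary$mean_accuracy, mean(folds$accuracy))

  # n = 9286 rows at k = 10 gives fold sizes 929 / 928
  y <- factor(rep(c("a", "b"), c(4602, 4684)))
  set.seed(8)
  fold <- plmdetect:::stratified_folds(y, 10)
  expect_true(all(table(fold) %in% c(928L, 929L)))
  expect_equal(sum(table(fold)), 9286)

  expect_error(cross_validate(toy_table(12), model_spec("knn"), k = 10),
               "fewer than k")
})

test_that("cross-validation is deterministic given the seed", {
  ft <- toy_table(120)
  specs <- list(model_spec("knn"), model_spec("logistic_regression"),
                model_spec("mlp", iterations = 5L),
                model_spec("random_forest", n_trees = 10L))
  r1 <- cross_validate(ft, specs, k = 5, repeats = 1, seed = 9)
  r2 <- cross_validate(ft, specs, k = 5, repeats = 1, seed = 9)
  expect_identical(r1$folds, r2$folds)
  r3 <- cross_validate(ft, specs, k = 5, repeats = 1, seed = 10)
  expect_false(identical(r1$folds$accuracy, r3$folds$accuracy))
})
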