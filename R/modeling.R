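# The four classifiers with their published default hyperparameters, and
# repeated stratified k-fold cross-validation reporting confusion
# matrices, accuracy and probabilistic RMSE.
#
# k-NN uses class::knn and random forest uses randomForest behind this
# module's surface. The multilayer perceptron (per-sample stochastic
# gradient descent with momentum, sigmoid activations) and the
# ridge-penalized logistic regression (IRLS) are implemented here so the
# published hyperparameters (learning rate/momentum/iterations; ridge on
# raw coefficients) apply exactly as printed.

#' Classifier specification
#'
#' Defaults are the published values: k-NN with `K = 1` and Euclidean
#' distance on min-max normalized features; random forest with 100
#' trees; a 1-hidden-layer MLP with 42 sigmoid units, learning rate 0.3,
#' momentum 0.2 and 500 training iterations; logistic regression with
#' ridge penalty 1e-8.
#'
#' @param kind One of `"knn"`, `"random_forest"`, `"mlp"`,
#'   `"logistic_regression"`.
#' @param ... Hyperparameter overrides: `k` (knn); `n_trees`
#'   (random_forest); `hidden`, `learning_rate`, `momentum`, `iterations`
#'   (mlp); `ridge`, `max_iter` (logistic_regression).
#' @return A list of class `model_spec`.
#' @export
model_spec <- function(kind = c("knn", "random_forest", "mlp",
                                "logistic_regression"), ...) {
  kind <- match.arg(kind)
  defaults <- switch(kind,
    knn = list(k = 1L),
    random_forest = list(n_trees = 100L),
    mlp = list(hidden = 42L, learning_rate = 0.3, momentum = 0.2,
               iterations = 500L),
    logistic_regression = list(ridge = 1e-8, max_iter = 50L))
  over <- list(...)
  bad <- setdiff(names(over), names(defaults))
  if (length(bad))
    stop("unknown hyperparameter(s) for ", kind, ": ",
         paste(bad, collapse = ", "), call. = FALSE)
  defaults[names(over)] <- over
  structure(c(list(kind = kind), defaults), class = "model_spec")
}

# min-max normalization fitted on training data; constant columns map to 0
fit_minmax <- function(X) {
  lo <- apply(X, 2L, min); hi <- apply(X, 2L, max)
  span <- hi - lo
  span[span == 0] <- 1
  list(lo = lo, span = span)
}
apply_minmax <- function(X, mm) sweep(sweep(X, 2L, mm$lo), 2L, mm$span, "/")

prepare_xy <- function(feature_table) {
  X <- feature_matrix(feature_table)
  med <- apply(X, 2L, stats::median, na.rm = TRUE)
  med[is.na(med)] <- 0
  for (j in seq_len(ncol(X))) X[is.na(X[, j]), j] <- med[j]
  y <- factor(feature_table$label)
  list(X = X, y = y, medians = med)
}

sigmoid <- function(z) 1 / (1 + exp(-z))

mlp_fit <- function(X, y01, spec) {
  d <- ncol(X); h <- spec$hidden
  W1 <- matrix(stats::runif(h * d, -0.3, 0.3), h, d)
  b1 <- stats::runif(h, -0.3, 0.3)
  w2 <- stats::runif(h, -0.3, 0.3)
  b2 <- stats::runif(1, -0.3, 0.3)
  vW1 <- matrix(0, h, d); vb1 <- numeric(h); vw2 <- numeric(h); vb2 <- 0
  lr <- spec$learning_rate; mom <- spec$momentum
  n <- nrow(X)
  for (it in seq_len(spec$iterations)) {
    for (i in sample.int(n)) {
      x <- X[i, ]
      hid <- sigmoid(W1 %*% x + b1)
      out <- sigmoid(sum(w2 * hid) + b2)
      # squared-error loss, sigmoid derivatives
      d_out <- (out - y01[i]) * out * (1 - out)
      d_hid <- (w2 * d_out) * hid * (1 - hid)
      vw2 <- mom * vw2 - lr * d_out * as.numeric(hid)
      vb2 <- mom * vb2 - lr * d_out
      vW1 <- mom * vW1 - lr * (d_hid %*% t(x))
      vb1 <- mom * vb1 - lr * as.numeric(d_hid)
      w2 <- w2 + vw2; b2 <- b2 + vb2; W1 <- W1 + vW1; b1 <- b1 + vb1
    }
  }
  list(W1 = W1, b1 = b1, w2 = w2, b2 = b2)
}

mlp_prob <- function(fit, X) {
  H <- sigmoid(fit$W1 %*% t(X) + fit$b1)
  as.numeric(sigmoid(colSums(fit$w2 * H) + fit$b2))
}

logistic_fit <- function(X, y01, ridge, max_iter) {
  Xd <- cbind(`(Intercept)` = 1, X)
  p <- ncol(Xd)
  beta <- numeric(p)
  pen <- diag(c(0, rep(2 * ridge, p - 1L)))  # intercept unpenalized
  dev_old <- Inf
  for (it in seq_len(max_iter)) {
    eta <- as.numeric(Xd %*% beta)
    mu <- sigmoid(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    grad <- crossprod(Xd, y01 - mu) - pen %*% beta
    hess <- crossprod(Xd * w, Xd) + pen
    # rank-deficient systems (constant columns, p >= n folds): escalate a
    # scale-aware ridge until the Newton system solves
    step <- NULL
    for (lam in c(0, 1e-12, 1e-9, 1e-6, 1e-3) * max(diag(hess))) {
      step <- tryCatch(solve(hess + diag(lam, p), grad),
                       error = function(e) NULL)
      if (!is.null(step)) break
    }
    if (is.null(step)) stop("IRLS system is singular", call. = FALSE)
    beta <- beta + as.numeric(step)
    dev <- -2 * sum(y01 * log(pmax(mu, 1e-12)) +
                      (1 - y01) * log(pmax(1 - mu, 1e-12)))
    if (abs(dev_old - dev) < 1e-8) break
    dev_old <- dev
  }
  beta
}

#' Train a classifier
#'
#' Missing feature values are imputed with the training-set median. For
#' k-NN and the MLP, features are min-max normalized to \[0, 1\] with
#' parameters fitted on the training set only.
#'
#' @param spec A [model_spec()].
#' @param feature_table Labelled training [extract_feature_table()]
#'   result (>= 2 classes).
#' @return An object of class `plm_model` whose [predict_model()] output
#'   gives class probabilities for both classes.
#' @export
train_model <- function(spec, feature_table) {
  stopifnot(inherits(spec, "model_spec"))
  xy <- prepare_xy(feature_table)
  if (nlevels(xy$y) < 2L)
    stop("training set contains a single class: ", levels(xy$y), call. = FALSE)
  model <- list(spec = spec, levels = levels(xy$y), medians = xy$medians,
                features = colnames(xy$X))
  y01 <- as.integer(xy$y == levels(xy$y)[2L])
  if (spec$kind %in% c("knn", "mlp")) {
    model$minmax <- fit_minmax(xy$X)
    Xn <- apply_minmax(xy$X, model$minmax)
  }
  model$fit <- switch(spec$kind,
    knn = list(X = Xn, y = xy$y),
    random_forest = randomForest::randomForest(x = xy$X, y = xy$y,
                                               ntree = spec$n_trees),
    mlp = mlp_fit(Xn, y01, spec),
    logistic_regression = logistic_fit(xy$X, y01, spec$ridge, spec$max_iter))
  class(model) <- "plm_model"
  model
}

#' Predict class labels and probabilities
#'
#' @param model A [train_model()] result.
#' @param feature_table Feature table with the same attribute columns as
#'   the training table.
#' @return List with `labels` (factor) and `probabilities` (matrix with
#'   one column per class, rows summing to 1).
#' @export
predict_model <- function(model, feature_table) {
  stopifnot(inherits(model, "plm_model"))
  X <- feature_matrix(feature_table)
  miss <- setdiff(model$features, colnames(X))
  extra <- setdiff(colnames(X), model$features)
  if (length(miss) || length(extra))
    stop("feature columns do not match training registry",
         if (length(miss)) paste0("; missing: ", paste(utils::head(miss, 5), collapse = ", ")),
         if (length(extra)) paste0("; unexpected: ", paste(utils::head(extra, 5), collapse = ", ")),
         call. = FALSE)
  X <- X[, model$features, drop = FALSE]
  for (j in seq_len(ncol(X))) X[is.na(X[, j]), j] <- model$medians[j]
  spec <- model$spec
  p2 <- switch(spec$kind,
    knn = {
      Xn <- apply_minmax(X, model$minmax)
      pred <- class::knn(model$fit$X, Xn, model$fit$y, k = spec$k, prob = TRUE)
      win <- attr(pred, "prob")
      ifelse(pred == model$levels[2L], win, 1 - win)
    },
    random_forest = stats::predict(model$fit, X, type = "prob")[, model$levels[2L]],
    mlp = mlp_prob(model$fit, apply_minmax(X, model$minmax)),
    logistic_regression = sigmoid(as.numeric(cbind(1, X) %*% model$fit)))
  probs <- cbind(1 - p2, p2)
  colnames(probs) <- model$levels
  labels <- factor(model$levels[1L + (p2 >= 0.5)], levels = model$levels)
  list(labels = labels, probabilities = probs)
}

#' Confusion matrix, accuracy and probabilistic RMSE for one fold
#'
#' The confusion matrix follows the convention that columns are actual
#' classes and rows are predicted classes. RMSE is the probabilistic
#' form: `sqrt(mean over instances and classes of (p - y)^2)` with `y`
#' the one-hot truth.
#'
#' @param actual Factor (or vector) of true labels.
#' @param predicted Factor (or vector) of predicted labels.
#' @param probabilities Optional matrix of class probabilities (columns
#'   named by class); if omitted, hard 0/1 probabilities are used.
#' @return List of class `fold_result`: `confusion` (2x2, rows
#'   predicted), `accuracy`, `rmse`, `n`.
#' @export
confusion_and_metrics <- function(actual, predicted, probabilities = NULL) {
  if (length(actual) == 0L) stop("empty input", call. = FALSE)
  if (length(actual) != length(predicted))
    stop("actual and predicted differ in length", call. = FALSE)
  lev <- levels(factor(actual))
  actual <- factor(actual, levels = lev)
  predicted <- factor(predicted, levels = lev)
  cm <- table(predicted = predicted, actual = actual)
  acc <- sum(diag(cm)) / sum(cm)
  if (is.null(probabilities)) {
    probabilities <- outer(as.character(predicted), lev, `==`) * 1
    colnames(probabilities) <- lev
  }
  onehot <- outer(as.character(actual), colnames(probabilities), `==`) * 1
  rmse <- sqrt(mean((probabilities - onehot)^2))
  structure(list(confusion = cm, accuracy = acc, rmse = rmse,
                 n = length(actual)), class = "fold_result")
}

# Stratified fold ids: within each class, shuffle then deal round-robin.
# The deal offset rotates across classes so remainder epochs spread over
# different folds, keeping per-fold class counts within 1 AND total fold
# sizes within 1 (e.g. 9286 rows at k = 10 gives folds of 929 and 928).
stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  offset <- 0L
  for (cl in levels(y)) {
    idx <- which(y == cl)
    n <- length(idx)
    ids <- ((seq_len(n) - 1L + offset) %% k) + 1L
    fold[idx[sample.int(n)]] <- ids
    offset <- (offset + n %% k) %% k
  }
  fold
}

#' Repeated stratified k-fold cross-validation
#'
#' For each repeat, a fresh stratified partition is drawn (from `seed`);
#' each fold serves once as the test set while the other `k - 1` train.
#' Per-fold confusion matrices, accuracy and probabilistic RMSE are
#' collected, with per-model mean and standard deviation over all folds
#' and repeats.
#'
#' @param feature_table Labelled feature table (>= k rows per class).
#' @param specs List of [model_spec()]s (a single spec is accepted).
#' @param k Number of folds (default 10).
#' @param repeats Number of repetitions (default 10).
#' @param seed Integer seed; the full report is reproducible from it.
#' @return List of class `cv_report`: `folds` (one row per model, repeat
#'   and fold with confusion counts, accuracy, RMSE) and `summary` (mean
#'   and sd per model).
#' @export
cross_validate <- function(feature_table, specs, k = 10, repeats = 10, seed = 1) {
  if (inherits(specs, "model_spec")) specs <- list(specs)
  y <- factor(feature_table$label)
  if (nlevels(y) < 2L) stop("need two classes for cross-validation", call. = FALSE)
  if (min(table(y)) < k)
    stop("fewer than k = ", k, " rows in the smallest class", call. = FALSE)
  rows <- list()
  with_seed(seed, {
    for (r in seq_len(repeats)) {
      fold <- stratified_folds(y, k)
      for (spec in specs) {
        for (f in seq_len(k)) {
          train <- feature_table[fold != f, , drop = FALSE]
          test <- feature_table[fold == f, , drop = FALSE]
          model <- train_model(spec, train)
          pr <- predict_model(model, test)
          fr <- confusion_and_metrics(factor(test$label, levels = levels(y)),
                                      pr$labels, pr$probabilities)
          cm <- fr$confusion
          rows[[length(rows) + 1L]] <- data.frame(
            model = spec$kind, rep = r, fold = f,
            n = fr$n,
            pred1_act1 = cm[1, 1], pred1_act2 = cm[1, 2],
            pred2_act1 = cm[2, 1], pred2_act2 = cm[2, 2],
            accuracy = fr$accuracy, rmse = fr$rmse,
            stringsAsFactors = FALSE)
        }
      }
    }
  })
  folds <- do.call(rbind, rows)
  summary <- do.call(rbind, lapply(split(folds, folds$model), function(d)
    data.frame(model = d$model[1],
               mean_accuracy = mean(d$accuracy), sd_accuracy = stats::sd(d$accuracy),
               mean_rmse = mean(d$rmse), sd_rmse = stats::sd(d$rmse),
               stringsAsFactors = FALSE)))
  rownames(summary) <- NULL
  structure(list(folds = folds, summary = summary, k = k, repeats = repeats,
                 classes = levels(y)),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %d-fold x %d repeats, classes: %s\n",
              x$k, x$repeats, paste(x$classes, collapse = " / ")))
  s <- x$summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-20s accuracy %.4f +/- %.4f   RMSE %.4f +/- %.4f\n",
                s$model[i], s$mean_accuracy[i], s$sd_accuracy[i],
                s$mean_rmse[i], s$sd_rmse[i]))
  invisible(x)
}
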