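#' Train a melanoma / other nucleus classifier
#'
#' Fits one of three supervised learners with a calibrated melanoma-class
#' probability output:
#' * `"svm"` — radial-kernel support vector machine; probabilities by
#'   logistic (Platt-style) calibration of the decision values, fitted on
#'   the training margins. This keeps training fully deterministic.
#' * `"random_forest"` — probability = fraction of tree votes.
#' * `"naive_bayes"` — Gaussian naive Bayes posterior.
#'
#' @param data a `cell_dataset` with at least 2 rows per class.
#' @param algorithm one of `"svm"`, `"random_forest"`, `"naive_bayes"`.
#' @param hyperparams named list overriding defaults (`cost`, `gamma`
#'   for SVM; `ntree` for the forest).
#' @param seed integer seed (drives the forest's bootstrap).
#' @param transform optional `feature_transform` stored with the model and
#'   applied automatically inside [quantify_image()].
#' @return a `cell_classifier`.
#' @export
train_classifier <- function(data, algorithm = c("svm", "random_forest",
                                                 "naive_bayes"),
                             hyperparams = list(), seed = 1,
                             transform = NULL) {
  algorithm <- match.arg(algorithm)
  tab <- table(data$y)
  if (any(tab < 2)) stop("training requires at least 2 rows per class")
  if (all(apply(data$x, 2, function(c) max(c) == min(c)))) {
    stop("degenerate training data: all features constant")
  }
  p <- ncol(data$x)
  fit <- calib <- NULL
  if (algorithm == "svm") {
    cost <- hyperparams$cost %||% 1
    gamma <- hyperparams$gamma %||% (1 / p)
    fit <- e1071::svm(data$x, data$y, kernel = "radial", cost = cost,
                      gamma = gamma, scale = FALSE)
    dva <- attr(predict(fit, data$x, decision.values = TRUE),
                "decision.values")
    dv <- dva[, 1]
    sgn <- if (grepl("^melanoma", colnames(dva)[1])) 1 else -1
    y01 <- as.integer(data$y == "melanoma")
    calib <- suppressWarnings(
      stats::glm(y01 ~ d, data = data.frame(d = sgn * dv),
                 family = stats::binomial()))
    calib <- list(sign = sgn, coef = unname(stats::coef(calib)))
  } else if (algorithm == "random_forest") {
    ntree <- hyperparams$ntree %||% 100
    fit <- with_seed(seed, randomForest::randomForest(data$x, data$y,
                                                      ntree = ntree))
  } else {
    fit <- e1071::naiveBayes(data$x, data$y)
  }
  structure(list(
    algorithm = algorithm,
    fit = fit,
    calibration = calib,
    features = colnames(data$x),
    transform = transform,
    hyperparams = hyperparams,
    seed = seed,
    n_train = nrow(data$x),
    class_counts = as.list(tab)
  ), class = "cell_classifier")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Melanoma-class probability predictions
#'
#' @param model a `cell_classifier`.
#' @param x numeric matrix (or `cell_dataset`) whose columns must match the
#'   training feature set exactly.
#' @return numeric vector of melanoma probabilities in `[0, 1]`.
#' @export
predict_prob <- function(model, x) {
  if (inherits(x, "cell_dataset")) x <- x$x
  x <- as.matrix(x)
  if (!identical(colnames(x), model$features)) {
    stop("feature set does not match the training feature set")
  }
  if (model$algorithm == "svm") {
    dv <- attr(predict(model$fit, x, decision.values = TRUE),
               "decision.values")[, 1]
    z <- model$calibration$coef[1] +
      model$calibration$coef[2] * model$calibration$sign * dv
    stats::plogis(z)
  } else if (model$algorithm == "random_forest") {
    unname(predict(model$fit, x, type = "prob")[, "melanoma"])
  } else {
    unname(predict(model$fit, x, type = "raw")[, "melanoma"])
  }
}

#' Evaluate a classifier on a labelled dataset
#'
#' Thresholds the melanoma probability (inclusive: probability equal to the
#' threshold predicts melanoma) and reports the confusion matrix and the
#' standard metrics with melanoma as the positive class; ROC area is
#' computed threshold-free from the probabilities.
#'
#' @param model a `cell_classifier`.
#' @param data a `cell_dataset`.
#' @param threshold probability cutoff (default 0.5).
#' @param average `"positive"` reports melanoma-as-positive metrics;
#'   `"weighted"` averages the per-class one-vs-rest metrics weighted by
#'   class support.
#' @return an `eval_report` list: `confusion` (2x2), `tp_rate`, `fp_rate`,
#'   `precision`, `recall`, `f_measure`, `accuracy`, `roc_auc`
#'   (NA + `auc_undefined` flag for single-class data), `threshold`.
#' @export
evaluate_classifier <- function(model, data, threshold = 0.5,
                                average = c("positive", "weighted")) {
  average <- match.arg(average)
  prob <- predict_prob(model, data)
  pred <- factor(ifelse(prob >= threshold, "melanoma", "other"),
                 levels = c("melanoma", "other"))
  cm <- table(truth = data$y, predicted = pred)
  metrics_of <- function(pos) {
    neg <- setdiff(c("melanoma", "other"), pos)
    tp <- cm[pos, pos]; fn <- cm[pos, neg]
    fp <- cm[neg, pos]; tn <- cm[neg, neg]
    tpr <- if (tp + fn > 0) tp / (tp + fn) else 0
    fpr <- if (fp + tn > 0) fp / (fp + tn) else 0
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    f <- if (prec + tpr > 0) 2 * prec * tpr / (prec + tpr) else 0
    c(tp_rate = tpr, fp_rate = fpr, precision = prec, recall = tpr,
      f_measure = f)
  }
  if (average == "positive") {
    m <- metrics_of("melanoma")
  } else {
    w <- as.numeric(table(data$y)) / length(data$y)
    m <- w[1] * metrics_of("melanoma") + w[2] * metrics_of("other")
  }
  pos <- data$y == "melanoma"
  auc <- auc_score(prob, pos)
  out <- c(as.list(m), list(
    accuracy = mean(pred == data$y),
    roc_auc = auc,
    auc_undefined = is.na(auc),
    confusion = cm,
    threshold = threshold,
    probabilities = prob
  ))
  class(out) <- "eval_report"
  out
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(paste0("TP rate %.3f | FP rate %.3f | precision %.3f | ",
                     "recall %.3f | F %.3f | accuracy %.3f | AUC %s\n"),
              x$tp_rate, x$fp_rate, x$precision, x$recall, x$f_measure,
              x$accuracy,
              if (x$auc_undefined) "NA" else sprintf("%.3f", x$roc_auc)))
  invisible(x)
}

#' ROC points from a probability-threshold sweep
#'
#' Varies the decision threshold on the melanoma probability over a grid
#' and records (FP rate, TP rate) at each; the reported AUC is the
#' threshold-free rank AUC of the probabilities.
#'
#' @param model a `cell_classifier`.
#' @param data a `cell_dataset` with both classes.
#' @param grid probability thresholds.
#' @return list with `points` (data frame `threshold`, `fp_rate`,
#'   `tp_rate`) and `auc`.
#' @export
threshold_sweep <- function(model, data, grid = seq(0, 1, by = 0.01)) {
  prob <- predict_prob(model, data)
  pos <- data$y == "melanoma"
  pts <- data.frame(
    threshold = grid,
    fp_rate = vapply(grid, function(t) mean(prob[!pos] >= t), 0),
    tp_rate = vapply(grid, function(t) mean(prob[pos] >= t), 0)
  )
  list(points = pts, auc = auc_score(prob, pos))
}

#' Train and evaluate several algorithms on identical inputs
#'
#' @param train,internal_test,external `cell_dataset`s (shared feature
#'   catalogue and standardization).
#' @param algorithms character vector of [train_classifier()] algorithms.
#' @param seed integer seed.
#' @return list per algorithm: `model` plus `eval_report`s `internal` and
#'   `external`; also `summary` data frame of headline metrics.
#' @export
compare_algorithms <- function(train, internal_test, external,
                               algorithms = c("svm", "random_forest",
                                              "naive_bayes"),
                               seed = 1) {
  out <- list()
  rows <- list()
  for (alg in algorithms) {
    model <- train_classifier(train, alg, seed = derive_seed(seed, alg))
    rin <- evaluate_classifier(model, internal_test)
    rex <- evaluate_classifier(model, external)
    out[[alg]] <- list(model = model, internal = rin, external = rex)
    rows[[alg]] <- data.frame(
      algorithm = alg,
      acc_internal = rin$accuracy, auc_internal = rin$roc_auc,
      acc_external = rex$accuracy, auc_external = rex$roc_auc)
  }
  out$summary <- do.call(rbind, rows)
  rownames(out$summary) <- NULL
  out
}
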