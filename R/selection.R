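#' Area under the ROC curve of a score
#'
#' Threshold-free AUC via the rank (Mann-Whitney) formulation with midrank
#' tie handling; equals the probability that a random positive scores above
#' a random negative (ties counting one half).
#'
#' @param scores numeric vector.
#' @param positive logical vector, `TRUE` for the positive class.
#' @return AUC in `[0, 1]`; `NA` when a class is absent.
#' @export
auc_score <- function(scores, positive) {
  n1 <- sum(positive); n2 <- sum(!positive)
  if (n1 == 0 || n2 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

#' Rank features by two-sample t-test on a subsample
#'
#' Draws a class-stratified subsample without replacement (to avoid the
#' high significance that trivial mean differences attain at full sample
#' size), applies Welch's two-sample t-test to every feature and orders
#' features by ascending p-value; ties break on descending `|t|` then
#' feature name. Features with zero variance in both classes get p = 1 and
#' rank last.
#'
#' @param data a `cell_dataset` with both classes present.
#' @param subsample_fraction proportion of rows tested (default 0.05).
#' @param seed integer seed for the subsample draw.
#' @return a `feature_ranking` data frame: `feature`, `t`, `p_value`,
#'   `rank`, ordered most-significant first; attributes record the
#'   subsample size and seed.
#' @export
rank_features <- function(data, subsample_fraction = 0.05, seed = 1) {
  stopifnot(subsample_fraction > 0, subsample_fraction <= 1)
  idx <- with_seed(seed, {
    unlist(lapply(levels(data$y), function(l) {
      cls <- which(data$y == l)
      n <- max(2L, round(subsample_fraction * length(cls)))
      if (length(cls) > n) sample(cls, n) else cls
    }))
  })
  x <- data$x[idx, , drop = FALSE]
  y <- data$y[idx]
  a <- x[y == "melanoma", , drop = FALSE]
  b <- x[y == "other", , drop = FALSE]
  if (nrow(a) < 2 || nrow(b) < 2) stop("subsample lost a class; increase the fraction")
  m1 <- colMeans(a); m2 <- colMeans(b)
  v1 <- apply(a, 2, var); v2 <- apply(b, 2, var)
  n1 <- nrow(a); n2 <- nrow(b)
  se2 <- v1 / n1 + v2 / n2
  tt <- ifelse(se2 > 0, (m1 - m2) / sqrt(se2), 0)
  df <- ifelse(se2 > 0,
               se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1)), 1)
  p <- ifelse(se2 > 0, 2 * stats::pt(-abs(tt), df), 1)
  ord <- order(p, -abs(tt), colnames(x))
  out <- data.frame(feature = colnames(x)[ord], t = tt[ord],
                    p_value = p[ord], rank = seq_along(ord),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "subsample_size") <- length(idx)
  attr(out, "seed") <- seed
  class(out) <- c("feature_ranking", class(out))
  out
}

#' Backward feature elimination with an SVM accuracy trace
#'
#' Starting from the full ranked feature set, the least significant
#' feature(s) are removed one step at a time; after each removal an SVM is
#' refit on the training set and its accuracy recorded on the internal test
#' set and on the external validation set, down to a single feature.
#'
#' @param train,internal_test,external `cell_dataset`s sharing the feature
#'   catalogue.
#' @param ranking a [rank_features()] result covering all features.
#' @param step features removed per iteration (default 1).
#' @param cost,gamma SVM hyperparameters (`gamma = NULL` uses 1/k at k
#'   retained features).
#' @return a `selection_trace` data frame: `n_features`, `acc_internal`,
#'   `acc_external`, most-features first.
#' @export
backward_elimination <- function(train, internal_test, external, ranking,
                                 step = 1L, cost = 1, gamma = NULL) {
  feats <- ranking$feature
  stopifnot(setequal(feats, colnames(train$x)))
  counts <- seq(length(feats), 1L, by = -as.integer(step))
  if (counts[length(counts)] != 1L) counts <- c(counts, 1L)
  res <- data.frame(n_features = counts, acc_internal = NA_real_,
                    acc_external = NA_real_)
  for (i in seq_along(counts)) {
    k <- counts[i]
    sub <- feats[seq_len(k)]
    g <- if (is.null(gamma)) 1 / k else gamma
    fit <- e1071::svm(train$x[, sub, drop = FALSE], train$y,
                      kernel = "radial", cost = cost, gamma = g,
                      scale = FALSE)
    pin <- predict(fit, internal_test$x[, sub, drop = FALSE])
    pex <- predict(fit, external$x[, sub, drop = FALSE])
    res$acc_internal[i] <- mean(pin == internal_test$y)
    res$acc_external[i] <- mean(pex == external$y)
  }
  class(res) <- c("selection_trace", class(res))
  res
}

#' Optimal feature count from a cubic fit of the accuracy curve
#'
#' Fits a least-squares cubic polynomial to external-validation accuracy as
#' a function of retained feature count and returns the integer count in
#' the observed range that maximises the fitted curve. With fewer than four
#' trace points the empirical argmax is returned and flagged.
#'
#' @param trace a `selection_trace` from [backward_elimination()].
#' @param which accuracy column used (default `"acc_external"`).
#' @return list with `n_features`, `accuracy` (fitted value at the
#'   optimum), `coefficients` (cubic fit), `fallback` flag.
#' @export
fit_optimum <- function(trace, which = "acc_external") {
  k <- trace$n_features
  acc <- trace[[which]]
  if (length(k) < 4) {
    i <- which.max(acc)
    return(list(n_features = k[i], accuracy = acc[i],
                coefficients = NULL, fallback = TRUE))
  }
  fit <- stats::lm(acc ~ stats::poly(k, 3, raw = TRUE))
  grid <- seq(min(k), max(k))
  pred <- stats::predict(fit, newdata = data.frame(k = grid))
  i <- which.max(pred)
  list(n_features = grid[i], accuracy = unname(pred[i]),
       coefficients = unname(stats::coef(fit)), fallback = FALSE)
}

#' Univariate ROC analysis of selected features
#'
#' AUC of thresholding each feature alone, oriented so that AUC >= 0.5.
#' Constant features get AUC 0.5 and a flag.
#'
#' @param data a `cell_dataset` with both classes.
#' @param features character subset (default: all).
#' @return data frame `feature`, `auc`, `flipped`, `constant`, sorted by
#'   decreasing AUC.
#' @export
per_feature_roc <- function(data, features = NULL) {
  if (is.null(features)) features <- colnames(data$x)
  pos <- data$y == "melanoma"
  res <- lapply(features, function(f) {
    v <- data$x[, f]
    if (max(v) - min(v) <= .Machine$double.eps * max(1, abs(max(v)))) {
      return(data.frame(feature = f, auc = 0.5, flipped = FALSE,
                        constant = TRUE))
    }
    a <- auc_score(v, pos)
    data.frame(feature = f, auc = max(a, 1 - a), flipped = a < 0.5,
               constant = FALSE)
  })
  out <- do.call(rbind, res)
  out[order(-out$auc, out$feature), , drop = FALSE]
}
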