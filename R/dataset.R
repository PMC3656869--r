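#' Construct a labelled cell dataset
#'
#' Bundles a numeric feature matrix with a two-level class vector
#' (melanoma / other) and provenance metadata, the unit handed to class
#' balancing, splitting, standardization, feature selection and the
#' classifiers.
#'
#' @param x numeric matrix or data frame of features (rows = nuclei).
#' @param y factor (or coercible) with levels `c("melanoma", "other")`.
#' @param meta optional named list of provenance fields.
#' @return a `cell_dataset`.
#' @export
cell_dataset <- function(x, y, meta = list()) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- factor(as.character(y), levels = c("melanoma", "other"))
  stopifnot(nrow(x) == length(y), !anyNA(x), !anyNA(y))
  structure(list(x = x, y = y, meta = meta), class = "cell_dataset")
}

#' Build a cell dataset from feature tables
#'
#' @param tables one data frame (or a list of them) as produced by
#'   [extract_features()]; rows with `NA` class are dropped.
#' @param feature_names optional subset/order of feature columns (default:
#'   everything after the bookkeeping columns).
#' @return a `cell_dataset`.
#' @export
dataset_from_features <- function(tables, feature_names = NULL) {
  if (is.data.frame(tables)) tables <- list(tables)
  tab <- do.call(rbind, tables)
  tab <- tab[!is.na(tab$class), , drop = FALSE]
  if (is.null(feature_names)) {
    feature_names <- setdiff(colnames(tab),
                             c("image_id", "nucleus_id", "class",
                               "qc_degenerate", "truth_class"))
  }
  cell_dataset(tab[, feature_names, drop = FALSE], tab$class,
               meta = list(images = unique(tab$image_id),
                           n_input = nrow(tab)))
}

#' @export
print.cell_dataset <- function(x, ...) {
  cat(sprintf("Cell dataset: %d nuclei x %d features (%s)\n",
              nrow(x$x), ncol(x$x),
              paste(sprintf("%s=%d", levels(x$y), table(x$y)),
                    collapse = ", ")))
  invisible(x)
}

ds_subset <- function(ds, rows = NULL, features = NULL) {
  x <- ds$x
  y <- ds$y
  if (!is.null(rows)) { x <- x[rows, , drop = FALSE]; y <- y[rows] }
  if (!is.null(features)) x <- x[, features, drop = FALSE]
  structure(list(x = x, y = y, meta = ds$meta), class = "cell_dataset")
}

#' Downsample to equal class counts
#'
#' Each class is sampled without replacement down to the minority-class
#' count and the row order is shuffled, both deterministically from `seed`.
#'
#' @param data a `cell_dataset` containing both classes.
#' @param seed integer seed.
#' @param target_counts optional named vector (`melanoma`, `other`) of
#'   per-class target sizes, for reproducing near-equal rather than exactly
#'   equal balanced sets; targets are capped at the available counts.
#' @return balanced `cell_dataset`.
#' @export
balance_classes <- function(data, seed = 1, target_counts = NULL) {
  tab <- table(data$y)
  if (any(tab == 0)) stop("balancing requires both classes to be present")
  m <- min(tab)
  with_seed(seed, {
    keep <- unlist(lapply(levels(data$y), function(l) {
      idx <- which(data$y == l)
      target <- if (is.null(target_counts)) m else {
        min(target_counts[[l]], length(idx))
      }
      if (length(idx) > target) sample(idx, target) else idx
    }))
    keep <- sample(keep)
    out <- ds_subset(data, keep)
    out$meta$balance_seed <- seed
    out
  })
}

#' Stratified train/test split
#'
#' Splits by class stratum: `round(train_fraction * n_stratum)` rows per
#' class go to the training set, the remainder to the test set; the split
#' is an exact partition.
#'
#' @param data a `cell_dataset`.
#' @param train_fraction proportion in (0, 1) (default 0.665, with the
#'   complementary 0.335 forming the internal validation set).
#' @param seed integer seed.
#' @return list with `train` and `test` cell datasets.
#' @export
split_dataset <- function(data, train_fraction = 0.665, seed = 1) {
  stopifnot(train_fraction > 0, train_fraction < 1)
  with_seed(seed, {
    strata <- lapply(levels(data$y), function(l) which(data$y == l))
    ns <- lengths(strata)
    if (any(ns < 2)) stop("stratum with fewer than 2 rows cannot be split")
    # per-stratum sizes: floor, then distribute the remainder (largest
    # fractional part first) so the total equals round(fraction * n)
    target <- round(train_fraction * sum(ns))
    base <- floor(train_fraction * ns)
    rem <- order(train_fraction * ns - base, decreasing = TRUE)
    extra <- target - sum(base)
    if (extra > 0) base[rem[seq_len(extra)]] <- base[rem[seq_len(extra)]] + 1
    base <- pmin(pmax(base, 1L), ns - 1L)
    tr_idx <- unlist(lapply(seq_along(strata), function(i) {
      sample(strata[[i]], base[i])
    }))
    list(train = ds_subset(data, sort(tr_idx)),
         test = ds_subset(data, sort(setdiff(seq_along(data$y), tr_idx))))
  })
}

#' Fit a feature standardization on training data
#'
#' `"minmax"` rescales each column to `[0, 1]` (divided by the maximum
#' after shifting the minimum to 0); `"zscore"` centres and scales to unit
#' variance. Parameters are fitted on the training rows only and can then
#' be applied to any other dataset, so no information leaks from test data.
#' Zero-variance columns map to 0 and are flagged.
#'
#' @param train a `cell_dataset`.
#' @param method `"minmax"` or `"zscore"`.
#' @return a `feature_transform` list with `center`, `scale`, `constant`.
#' @export
fit_standardization <- function(train, method = c("minmax", "zscore")) {
  method <- match.arg(method)
  x <- train$x
  if (method == "minmax") {
    center <- apply(x, 2, min)
    scale <- apply(x, 2, max) - center
  } else {
    center <- colMeans(x)
    scale <- apply(x, 2, sd)
  }
  constant <- scale <= .Machine$double.eps * pmax(1, abs(center))
  scale[constant] <- 1
  structure(list(method = method, center = center, scale = scale,
                 constant = constant),
            class = "feature_transform")
}

#' Apply (or invert) a fitted standardization
#'
#' @param transform a `feature_transform` from [fit_standardization()].
#' @param data a `cell_dataset` or numeric matrix with matching columns.
#' @param inverse undo the transform.
#' @return object of the same type as `data`.
#' @export
apply_standardization <- function(transform, data, inverse = FALSE) {
  x <- if (inherits(data, "cell_dataset")) data$x else as.matrix(data)
  stopifnot(identical(colnames(x), names(transform$center)))
  if (!inverse) {
    x <- sweep(sweep(x, 2, transform$center, "-"), 2, transform$scale, "/")
    x[, transform$constant] <- 0
  } else {
    x <- sweep(sweep(x, 2, transform$scale, "*"), 2, transform$center, "+")
  }
  if (inherits(data, "cell_dataset")) {
    out <- data
    out$x <- x
    out
  } else {
    x
  }
}

#' Standardize train and further datasets without leakage
#'
#' Convenience wrapper: fits on `train` and applies the same parameters to
#' every dataset supplied.
#'
#' @param train a `cell_dataset`.
#' @param ... further `cell_dataset`s transformed with the train-fitted
#'   parameters.
#' @param method see [fit_standardization()].
#' @return list with `transform`, `train`, and the transformed `...`
#'   (named as supplied).
#' @export
standardize <- function(train, ..., method = c("minmax", "zscore")) {
  tf <- fit_standardization(train, method)
  rest <- lapply(list(...), function(d) apply_standardization(tf, d))
  c(list(transform = tf, train = apply_standardization(tf, train)), rest)
}
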